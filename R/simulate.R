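## Per-carbon bookkeeping for citrate. Positions 1..6:
##   1,2  acetyl-CoA-derived carbons
##   3..5 oxaloacetate-derived carbons (pyruvate-derived under PC anaplerosis)
##   6    the oxaloacetate-carboxyl / carboxylation-derived carbon --
##        the position the C5 fragment (273 m/z) lacks.
## Each routing pathway, under a given tracer, fixes a deterministic 0/1
## label pattern over the six positions; CO2 fixation flips position 6
## with probability f_fix under the bicarbonate tracer.

route_label_pattern <- function(route, tracer_name) {
  zero <- rep(0L, 6L)
  switch(route,
    f_ox_glc  = if (tracer_name == "U13C6_glucose")   c(1L,1L,0L,0L,0L,0L) else zero,
    f_ox_gln  = if (tracer_name == "U13C5_glutamine") c(0L,0L,1L,1L,1L,1L) else zero,
    f_red_gln = if (tracer_name == "U13C5_glutamine") c(1L,1L,1L,1L,1L,0L) else zero,
    f_pc      = if (tracer_name == "U13C6_glucose")   c(0L,0L,1L,1L,1L,0L) else zero,
    f_unlab   = zero,
    stop("unknown route: ", route, call. = FALSE)
  )
}

## Distribution over 6-position label patterns implied by a routing mixture
## and tracer: a list of (pattern, weight). Exported for oracle-style checks.
citrate_pattern_distribution <- function(fractions, tracer) {
  stopifnot(inherits(fractions, "routing_fractions"),
            inherits(tracer, "tracer_spec"))
  pats <- list(); wts <- numeric(0)
  add <- function(p, w) {
    if (w <= 0) return()
    pats[[length(pats) + 1L]] <<- p
    wts[length(wts) + 1L] <<- w
  }
  fix <- if (tracer$name == "C13_bicarbonate") fractions$f_fix else 0
  for (r in route_names) {
    w <- fractions[[r]]
    if (w <= 0) next
    base <- route_label_pattern(r, tracer$name)
    if (fix > 0) {
      unfixed <- base; unfixed[6] <- 0L
      fixed <- base; fixed[6] <- 1L
      add(unfixed, w * (1 - fix))
      add(fixed, w * fix)
    } else {
      add(base, w)
    }
  }
  list(patterns = pats, weights = wts)
}

#' Simulate citrate fragment mass isotopomer distributions
#'
#' Forward model of the single-turn citrate labelling experiment: each
#' carbon-routing pathway deposits tracer-derived 13C at fixed citrate
#' positions, and each GC-MS fragment reports the mass shift summed over the
#' positions it retains. The full-molecule fragments (375, 459 m/z) see all
#' six positions; the C5 fragment (273 m/z) lacks the
#' carboxylation-derived carboxyl carbon, so species labelled at that
#' position appear one shift lower. Under U-13C6-glucose the oxidative
#' glucose route yields m+2 and pyruvate-carboxylase anaplerosis m+3; under
#' U-13C5-glutamine the oxidative route yields m+4 (m+3 in the C5 fragment)
#' and reductive carboxylation m+5 (retained in full by the C5 fragment);
#' under 13C-bicarbonate CO2 fixation yields m+1 in full fragments and m+0
#' in the C5 fragment.
#'
#' @param fractions A [routing_fractions()] object.
#' @param tracer A [tracer_spec()] object.
#' @param fragments Fragment catalogue rows (default the full citrate
#'   catalogue); see [citrate_fragments()].
#' @return A named list (names = nominal m/z) of MID vectors over shifts
#'   m+0..m+k, each summing to 1. Tracer-derived label only: natural
#'   abundance is applied separately by [generate_intensity_table()].
#' @export
#' @examples
#' simulate_citrate_mids(routing_fractions(f_red_gln = 1),
#'                       tracer_spec("U13C5_glutamine"))
simulate_citrate_mids <- function(fractions, tracer,
                                  fragments = citrate_fragments()) {
  if (!inherits(fractions, "routing_fractions")) {
    stop("fractions must be a routing_fractions object", call. = FALSE)
  }
  if (!inherits(tracer, "tracer_spec")) {
    stop("tracer must be a tracer_spec object", call. = FALSE)
  }
  if (any(fragments$metabolite != "citrate")) {
    stop("simulate_citrate_mids only handles citrate fragments", call. = FALSE)
  }
  dist <- citrate_pattern_distribution(fractions, tracer)
  out <- vector("list", nrow(fragments))
  names(out) <- as.character(fragments$nominal_mz)
  for (i in seq_len(nrow(fragments))) {
    keep <- seq_len(6L)
    if (fragments$lost_carbon_position[i] != "none") keep <- 1:5
    n_c <- fragments$metabolite_carbons_retained[i]
    mid <- numeric(n_c + 1L)
    for (j in seq_along(dist$patterns)) {
      shift <- sum(dist$patterns[[j]][keep])
      mid[shift + 1L] <- mid[shift + 1L] + dist$weights[j]
    }
    out[[i]] <- as_mid(mid)
  }
  out
}

#' Convolve a MID with the natural 13C-abundance envelope
#'
#' Tracer-derived label and natural-abundance 13C combine additively in mass
#' shift: the measured MID is the tracer MID convolved with a binomial
#' envelope over all carbons in the derivatized fragment (metabolite carbons
#' retained plus derivatization-reagent carbons) at the natural 13C
#' probability. Only carbon isotopes are modelled.
#'
#' @param mid Tracer-derived MID vector.
#' @param n_carbons Total carbons in the derivatized fragment.
#' @param p13c Natural 13C abundance (default 0.0107). `p13c = 0` is the
#'   identity.
#' @return The convolved MID (length `length(mid) + n_carbons`).
#' @export
convolve_natural_abundance <- function(mid, n_carbons, p13c = 0.0107) {
  if (p13c < 0 || p13c > 0.05) stop("p13c must lie in [0, 0.05]", call. = FALSE)
  mid <- as_mid(mid)
  env <- stats::dbinom(0:n_carbons, n_carbons, p13c)
  out <- numeric(length(mid) + n_carbons)
  for (j in seq_along(mid)) {
    idx <- j:(j + n_carbons)
    out[idx] <- out[idx] + mid[j] * env
  }
  as_mid(out)
}

#' Generate a GC-MS isotopologue intensity table
#'
#' Emulates the per-sample peak-area export of a pSIRM measurement: each
#' fragment's tracer MID is convolved with the natural-abundance envelope,
#' scaled by the metabolite quantity, perturbed by log-normal multiplicative
#' noise plus an additive floor, and emitted together with a cinnamic-acid
#' internal-standard row. With `multiplicative_cv = 0` and
#' `additive_floor = 0` the table is exactly the scaled convolution.
#'
#' @param mids Named list (names = nominal m/z as character) of tracer MIDs,
#'   e.g. the output of [simulate_citrate_mids()].
#' @param quantities Named numeric vector, metabolite -> amount (arbitrary
#'   intensity units), all >= 0.
#' @param fragments Fragment catalogue rows covering every m/z in `mids`.
#' @param p13c Natural 13C abundance in \[0, 0.05\].
#' @param noise A [noise_model()].
#' @param internal_standard_area Expected cinnamic-acid peak area per sample.
#' @param n_samples Number of replicate sample columns.
#' @param sample_names Optional column names (default `S1..Sn`).
#' @return A data.frame in the wide isotopologue-table schema: `metabolite`,
#'   `fragment_mz`, `mass_shift`, then one intensity column per sample,
#'   including a `cinnamic_acid` internal-standard row.
#' @export
generate_intensity_table <- function(mids, quantities,
                                     fragments = citrate_fragments(),
                                     p13c = 0.0107,
                                     noise = noise_model(),
                                     internal_standard_area = 1e6,
                                     n_samples = 1L,
                                     sample_names = NULL) {
  if (any(quantities < 0)) stop("quantities must be >= 0", call. = FALSE)
  if (is.null(sample_names)) sample_names <- paste0("S", seq_len(n_samples))
  stopifnot(length(sample_names) == n_samples)
  frag <- fragment_lookup(as.integer(names(mids)), fragments)

  rows <- list()
  for (i in seq_along(mids)) {
    n_c <- frag$metabolite_carbons_retained[i] + frag$extra_carbons[i]
    conv <- convolve_natural_abundance(mids[[i]], n_c, p13c)
    q <- quantities[[frag$metabolite[i]]]
    if (is.null(q) || is.na(q)) {
      stop("no quantity supplied for metabolite ", frag$metabolite[i],
           call. = FALSE)
    }
    rows[[i]] <- data.frame(
      metabolite = frag$metabolite[i],
      fragment_mz = frag$nominal_mz[i],
      mass_shift = seq_along(conv) - 1L,
      expected = q * as.numeric(conv),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    metabolite = "cinnamic_acid", fragment_mz = 131L, mass_shift = 0L,
    expected = internal_standard_area, stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)

  set.seed(noise$seed)
  for (s in sample_names) {
    x <- tab$expected
    if (noise$multiplicative_cv > 0) {
      sdlog <- sqrt(log1p(noise$multiplicative_cv^2))
      x <- x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (noise$additive_floor > 0) {
      x <- x + stats::runif(length(x), 0, noise$additive_floor)
    }
    tab[[s]] <- x
  }
  tab$expected <- NULL
  tab
}

#' Generate replicate sample/control expression experiments
#'
#' Emulates the input structure of a three-experiment knock-down microarray
#' study: per experiment, one control and one sample (knock-down)
#' log2-expression vector over a shared gene universe. A chosen subset of
#' genes is truly regulated, carrying a signed log2 effect consistently
#' across experiments; all genes receive intensity-dependent noise (spread
#' inflated at low mean expression, as on real arrays).
#'
#' @param n_genes Number of genes.
#' @param n_regulated Number of truly regulated genes (`<= n_genes`).
#' @param log2_effect Absolute log2 effect size of regulated genes.
#' @param replicate_cv Baseline replicate noise SD on the log2 scale at high
#'   intensity; inflated up to ~5-fold at the low-intensity end.
#' @param n_experiments Number of independent experiments (default 3).
#' @param seed Integer seed.
#' @return A list with `experiments` (a list of `list(sample=, control=)`
#'   named log2 vectors) and `truth` (data.frame `gene`, `regulated`,
#'   `sign` in \{-1, 0, +1\}).
#' @export
generate_expression_experiments <- function(n_genes, n_regulated,
                                            log2_effect = 2,
                                            replicate_cv = 0.25,
                                            n_experiments = 3L,
                                            seed = 1L) {
  if (n_regulated > n_genes) stop("n_regulated must be <= n_genes", call. = FALSE)
  if (n_experiments < 1) stop("need at least one experiment", call. = FALSE)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  base <- stats::runif(n_genes, 6, 14)       # log2 baseline intensity
  sd_gene <- replicate_cv * (1 + 4 * 2^(-(base - 6)))
  reg_idx <- if (n_regulated > 0) sample.int(n_genes, n_regulated) else integer(0)
  sign_vec <- integer(n_genes)
  sign_vec[reg_idx] <- sample(c(-1L, 1L), n_regulated, replace = TRUE)
  effect <- sign_vec * log2_effect

  experiments <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    control <- base + stats::rnorm(n_genes, 0, sd_gene)
    sample_ <- base + effect + stats::rnorm(n_genes, 0, sd_gene)
    names(control) <- names(sample_) <- genes
    experiments[[e]] <- list(sample = sample_, control = control)
  }
  names(experiments) <- paste0("exp", seq_len(n_experiments))
  list(experiments = experiments,
       truth = data.frame(gene = genes,
                          regulated = sign_vec != 0L,
                          sign = sign_vec,
                          stringsAsFactors = FALSE))
}

#' Generate paired binary high-expression call vectors
#'
#' Emulates a two-gene high-call dataset for the co-occurrence /
#' mutual-exclusivity screen. The joint cell probabilities preserve the
#' requested marginals while depleting (`mode = "exclusive"`) or enriching
#' (`mode = "cooccurring"`) the joint-high cell by `strength`:
#' `p11 = (1 - strength) * p_a * p_b` for exclusivity, and
#' `p11 = p_a * p_b + strength * (min(p_a, p_b) - p_a * p_b)` for
#' co-occurrence. `strength = 0` is independence in both modes;
#' `strength = 1` gives zero joint highs (hard exclusivity) or maximal
#' nesting (co-occurrence).
#'
#' @param n_samples Number of samples.
#' @param p_a,p_b Marginal high-call probabilities, in (0, 1).
#' @param mode `"independent"`, `"exclusive"` or `"cooccurring"`.
#' @param strength Association strength in \[0, 1\].
#' @param seed Integer seed.
#' @return A list with logical vectors `a` and `b` of length `n_samples`.
#' @export
generate_binary_association_dataset <- function(n_samples, p_a, p_b,
                                                mode = c("independent",
                                                         "exclusive",
                                                         "cooccurring"),
                                                strength = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    stop("p_a and p_b must lie in (0, 1)", call. = FALSE)
  }
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]", call. = FALSE)
  p11 <- switch(mode,
    independent = p_a * p_b,
    exclusive   = (1 - strength) * p_a * p_b,
    cooccurring = p_a * p_b + strength * (min(p_a, p_b) - p_a * p_b))
  p10 <- p_a - p11
  p01 <- p_b - p11
  p00 <- 1 - p11 - p10 - p01
  if (min(p10, p01, p00) < -1e-12) {
    stop("requested marginals and strength give an infeasible joint table",
         call. = FALSE)
  }
  set.seed(seed)
  cell <- sample.int(4L, n_samples, replace = TRUE,
                     prob = pmax(c(p11, p10, p01, p00), 0))
  list(a = cell %in% c(1L, 2L), b = cell %in% c(1L, 3L))
}
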