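#' Tracer specification
#'
#' Describes the 13C-labelled substrate applied in a pulse-labelling
#' experiment. Supported tracers are uniformly labelled glucose
#' (`"U13C6_glucose"`), uniformly labelled glutamine (`"U13C5_glutamine"`),
#' 13C sodium bicarbonate (`"C13_bicarbonate"`) and an unlabelled control
#' (`"unlabeled"`). The labelling duration is carried as metadata only; the
#' single-turn forward model does not integrate over time.
#'
#' @param name One of `"U13C6_glucose"`, `"U13C5_glutamine"`,
#'   `"C13_bicarbonate"`, `"unlabeled"`.
#' @param labeling_minutes Positive labelling duration in minutes. Defaults
#'   follow common pulse lengths: 7 min for glucose, 15 min for glutamine,
#'   20 min for bicarbonate.
#' @return An object of class `tracer_spec`.
#' @export
#' @examples
#' tracer_spec("U13C5_glutamine")
tracer_spec <- function(name = c("U13C6_glucose", "U13C5_glutamine",
                                 "C13_bicarbonate", "unlabeled"),
                        labeling_minutes = NULL) {
  name <- match.arg(name)
  if (is.null(labeling_minutes)) {
    labeling_minutes <- switch(name,
      U13C6_glucose = 7, U13C5_glutamine = 15,
      C13_bicarbonate = 20, unlabeled = 1)
  }
  if (!is.numeric(labeling_minutes) || length(labeling_minutes) != 1 ||
      !is.finite(labeling_minutes) || labeling_minutes <= 0) {
    stop("labeling_minutes must be a single positive number", call. = FALSE)
  }
  structure(list(name = name, labeling_minutes = labeling_minutes),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("<tracer_spec> %s (%g min pulse)\n", x$name, x$labeling_minutes))
  invisible(x)
}

#' Carbon-routing fractions feeding citrate
#'
#' Mixture weights of the pathways that can produce a citrate molecule in a
#' single TCA turn:
#' \describe{
#'   \item{f_ox_glc}{oxidative route with glucose-derived (labelled)
#'     acetyl-CoA condensing with unlabelled oxaloacetate;}
#'   \item{f_ox_gln}{oxidative glutamine route: glutamine-derived
#'     oxaloacetate (via alpha-ketoglutarate and succinate) plus unlabelled
#'     acetyl-CoA;}
#'   \item{f_red_gln}{reductive carboxylation of glutamine-derived
#'     alpha-ketoglutarate by isocitrate dehydrogenase running in reverse;}
#'   \item{f_pc}{pyruvate-carboxylase anaplerosis: pyruvate carboxylated to
#'     oxaloacetate, condensing with unlabelled acetyl-CoA;}
#'   \item{f_unlab}{fully unlabelled citrate.}
#' }
#' The five route fractions must lie in \[0,1\] and sum to 1. `f_fix` is
#' orthogonal to the route mixture: it is the probability that the
#' carboxylation-derived carbon position carries a bicarbonate-derived 13C
#' (visible only under the bicarbonate tracer).
#'
#' @param f_ox_glc,f_ox_gln,f_red_gln,f_pc,f_unlab Route fractions, sum 1.
#' @param f_fix Fraction of citrate molecules carrying one
#'   bicarbonate-derived carbon at the carboxylation position.
#' @return An object of class `routing_fractions`.
#' @export
#' @examples
#' routing_fractions(f_red_gln = 1)
routing_fractions <- function(f_ox_glc = 0, f_ox_gln = 0, f_red_gln = 0,
                              f_pc = 0, f_unlab = 0, f_fix = 0) {
  f <- c(f_ox_glc = unname(f_ox_glc), f_ox_gln = unname(f_ox_gln),
         f_red_gln = unname(f_red_gln), f_pc = unname(f_pc),
         f_unlab = unname(f_unlab), f_fix = unname(f_fix))
  if (!is.numeric(f) || anyNA(f) || any(f < 0) || any(f > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  routes <- f[setdiff(names(f), "f_fix")]
  if (abs(sum(routes) - 1) > 1e-9) {
    stop(sprintf(
      "route fractions must sum to 1 (got %.12g); f_fix is not part of the sum",
      sum(routes)), call. = FALSE)
  }
  structure(as.list(f), class = "routing_fractions")
}

#' @export
print.routing_fractions <- function(x, ...) {
  cat("<routing_fractions>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

route_names <- c("f_ox_glc", "f_ox_gln", "f_red_gln", "f_pc", "f_unlab")

#' Citrate GC-MS fragment catalogue
#'
#' The three citrate fragments used for fragment-resolved routing inference:
#' \itemize{
#'   \item 273 m/z (MSTFA derivatization): retains five of the six citrate
#'     carbons, lacking the oxaloacetate/carboxylation-derived carboxyl
#'     carbon ("C5 fragment");
#'   \item 375 m/z (MSTFA): the full six-carbon metabolite;
#'   \item 459 m/z (MBTSTFA): the full six-carbon metabolite under the
#'     alternative derivatization.
#' }
#' `extra_carbons` counts derivatization-reagent carbons retained in the
#' fragment; they enter the natural-abundance envelope, nothing else.
#'
#' @return A data.frame with one row per fragment: `metabolite`,
#'   `nominal_mz`, `metabolite_carbons_retained`, `lost_carbon_position`,
#'   `derivatization`, `extra_carbons`.
#' @export
#' @examples
#' citrate_fragments()
citrate_fragments <- function() {
  data.frame(
    metabolite = "citrate",
    nominal_mz = c(273L, 375L, 459L),
    metabolite_carbons_retained = c(5L, 6L, 6L),
    lost_carbon_position = c("oaa_carboxyl", "none", "none"),
    derivatization = c("MSTFA", "MSTFA", "MBTSTFA"),
    extra_carbons = c(6L, 9L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Look up fragments in a catalogue
#'
#' @param mz Integer vector of nominal m/z values.
#' @param catalogue A fragment catalogue data.frame
#'   (default [citrate_fragments()]).
#' @return The catalogue rows for `mz`, in the requested order.
#' @export
fragment_lookup <- function(mz, catalogue = citrate_fragments()) {
  idx <- match(mz, catalogue$nominal_mz)
  if (anyNA(idx)) {
    stop(sprintf("unknown fragment m/z: %s (catalogue has %s)",
                 paste(mz[is.na(idx)], collapse = ", "),
                 paste(catalogue$nominal_mz, collapse = ", ")),
         call. = FALSE)
  }
  catalogue[idx, , drop = FALSE]
}

#' Noise model for simulated GC-MS intensities
#'
#' Log-normal multiplicative noise with a given coefficient of variation,
#' plus a uniform additive intensity floor.
#'
#' @param multiplicative_cv Coefficient of variation of the multiplicative
#'   term (>= 0; 0 disables it).
#' @param additive_floor Maximum additive intensity perturbation (>= 0).
#' @param seed Integer seed used whenever the model is applied.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0, additive_floor = 0, seed = 1L) {
  if (multiplicative_cv < 0 || additive_floor < 0) {
    stop("multiplicative_cv and additive_floor must be >= 0", call. = FALSE)
  }
  structure(list(multiplicative_cv = multiplicative_cv,
                 additive_floor = additive_floor,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Validate a mass isotopomer distribution vector
#'
#' @param mid Numeric vector of isotopologue fractions over shifts m+0..m+n.
#' @param tol Tolerance on the unit sum.
#' @return `mid`, invisibly, named `m+0` ... `m+n`.
#' @export
as_mid <- function(mid, tol = 1e-9) {
  if (!is.numeric(mid) || length(mid) < 1 || anyNA(mid)) {
    stop("MID must be a numeric vector without NAs", call. = FALSE)
  }
  if (any(mid < -tol)) stop("MID entries must be >= 0", call. = FALSE)
  if (abs(sum(mid) - 1) > tol) {
    stop(sprintf("MID must sum to 1 (got %.12g)", sum(mid)), call. = FALSE)
  }
  mid <- pmax(mid, 0)
  names(mid) <- paste0("m+", seq_along(mid) - 1L)
  mid
}
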