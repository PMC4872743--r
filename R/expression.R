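#' Assemble a replicate experiment set
#'
#' An experiment set holds, per independent experiment, one control and one
#' sample (e.g. knock-down) log2-expression vector. Gene universes are
#' intersected across experiments; genes must be named.
#'
#' @param experiments A list of `list(sample =, control =)` named numeric
#'   vectors (log2 scale).
#' @return An object of class `experiment_set` (the list, genes aligned).
#' @export
as_experiment_set <- function(experiments) {
  if (inherits(experiments, "experiment_set")) return(experiments)
  if (!is.list(experiments) || length(experiments) < 1) {
    stop("need at least one experiment", call. = FALSE)
  }
  for (e in experiments) {
    if (!all(c("sample", "control") %in% names(e))) {
      stop("each experiment needs 'sample' and 'control' vectors", call. = FALSE)
    }
    if (is.null(names(e$sample)) || is.null(names(e$control))) {
      stop("expression vectors must be gene-named", call. = FALSE)
    }
  }
  genes <- Reduce(intersect, lapply(experiments, function(e)
    intersect(names(e$sample), names(e$control))))
  if (length(genes) == 0) stop("no genes shared across experiments", call. = FALSE)
  out <- lapply(experiments, function(e)
    list(sample = e$sample[genes], control = e$control[genes]))
  if (is.null(names(out))) names(out) <- paste0("exp", seq_along(out))
  structure(out, class = "experiment_set")
}

#' Discard consistently low-expressed genes
#'
#' A gene is discarded only when its expression lies below the per-sample
#' median in every sample (control and knock-down) of every experiment;
#' rising above the median anywhere retains it.
#'
#' @param set An [as_experiment_set()] object or compatible list.
#' @return The filtered `experiment_set`.
#' @export
filter_low_expression <- function(set) {
  set <- as_experiment_set(set)
  genes <- names(set[[1]]$sample)
  low_everywhere <- rep(TRUE, length(genes))
  for (e in set) {
    for (v in list(e$sample, e$control)) {
      low_everywhere <- low_everywhere & (v < stats::median(v))
    }
  }
  keep <- genes[!low_everywhere]
  if (length(keep) == 0) {
    stop("all genes discarded by the low-expression filter; review threshold",
         call. = FALSE)
  }
  out <- lapply(unclass(set), function(e)
    list(sample = e$sample[keep], control = e$control[keep]))
  structure(out, class = "experiment_set")
}

#' Average technical replicate columns of an expression matrix
#'
#' Arithmetic mean on the log2 scale within technical-replicate groups.
#'
#' @param mat Gene x sample numeric matrix.
#' @param groups Named character vector mapping each column to its group.
#' @return A matrix with one averaged column per group.
#' @export
average_technical_replicates <- function(mat, groups) {
  if (!all(colnames(mat) %in% names(groups))) {
    stop("groups must name every column of mat", call. = FALSE)
  }
  g <- unname(groups[colnames(mat)])
  out <- vapply(unique(g), function(gg)
    rowMeans(mat[, g == gg, drop = FALSE]), numeric(nrow(mat)))
  rownames(out) <- rownames(mat)
  out
}

rolling_mad_sigma <- function(fc, a, window) {
  n <- length(fc)
  if (window > n) {
    stop("window (", window, ") larger than gene count (", n, ")", call. = FALSE)
  }
  if (window < 3) stop("window must be >= 3", call. = FALSE)
  ord <- order(a)
  sig_sorted <- zoo::rollapply(fc[ord], width = window, FUN = stats::mad,
                               fill = NA, align = "center")
  ## extend the first/last full-window estimate into the edges
  first <- which(!is.na(sig_sorted))[1]
  last <- max(which(!is.na(sig_sorted)))
  sig_sorted[seq_len(first - 1)] <- sig_sorted[first]
  if (last < n) sig_sorted[(last + 1):n] <- sig_sorted[last]
  sig <- numeric(n)
  sig[ord] <- sig_sorted
  sig
}

#' Error-model z-transformation of fold changes
#'
#' Per experiment, the log2 fold change `fc = sample - control` is divided
#' by an intensity-dependent spread estimate: genes are ranked by mean
#' expression `a = (sample + control) / 2` and the spread `sigma(a)` is the
#' rolling median absolute deviation (scaled by 1.4826) of `fc` in a window
#' of neighbouring genes. This standardizes fold changes against the
#' noise level typical of their intensity range, so `z` is comparable across
#' the signal range of the array.
#'
#' @param set An experiment set (ideally after [filter_low_expression()]).
#' @param window Rolling-window size in genes (default 200).
#' @param sigma Optional user-supplied spread function `function(a, fc)`
#'   returning a per-gene sigma vector, replacing the rolling-MAD model.
#' @return An object of class `zscore_set`: `z` (gene x experiment matrix)
#'   and `details` (per experiment: data.frame `gene`, `fc`, `mean_expr`,
#'   `sigma`, `z`).
#' @export
z_transform <- function(set, window = 200L, sigma = NULL) {
  set <- as_experiment_set(set)
  genes <- names(set[[1]]$sample)
  z <- matrix(NA_real_, length(genes), length(set),
              dimnames = list(genes, names(set)))
  details <- list()
  for (i in seq_along(set)) {
    e <- set[[i]]
    fc <- e$sample - e$control
    a <- (e$sample + e$control) / 2
    sig <- if (is.null(sigma)) rolling_mad_sigma(fc, a, window) else sigma(a, fc)
    sig_safe <- pmax(sig, .Machine$double.eps)
    zi <- fc / sig_safe
    zi[fc == 0] <- 0
    z[, i] <- zi
    details[[i]] <- data.frame(gene = genes, fc = fc, mean_expr = a,
                               sigma = sig, z = zi, row.names = NULL,
                               stringsAsFactors = FALSE)
  }
  names(details) <- names(set)
  structure(list(z = z, details = details), class = "zscore_set")
}

get_z_matrix <- function(z) {
  if (inherits(z, "zscore_set")) z$z
  else if (is.matrix(z)) z
  else stop("expected a zscore_set or a gene x experiment z matrix",
            call. = FALSE)
}

#' Select consistently top-ranked genes across experiments
#'
#' Per experiment the selection threshold is the empirical `(1 - q)`
#' quantile (type 7) of the absolute z values; a gene is selected when its
#' absolute z meets or exceeds the threshold in every experiment and its z
#' has the same (nonzero) sign in every experiment.
#'
#' @param z A `zscore_set` or gene x experiment z matrix.
#' @param q Top fraction per experiment (default 0.10).
#' @return A list of class `selection_result`: `selected` (data.frame
#'   `gene`, `sign`), `thresholds` (per experiment), `q`.
#' @export
select_consistent_top <- function(z, q = 0.10) {
  zm <- get_z_matrix(z)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  thr <- apply(abs(zm), 2, stats::quantile, probs = 1 - q, type = 7)
  in_top <- sweep(abs(zm), 2, thr, ">=")
  sgn <- sign(zm)
  consistent <- apply(in_top, 1, all) &
    (apply(sgn == 1, 1, all) | apply(sgn == -1, 1, all))
  sel <- data.frame(gene = rownames(zm)[consistent],
                    sign = sgn[consistent, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(selected = sel, thresholds = thr, q = q),
            class = "selection_result")
}

#' Resampling FDR estimate for the consistent-top selection
#'
#' Each of `n_draws` null datasets is built by resampling, for every
#' experiment independently, the experiment's z values with replacement --
#' destroying the gene matching across experiments while preserving each
#' experiment's marginal z distribution (which the selection thresholds
#' depend on). The selection is re-applied to each null dataset and the FDR
#' estimated as the mean null selection count divided by the observed
#' count, clipped to \[0, 1\].
#'
#' @param z A `zscore_set` or z matrix.
#' @param q Top fraction passed to [select_consistent_top()].
#' @param n_draws Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return A list of class `fdr_report`: `fdr`, `observed`, `null_counts`,
#'   `n_draws`, `q`, `seed`. When nothing is observed selected, `fdr` is
#'   `NA` with `note = "undefined"`.
#' @export
estimate_fdr <- function(z, q = 0.10, n_draws = 1000L, seed = 1L) {
  zm <- get_z_matrix(z)
  observed <- nrow(select_consistent_top(zm, q)$selected)
  set.seed(seed)
  null_counts <- integer(n_draws)
  n <- nrow(zm)
  for (d in seq_len(n_draws)) {
    znull <- apply(zm, 2, function(col) col[sample.int(n, n, replace = TRUE)])
    rownames(znull) <- rownames(zm)
    null_counts[d] <- nrow(select_consistent_top(znull, q)$selected)
  }
  if (observed == 0) {
    return(structure(list(fdr = NA_real_, observed = 0L,
                          null_counts = null_counts, n_draws = n_draws,
                          q = q, seed = seed, note = "undefined"),
                     class = "fdr_report"))
  }
  structure(list(fdr = min(max(mean(null_counts) / observed, 0), 1),
                 observed = observed, null_counts = null_counts,
                 n_draws = n_draws, q = q, seed = seed, note = NULL),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("<fdr_report> observed %d selections; %d draws; FDR = %s\n",
              x$observed, x$n_draws,
              if (is.na(x$fdr)) "undefined" else format(x$fdr)))
  invisible(x)
}

#' Rank a gene among down-regulated genes
#'
#' Position of a gene's z value within the ascending-sorted z values, per
#' experiment and pooled (the rank of the gene's mean z among all genes'
#' mean z). Rank 1 is the most strongly down-regulated gene. Ties report
#' the minimum rank and are flagged.
#'
#' @param z A `zscore_set` or z matrix.
#' @param gene Gene identifier.
#' @return A list: `per_experiment` (integer ranks), `pooled`, `tie`.
#' @export
rank_knockdown_target <- function(z, gene) {
  zm <- get_z_matrix(z)
  if (!gene %in% rownames(zm)) stop("gene not found: ", gene, call. = FALSE)
  per <- apply(zm, 2, function(col) rank(col, ties.method = "min")[gene])
  ties <- apply(zm, 2, function(col) sum(col == col[gene]) > 1)
  zbar <- rowMeans(zm)
  pooled <- rank(zbar, ties.method = "min")[[gene]]
  list(per_experiment = per, pooled = pooled,
       tie = any(ties) || sum(zbar == zbar[gene]) > 1)
}
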