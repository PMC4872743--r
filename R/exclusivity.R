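#' Binarize an expression matrix into high-expression calls
#'
#' Two rules are supported:
#' \describe{
#'   \item{`above_mean_plus_sd`}{a sample is a high expressor of a gene when
#'     its expression strictly exceeds the gene's mean plus one sample
#'     standard deviation (n-1 denominator) across samples -- the rule used
#'     for tumor RNA-seq panels;}
#'   \item{`above_median_profile`}{the gene's median profile is subtracted
#'     and samples with a strictly positive residual are high -- the rule
#'     used for cell-line panels.}
#' }
#' Boundary samples (exactly at the threshold) are not high. A constant
#' gene yields all-false calls under the mean+SD rule, with a warning.
#'
#' @param mat Gene x sample numeric matrix (log2 expression), >= 2 samples.
#' @param rule `"above_mean_plus_sd"` or `"above_median_profile"`.
#' @return An object of class `binary_calls`: `calls` (logical gene x
#'   sample matrix), `thresholds` (per gene), `rule`.
#' @export
binarize <- function(mat, rule = c("above_mean_plus_sd",
                                   "above_median_profile")) {
  rule <- match.arg(rule)
  if (ncol(mat) < 2) stop("need at least two samples", call. = FALSE)
  if (rule == "above_mean_plus_sd") {
    mu <- rowMeans(mat)
    sd_ <- apply(mat, 1, stats::sd)
    if (any(sd_ == 0)) {
      warning("constant gene(s) under mean+SD rule: all-false calls for ",
              paste(rownames(mat)[sd_ == 0], collapse = ", "), call. = FALSE)
    }
    thr <- mu + sd_
  } else {
    thr <- apply(mat, 1, stats::median)
  }
  calls <- sweep(mat, 1, thr, ">")
  structure(list(calls = calls, thresholds = thr, rule = rule),
            class = "binary_calls")
}

#' Hypergeometric co-occurrence / mutual-exclusivity test for a gene pair
#'
#' With `n` samples, `a` highs of gene A, `b` highs of gene B and `k` joint
#' highs, the joint-high count under fixed margins is hypergeometric.
#' `p_cooccurrence = P[X >= k]` (upper tail: at least this much overlap by
#' chance) and `p_exclusivity = P[X <= k]` (lower tail: at most this much).
#' The odds ratio is `(n11 * n00) / (n10 * n01)`, with the
#' Haldane-Anscombe 0.5 continuity correction added to every cell only when
#' some cell is zero.
#'
#' @param calls_a,calls_b Logical call vectors of equal length.
#' @return An object of class `pair_association`: `counts` (named `n11`,
#'   `n10`, `n01`, `n00`), `n`, `odds_ratio`, `continuity_corrected`,
#'   `p_cooccurrence`, `p_exclusivity`.
#' @export
#' @examples
#' v <- c(rep(TRUE, 5), rep(FALSE, 5))
#' pair_test(v, v)$p_cooccurrence  # 1/252
pair_test <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  n <- length(calls_a)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  calls_a <- as.logical(calls_a); calls_b <- as.logical(calls_b)
  k <- sum(calls_a & calls_b)
  a <- sum(calls_a); b <- sum(calls_b)
  counts <- c(n11 = k, n10 = a - k, n01 = b - k, n00 = n - a - b + k)
  p_co <- stats::phyper(k - 1, a, n - a, b, lower.tail = FALSE)
  p_ex <- stats::phyper(k, a, n - a, b)
  cc <- any(counts == 0)
  ct <- counts + if (cc) 0.5 else 0
  or_ <- (ct[["n11"]] * ct[["n00"]]) / (ct[["n10"]] * ct[["n01"]])
  structure(list(counts = counts, n = n, odds_ratio = or_,
                 continuity_corrected = cc,
                 p_cooccurrence = p_co, p_exclusivity = p_ex),
            class = "pair_association")
}

#' @export
print.pair_association <- function(x, ...) {
  cat(sprintf(
    "<pair_association> n=%d  n11=%d n10=%d n01=%d n00=%d\n  OR=%.4g%s  p_co=%.4g  p_excl=%.4g\n",
    x$n, x$counts[["n11"]], x$counts[["n10"]], x$counts[["n01"]],
    x$counts[["n00"]], x$odds_ratio,
    if (x$continuity_corrected) " (continuity-corrected)" else "",
    x$p_cooccurrence, x$p_exclusivity))
  invisible(x)
}

#' Classify a pair association by odds-ratio bands
#'
#' `mutually_exclusive` when the odds ratio falls below the low bound
#' (default 0.1), `co_occurring` when it exceeds the high bound (default
#' 2), else `neither`.
#'
#' @param assoc A [pair_test()] result (or anything with `$odds_ratio`).
#' @param or_bounds Numeric `c(low, high)` bounds.
#' @return `"mutually_exclusive"`, `"co_occurring"` or `"neither"`.
#' @export
classify_pair <- function(assoc, or_bounds = c(0.1, 2)) {
  stopifnot(length(or_bounds) == 2, or_bounds[1] < or_bounds[2])
  or_ <- assoc$odds_ratio
  if (or_ < or_bounds[1]) "mutually_exclusive"
  else if (or_ > or_bounds[2]) "co_occurring"
  else "neither"
}

#' Venn partition of expressor samples for two or three genes
#'
#' Counts samples in every region of the expressor Venn diagram and, for a
#' designated gene pair, reports the union count and the percentage of
#' union members high for exactly one of the two genes -- the
#' mutual-exclusivity percentage.
#'
#' @param calls Named list of 2 or 3 logical call vectors (equal length).
#' @param pair Indices or names of the designated pair (default the first
#'   two genes).
#' @return A list of class `venn_partition`: `regions` (named counts; for
#'   three genes `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC` exclusive regions),
#'   `none`, `n`, `pair` with `union`, `exactly_one` and
#'   `exclusive_percent`.
#' @export
expressor_venn <- function(calls, pair = c(1L, 2L)) {
  if (!is.list(calls) || !length(calls) %in% c(2L, 3L)) {
    stop("calls must be a list of 2 or 3 logical vectors", call. = FALSE)
  }
  if (length(unique(lengths(calls))) != 1) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  if (is.null(names(calls))) names(calls) <- LETTERS[seq_along(calls)]
  m <- vapply(calls, as.logical, logical(length(calls[[1]])))
  n <- nrow(m)
  if (ncol(m) == 2) {
    regions <- c(
      sum(m[, 1] & !m[, 2]), sum(!m[, 1] & m[, 2]), sum(m[, 1] & m[, 2]))
    names(regions) <- c(names(calls), paste(names(calls), collapse = ""))
  } else {
    A <- m[, 1]; B <- m[, 2]; C <- m[, 3]
    regions <- c(
      sum(A & !B & !C), sum(!A & B & !C), sum(!A & !B & C),
      sum(A & B & !C), sum(A & !B & C), sum(!A & B & C), sum(A & B & C))
    names(regions) <- c(names(calls),
                        paste0(names(calls)[1], names(calls)[2]),
                        paste0(names(calls)[1], names(calls)[3]),
                        paste0(names(calls)[2], names(calls)[3]),
                        paste0(names(calls), collapse = ""))
  }
  pa <- m[, pair[1]]; pb <- m[, pair[2]]
  union_ <- sum(pa | pb)
  exactly_one <- sum(xor(pa, pb))
  structure(list(
    regions = regions, none = n - sum(rowSums(m) > 0), n = n,
    pair = list(genes = colnames(m)[if (is.numeric(pair)) pair else
      match(pair, colnames(m))],
      union = union_, exactly_one = exactly_one,
      exclusive_percent = if (union_ > 0) 100 * exactly_one / union_
                          else NA_real_)),
    class = "venn_partition")
}

#' Hierarchical clustering and pairwise correlation of gene profiles
#'
#' Gene profiles are z-scored across samples, clustered on Euclidean
#' distance by agglomerative hierarchical clustering (average linkage by
#' default), and every gene pair is tested for nonzero Pearson correlation
#' (two-sided t-based test). Pairs involving a constant gene are reported
#' with `NA` correlation.
#'
#' @param mat Gene x sample numeric matrix, >= 3 samples.
#' @param linkage Agglomeration method for [stats::hclust()] (`"average"`,
#'   `"single"`, `"complete"`, `"ward.D2"`, ...).
#' @return A list: `order` (gene names in dendrogram order), `hclust`,
#'   `correlations` (data.frame `gene_a`, `gene_b`, `r`, `p_value`).
#' @export
cluster_and_correlate <- function(mat, linkage = "average") {
  if (ncol(mat) < 3) stop("need at least three samples", call. = FALSE)
  sd_ <- apply(mat, 1, stats::sd)
  zs <- mat
  zs[sd_ > 0, ] <- t(scale(t(mat[sd_ > 0, , drop = FALSE])))
  zs[sd_ == 0, ] <- 0
  hc <- stats::hclust(stats::dist(zs), method = linkage)
  genes <- rownames(mat)
  pairs <- utils::combn(seq_along(genes), 2)
  cors <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (sd_[i] == 0 || sd_[j] == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(mat[i, ], mat[j, ], method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  })
  list(order = genes[hc$order], hclust = hc,
       correlations = data.frame(
         gene_a = genes[pairs[1, ]], gene_b = genes[pairs[2, ]],
         r = cors[1, ], p_value = cors[2, ],
         stringsAsFactors = FALSE))
}
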