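## Internal helpers for the wide isotopologue-table schema:
## columns metabolite, fragment_mz, mass_shift, then one column per sample.

INTERNAL_STANDARD <- "cinnamic_acid"

sample_columns <- function(table) {
  setdiff(colnames(table), c("metabolite", "fragment_mz", "mass_shift"))
}

check_isotopologue_table <- function(table) {
  need <- c("metabolite", "fragment_mz", "mass_shift")
  if (!all(need %in% colnames(table))) {
    stop("isotopologue table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  smp <- sample_columns(table)
  if (length(smp) == 0) stop("isotopologue table has no sample columns", call. = FALSE)
  key <- paste(table$metabolite, table$fragment_mz, table$mass_shift)
  if (anyDuplicated(key)) {
    stop("duplicate (metabolite, fragment_mz, mass_shift) rows", call. = FALSE)
  }
  for (s in smp) {
    if (any(table[[s]] < 0, na.rm = TRUE)) {
      stop("negative intensities in sample ", s, call. = FALSE)
    }
  }
  smp
}

internal_standard_intensity <- function(table, samples,
                                        standard = INTERNAL_STANDARD) {
  is_rows <- table$metabolite == standard
  if (!any(is_rows)) {
    stop("internal-standard row ('", standard, "') missing", call. = FALSE)
  }
  vapply(samples, function(s) {
    v <- sum(table[[s]][is_rows])
    if (!is.finite(v) || v <= 0) {
      stop("internal standard missing or non-positive in sample ", s,
           call. = FALSE)
    }
    v
  }, numeric(1))
}

#' Average technical duplicate sample columns
#'
#' Technical duplicates of the same biological sample are averaged on the
#' raw intensity scale before any MID computation or normalization.
#'
#' @param table A wide isotopologue table.
#' @param groups Named character vector mapping each sample column to its
#'   technical-replicate group; columns sharing a group are averaged into a
#'   single column named after the group.
#' @return The table with one averaged column per group.
#' @export
average_technical_duplicates <- function(table, groups) {
  smp <- check_isotopologue_table(table)
  if (!all(smp %in% names(groups))) {
    stop("groups must name every sample column", call. = FALSE)
  }
  out <- table[, c("metabolite", "fragment_mz", "mass_shift"), drop = FALSE]
  for (g in unique(unname(groups[smp]))) {
    cols <- smp[groups[smp] == g]
    out[[g]] <- rowMeans(as.matrix(table[, cols, drop = FALSE]))
  }
  out
}

#' Normalize metabolite quantities to the internal standard
#'
#' Per sample, the total intensity of each metabolite's quantifier fragment
#' (summed over mass shifts) is divided by that sample's cinnamic-acid
#' internal-standard intensity, yielding a unitless relative quantity that
#' is invariant to per-sample scale (injection volume, detector response).
#'
#' @param table A wide isotopologue table including the internal-standard
#'   row.
#' @param catalogue Optional fragment catalogue used to pick each
#'   metabolite's quantifier fragment (the one retaining the most metabolite
#'   carbons; catalogue order breaks ties). Without a catalogue the fragment
#'   with the largest m/z is used.
#' @param standard Internal-standard metabolite name.
#' @return A data.frame `metabolite`, `fragment_mz` (quantifier), `sample`,
#'   `normalized_quantity`.
#' @export
normalize_to_internal_standard <- function(table, catalogue = NULL,
                                           standard = INTERNAL_STANDARD) {
  smp <- check_isotopologue_table(table)
  ist <- internal_standard_intensity(table, smp, standard)
  mets <- setdiff(unique(table$metabolite), standard)
  out <- list()
  for (m in mets) {
    sub <- table[table$metabolite == m, , drop = FALSE]
    mzs <- unique(sub$fragment_mz)
    if (!is.null(catalogue)) {
      cat_m <- catalogue[catalogue$metabolite == m &
                           catalogue$nominal_mz %in% mzs, , drop = FALSE]
      quant_mz <- if (nrow(cat_m)) {
        cat_m$nominal_mz[which.max(cat_m$metabolite_carbons_retained)]
      } else max(mzs)
    } else {
      quant_mz <- max(mzs)
    }
    qrows <- sub[sub$fragment_mz == quant_mz, , drop = FALSE]
    for (s in smp) {
      out[[length(out) + 1L]] <- data.frame(
        metabolite = m, fragment_mz = quant_mz, sample = s,
        normalized_quantity = sum(qrows[[s]]) / ist[[s]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Extract a raw mass isotopomer distribution
#'
#' Renormalizes one fragment's per-shift intensities in one sample to sum 1.
#' Mass shifts absent from the table are treated as zero.
#'
#' @param table A wide isotopologue table.
#' @param metabolite,fragment_mz,sample Row/column selectors.
#' @return A MID vector over shifts m+0..m+max.
#' @export
raw_mid <- function(table, metabolite, fragment_mz, sample) {
  check_isotopologue_table(table)
  sub <- table[table$metabolite == metabolite &
                 table$fragment_mz == fragment_mz, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no rows for ", metabolite, " fragment ", fragment_mz, call. = FALSE)
  }
  if (!sample %in% colnames(sub)) stop("unknown sample ", sample, call. = FALSE)
  shifts <- sub$mass_shift
  v <- numeric(max(shifts) + 1L)
  v[shifts + 1L] <- sub[[sample]]
  tot <- sum(v)
  if (tot <= 0) {
    stop("all-zero intensities for ", metabolite, " fragment ", fragment_mz,
         " in sample ", sample, ": MID undefined", call. = FALSE)
  }
  as_mid(v / tot)
}

#' Theoretical unlabelled reference spectrum
#'
#' Binomial natural-abundance MID of an unlabelled fragment with
#' `n_carbons` carbons at 13C probability `p13c`. Used as a fallback
#' reference when no measured identification standard is available, and as
#' an independent oracle for the measured-reference path.
#'
#' @param n_carbons Total carbons in the derivatized fragment.
#' @param p13c Natural 13C abundance.
#' @return A MID vector.
#' @export
natural_abundance_reference <- function(n_carbons, p13c = 0.0107) {
  as_mid(stats::dbinom(0:n_carbons, n_carbons, p13c))
}

#' Estimate 13C label incorporation against an unlabelled reference
#'
#' The measured MID of an unlabelled identification standard (reflecting
#' natural 13C abundance) is scaled to the sample's shift-0 mass to predict
#' the unlabelled component at every shift:
#' `expected_j = sample[0] * reference[j] / reference[0]`. Mass above that
#' prediction is tracer-derived excess, `excess_j = max(sample_j -
#' expected_j, 0)` for `j >= 1`, and the label incorporation is
#' `sum(excess) / (sample[0] + sum(excess))`, clipped to \[0, 1\]. Negative
#' excesses (noise pushing measured below expected) are clipped to zero and
#' their magnitude reported as a QC metric.
#'
#' @param sample_mid Measured MID of the sample.
#' @param reference Unlabelled reference MID (measured standard or
#'   [natural_abundance_reference()]). Its shift-0 mass must be positive.
#' @return A list: `incorporation` (fraction in \[0,1\]), `excess_mid`
#'   (renormalized excess vector; all-`NA` when no excess), and
#'   `clipped_mass` (total negative excess removed).
#' @export
#' @examples
#' label_incorporation(c(0.475, 0.025, 0.5), c(0.95, 0.05))
label_incorporation <- function(sample_mid, reference) {
  s <- as_mid(sample_mid)
  r <- as_mid(reference)
  if (r[1] <= 0) {
    stop("degenerate reference: shift-0 mass must be > 0", call. = FALSE)
  }
  n <- max(length(s), length(r))
  s <- c(s, numeric(n - length(s)))
  r <- c(r, numeric(n - length(r)))
  expected <- s[1] * r / r[1]
  diff <- s - expected
  diff[1] <- 0
  excess <- pmax(diff, 0)
  clipped <- -sum(pmin(diff[-1], 0))
  tot_excess <- sum(excess)
  incorporation <- min(max(tot_excess / (s[1] + tot_excess), 0), 1)
  excess_mid <- if (tot_excess > 0) as_mid(excess / tot_excess) else {
    v <- rep(NA_real_, n); names(v) <- paste0("m+", 0:(n - 1)); v
  }
  list(incorporation = incorporation, excess_mid = excess_mid,
       clipped_mass = clipped)
}

ref_key <- function(metabolite, fragment_mz) paste0(metabolite, ":", fragment_mz)

#' Labelled metabolite quantities
#'
#' Composes internal-standard normalization and label-incorporation
#' estimation into the per-metabolite activity readout: for each metabolite,
#' fragment and sample, `labelled_quantity = label_incorporation *
#' normalized_quantity`.
#'
#' @param table A wide isotopologue table including the internal standard.
#' @param references Named list of unlabelled reference MIDs keyed
#'   `"metabolite:mz"` (e.g. `"citrate:273"`). Fragments without an entry
#'   fall back to the theoretical binomial reference when `catalogue` covers
#'   them, else error.
#' @param tracer A [tracer_spec()] recorded in the output.
#' @param catalogue Fragment catalogue for quantifier choice and fallback
#'   reference carbon counts.
#' @param p13c Natural abundance used for fallback references.
#' @return A data.frame `metabolite`, `fragment_mz`, `sample`, `tracer`,
#'   `label_incorporation`, `normalized_quantity`, `labelled_quantity`.
#' @export
labelled_quantities <- function(table, references = list(),
                                tracer = tracer_spec("unlabeled"),
                                catalogue = citrate_fragments(),
                                p13c = 0.0107) {
  smp <- check_isotopologue_table(table)
  normq <- normalize_to_internal_standard(table, catalogue = catalogue)
  mets <- setdiff(unique(table$metabolite), INTERNAL_STANDARD)
  out <- list()
  for (m in mets) {
    sub <- table[table$metabolite == m, , drop = FALSE]
    for (mz in unique(sub$fragment_mz)) {
      key <- ref_key(m, mz)
      ref <- references[[key]]
      if (is.null(ref)) {
        cat_row <- catalogue[catalogue$metabolite == m &
                               catalogue$nominal_mz == mz, , drop = FALSE]
        if (nrow(cat_row) == 0) {
          stop("no reference and no catalogue entry for ", key, call. = FALSE)
        }
        ref <- natural_abundance_reference(
          cat_row$metabolite_carbons_retained[1] + cat_row$extra_carbons[1],
          p13c)
      }
      for (s in smp) {
        inc <- tryCatch(
          label_incorporation(raw_mid(table, m, mz, s), ref),
          error = function(e) {
            stop("labelled_quantities failed for ", key, " sample ", s, ": ",
                 conditionMessage(e), call. = FALSE)
          })
        nq <- normq$normalized_quantity[normq$metabolite == m &
                                          normq$sample == s]
        out[[length(out) + 1L]] <- data.frame(
          metabolite = m, fragment_mz = mz, sample = s, tracer = tracer$name,
          label_incorporation = inc$incorporation,
          normalized_quantity = nq,
          labelled_quantity = inc$incorporation * nq,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
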