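## Delimited-text dialect used throughout: tab-separated, UTF-8, "." decimal,
## NA as empty field, header row.

#' Write / read a wide isotopologue table
#'
#' Tab-delimited text with columns `metabolite`, `fragment_mz`,
#' `mass_shift`, then one intensity column per sample.
#'
#' @param table The table data.frame.
#' @param path File path.
#' @return `read_isotopologue_table()` returns the table; the writer
#'   returns `path` invisibly.
#' @export
write_isotopologue_table <- function(table, path) {
  check_isotopologue_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_isotopologue_table
#' @export
read_isotopologue_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  tab$fragment_mz <- as.integer(tab$fragment_mz)
  tab$mass_shift <- as.integer(tab$mass_shift)
  check_isotopologue_table(tab)
  tab
}

#' Read a gene x sample expression matrix
#'
#' Tab-delimited text: first column gene identifiers, header row of sample
#' names. Duplicate gene rows (e.g. same-gene probes) are summarized by
#' their median per sample.
#'
#' @param path File path.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      stop("parse error reading ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("parse error: expected gene column plus >= 1 sample column in ",
         path, call. = FALSE)
  }
  smp <- colnames(raw)[-1]
  if (anyDuplicated(smp)) {
    stop("duplicate sample names: ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "), call. = FALSE)
  }
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !(is.na(v) | v == ""))
      if (length(bad)) {
        stop(sprintf("non-numeric cell in column '%s', data line %d: '%s'",
                     smp[j], bad[1], v[bad[1]]), call. = FALSE)
      }
      vals[[j]] <- vn
    }
  }
  mat <- as.matrix(vals)
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) {
    mat <- do.call(rbind, lapply(split(seq_along(genes), genes), function(idx)
      apply(mat[idx, , drop = FALSE], 2, stats::median)))
    mat <- mat[unique(genes), , drop = FALSE]
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Write a gene x sample expression matrix
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path File path.
#' @param gene_col Header for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a GEO series-matrix-style expression file
#'
#' Skips the `!`-prefixed header block and reads the table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` (or, absent
#' those markers, all non-`!` lines) as a gene x sample matrix.
#'
#' @param path File path.
#' @return A numeric matrix (duplicate identifiers median-collapsed).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  body <- if (length(beg) && length(end)) lines[(beg[1] + 1):(end[1] - 1)]
          else lines[!startsWith(lines, "!")]
  body <- body[nzchar(body)]
  if (length(body) < 2) stop("no table found in ", path, call. = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(gsub('"', "", body), tmp)
  read_expression_matrix(tmp)
}

#' Write / read an unlabelled reference spectrum
#'
#' Two-column tab-delimited file: `mass_shift`, `fraction`.
#'
#' @param mid MID vector.
#' @param path File path.
#' @return The reader returns a MID vector; the writer `path`, invisibly.
#' @export
write_reference_spectrum <- function(mid, path) {
  mid <- as_mid(mid)
  utils::write.table(
    data.frame(mass_shift = seq_along(mid) - 1L, fraction = as.numeric(mid)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_spectrum
#' @export
read_reference_spectrum <- function(path) {
  df <- utils::read.delim(path)
  v <- numeric(max(df$mass_shift) + 1L)
  v[df$mass_shift + 1L] <- df$fraction
  as_mid(v)
}

#' Build and validate a pipeline configuration
#'
#' All stage parameters are validated against their preconditions before
#' any stage runs. The configuration round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Global integer seed; each stage derives its own seed from it.
#' @param q Top fraction for the selection stage, in (0, 1).
#' @param n_draws Random draws for the FDR stage (>= 1).
#' @param p13c Natural 13C abundance, in \[0, 0.05\].
#' @param or_bounds Odds-ratio classification bounds `c(low, high)`.
#' @param linkage Clustering linkage method.
#' @param window z-transformation window (genes).
#' @param n_bootstrap Bootstrap replicates for the routing fit.
#' @param noise A [noise_model()].
#' @param out_dir Output directory for stage files (`NULL` = no files).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, q = 0.10, n_draws = 1000L,
                            p13c = 0.0107, or_bounds = c(0.1, 2),
                            linkage = "average", window = 200L,
                            n_bootstrap = 200L, noise = noise_model(),
                            out_dir = NULL) {
  if (q <= 0 || q >= 1) stop("config invalid: q must lie in (0, 1)", call. = FALSE)
  if (n_draws < 1) stop("config invalid: n_draws must be >= 1", call. = FALSE)
  if (p13c < 0 || p13c > 0.05) {
    stop("config invalid: p13c must lie in [0, 0.05]", call. = FALSE)
  }
  if (length(or_bounds) != 2 || or_bounds[1] >= or_bounds[2]) {
    stop("config invalid: or_bounds must be c(low, high) with low < high",
         call. = FALSE)
  }
  if (window < 3) stop("config invalid: window must be >= 3", call. = FALSE)
  if (n_bootstrap < 0) stop("config invalid: n_bootstrap must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), q = q, n_draws = as.integer(n_draws),
                 p13c = p13c, or_bounds = or_bounds, linkage = linkage,
                 window = as.integer(window),
                 n_bootstrap = as.integer(n_bootstrap),
                 noise = unclass(noise), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for config files", call. = FALSE)
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for config files", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  nm <- raw$noise
  do.call(pipeline_config, c(
    raw[setdiff(names(raw), "noise")],
    list(noise = noise_model(nm$multiplicative_cv, nm$additive_floor,
                             nm$seed))))
}

stage_seed <- function(config, tag) {
  ## deterministic per-stage seed below 2^31
  (config$seed * 1000L + utils::head(utf8ToInt(tag), 1L)) %% .Machine$integer.max
}

#' Run the synthetic end-to-end demonstration pipeline
#'
#' Executes the three analysis arms on synthetic data generated under the
#' configuration's seed: (1) simulate citrate routing MIDs, build an
#' intensity table, recover label incorporation and fit routing fractions;
#' (2) generate a three-experiment expression study, z-transform, select
#' and estimate the FDR; (3) generate an association dataset and run the
#' pair test. Any stage failure aborts with the stage name; the manifest is
#' returned (and written to `out_dir` when set) regardless.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_manifest`: `config`, `package_version`,
#'   `timings` (seconds per stage), `warnings`, and `results` per stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("isoroute")),
                   timings = list(), warnings = list(), results = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest$timings[[name]] <<- proc.time()[["elapsed"]] - t0
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings[[name]] <<-
          c(manifest$warnings[[name]], conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    manifest$results[[name]] <<- res
    res
  }

  run_stage("routing", function() {
    truth <- routing_fractions(0.35, 0.25, 0.2, 0.05, 0.15, f_fix = 0.1)
    tracers <- list(tracer_spec("U13C6_glucose"),
                    tracer_spec("U13C5_glutamine"),
                    tracer_spec("C13_bicarbonate"))
    mids <- list()
    for (tr in tracers) {
      sim <- simulate_citrate_mids(truth, tr)
      for (mz in names(sim)) mids[[mid_key(tr$name, mz)]] <- sim[[mz]]
    }
    fit <- fit_routing_fractions(mids, n_bootstrap = config$n_bootstrap,
                                 seed = stage_seed(config, "routing"))
    list(truth = unclass(truth), fit = fit,
         evidence = extract_routing_evidence(mids))
  })

  run_stage("expression", function() {
    gen <- generate_expression_experiments(
      n_genes = 2000, n_regulated = 100, log2_effect = 2,
      replicate_cv = 0.25, seed = stage_seed(config, "expression"))
    zs <- z_transform(filter_low_expression(gen$experiments),
                      window = config$window)
    sel <- select_consistent_top(zs, q = config$q)
    fdr <- estimate_fdr(zs, q = config$q, n_draws = config$n_draws,
                        seed = stage_seed(config, "fdr"))
    list(selection = sel, fdr = fdr, truth = gen$truth)
  })

  run_stage("association", function() {
    ds <- generate_binary_association_dataset(
      200, 0.4, 0.4, mode = "exclusive", strength = 0.9,
      seed = stage_seed(config, "association"))
    assoc <- pair_test(ds$a, ds$b)
    list(association = assoc,
         class = classify_pair(assoc, config$or_bounds))
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS_free <- file.path(config$out_dir, "manifest.json")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(config = unclass(config),
             package_version = manifest$package_version,
             timings = manifest$timings),
        saveRDS_free, auto_unbox = TRUE, digits = NA)
    }
  }
  structure(manifest, class = "run_manifest")
}
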