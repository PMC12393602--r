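# End-to-end orchestration: config-driven runs over fixture-style input
# directories, per-stage TSV outputs, a log with per-stage counts, and a
# final plain-text report.

#' Build a pipeline run configuration
#'
#' @param input_dir directory holding the pipeline inputs in the layout
#'   written by [write_fixture()] (`calls.tsv`, `samples.tsv`,
#'   `pc_matrix.tsv`, `genes.bed`, `pli.tsv`, `genome.tsv`,
#'   `gene_sets/`).
#' @param outdir output directory for stage artifacts.
#' @param window_size,window_step sliding-window geometry in bp.
#' @param n_perm permutations for the min(P) null.
#' @param alpha family-wise error rate for the significance threshold.
#' @param seed master RNG seed, recorded in every output header.
#' @param knn_k,n_pcs ancestry-clustering parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, outdir, window_size = 200e3,
                       window_step = 10e3, n_perm = 1000, alpha = 0.05,
                       seed = 1, knn_k = 15, n_pcs = 6) {
  structure(list(input_dir = input_dir, outdir = outdir,
                 window_size = window_size, window_step = window_step,
                 n_perm = n_perm, alpha = alpha, seed = seed,
                 knn_k = knn_k, n_pcs = n_pcs),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Returns issues as data, not exceptions: an empty character vector
#' means the configuration is runnable; otherwise each element names the
#' offending field.
#'
#' @param config a [run_config()].
#' @return character vector of issues.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  req <- c("calls.tsv", "samples.tsv", "pc_matrix.tsv", "genes.bed",
           "pli.tsv", "genome.tsv")
  if (!dir.exists(config$input_dir %||% "")) {
    issues <- c(issues, sprintf("input_dir: '%s' does not exist",
                                config$input_dir))
  } else {
    for (f in req) {
      p <- file.path(config$input_dir, f)
      if (!file.exists(p)) {
        issues <- c(issues, sprintf("input_dir: missing required file %s", f))
      }
    }
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    issues <- c(issues, "alpha: must lie in (0, 1)")
  }
  if (config$window_step > config$window_size) {
    issues <- c(issues, "window_step: must not exceed window_size")
  }
  if (config$window_step <= 0) {
    issues <- c(issues, "window_step: must be positive")
  }
  if (!is.numeric(config$n_perm) || config$n_perm < 0) {
    issues <- c(issues, "n_perm: must be a nonnegative integer")
  }
  if (!is.numeric(config$seed) || is.na(config$seed)) {
    issues <- c(issues, "seed: must be an integer")
  }
  issues
}

#' Run the full pipeline on an input directory
#'
#' Stages run in order: QC cascade, ancestry clustering and strata
#' construction, global burden suite, then window association for
#' deletions and duplications with min(P) thresholds. Each stage writes
#' a TSV under `outdir`, every output carries a header comment with the
#' package version, seed and a configuration hash, and a run log records
#' per-stage counts. A stage failure halts the run naming the stage;
#' artifacts written before the failure are preserved.
#'
#' @param config a validated [run_config()].
#' @return list with `status` (0 on success), `outdir`, `report`
#'   (character lines), `burden`, `assoc` (per-type `assoc_run`s).
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hashed <- unclass(config)
  hashed$outdir <- NULL  # analysis identity does not depend on where output lands
  cfg_hash <- fnv1a_hash(paste(deparse(hashed), collapse = ""))
  hdr <- c(sprintf("rarecnv %s", as.character(utils::packageVersion("rarecnv"))),
           sprintf("seed=%s", config$seed),
           sprintf("config_hash=%s", cfg_hash))
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste0("# ", hdr), log_lines,
                   sprintf("FAILED at stage '%s': %s", name,
                           conditionMessage(e))),
                 file.path(config$outdir, "run.log"))
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  write_stage_tsv <- function(df, file) {
    con <- file(file.path(config$outdir, file), "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  inputs <- stage("read_inputs", read_fixture(config$input_dir))
  log_add("inputs: %d samples, %d raw calls", nrow(inputs$samples),
          nrow(inputs$calls))

  qc <- stage("qc", run_qc_cascade(inputs$samples, inputs$calls))
  write_stage_tsv(qc$report, "qc_report.tsv")
  for (i in seq_len(nrow(qc$report))) {
    log_add("qc/%s: %d in, %d removed, %d retained", qc$report$stage[i],
            qc$report$n_in[i], qc$report$removed[i], qc$report$retained[i])
  }

  strata <- stage("strata", {
    labels <- cluster_ancestry(inputs$pc, n_pcs = config$n_pcs,
                               knn_k = min(config$knn_k,
                                           nrow(qc$samples) - 1),
                               seed = substream_seed(config$seed, 11L))
    build_strata(qc$samples, labels)
  })
  write_stage_tsv(strata$assignment, "strata.tsv")
  log_add("strata: %d retained strata, %d samples in, %d dropped",
          nrow(strata$strata), nrow(strata$assignment), nrow(strata$dropped))

  burden <- stage("burden", run_burden_suite(
    qc$samples, qc$analysis_grade, inputs$genes, inputs$gene_sets,
    strata = strata))
  write_stage_tsv(burden, "burden.tsv")
  log_add("burden: %d metric x model rows", nrow(burden))

  windows <- make_windows(inputs$genome, config$window_size,
                          config$window_step)
  assoc <- list()
  for (ty in CNV_TYPES) {
    assoc[[ty]] <- stage(paste0("assoc_", ty), run_association(
      qc$analysis_grade, windows, strata$assignment, cnv_type = ty,
      mode = "window", n_perm = config$n_perm, alpha = config$alpha,
      seed = substream_seed(config$seed, 100L + match(ty, CNV_TYPES))))
    write_association_results(assoc[[ty]],
                              file.path(config$outdir,
                                        sprintf("assoc_%s.tsv", ty)),
                              header_lines = hdr)
    log_add("assoc_%s: %d windows, lambda %.3f, threshold %.4g", ty,
            nrow(assoc[[ty]]$results), assoc[[ty]]$lambda,
            assoc[[ty]]$threshold)
  }

  report <- c(
    hdr,
    "",
    "== burden ==",
    utils::capture.output(print(burden, row.names = FALSE)),
    ""
  )
  for (ty in CNV_TYPES) {
    r <- assoc[[ty]]$results
    top <- head(r[order(r$p), ], 5)
    report <- c(report,
                sprintf("== association (%s windows) ==", ty),
                sprintf("threshold = %.4g, lambda = %.3f",
                        assoc[[ty]]$threshold, assoc[[ty]]$lambda),
                utils::capture.output(print(top, row.names = FALSE)),
                "")
  }
  writeLines(report, file.path(config$outdir, "report.txt"))
  writeLines(c(paste0("# ", hdr), log_lines),
             file.path(config$outdir, "run.log"))
  list(status = 0L, outdir = config$outdir, report = report,
       burden = burden, assoc = assoc, strata = strata, qc = qc)
}
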