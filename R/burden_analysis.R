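# Global CNV burden pipeline: per-sample burden metrics over CNV classes
# (type, size, genic status, pLI constraint bins, gene sets, singletons),
# tested with both the covariate-adjusted logistic model and stratified
# CMH carrier tests; plus gene-set Fisher tests, call-size comparisons,
# leave-one-out sensitivity, and known-CNV catalog matching.

#' Define a burden metric
#'
#' A burden metric counts, per sample, the analysis-grade calls
#' satisfying every configured predicate.
#'
#' @param name metric label.
#' @param cnv_types subset of `c("DEL", "DUP")`.
#' @param size_range optional `(lo, hi]` length bounds in bp (`Inf`
#'   allowed as `hi`).
#' @param genic_filter `"any"`, `"genic"` (>= 1 coding base overlapped)
#'   or `"nongenic"`.
#' @param pli_bin `"none"`, `">0.9"`, `">0.995"` or `"<0.9"` — the call
#'   must overlap >= 1 coding base of >= 1 gene in the pLI bin.
#' @param gene_set optional gene-set id; the call must overlap >= 1
#'   coding base of a member gene.
#' @param singleton_only count only singleton calls (see
#'   [mark_singletons()]).
#' @return list of class `burden_spec`.
#' @export
burden_spec <- function(name, cnv_types = c("DEL", "DUP"), size_range = NULL,
                        genic_filter = c("any", "genic", "nongenic"),
                        pli_bin = c("none", ">0.9", ">0.995", "<0.9"),
                        gene_set = NULL, singleton_only = FALSE) {
  genic_filter <- match.arg(genic_filter)
  pli_bin <- match.arg(pli_bin)
  stopifnot(all(cnv_types %in% CNV_TYPES))
  if (!is.null(size_range)) {
    if (length(size_range) != 2 || !(size_range[1] < size_range[2])) {
      stop("size_range must be (lo, hi] with lo < hi", call. = FALSE)
    }
  }
  structure(list(name = name, cnv_types = cnv_types, size_range = size_range,
                 genic_filter = genic_filter, pli_bin = pli_bin,
                 gene_set = gene_set, singleton_only = singleton_only),
            class = "burden_spec")
}

#' Default global burden metric battery
#'
#' The battery mirrors a standard rare-CNV burden analysis: all calls,
#' per-type, very large (> 1 Mb), genic/non-genic, constrained-gene
#' (pLI > 0.9 and > 0.995) deletions, and singletons.
#'
#' @return named list of [burden_spec()]s.
#' @export
default_burden_specs <- function() {
  specs <- list(
    burden_spec("all"),
    burden_spec("del", "DEL"),
    burden_spec("dup", "DUP"),
    burden_spec("gt1mb", size_range = c(1e6, Inf)),
    burden_spec("genic", genic_filter = "genic"),
    burden_spec("nongenic", genic_filter = "nongenic"),
    burden_spec("del_pli_gt0.9", "DEL", pli_bin = ">0.9"),
    burden_spec("del_pli_gt0.995", "DEL", pli_bin = ">0.995"),
    burden_spec("singleton", singleton_only = TRUE)
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Mark singleton calls
#'
#' A call is a singleton when no other sample in the callset carries a
#' matching call under the locus-identity rule (same type, >= `min_recip`
#' reciprocal overlap; default 50%).
#'
#' @param calls a CNV call table.
#' @param min_recip reciprocal-overlap fraction.
#' @return logical vector, one element per call.
#' @export
mark_singletons <- function(calls, min_recip = 0.5) {
  carrier_count_per_call(validate_cnv_calls(calls), min_recip) == 1
}

#' Per-sample burden counts under a metric
#'
#' @param calls analysis-grade CNV calls.
#' @param samples a sample table (defines the output order; samples with
#'   no matching call count 0).
#' @param genes a gene-model table (needed for genic/pLI/gene-set
#'   predicates).
#' @param gene_sets named list of gene-id character vectors.
#' @param spec a [burden_spec()].
#' @return named numeric vector of per-sample counts.
#' @export
compute_burden <- function(calls, samples, genes = NULL, gene_sets = list(),
                           spec = burden_spec("all")) {
  calls <- validate_cnv_calls(calls)
  keep <- calls$cnv_type %in% spec$cnv_types
  if (!is.null(spec$size_range)) {
    keep <- keep & calls$length > spec$size_range[1] &
      calls$length <= spec$size_range[2]
  }
  needs_genes <- spec$genic_filter != "any" || spec$pli_bin != "none" ||
    !is.null(spec$gene_set)
  if (needs_genes && is.null(genes)) {
    stop("spec '", spec$name, "' needs a gene annotation", call. = FALSE)
  }
  if (spec$genic_filter != "any") {
    genic <- coding_overlap_bp(calls, genes) >= 1
    keep <- keep & if (spec$genic_filter == "genic") genic else !genic
  }
  if (spec$pli_bin != "none") {
    bin_genes <- switch(spec$pli_bin,
                        ">0.9" = genes[!is.na(genes$pli) & genes$pli > 0.9, ],
                        ">0.995" = genes[!is.na(genes$pli) & genes$pli > 0.995, ],
                        "<0.9" = genes[!is.na(genes$pli) & genes$pli < 0.9, ])
    keep <- keep & coding_overlap_bp(calls, bin_genes) >= 1
  }
  if (!is.null(spec$gene_set)) {
    if (!spec$gene_set %in% names(gene_sets)) {
      stop("unknown gene set id: ", spec$gene_set, call. = FALSE)
    }
    member <- genes[genes$gene_id %in% gene_sets[[spec$gene_set]], ]
    keep <- keep & coding_overlap_bp(calls, member) >= 1
  }
  if (spec$singleton_only) {
    keep <- keep & mark_singletons(calls)
  }
  counts <- table(factor(calls$sample_id[keep], levels = samples$sample_id))
  setNames(as.numeric(counts), samples$sample_id)
}

#' Run the global burden test battery
#'
#' For every metric the suite emits two complementary tests: the
#' covariate-adjusted logistic regression odds ratio per unit burden
#' ([fit_burden_logistic()]) and the stratified CMH carrier test
#' (carrier = at least one call matching the metric). A metric whose
#' kernel errors (e.g. a degenerate carrier table) is flagged in the
#' `note` column and the remaining metrics still run.
#'
#' @param samples a sample table.
#' @param calls analysis-grade CNV calls.
#' @param genes gene-model table.
#' @param gene_sets named list of gene-id vectors.
#' @param specs list of [burden_spec()]s (default battery:
#'   [default_burden_specs()]).
#' @param strata a `strata` object from [build_strata()].
#' @return data.frame with one row per (metric, model): `spec`, `model`
#'   (`"logistic"`/`"cmh"`), `or`, `ci_low`, `ci_high`, `p`,
#'   `n_case_carriers`, `n_control_carriers`, `note`.
#' @export
run_burden_suite <- function(samples, calls, genes = NULL,
                             gene_sets = list(),
                             specs = default_burden_specs(), strata) {
  assignment <- strata$assignment
  in_strata <- samples$sample_id %in% assignment$sample_id
  rows <- list()
  for (spec in specs) {
    burden <- tryCatch(
      compute_burden(calls, samples, genes, gene_sets, spec),
      error = function(e) e
    )
    if (inherits(burden, "error")) {
      rows[[length(rows) + 1]] <- burden_row(spec$name, "logistic",
                                             note = conditionMessage(burden))
      rows[[length(rows) + 1]] <- burden_row(spec$name, "cmh",
                                             note = conditionMessage(burden))
      next
    }
    fit <- tryCatch(fit_burden_logistic(samples, burden, assignment),
                    error = function(e) e)
    rows[[length(rows) + 1]] <- if (inherits(fit, "error")) {
      burden_row(spec$name, "logistic", note = conditionMessage(fit))
    } else {
      burden_row(spec$name, "logistic", or = fit$or, ci_low = fit$ci_low,
                 ci_high = fit$ci_high, p = fit$p)
    }
    carrier <- burden[assignment$sample_id] >= 1
    tab <- aggregate_carriers(carrier, assignment)
    cm <- tryCatch(cmh_test(tab), error = function(e) e)
    rows[[length(rows) + 1]] <- if (inherits(cm, "error")) {
      burden_row(spec$name, "cmh", note = conditionMessage(cm))
    } else {
      burden_row(spec$name, "cmh", or = cm$or_mh, ci_low = cm$ci_low,
                 ci_high = cm$ci_high, p = cm$p,
                 n_case_carriers = sum(tab$case_carriers),
                 n_control_carriers = sum(tab$control_carriers),
                 note = if (cm$degenerate) "degenerate" else "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

burden_row <- function(spec, model, or = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p = NA_real_,
                       n_case_carriers = NA_integer_,
                       n_control_carriers = NA_integer_, note = "") {
  data.frame(spec = spec, model = model, or = or, ci_low = ci_low,
             ci_high = ci_high, p = p, n_case_carriers = n_case_carriers,
             n_control_carriers = n_control_carriers, note = note,
             stringsAsFactors = FALSE)
}

# carrier: logical named by assignment$sample_id order
aggregate_carriers <- function(carrier, assignment) {
  pieces <- lapply(unique(assignment$stratum_id), function(s) {
    idx <- which(assignment$stratum_id == s)
    st <- assignment$status[idx]
    data.frame(case_carriers = sum(carrier[idx][st == "case"]),
               case_total = sum(st == "case"),
               control_carriers = sum(carrier[idx][st == "control"]),
               control_total = sum(st == "control"))
  })
  do.call(rbind, pieces)
}

#' Gene-set carrier Fisher test
#'
#' Builds the 2x2 case/control carrier table for samples with at least
#' one call of `cnv_type` overlapping coding bases of any member gene,
#' and runs [fisher_or()].
#'
#' @param samples a sample table.
#' @param calls analysis-grade CNV calls.
#' @param genes gene-model table.
#' @param gene_sets named list of gene-id vectors.
#' @param gene_set the gene-set id to test.
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @return list with `or`, `p`, `n_case_carriers`, `n_control_carriers`.
#' @export
geneset_carrier_fisher <- function(samples, calls, genes, gene_sets,
                                   gene_set, cnv_type = "DEL") {
  spec <- burden_spec(paste0("set_", gene_set), cnv_types = cnv_type,
                      gene_set = gene_set)
  burden <- compute_burden(calls, samples, genes, gene_sets, spec)
  carrier <- burden >= 1
  is_case <- samples$status == "case"
  a <- sum(carrier & is_case); b <- sum(!carrier & is_case)
  c0 <- sum(carrier & !is_case); d <- sum(!carrier & !is_case)
  if (a + c0 == 0) {
    stop("gene set '", gene_set, "': no ", cnv_type,
         " carriers in the cohort; carrier table is degenerate",
         call. = FALSE)
  }
  res <- tryCatch(fisher_or(a, b, c0, d), error = function(e) {
    stop("gene set '", gene_set, "': ", conditionMessage(e), call. = FALSE)
  })
  list(or = res$or, p = res$p, n_case_carriers = a, n_control_carriers = c0)
}

#' Compare call sizes between cases and controls
#'
#' Two-sided Wilcoxon rank-sum test on call lengths grouped by the
#' carrier's case/control status. Apply any subset filter (e.g. > 1 Mb)
#' upstream.
#'
#' @param calls a CNV call table.
#' @param samples a sample table (maps calls to status).
#' @return list with `statistic` (rank-sum W) and `p`.
#' @export
compare_call_sizes <- function(calls, samples) {
  status <- samples$status[match(calls$sample_id, samples$sample_id)]
  if (!any(status == "case", na.rm = TRUE) ||
      !any(status == "control", na.rm = TRUE)) {
    stop("both case and control calls are required", call. = FALSE)
  }
  wt <- wilcox.test(calls$length[status == "case"],
                    calls$length[status == "control"], exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Leave-one-dataset-out sensitivity analysis
#'
#' Re-runs a burden/association summary excluding each dataset in turn,
#' rebuilding strata each time. A run whose exclusion empties all strata
#' is flagged in `note` and the remaining runs continue.
#'
#' @param samples a sample table spanning >= 2 datasets.
#' @param calls a CNV call table.
#' @param runner `function(samples, calls, strata)` returning a one-row
#'   data.frame of summary statistics.
#' @param ... passed to [build_strata()].
#' @return data.frame with one row per held-out dataset (column
#'   `excluded_dataset`, plus the runner's columns and `note`).
#' @export
leave_one_out <- function(samples, calls, runner, ...) {
  datasets <- unique(samples$dataset_id)
  if (length(datasets) < 2) stop("need >= 2 datasets", call. = FALSE)
  rows <- lapply(datasets, function(ds) {
    sub_s <- samples[samples$dataset_id != ds, , drop = FALSE]
    sub_c <- calls[calls$sample_id %in% sub_s$sample_id, , drop = FALSE]
    strata <- build_strata(sub_s, ...)
    if (nrow(strata$strata) == 0) {
      return(data.frame(excluded_dataset = ds, note = "all strata empty",
                        stringsAsFactors = FALSE))
    }
    out <- runner(sub_s, sub_c, strata)
    out$excluded_dataset <- ds
    out$note <- ""
    out
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}

#' Match calls against a known-CNV catalog
#'
#' A call hits a catalog locus when it has the same CNV type and covers
#' at least `min_cov` (default 50%) of the catalog locus.
#'
#' @param calls a CNV call table.
#' @param catalog data.frame with `locus_id`, `chrom`, `start`, `end`,
#'   `cnv_type` (e.g. a curated neurodevelopmental-CNV list read from a
#'   BED + type column).
#' @param min_cov fraction of the catalog locus that must be covered.
#' @return data.frame of hits: `call_row`, `sample_id`, `locus_id`.
#' @export
match_known_cnvs <- function(calls, catalog, min_cov = 0.5) {
  calls <- validate_cnv_calls(calls)
  catalog$chrom <- norm_chrom(catalog$chrom)
  hits <- list()
  for (i in seq_len(nrow(catalog))) {
    same <- which(calls$chrom == catalog$chrom[i] &
                    calls$cnv_type == catalog$cnv_type[i])
    if (!length(same)) next
    ov <- pmax(0, pmin(calls$end[same], catalog$end[i]) -
                 pmax(calls$start[same], catalog$start[i]))
    need <- min_cov * (catalog$end[i] - catalog$start[i])
    hit <- same[ov >= need]
    if (length(hit)) {
      hits[[length(hits) + 1]] <- data.frame(
        call_row = hit, sample_id = calls$sample_id[hit],
        locus_id = catalog$locus_id[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(call_row = integer(0), sample_id = character(0),
                      locus_id = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
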