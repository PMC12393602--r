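# Gene-based and sliding-window carrier association across strata, with
# external count-table merging and min(P) genome-wide significance.

#' Generate sliding windows over a genome
#'
#' Per chromosome, fixed-size windows start at 0 and advance by `step`;
#' only fully contained windows are emitted. A chromosome shorter than
#' `size` yields a single whole-chromosome window so that toy genomes
#' remain testable.
#'
#' @param genome a [genome_layout()] data.frame (`chrom`, `length`).
#' @param size window size in bp (default 200 kb).
#' @param step step between window starts in bp (default 10 kb).
#' @return data.frame of half-open windows: `locus_id`, `chrom`, `start`,
#'   `end`.
#' @examples
#' nrow(make_windows(genome_layout("1", 1e6)))  # 81
#' @export
make_windows <- function(genome, size = 200e3, step = 10e3) {
  if (!(size >= step && step > 0)) {
    stop("need size >= step > 0", call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    ch <- genome$chrom[i]
    if (L < size) {
      starts <- 0
      ends <- L
    } else {
      starts <- seq(0, L - size, by = step)
      ends <- starts + size
    }
    data.frame(locus_id = sprintf("%s:%.0f-%.0f", ch, starts, ends),
               chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# Locus x sample carrier matrix. mode "window": any >= 1 bp overlap
# between a call of the given type and the window. mode "gene": the call
# must overlap >= 1 coding base of the gene (loci = gene models).
carrier_matrix <- function(calls, loci, sample_ids, cnv_type,
                           mode = c("window", "gene")) {
  mode <- match.arg(mode)
  calls <- calls[calls$cnv_type == cnv_type, , drop = FALSE]
  if (mode == "gene") {
    locus_ids <- unique(loci$gene_id)
    ivl <- data.frame(locus_id = loci$gene_id, chrom = loci$chrom,
                      start = loci$start, end = loci$end,
                      stringsAsFactors = FALSE)
  } else {
    locus_ids <- loci$locus_id
    ivl <- loci
  }
  M <- matrix(FALSE, length(locus_ids), length(sample_ids),
              dimnames = list(locus_ids, sample_ids))
  unknown <- setdiff(calls$sample_id, sample_ids)
  calls <- calls[!calls$sample_id %in% unknown, , drop = FALSE]
  for (ch in intersect(unique(ivl$chrom), unique(calls$chrom))) {
    li <- which(ivl$chrom == ch)
    ci <- which(calls$chrom == ch)
    lr <- as_iranges0(ivl$start[li], ivl$end[li])
    cr <- as_iranges0(calls$start[ci], calls$end[ci])
    hits <- IRanges::findOverlaps(cr, lr)
    if (length(hits) == 0) next
    row_id <- ivl$locus_id[li][S4Vectors::subjectHits(hits)]
    col_id <- calls$sample_id[ci][S4Vectors::queryHits(hits)]
    M[cbind(match(row_id, locus_ids), match(col_id, sample_ids))] <- TRUE
  }
  M
}

#' Per-locus stratified carrier counts
#'
#' Counts, per locus and stratum, the case and control samples carrying
#' at least one call of `cnv_type` hitting the locus (a sample counts
#' once regardless of how many of its calls hit). In `"gene"` mode only
#' calls overlapping coding bases count; in `"window"` mode any >= 1 bp
#' overlap with the window counts.
#'
#' @param calls analysis-grade CNV calls.
#' @param loci windows from [make_windows()] (window mode) or a
#'   gene-model table (gene mode).
#' @param assignment stratum assignment (`sample_id`, `stratum_id`,
#'   `status`).
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @param mode `"window"` or `"gene"`.
#' @return a [stratified_counts()] data.frame.
#' @export
carrier_counts <- function(calls, loci, assignment, cnv_type,
                           mode = c("window", "gene")) {
  mode <- match.arg(mode)
  M <- carrier_matrix(calls, loci, assignment$sample_id, cnv_type, mode)
  counts_from_carrier_matrix(M, assignment, cnv_type)
}

counts_from_carrier_matrix <- function(M, assignment, cnv_type) {
  strata_ids <- unique(assignment$stratum_id)
  pieces <- lapply(strata_ids, function(s) {
    idx <- which(assignment$stratum_id == s)
    case_idx <- idx[assignment$status[idx] == "case"]
    ctrl_idx <- idx[assignment$status[idx] == "control"]
    data.frame(locus_id = rownames(M), cnv_type = cnv_type, stratum_id = s,
               case_carriers = as.integer(rowSums(M[, case_idx, drop = FALSE])),
               case_total = length(case_idx),
               control_carriers = as.integer(rowSums(M[, ctrl_idx, drop = FALSE])),
               control_total = length(ctrl_idx),
               stringsAsFactors = FALSE)
  })
  stratified_counts(do.call(rbind, pieces))
}

#' Merge internal and external stratified count tables
#'
#' Concatenates per-locus strata contributed by external cohorts (which
#' share only counts, not individual-level data) onto the internal count
#' table. External stratum ids must not collide with internal ones, and
#' each external stratum must report consistent arm totals across loci.
#'
#' @param internal,external [stratified_counts()] tables.
#' @return the merged [stratified_counts()] table.
#' @export
merge_external_counts <- function(internal, external) {
  internal <- stratified_counts(internal)
  if (is.null(external) || nrow(external) == 0) return(internal)
  external <- stratified_counts(external)
  clash <- intersect(unique(internal$stratum_id), unique(external$stratum_id))
  if (length(clash)) {
    stop("external stratum id(s) collide with internal strata: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  for (s in unique(external$stratum_id)) {
    sub <- external[external$stratum_id == s, ]
    if (length(unique(sub$case_total)) > 1 ||
        length(unique(sub$control_total)) > 1) {
      stop("external stratum ", s,
           " reports conflicting arm totals across loci", call. = FALSE)
    }
  }
  stratified_counts(rbind(internal, external))
}

#' Stratified CMH association with min(P) genome-wide significance
#'
#' The locus-association driver for one test family (gene or window loci,
#' one CNV type): builds the per-locus stratified carrier tables, runs
#' the CMH test at every locus, derives the empirical genome-wide
#' significance threshold and FWER-adjusted p-values from a within-stratum
#' label-permutation min(P) null, doubles the adjusted p-values to account
#' for running the scan once per CNV type, and reports the genomic
#' inflation factor of the raw p-values. External count-only strata enter
#' every observed test but are held fixed during permutation (their labels
#' cannot be permuted).
#'
#' @param calls analysis-grade CNV calls.
#' @param loci windows ([make_windows()]) or gene models, per `mode`.
#' @param assignment stratum assignment (`sample_id`, `stratum_id`,
#'   `status`).
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @param mode `"window"` or `"gene"`.
#' @param external optional [stratified_counts()] external table for the
#'   same loci and CNV type.
#' @param n_perm permutations for the min(P) null (`0` = observed only).
#' @param alpha FWER defining the significance threshold.
#' @param seed RNG seed.
#' @param two_rounds double the FWER-adjusted p-values (one scan per CNV
#'   type); default `TRUE`.
#' @return list of class `assoc_run`: `results` (per-locus data.frame
#'   with carrier counts, MH odds ratio and CI, raw/adjusted p),
#'   `null` (the [minp_permutation()] object), `threshold`, `lambda`,
#'   `cnv_type`, `mode`, `n_perm`, `seed`.
#' @export
run_association <- function(calls, loci, assignment, cnv_type,
                            mode = c("window", "gene"), external = NULL,
                            n_perm = 1000, alpha = 0.05, seed = 1,
                            two_rounds = TRUE) {
  mode <- match.arg(mode)
  M <- carrier_matrix(calls, loci, assignment$sample_id, cnv_type, mode)
  if (nrow(M) == 0) stop("no loci to test", call. = FALSE)
  if (!is.null(external)) {
    external <- external[external$cnv_type == cnv_type, , drop = FALSE]
  }
  null <- minp_permutation(M, assignment, n_perm = n_perm, alpha = alpha,
                           seed = seed, external = external)
  tab <- counts_from_carrier_matrix(M, assignment, cnv_type)
  if (!is.null(external) && nrow(external)) {
    tab <- merge_external_counts(tab, external)
  }
  # per-locus MH OR and CI from the merged table (same kernel as the null)
  or_rows <- lapply(split(tab, tab$locus_id), function(g) {
    r <- cmh_test(g)
    data.frame(locus_id = g$locus_id[1],
               n_case_carriers = sum(g$case_carriers),
               n_control_carriers = sum(g$control_carriers),
               or = r$or_mh, ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  })
  or_df <- do.call(rbind, or_rows)
  results <- merge(null$observed, or_df, by = "locus_id", sort = FALSE)
  results <- results[match(rownames(M), results$locus_id), , drop = FALSE]
  if (n_perm > 0) {
    results$p_adjusted <- null$p_adjusted
    results$p_final <- if (two_rounds) {
      adjust_two_rounds(null$p_adjusted)
    } else {
      null$p_adjusted
    }
  } else {
    results$p_adjusted <- NA_real_
    results$p_final <- NA_real_
  }
  lambda <- genomic_lambda(results$p)
  rownames(results) <- NULL
  structure(list(results = results, null = null,
                 threshold = null$threshold, lambda = lambda,
                 cnv_type = cnv_type, mode = mode,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "assoc_run")
}

#' @export
print.assoc_run <- function(x, ...) {
  cat(sprintf("Association run (%s, %s mode): %d loci, lambda = %.3f\n",
              x$cnv_type, x$mode, nrow(x$results), x$lambda))
  if (x$n_perm > 0) {
    cat(sprintf("min(P) threshold (alpha = %.2f, %d perms): %.3g\n",
                x$null$alpha, x$n_perm, x$threshold))
  }
  top <- x$results[order(x$results$p), ]
  print(head(top, 5))
  invisible(x)
}

#' Write association results as TSV
#'
#' Fixed column order: `locus_id`, `cnv_type`, `n_case_carriers`,
#' `n_control_carriers`, `or`, `ci_low`, `ci_high`, `p`, `p_adjusted`,
#' `p_final`.
#'
#' @param run an `assoc_run` from [run_association()].
#' @param path output path.
#' @param header_lines optional comment lines (prefixed `#`) written
#'   before the table.
#' @return `path`, invisibly.
#' @export
write_association_results <- function(run, path, header_lines = character(0)) {
  df <- run$results
  df$cnv_type <- run$cnv_type
  df <- df[c("locus_id", "cnv_type", "n_case_carriers", "n_control_carriers",
             "or", "ci_low", "ci_high", "p", "p_adjusted", "p_final")]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
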