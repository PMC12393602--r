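# Sample- and call-level QC filter cascade: raw calls -> qualifying calls
# -> analysis-grade calls, plus the filter profile used by external
# biobank-style callsets (merging, frequency and blacklist filters).

#' Define a QC filter profile
#'
#' Bundles the thresholds of the filter cascade for one array group or
#' external callset. Defaults correspond to the 610K/GSA-style profile:
#' at most 30 raw calls per sample summing to at most 20 Mb; qualifying
#' calls span >= 10 probes with length in [30 kb, 20 Mb] on autosomes;
#' analysis-grade calls are additionally > 100 kb with >= 15 probes.
#' Denser arrays (OmniExpress-style) use `max_raw_calls = 15`.
#'
#' @param profile_name label for reports.
#' @param max_raw_calls maximum raw CNV calls per retained sample.
#' @param max_total_bp maximum summed raw call length per sample (bp).
#' @param min_probes_qualifying,min_len_qualifying,max_len_qualifying
#'   qualifying-call thresholds (probes; bp, inclusive bounds).
#' @param min_len_analysis analysis-grade length threshold (strictly
#'   greater than).
#' @param min_probes_analysis analysis-grade probe threshold (at least).
#' @param outlier_sd_multiplier intensity-metric outlier cut in SD units
#'   around the per-dataset median.
#' @param max_frequency optional carrier-frequency cap for
#'   [filter_by_frequency()]; `NA` disables frequency filtering.
#' @return a list of class `qc_profile`.
#' @export
qc_profile <- function(profile_name = "610K",
                       max_raw_calls = 30,
                       max_total_bp = 20e6,
                       min_probes_qualifying = 10,
                       min_len_qualifying = 30e3,
                       max_len_qualifying = 20e6,
                       min_len_analysis = 100e3,
                       min_probes_analysis = 15,
                       outlier_sd_multiplier = 3,
                       max_frequency = NA_real_) {
  if (!(min_len_qualifying < max_len_qualifying)) {
    stop("min_len_qualifying must be < max_len_qualifying", call. = FALSE)
  }
  thresholds <- c(max_raw_calls, max_total_bp, min_probes_qualifying,
                  min_len_qualifying, max_len_qualifying, min_len_analysis,
                  min_probes_analysis, outlier_sd_multiplier)
  if (any(thresholds <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(list(profile_name = profile_name,
                 max_raw_calls = max_raw_calls,
                 max_total_bp = max_total_bp,
                 min_probes_qualifying = min_probes_qualifying,
                 min_len_qualifying = min_len_qualifying,
                 max_len_qualifying = max_len_qualifying,
                 min_len_analysis = min_len_analysis,
                 min_probes_analysis = min_probes_analysis,
                 outlier_sd_multiplier = outlier_sd_multiplier,
                 max_frequency = max_frequency),
            class = "qc_profile")
}

#' Default per-array-group QC profiles
#'
#' OmniExpress-style arrays allow at most 15 raw calls per sample; 610K
#' and GSA arrays allow 30; all cap total raw call length at 20 Mb.
#'
#' @return named list of [qc_profile()] objects keyed by array group.
#' @export
default_qc_profiles <- function() {
  list(
    OmniExpress = qc_profile("OmniExpress", max_raw_calls = 15),
    `610K` = qc_profile("610K", max_raw_calls = 30),
    GSA = qc_profile("GSA", max_raw_calls = 30)
  )
}

#' Flag per-dataset intensity-metric outliers
#'
#' Within each dataset, a sample is flagged when any of its three
#' intensity metrics (LRR SD, BAF drift, GCWF) lies more than
#' `k` standard deviations from the dataset median of that metric.
#' Datasets with fewer than 3 samples are skipped with a warning.
#'
#' @param samples a sample table ([sample_table()]).
#' @param k SD multiplier (default 3).
#' @return character vector of flagged `sample_id`s.
#' @export
flag_intensity_outliers <- function(samples, k = 3) {
  flagged <- character(0)
  for (ds in unique(samples$dataset_id)) {
    sub <- samples[samples$dataset_id == ds, ]
    if (nrow(sub) < 3) {
      warning("dataset ", ds, " has < 3 samples; no outlier flags applied")
      next
    }
    hit <- rep(FALSE, nrow(sub))
    for (metric in c("lrr_sd", "baf_drift", "gcwf")) {
      x <- sub[[metric]]
      s <- sd(x)
      if (is.na(s) || s == 0) next
      hit <- hit | (abs(x - median(x)) > k * s)
    }
    flagged <- c(flagged, sub$sample_id[hit])
  }
  flagged
}

#' Apply per-array-group raw-call-count and footprint limits
#'
#' A sample is retained when its raw CNV call count does not exceed its
#' array group's `max_raw_calls` and its summed raw call length does not
#' exceed `max_total_bp`. Counts and footprints are computed from `calls`
#' when supplied, otherwise taken from the `n_cnv_raw` / `total_cnv_bp`
#' sample columns.
#'
#' @param samples a sample table.
#' @param calls optional raw CNV call table used to count calls per sample.
#' @param profiles named list of [qc_profile()]s keyed by `array_group`.
#' @return character vector of retained `sample_id`s.
#' @export
apply_raw_call_limits <- function(samples, calls = NULL,
                                  profiles = default_qc_profiles()) {
  missing_prof <- setdiff(unique(samples$array_group), names(profiles))
  if (length(missing_prof)) {
    stop("no QC profile for array group(s): ",
         paste(missing_prof, collapse = ", "), call. = FALSE)
  }
  if (!is.null(calls)) {
    n_raw <- table(factor(calls$sample_id, levels = samples$sample_id))
    bp <- tapply(calls$length, factor(calls$sample_id, levels = samples$sample_id),
                 sum, default = 0)
    n_raw <- as.numeric(n_raw)
    bp <- as.numeric(bp)
  } else {
    n_raw <- samples$n_cnv_raw
    bp <- ifelse(is.na(samples$total_cnv_bp), 0, samples$total_cnv_bp)
  }
  max_calls <- vapply(samples$array_group,
                      function(g) profiles[[g]]$max_raw_calls, numeric(1))
  max_bp <- vapply(samples$array_group,
                   function(g) profiles[[g]]$max_total_bp, numeric(1))
  samples$sample_id[n_raw <= max_calls & bp <= max_bp]
}

#' Filter to qualifying CNV calls
#'
#' Retains calls spanning at least `min_probes_qualifying` probes, with
#' length between `min_len_qualifying` and `max_len_qualifying`
#' (inclusive), on autosomes 1-22.
#'
#' @param calls a CNV call table.
#' @param profile a [qc_profile()].
#' @return the retained calls.
#' @export
filter_qualifying <- function(calls, profile = qc_profile()) {
  calls <- validate_cnv_calls(calls)
  keep <- calls$n_probes >= profile$min_probes_qualifying &
    calls$length >= profile$min_len_qualifying &
    calls$length <= profile$max_len_qualifying &
    calls$autosomal
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter to analysis-grade CNV calls
#'
#' Retains qualifying calls strictly longer than `min_len_analysis`
#' (default 100 kb) spanning at least `min_probes_analysis` probes
#' (default 15). These are the calls entering burden and association.
#'
#' @inheritParams filter_qualifying
#' @return the retained calls.
#' @export
filter_analysis_grade <- function(calls, profile = qc_profile()) {
  calls <- validate_cnv_calls(calls)
  keep <- calls$length > profile$min_len_analysis &
    calls$n_probes >= profile$min_probes_analysis
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent same-type calls within a sample
#'
#' Within each (sample, chromosome, CNV type) group, neighbouring calls
#' are merged when the intervening gap is smaller than `max_gap_frac`
#' (default 20%) of the total length of the merged call. The scan runs
#' left to right and repeats to a fixed point; probe counts are summed.
#'
#' @param calls a CNV call table.
#' @param max_gap_frac gap threshold as a fraction of the merged span.
#' @return the merged call table.
#' @export
merge_adjacent_calls <- function(calls, max_gap_frac = 0.2) {
  calls <- validate_cnv_calls(calls)
  if (nrow(calls) == 0) return(calls)
  key <- interaction(calls$sample_id, calls$chrom, calls$cnv_type, drop = TRUE)
  pieces <- lapply(split(calls, key), function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < nrow(g)) {
        gap <- g$start[i + 1] - g$end[i]
        span <- max(g$end[i], g$end[i + 1]) - g$start[i]
        if (gap < max_gap_frac * span) {
          g$end[i] <- max(g$end[i], g$end[i + 1])
          g$n_probes[i] <- g$n_probes[i] + g$n_probes[i + 1]
          g$copy_number[i] <- NA_integer_
          g <- g[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else {
          i <- i + 1
        }
      }
      if (!merged_any) break
    }
    g
  })
  out <- do.call(rbind, pieces)
  validate_cnv_calls(out[order(out$sample_id, out$chrom, out$start), ,
                         drop = FALSE])
}

# Distinct samples carrying a call matching each input call under the
# reciprocal-overlap, same-type locus-identity rule (the call's own
# sample included).
carrier_count_per_call <- function(calls, min_recip = 0.5) {
  n <- nrow(calls)
  counts <- integer(n)
  if (n == 0) return(counts)
  key <- interaction(calls$chrom, calls$cnv_type, drop = TRUE)
  idx_groups <- split(seq_len(n), key)
  for (idx in idx_groups) {
    r <- as_iranges0(calls$start[idx], calls$end[idx])
    hits <- IRanges::findOverlaps(r, r)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- pmin(IRanges::end(r)[qi], IRanges::end(r)[si]) -
      pmax(IRanges::start(r)[qi], IRanges::start(r)[si]) + 1L
    len_q <- calls$length[idx][qi]
    len_s <- calls$length[idx][si]
    ok <- w >= min_recip * len_q & w >= min_recip * len_s
    qi <- qi[ok]; si <- si[ok]
    samp <- calls$sample_id[idx]
    counts[idx] <- vapply(split(samp[si], factor(qi, levels = seq_along(idx))),
                          function(s) length(unique(s)), integer(1))
  }
  counts
}

#' Remove common CNVs by carrier frequency
#'
#' Two same-type calls are treated as the same CNV locus when they share
#' at least `min_recip` reciprocal overlap (default 50%). A call is
#' removed when the number of distinct samples carrying a matching call
#' (itself included) reaches `max_freq * n_samples`.
#'
#' @param calls a CNV call table.
#' @param n_samples number of samples in the callset (denominator).
#' @param max_freq maximum carrier frequency, in (0, 1].
#' @param min_recip reciprocal-overlap fraction defining locus identity.
#' @return the retained calls.
#' @export
filter_by_frequency <- function(calls, n_samples, max_freq = 0.01,
                                min_recip = 0.5) {
  if (!is.numeric(max_freq) || max_freq <= 0 || max_freq > 1) {
    stop("max_freq must lie in (0, 1]", call. = FALSE)
  }
  calls <- validate_cnv_calls(calls)
  counts <- carrier_count_per_call(calls, min_recip)
  out <- calls[counts < max_freq * n_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove calls overlapping blacklisted regions
#'
#' Removes calls overlapping centromere/telomere/blacklist intervals by
#' at least `min_overlap` bases (default: any overlap).
#'
#' @param calls a CNV call table.
#' @param blacklist data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. read from a BED file.
#' @param min_overlap minimum shared bases triggering removal.
#' @return the retained calls.
#' @export
exclude_regions <- function(calls, blacklist, min_overlap = 1) {
  calls <- validate_cnv_calls(calls)
  if (is.null(blacklist) || nrow(blacklist) == 0) return(calls)
  blacklist$chrom <- norm_chrom(blacklist$chrom)
  drop <- rep(FALSE, nrow(calls))
  for (ch in intersect(unique(calls$chrom), unique(blacklist$chrom))) {
    ci <- which(calls$chrom == ch)
    b <- blacklist[blacklist$chrom == ch, ]
    ov <- vapply(ci, function(i) {
      overlap_bp(calls$start[i], calls$end[i], b$start, b$end)
    }, numeric(1))
    drop[ci] <- ov >= min_overlap
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a blacklist BED file
#' @param path BED file (`chrom start end [name]`), no header.
#' @return data.frame with `chrom`, `start`, `end` (and `name` if present).
#' @export
read_blacklist_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df$chrom <- norm_chrom(df$chrom)
  df
}

#' Biobank-style sample QC (intensity bounds plus call-count caps)
#'
#' Retains samples with LRR SD < 0.3, BAF drift < 0.01 and absolute
#' waviness factor < 0.05, at most 50 CNV calls, and no call longer than
#' 20 Mb. This is the external-biobank profile; `abs_wf` must be present.
#'
#' @param samples a sample table with non-missing `abs_wf`.
#' @param calls the samples' CNV calls.
#' @param lrr_sd_max,baf_drift_max,abs_wf_max strict upper intensity bounds.
#' @param max_calls maximum number of calls per retained sample.
#' @param max_call_len maximum single-call length (bp) per retained sample.
#' @return character vector of retained `sample_id`s.
#' @export
biovu_sample_qc <- function(samples, calls, lrr_sd_max = 0.3,
                            baf_drift_max = 0.01, abs_wf_max = 0.05,
                            max_calls = 50, max_call_len = 20e6) {
  if (any(is.na(samples$abs_wf))) {
    stop("abs_wf is required (and missing) for the biobank QC profile",
         call. = FALSE)
  }
  n_calls <- as.numeric(table(factor(calls$sample_id,
                                     levels = samples$sample_id)))
  max_len <- tapply(calls$length, factor(calls$sample_id,
                                         levels = samples$sample_id),
                    max, default = 0)
  keep <- samples$lrr_sd < lrr_sd_max &
    samples$baf_drift < baf_drift_max &
    samples$abs_wf < abs_wf_max &
    n_calls <= max_calls &
    as.numeric(max_len) <= max_call_len
  samples$sample_id[keep]
}

#' Flag CNV-count outliers after rank-based inverse-normal transform
#'
#' Per-sample CNV counts are quantile-normalized (rank-based inverse
#' normal transform) and samples with |z| above `z_max` (default 1.96)
#' are flagged. Optional companion to [biovu_sample_qc()].
#'
#' @param samples a sample table (uses `n_cnv_raw`).
#' @param z_max absolute z-score threshold.
#' @return character vector of flagged `sample_id`s.
#' @export
flag_count_outliers <- function(samples, z_max = 1.96) {
  n <- nrow(samples)
  z <- qnorm((rank(samples$n_cnv_raw, ties.method = "average") - 0.5) / n)
  samples$sample_id[abs(z) > z_max]
}

#' Run the internal-cohort filter cascade with a stage report
#'
#' Applies, in order: intensity-outlier removal, raw call-count/footprint
#' limits, qualifying-call filtering, analysis-grade filtering. Returns
#' the retained samples and calls plus a per-stage report.
#'
#' @param samples a sample table.
#' @param calls a raw CNV call table.
#' @param profiles named list of per-array-group [qc_profile()]s.
#' @return list with `samples`, `qualifying`, `analysis_grade` (call
#'   tables) and `report` (data.frame of stage, n_in, removed, retained).
#' @export
run_qc_cascade <- function(samples, calls, profiles = default_qc_profiles()) {
  report <- list()
  note <- function(stage, n_in, retained) {
    data.frame(stage = stage, n_in = n_in, removed = n_in - retained,
               retained = retained, stringsAsFactors = FALSE)
  }

  out <- flag_intensity_outliers(samples)
  keep_samples <- samples[!samples$sample_id %in% out, , drop = FALSE]
  report$outliers <- note("intensity_outliers", nrow(samples), nrow(keep_samples))

  kept_ids <- apply_raw_call_limits(keep_samples, calls, profiles)
  n_in <- nrow(keep_samples)
  keep_samples <- keep_samples[keep_samples$sample_id %in% kept_ids, , drop = FALSE]
  report$limits <- note("raw_call_limits", n_in, nrow(keep_samples))

  calls_kept <- calls[calls$sample_id %in% keep_samples$sample_id, , drop = FALSE]
  any_profile <- profiles[[1]]
  qual <- filter_qualifying(calls_kept, any_profile)
  report$qualifying <- note("qualifying_calls", nrow(calls_kept), nrow(qual))

  grade <- filter_analysis_grade(qual, any_profile)
  report$analysis <- note("analysis_grade_calls", nrow(qual), nrow(grade))

  list(samples = keep_samples, qualifying = qual, analysis_grade = grade,
       report = do.call(rbind, unname(report)))
}
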