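# Domain tables, readers/writers and interval arithmetic.
#
# All coordinates are internally 0-based half-open (BED convention), so
# length = end - start with no off-by-one cases. 1-based inclusive input
# dialects are converted on ingest.

CNV_TYPES <- c("DEL", "DUP")

#' Construct and validate a CNV call table
#'
#' A CNV call table has one row per called deletion/duplication segment in
#' one sample, with 0-based half-open coordinates. This constructor checks
#' the invariants every downstream stage relies on: `start < end`,
#' `n_probes >= 1` and `cnv_type` in `DEL`/`DUP`. Chromosome tokens are
#' normalized by stripping a leading `"chr"`; non-autosomal rows are kept
#' but flagged in the `autosomal` column (all association and burden stages
#' operate on autosomes 1-22 only).
#'
#' @param sample_id character, sample identifiers.
#' @param chrom chromosome tokens (`"1"`..`"22"`, `"X"`, `"Y"`, with or
#'   without a `"chr"` prefix).
#' @param start,end integer base positions, 0-based half-open.
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @param n_probes positive integer, array probes supporting the call.
#' @param dataset_id dataset/cohort label (recycled if scalar).
#' @param copy_number optional integer copy-number estimate.
#' @return A `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `n_probes`, `dataset_id`, `copy_number`,
#'   `autosomal`, plus a derived `length` column (`end - start`).
#' @examples
#' cnv_calls("S1", "chr2", 50835000, 51160000, "DEL", 45)$length
#' @export
cnv_calls <- function(sample_id, chrom, start, end, cnv_type, n_probes,
                      dataset_id = "internal", copy_number = NA_integer_) {
  calls <- data.frame(
    sample_id = as.character(sample_id),
    chrom = norm_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    cnv_type = as.character(cnv_type),
    n_probes = as.integer(n_probes),
    dataset_id = as.character(dataset_id),
    copy_number = as.integer(copy_number),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(calls)
}

#' Validate a CNV call table
#'
#' Checks the call-table invariants and (re)computes the derived `length`
#' and `autosomal` columns. Called by [cnv_calls()] and the readers;
#' useful directly after manual edits to a call table.
#'
#' @param calls a data.frame of CNV calls (see [cnv_calls()]).
#' @return The validated table, with `length` and `autosomal` columns.
#' @export
validate_cnv_calls <- function(calls) {
  stopifnot_cols(calls, c("sample_id", "chrom", "start", "end",
                          "cnv_type", "n_probes"), "CNV call table")
  if (!"dataset_id" %in% names(calls)) calls$dataset_id <- "internal"
  if (!"copy_number" %in% names(calls)) calls$copy_number <- NA_integer_
  calls$chrom <- norm_chrom(calls$chrom)
  bad <- which(!(calls$start < calls$end))
  if (length(bad)) {
    stop(sprintf("CNV call row %d: start (%s) must be < end (%s)",
                 bad[1], calls$start[bad[1]], calls$end[bad[1]]), call. = FALSE)
  }
  bad <- which(is.na(calls$n_probes) | calls$n_probes < 1)
  if (length(bad)) {
    stop(sprintf("CNV call row %d: n_probes must be >= 1 (got %s)",
                 bad[1], calls$n_probes[bad[1]]), call. = FALSE)
  }
  bad <- which(!calls$cnv_type %in% CNV_TYPES)
  if (length(bad)) {
    stop(sprintf("CNV call row %d: unknown cnv_type '%s' (allowed: %s)",
                 bad[1], calls$cnv_type[bad[1]],
                 paste(CNV_TYPES, collapse = ", ")), call. = FALSE)
  }
  calls$start <- as.numeric(calls$start)
  calls$end <- as.numeric(calls$end)
  calls$n_probes <- as.integer(calls$n_probes)
  calls$length <- calls$end - calls$start
  calls$autosomal <- is_autosome(calls$chrom)
  rownames(calls) <- NULL
  calls
}

#' Read CNV calls from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`tsv`}{the native 7-column header TSV written by
#'     [write_cnv_calls()]: `sample_id chrom start end cnv_type n_probes
#'     dataset_id`, 0-based half-open.}
#'   \item{`bed`}{BED-like, no header: `chrom start end sample_id cnv_type
#'     n_probes`, 0-based half-open.}
#'   \item{`penncnv`}{PennCNV free-text output lines, e.g.
#'     `chr2:50835001-51160000 numsnp=45 length=325,000 state2,cn=1
#'     sampleA.txt ...`; coordinates 1-based inclusive, converted on
#'     ingest; `cn < 2` maps to DEL, `cn > 2` to DUP.}
#' }
#' The `coords` argument overrides the dialect's coordinate convention;
#' 1-based inclusive input is converted to 0-based half-open.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"bed"`, `"penncnv"`.
#' @param coords `"0-based"` (half-open) or `"1-based"` (inclusive);
#'   defaults to the dialect's convention.
#' @param dataset_id dataset label attached when the file carries none.
#' @return a validated CNV call table (see [cnv_calls()]).
#' @export
read_cnv_calls <- function(path, dialect = c("tsv", "bed", "penncnv"),
                           coords = NULL, dataset_id = "internal") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  coords <- coords %||% switch(dialect, tsv = "0-based", bed = "0-based",
                               penncnv = "1-based")
  coords <- match.arg(coords, c("0-based", "1-based"))
  if (dialect == "penncnv") {
    calls <- parse_penncnv_lines(readLines(path), dataset_id)
  } else {
    if (dialect == "tsv") {
      df <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, colClasses = "character")
      stopifnot_cols(df, c("sample_id", "chrom", "start", "end",
                           "cnv_type", "n_probes"), path)
      if (!"dataset_id" %in% names(df)) df$dataset_id <- dataset_id
    } else {
      df <- read.table(path, header = FALSE, sep = "\t",
                       stringsAsFactors = FALSE, colClasses = "character")
      if (ncol(df) < 6) {
        stop(sprintf("%s: BED-like dialect needs 6 columns, found %d",
                     path, ncol(df)), call. = FALSE)
      }
      names(df)[1:6] <- c("chrom", "start", "end", "sample_id",
                          "cnv_type", "n_probes")
      df$dataset_id <- dataset_id
    }
    for (col in c("start", "end", "n_probes")) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(val) & !is.na(df[[col]]))
      if (length(bad)) {
        stop(sprintf("%s: line %d: field '%s' is not numeric ('%s')",
                     path, bad[1] + as.integer(dialect == "tsv"), col,
                     df[[col]][bad[1]]), call. = FALSE)
      }
      df[[col]] <- val
    }
    bad <- which(!df$cnv_type %in% CNV_TYPES)
    if (length(bad)) {
      stop(sprintf("%s: line %d: unknown cnv_type token '%s'",
                   path, bad[1] + as.integer(dialect == "tsv"),
                   df$cnv_type[bad[1]]), call. = FALSE)
    }
    calls <- df[c("sample_id", "chrom", "start", "end", "cnv_type",
                  "n_probes", "dataset_id")]
  }
  if (coords == "1-based") {
    calls$start <- calls$start - 1  # [s, e] 1-based closed -> [s-1, e) 0-based
  }
  validate_cnv_calls(calls)
}

parse_penncnv_lines <- function(lines, dataset_id) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    reg <- regmatches(toks[1],
                      regexec("^(chr)?([0-9XY]+):([0-9,]+)-([0-9,]+)$", toks[1]))[[1]]
    if (length(reg) == 0) {
      stop(sprintf("line %d: cannot parse region token '%s'", i, toks[1]),
           call. = FALSE)
    }
    numsnp <- sub("^numsnp=", "", grep("^numsnp=", toks, value = TRUE)[1])
    cn_tok <- grep("cn=", toks, value = TRUE)[1]
    if (is.na(numsnp) || is.na(cn_tok)) {
      stop(sprintf("line %d: missing numsnp= or cn= field", i), call. = FALSE)
    }
    cn <- as.integer(sub(".*cn=([0-9]+).*", "\\1", cn_tok))
    sample_tok <- toks[!grepl("=", toks)][-1][1]
    if (is.na(sample_tok)) {
      stop(sprintf("line %d: missing sample field", i), call. = FALSE)
    }
    data.frame(
      sample_id = sub("\\.[A-Za-z0-9]+$", "", basename(sample_tok)),
      chrom = reg[3],
      start = as.numeric(gsub(",", "", reg[4])),
      end = as.numeric(gsub(",", "", reg[5])),
      cnv_type = if (cn < 2) "DEL" else "DUP",
      n_probes = as.integer(numsnp),
      dataset_id = dataset_id,
      copy_number = cn,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write CNV calls in the native TSV dialect
#'
#' Writes the 7-column 0-based half-open TSV read back bit-exactly by
#' `read_cnv_calls(path, dialect = "tsv")`.
#'
#' @param calls a CNV call table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  calls <- validate_cnv_calls(calls)
  out <- calls[c("sample_id", "chrom", "start", "end", "cnv_type",
                 "n_probes", "dataset_id")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SAMPLE_REQUIRED <- c("sample_id", "dataset_id", "array_group", "sex",
                     "status", "lrr_sd", "baf_drift", "gcwf", "n_cnv_raw")

#' Construct and validate a sample metadata table
#'
#' One row per genotyped sample: cohort membership, array group, sex,
#' case/control status, the PennCNV intensity QC metrics (LRR SD, BAF
#' drift, GC waviness factor, optionally absolute waviness factor) and raw
#' call summaries used as QC thresholds and regression covariates.
#'
#' @param df a data.frame with at least the columns `sample_id`,
#'   `dataset_id`, `array_group`, `sex` (`M`/`F`), `status`
#'   (`case`/`control`), `lrr_sd`, `baf_drift`, `gcwf`, `n_cnv_raw`;
#'   optional `abs_wf`, `total_cnv_bp`, `ancestry_cluster`.
#' @return the validated data.frame.
#' @export
sample_table <- function(df) {
  stopifnot_cols(df, SAMPLE_REQUIRED, "sample table")
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$sex), c("M", "F"))
  if (length(bad)) {
    stop(sprintf("sex value(s) %s not allowed (allowed: M, F)",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad)) {
    stop(sprintf("status value(s) %s not allowed (allowed: case, control)",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  for (col in c("lrr_sd", "baf_drift", "n_cnv_raw")) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) {
      stop(col, " must be nonnegative", call. = FALSE)
    }
  }
  if (!"abs_wf" %in% names(df)) df$abs_wf <- NA_real_
  if (!"total_cnv_bp" %in% names(df)) df$total_cnv_bp <- NA_real_
  if (!"ancestry_cluster" %in% names(df)) df$ancestry_cluster <- NA_integer_
  rownames(df) <- NULL
  df
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with a header naming at least the required columns of
#'   [sample_table()].
#' @return a validated sample table.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  sample_table(df)
}

#' Write a sample metadata table to TSV
#' @param samples a sample table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a coding-interval BED plus a pLI table
#'
#' The BED carries one row per coding interval (`chrom start end gene_id`,
#' 0-based half-open); intervals of the same gene are merged to a sorted
#' non-overlapping set. The pLI table is a 2-column TSV (`gene_id`, `pli`)
#' giving each gene's probability of loss-of-function intolerance; genes
#' absent from it carry `NA`.
#'
#' @param coding_bed path to the coding-interval BED.
#' @param pli_tsv optional path to the pLI TSV.
#' @return a gene-model data.frame with one row per merged coding interval:
#'   `gene_id`, `chrom`, `start`, `end`, `pli`.
#' @export
read_gene_annotation <- function(coding_bed, pli_tsv = NULL) {
  bed <- read.table(coding_bed, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop(coding_bed, ": need chrom/start/end/gene_id",
                          call. = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "gene_id")
  pli <- NULL
  if (!is.null(pli_tsv)) {
    pli_df <- read.table(pli_tsv, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    stopifnot_cols(pli_df, c("gene_id", "pli"), pli_tsv)
    pli <- setNames(pli_df$pli, pli_df$gene_id)
  }
  gene_models(bed$gene_id, bed$chrom, bed$start, bed$end, pli = pli)
}

#' Construct a gene-model table from coding intervals
#'
#' @param gene_id,chrom,start,end per-interval vectors (0-based half-open).
#' @param pli named numeric vector of pLI values keyed by gene id, or a
#'   per-interval numeric vector, or `NULL`.
#' @return a gene-model data.frame (merged, sorted, non-overlapping
#'   intervals per gene) with columns `gene_id`, `chrom`, `start`, `end`,
#'   `pli`.
#' @export
gene_models <- function(gene_id, chrom, start, end, pli = NULL) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = norm_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop(sprintf("gene %s: interval start (%s) >= end (%s)",
                 df$gene_id[bad], df$start[bad], df$end[bad]), call. = FALSE)
  }
  if (length(pli) && is.null(names(pli))) {
    pli <- tapply(pli, df$gene_id, function(x) x[1])
  }
  per_gene <- split(df, df$gene_id)
  merged <- lapply(per_gene, function(g) {
    if (length(unique(g$chrom)) > 1) {
      stop("gene ", g$gene_id[1], ": intervals span multiple chromosomes",
           call. = FALSE)
    }
    red <- IRanges::reduce(as_iranges0(g$start, g$end))
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = IRanges::start(red) - 1, end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  p <- if (is.null(pli)) rep(NA_real_, nrow(out)) else unname(pli[out$gene_id])
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad)) {
    stop(sprintf("gene %s: pLI %s outside [0, 1]", out$gene_id[bad[1]],
                 p[bad[1]]), call. = FALSE)
  }
  out$pli <- as.numeric(p)
  rownames(out) <- NULL
  out
}

#' Read a genome layout (autosome lengths) from a 2-column TSV
#'
#' @param path TSV with header columns `chrom` and `length`.
#' @return a data.frame `chrom`/`length` validated by [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot_cols(df, c("chrom", "length"), path)
  genome_layout(df$chrom, df$length)
}

#' Construct a genome layout
#' @param chrom unique chromosome tokens.
#' @param length chromosome lengths in bp, all positive.
#' @return a data.frame with columns `chrom` and `length`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- norm_chrom(chrom)
  if (anyDuplicated(chrom)) stop("duplicate chromosome tokens", call. = FALSE)
  if (any(length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  data.frame(chrom = chrom, length = as.numeric(length),
             stringsAsFactors = FALSE)
}

#' Shared bases between one call and a set of intervals
#'
#' Exact count of bases shared between the half-open interval
#' `[call_start, call_end)` and a set of half-open intervals on the same
#' chromosome. Overlapping intervals are merged first, so no base is
#' counted twice.
#'
#' @param call_start,call_end the call's coordinates (0-based half-open).
#' @param int_start,int_end vectors of interval coordinates.
#' @return a nonnegative integer count of shared bases.
#' @examples
#' overlap_bp(100, 200, 150, 250)  # 50
#' @export
overlap_bp <- function(call_start, call_end, int_start, int_end) {
  if (length(int_start) == 0) return(0)
  red <- IRanges::reduce(as_iranges0(int_start, int_end))
  s <- IRanges::start(red) - 1
  e <- IRanges::end(red)
  sum(pmax(0, pmin(call_end, e) - pmax(call_start, s)))
}

# Per-call coding-base overlap against a gene-model table, optionally
# restricted to a subset of gene ids. Vectorized over calls via IRanges.
coding_overlap_bp <- function(calls, genes, gene_ids = NULL) {
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, ]
  out <- numeric(nrow(calls))
  if (nrow(genes) == 0 || nrow(calls) == 0) return(out)
  for (ch in intersect(unique(calls$chrom), unique(genes$chrom))) {
    ci <- which(calls$chrom == ch)
    g <- genes[genes$chrom == ch, ]
    # intervals of distinct genes may overlap; merge so bases count once
    red <- IRanges::reduce(as_iranges0(g$start, g$end))
    cr <- as_iranges0(calls$start[ci], calls$end[ci])
    hits <- IRanges::findOverlaps(cr, red)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      w <- pmin(IRanges::end(cr)[qi], IRanges::end(red)[si]) -
        pmax(IRanges::start(cr)[qi], IRanges::start(red)[si]) + 1L
      out[ci] <- out[ci] + as.numeric(tapply(w, factor(qi, levels = seq_along(ci)),
                                             sum, default = 0))
    }
  }
  out
}

#' Classify calls as genic
#'
#' A call is genic if it overlaps at least one protein-coding base of any
#' gene in the annotation.
#'
#' @param calls a CNV call table.
#' @param genes a gene-model table ([gene_models()]).
#' @return logical vector, one element per call.
#' @export
is_genic <- function(calls, genes) {
  coding_overlap_bp(calls, genes) >= 1
}
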