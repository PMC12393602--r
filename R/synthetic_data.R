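# Synthetic stratified case/control CNV cohorts. The generator emulates
# the statistical structure the analysis assumes — strata defined by
# array group x ancestry cluster x sex with their own baseline call
# rates, log-normal call lengths, probe counts proportional to length,
# per-sample intensity covariates, ancestry-separated PC coordinates,
# and planted risk loci parameterized by control carrier frequency and
# carrier odds ratio — so that every pipeline stage is testable without
# any external download. It does not simulate probe-level intensity
# signal (LRR/BAF tracks).

#' Build a simulation configuration
#'
#' Defaults describe a small stratified cohort on a 3-autosome toy
#' genome: 4 strata (2 array groups x 2 ancestry clusters x both sexes,
#' 15 cases / 20 controls each), 1 background call per sample on
#' average, log-normal call lengths with median 150 kb, one probe per
#' 5 kb, and one planted 300 kb duplication at 5% control carrier
#' frequency with carrier odds ratio 6.
#'
#' @param seed master RNG seed; all randomness flows from it.
#' @param genome a [genome_layout()] data.frame.
#' @param strata_spec data.frame with one row per stratum:
#'   `array_group`, `ancestry_cluster`, `sex`, `n_case`, `n_control`,
#'   `baseline_call_rate` (mean background calls per sample),
#'   `probe_density` (probes per bp); optional `dataset_id`.
#' @param length_meanlog,length_sdlog log-normal call length model (bp).
#' @param planted_loci data.frame with `locus_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `control_freq` (carrier frequency in controls,
#'   in [0, 1)), `odds_ratio` (carrier odds ratio, > 0); or `NULL`.
#' @param n_genes,coding_fraction gene fixture size and coding fraction
#'   per gene.
#' @param pli_high_frac fraction of genes drawn from the constrained
#'   (pLI ~ U(0.95, 1)) mixture component; the rest from U(0, 0.5).
#' @param lrr_sd_model named list per array group of `c(mean, sd)` for
#'   per-sample LRR SD.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = genome_layout(c("1", "2", "3"),
                                              c(5e6, 4e6, 3e6)),
                       strata_spec = default_strata_spec(),
                       length_meanlog = log(150e3),
                       length_sdlog = 0.7,
                       planted_loci = default_planted_loci(),
                       n_genes = 60,
                       coding_fraction = 0.4,
                       pli_high_frac = 0.2,
                       lrr_sd_model = list(default = c(0.12, 0.02))) {
  stopifnot_cols(strata_spec, c("array_group", "ancestry_cluster", "sex",
                                "n_case", "n_control", "baseline_call_rate",
                                "probe_density"), "strata_spec")
  if (!"dataset_id" %in% names(strata_spec)) {
    strata_spec$dataset_id <- paste0("ds_", strata_spec$array_group)
  }
  if (!is.null(planted_loci) && nrow(planted_loci)) {
    stopifnot_cols(planted_loci, c("locus_id", "chrom", "start", "end",
                                   "cnv_type", "control_freq", "odds_ratio"),
                   "planted_loci")
    planted_loci$chrom <- norm_chrom(planted_loci$chrom)
    if (any(planted_loci$control_freq < 0 | planted_loci$control_freq >= 1)) {
      stop("planted control_freq must lie in [0, 1)", call. = FALSE)
    }
    if (any(planted_loci$odds_ratio <= 0)) {
      stop("planted odds ratios must be > 0", call. = FALSE)
    }
    glen <- setNames(genome$length, genome$chrom)
    bad <- which(!(planted_loci$chrom %in% genome$chrom) |
                   planted_loci$start < 0 |
                   planted_loci$end > glen[planted_loci$chrom])
    if (length(bad)) {
      stop("planted locus ", planted_loci$locus_id[bad[1]],
           " lies outside the genome", call. = FALSE)
    }
  }
  structure(list(seed = seed, genome = genome, strata_spec = strata_spec,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 planted_loci = planted_loci, n_genes = n_genes,
                 coding_fraction = coding_fraction,
                 pli_high_frac = pli_high_frac,
                 lrr_sd_model = lrr_sd_model),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_strata_spec <- function() {
  data.frame(
    array_group = rep(c("GSA", "OmniExpress"), each = 2),
    ancestry_cluster = rep(c(1L, 2L), each = 2),
    sex = rep(c("M", "F"), 2),
    n_case = 15L, n_control = 20L,
    baseline_call_rate = 1.0,
    probe_density = 1 / 5000,
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_planted_loci <- function() {
  data.frame(locus_id = "planted_dup_1", chrom = "1",
             start = 1e6, end = 1.3e6, cnv_type = "DUP",
             control_freq = 0.05, odds_ratio = 6,
             stringsAsFactors = FALSE)
}

# carrier frequency in cases implied by (control freq f, carrier OR)
case_carrier_freq <- function(f, or) f * or / (1 - f + f * or)

#' Simulate a stratified case/control CNV cohort
#'
#' Background calls arrive per sample as Poisson counts at the stratum's
#' baseline rate, positioned uniformly on chromosomes chosen
#' proportionally to length, with log-normal lengths and probe counts
#' rounded from length x probe density. Planted risk loci add one call
#' spanning the locus to each carrier; carrier status is drawn per
#' sample at the control frequency `f` for controls and
#' `f*OR / (1 - f + f*OR)` for cases. Per-sample intensity covariates
#' and a cluster-separated PC matrix are generated alongside.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `samples` (a [sample_table()]),
#'   `calls` (a CNV call table), `pc` (samples x 6 PC matrix),
#'   `planted` (data.frame `locus_id`, `sample_id` of planted carriers),
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  spec <- config$strata_spec
  genome <- config$genome
  n_per <- spec$n_case + spec$n_control
  n_total <- sum(n_per)
  row_of <- rep(seq_len(nrow(spec)), n_per)
  status <- unlist(lapply(seq_len(nrow(spec)), function(i) {
    c(rep("case", spec$n_case[i]), rep("control", spec$n_control[i]))
  }))
  ids <- sprintf("S%05d", seq_len(n_total))

  lrr_model <- function(g) {
    config$lrr_sd_model[[g]] %||% config$lrr_sd_model[["default"]]
  }
  lrr_par <- t(vapply(spec$array_group[row_of], lrr_model, numeric(2)))
  lrr_sd <- pmax(0.02, rnorm(n_total, lrr_par[, 1], lrr_par[, 2]))

  samples <- sample_table(data.frame(
    sample_id = ids,
    dataset_id = spec$dataset_id[row_of],
    array_group = spec$array_group[row_of],
    sex = spec$sex[row_of],
    status = status,
    lrr_sd = lrr_sd,
    baf_drift = abs(rnorm(n_total, 0.002, 0.0015)),
    gcwf = rnorm(n_total, 0, 0.01),
    n_cnv_raw = 0L,
    ancestry_cluster = spec$ancestry_cluster[row_of],
    stringsAsFactors = FALSE
  ))

  # background calls
  rate <- spec$baseline_call_rate[row_of]
  dens <- spec$probe_density[row_of]
  n_bg <- rpois(n_total, rate)
  owner <- rep(seq_len(n_total), n_bg)
  n_calls <- length(owner)
  calls <- NULL
  if (n_calls > 0) {
    chrom_i <- sample.int(nrow(genome), n_calls, replace = TRUE,
                          prob = genome$length)
    L <- genome$length[chrom_i]
    len <- pmin(pmax(round(rlnorm(n_calls, config$length_meanlog,
                                  config$length_sdlog)), 5e3), 0.9 * L)
    start <- floor(runif(n_calls, 0, L - len))
    calls <- data.frame(
      sample_id = ids[owner],
      chrom = genome$chrom[chrom_i],
      start = start, end = start + len,
      cnv_type = sample(CNV_TYPES, n_calls, replace = TRUE),
      n_probes = pmax(1L, as.integer(round(len * dens[owner]))),
      dataset_id = samples$dataset_id[owner],
      stringsAsFactors = FALSE
    )
  }

  # planted risk loci
  planted <- data.frame(locus_id = character(0), sample_id = character(0),
                        stringsAsFactors = FALSE)
  pl <- config$planted_loci
  if (!is.null(pl) && nrow(pl)) {
    for (k in seq_len(nrow(pl))) {
      f_ctrl <- pl$control_freq[k]
      f_case <- case_carrier_freq(f_ctrl, pl$odds_ratio[k])
      prob <- ifelse(samples$status == "case", f_case, f_ctrl)
      carrier <- runif(n_total) < prob
      if (!any(carrier)) next
      len <- pl$end[k] - pl$start[k]
      add <- data.frame(
        sample_id = ids[carrier],
        chrom = pl$chrom[k],
        start = pl$start[k], end = pl$end[k],
        cnv_type = pl$cnv_type[k],
        n_probes = pmax(1L, as.integer(round(len * dens[carrier]))),
        dataset_id = samples$dataset_id[carrier],
        stringsAsFactors = FALSE
      )
      calls <- rbind(calls, add)
      planted <- rbind(planted,
                       data.frame(locus_id = pl$locus_id[k],
                                  sample_id = ids[carrier],
                                  stringsAsFactors = FALSE))
    }
  }
  if (is.null(calls)) {
    calls <- cnv_calls(character(0), character(0), numeric(0), numeric(0),
                       character(0), integer(0), dataset_id = character(0),
                       copy_number = integer(0))
  } else {
    calls <- validate_cnv_calls(calls)
    calls <- calls[order(calls$sample_id, calls$chrom, calls$start), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }

  tabulated <- table(factor(calls$sample_id, levels = ids))
  samples$n_cnv_raw <- as.integer(tabulated) + rpois(n_total, 1)
  samples$total_cnv_bp <- as.numeric(tapply(
    calls$length, factor(calls$sample_id, levels = ids), sum, default = 0))

  # cluster-separated PC coordinates (6 PCs, unit noise)
  cl <- samples$ancestry_cluster
  pc <- matrix(rnorm(n_total * 6), n_total, 6,
               dimnames = list(ids, paste0("PC", 1:6)))
  pc[, 1] <- pc[, 1] + 12 * (cl - 1)
  pc[, 2] <- pc[, 2] + 6 * ((cl - 1) %% 2)

  structure(list(samples = samples, calls = calls, pc = pc,
                 planted = planted, config = config),
            class = "sim_cohort")
}

#' Generate a deterministic gene fixture
#'
#' Places `n_genes` non-overlapping genes along the toy genome (spans
#' 8-40 kb separated by 5-40 kb gaps), splits each into 1-4 coding
#' intervals totalling the configured coding fraction, and draws pLI
#' from the two-component mixture (constrained component U(0.95, 1) with
#' probability `pli_high_frac`, background U(0, 0.5) otherwise). Also
#' returns two toy gene sets: `denovo` (constrained genes, up to 10) and
#' `ndd` (a 15-gene sample).
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a [gene_models()] table) and `gene_sets`
#'   (named list of gene-id vectors).
#' @export
generate_gene_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, 7919L), {
    genome <- config$genome
    rows <- list()
    placed <- 0
    for (i in seq_len(nrow(genome))) {
      pos <- 0
      while (placed < config$n_genes) {
        gap <- runif(1, 5e3, 40e3)
        span <- runif(1, 8e3, 40e3)
        if (pos + gap + span > genome$length[i]) break
        g_start <- round(pos + gap)
        g_end <- round(g_start + span)
        placed <- placed + 1
        gid <- sprintf("G%04d", placed)
        n_ex <- sample.int(4, 1)
        # exon starts spread over the span; widths sum to coding fraction
        ex_w <- round(config$coding_fraction * span / n_ex)
        ex_gap <- (span - n_ex * ex_w) / max(1, n_ex)
        ex_start <- round(g_start + (seq_len(n_ex) - 1) * (ex_w + ex_gap))
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gid, chrom = genome$chrom[i],
          start = ex_start, end = ex_start + ex_w,
          stringsAsFactors = FALSE)
        pos <- g_end
      }
    }
    if (placed < config$n_genes) {
      stop(sprintf("could only place %d of %d genes in the genome",
                   placed, config$n_genes), call. = FALSE)
    }
    bed <- do.call(rbind, rows)
    gene_ids <- sprintf("G%04d", seq_len(placed))
    high <- runif(placed) < config$pli_high_frac
    pli <- ifelse(high, runif(placed, 0.95, 1), runif(placed, 0, 0.5))
    genes <- gene_models(bed$gene_id, bed$chrom, bed$start, bed$end,
                         pli = setNames(pli, gene_ids))
    constrained <- gene_ids[pli > 0.5]
    gene_sets <- list(
      denovo = head(constrained, 10),
      ndd = sort(sample(gene_ids, min(15, placed)))
    )
    list(genes = genes, gene_sets = gene_sets)
  })
}

#' Write a complete pipeline fixture to disk
#'
#' Emits every input file the pipeline reads — calls, sample table, PC
#' matrix, coding-interval BED, pLI table, genome layout, gene sets and a
#' known-CNV catalog — plus a manifest recording ground truth: planted
#' loci with their carrier counts and the filter-cascade survivor counts
#' (computed by running the QC cascade on the written data). Output is
#' plain TSV/BED text and byte-identical across writes for a fixed seed.
#'
#' @param outdir output directory (created if needed).
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param gene_fixture result of [generate_gene_fixture()].
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(outdir, sim, gene_fixture) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "gene_sets"), showWarnings = FALSE)
  paths <- c(
    calls = file.path(outdir, "calls.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    pc = file.path(outdir, "pc_matrix.tsv"),
    genes_bed = file.path(outdir, "genes.bed"),
    pli = file.path(outdir, "pli.tsv"),
    genome = file.path(outdir, "genome.tsv"),
    catalog = file.path(outdir, "catalog.tsv"),
    manifest = file.path(outdir, "manifest.tsv"),
    summary = file.path(outdir, "summary.txt")
  )
  write_cnv_calls(sim$calls, paths["calls"])

  samples <- sim$samples
  for (col in c("lrr_sd", "baf_drift", "gcwf")) {
    samples[[col]] <- round(samples[[col]], 6)
  }
  write.table(samples[SAMPLE_REQUIRED_OUT()], paths["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)

  pc <- data.frame(sample_id = rownames(sim$pc), round(sim$pc, 6),
                   stringsAsFactors = FALSE)
  write.table(pc, paths["pc"], sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- gene_fixture$genes
  bed <- data.frame(chrom = genes$chrom,
                    start = format(genes$start, scientific = FALSE, trim = TRUE),
                    end = format(genes$end, scientific = FALSE, trim = TRUE),
                    gene_id = genes$gene_id)
  write.table(bed, paths["genes_bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pli <- unique(data.frame(gene_id = genes$gene_id,
                           pli = round(genes$pli, 6)))
  write.table(pli, paths["pli"], sep = "\t", quote = FALSE, row.names = FALSE)

  gl <- sim$config$genome
  gl$length <- format(gl$length, scientific = FALSE, trim = TRUE)
  write.table(gl, paths["genome"], sep = "\t", quote = FALSE, row.names = FALSE)

  for (nm in names(gene_fixture$gene_sets)) {
    p <- file.path(outdir, "gene_sets", paste0(nm, ".tsv"))
    writeLines(c("gene_id", gene_fixture$gene_sets[[nm]]), p)
    paths[paste0("gene_set_", nm)] <- p
  }

  # toy known-CNV catalog: the planted loci plus one decoy interval
  pl <- sim$config$planted_loci
  catalog <- data.frame(locus_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        cnv_type = character(0))
  if (!is.null(pl) && nrow(pl)) {
    catalog <- pl[c("locus_id", "chrom", "start", "end", "cnv_type")]
  }
  catalog <- rbind(catalog,
                   data.frame(locus_id = "decoy_del",
                              chrom = gl$chrom[nrow(gl)],
                              start = 100000, end = 350000,
                              cnv_type = "DEL"))
  catalog$start <- format(catalog$start, scientific = FALSE, trim = TRUE)
  catalog$end <- format(catalog$end, scientific = FALSE, trim = TRUE)
  write.table(catalog, paths["catalog"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  # ground truth manifest: survivor counts by construction equal what the
  # QC cascade reports on the files just written
  qc <- run_qc_cascade(sim$samples, sim$calls)
  manifest <- rbind(
    data.frame(key = "n_samples", value = nrow(sim$samples)),
    data.frame(key = "n_calls_raw", value = nrow(sim$calls)),
    data.frame(key = "n_samples_post_qc", value = nrow(qc$samples)),
    data.frame(key = "n_qualifying", value = nrow(qc$qualifying)),
    data.frame(key = "n_analysis_grade", value = nrow(qc$analysis_grade))
  )
  if (nrow(sim$planted)) {
    per_locus <- table(sim$planted$locus_id)
    manifest <- rbind(manifest, data.frame(
      key = paste0("planted_carriers_", names(per_locus)),
      value = as.integer(per_locus)))
  }
  write.table(manifest, paths["manifest"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  writeLines(c(
    sprintf("synthetic cohort fixture (seed %s)", sim$config$seed),
    sprintf("%d samples in %d strata; %d raw calls",
            nrow(sim$samples), nrow(sim$config$strata_spec), nrow(sim$calls)),
    sprintf("planted loci: %s",
            if (is.null(pl) || !nrow(pl)) "none"
            else paste(pl$locus_id, collapse = ", "))
  ), paths["summary"])
  invisible(paths)
}

SAMPLE_REQUIRED_OUT <- function() {
  c("sample_id", "dataset_id", "array_group", "sex", "status", "lrr_sd",
    "baf_drift", "gcwf", "n_cnv_raw", "total_cnv_bp", "ancestry_cluster")
}

#' Read a fixture directory back into memory
#'
#' @param dir a directory written by [write_fixture()].
#' @return list with `samples`, `calls`, `pc`, `genes`, `gene_sets`,
#'   `genome`, `catalog`, `manifest`.
#' @export
read_fixture <- function(dir) {
  gene_set_files <- list.files(file.path(dir, "gene_sets"),
                               full.names = TRUE)
  gene_sets <- lapply(gene_set_files, function(p) {
    read.table(p, header = TRUE, stringsAsFactors = FALSE)$gene_id
  })
  names(gene_sets) <- sub("\\.tsv$", "", basename(gene_set_files))
  manifest <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  list(
    samples = read_sample_table(file.path(dir, "samples.tsv")),
    calls = read_cnv_calls(file.path(dir, "calls.tsv"), "tsv"),
    pc = read.table(file.path(dir, "pc_matrix.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE),
    genes = read_gene_annotation(file.path(dir, "genes.bed"),
                                 file.path(dir, "pli.tsv")),
    gene_sets = gene_sets,
    genome = read_genome_layout(file.path(dir, "genome.tsv")),
    catalog = read.table(file.path(dir, "catalog.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE),
    manifest = setNames(manifest$value, manifest$key)
  )
}
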