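toy_genes <- function() {
  gene_models(c("GHI", "GHI", "GLO", "GSET"),
              c("1", "1", "1", "2"),
              c(1.0e6, 1.2e6, 3.0e6, 0.5e6),
              c(1.1e6, 1.3e6, 3.1e6, 0.6e6),
              pli = c(GHI = 0.97, GLO = 0.3, GSET = 0.999))
}

test_that("singleton marking follows the 50% reciprocal-overlap rule", {
  solo <- cnv_calls("a", "1", 1e6, 1.2e6, "DEL", 20)
  expect_true(mark_singletons(solo))

  dup2 <- cnv_calls(c("a", "b"), "1", 1e6, 1.2e6, "DEL", 20)
  expect_equal(mark_singletons(dup2), c(FALSE, FALSE))

  # 40% reciprocal overlap: both remain singletons under the 50% rule
  part <- cnv_calls(c("a", "b"), "1", c(0, 60e3), c(100e3, 160e3), "DEL", 20)
  expect_equal(mark_singletons(part), c(TRUE, TRUE))
  # ...but not under a 30% rule
  expect_equal(mark_singletons(part, min_recip = 0.3), c(FALSE, FALSE))

  # same coordinates, opposite types: still singletons
  mixed <- cnv_calls(c("a", "b"), "1", 1e6, 1.2e6, c("DEL", "DUP"), 20)
  expect_equal(mark_singletons(mixed), c(TRUE, TRUE))
})

test_that("burden predicates compose: type, size, genic, pLI, gene set", {
  genes <- toy_genes()
  samples <- sample_table(data.frame(
    sample_id = c("a", "b"), dataset_id = "d", array_group = "GSA",
    sex = "M", status = c("case", "control"), lrr_sd = 0.1,
    baf_drift = 0.002, gcwf = 0, n_cnv_raw = 1L, stringsAsFactors = FALSE))
  # one 1.5 Mb deletion over the pLI 0.97 gene's coding bases
  calls <- cnv_calls("a", "1", 0.9e6, 2.4e6, "DEL", 40)

  for (spec in list(burden_spec("del", "DEL"),
                    burden_spec("genic", genic_filter = "genic"),
                    burden_spec("pli", "DEL", pli_bin = ">0.9"),
                    burden_spec("big", size_range = c(1e6, Inf)))) {
    b <- compute_burden(calls, samples, genes, spec = spec)
    expect_equal(unname(b), c(1, 0), label = spec$name)
  }
  expect_equal(unname(compute_burden(calls, samples, genes,
                                     spec = burden_spec("dup", "DUP"))),
               c(0, 0))
  # no calls at all -> all-zero vector
  expect_equal(unname(compute_burden(calls[0, ], samples, genes,
                                     spec = burden_spec("all"))), c(0, 0))
  # intron-only overlap of a constrained gene does not count in the bin
  intronic <- cnv_calls("a", "1", 1.11e6, 1.19e6, "DEL", 20)
  expect_equal(unname(compute_burden(intronic, samples, genes,
                                     spec = burden_spec("pli", pli_bin = ">0.9"))),
               c(0, 0))
  expect_error(compute_burden(calls, samples, genes,
                              gene_sets = list(),
                              spec = burden_spec("gs", gene_set = "nope")),
               "unknown gene set")
})

test_that("burden counts decompose exactly and pLI bins nest", {
  set.seed(31)
  fx <- read_fixture(toy_fixture_dir())
  calls <- filter_analysis_grade(filter_qualifying(fx$calls))
  for (ty in c("DEL", "DUP")) {
    total <- compute_burden(calls, fx$samples, fx$genes,
                            spec = burden_spec("t", ty))
    genic <- compute_burden(calls, fx$samples, fx$genes,
                            spec = burden_spec("g", ty, genic_filter = "genic"))
    nong <- compute_burden(calls, fx$samples, fx$genes,
                           spec = burden_spec("n", ty, genic_filter = "nongenic"))
    expect_equal(genic + nong, total)
  }
  hi <- compute_burden(calls, fx$samples, fx$genes,
                       spec = burden_spec("h", pli_bin = ">0.995"))
  lo <- compute_burden(calls, fx$samples, fx$genes,
                       spec = burden_spec("l", pli_bin = ">0.9"))
  expect_true(all(hi <= lo))
})

test_that("gene-set Fisher test surfaces carrier tables and errors", {
  genes <- toy_genes()
  n_case <- 40; n_ctrl <- 60
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%03d", 1:(n_case + n_ctrl)), dataset_id = "d",
    array_group = "GSA", sex = "M",
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    lrr_sd = 0.1, baf_drift = 0.002, gcwf = 0, n_cnv_raw = 1L,
    stringsAsFactors = FALSE))
  # 5 case carriers and 1 control carrier of a DEL over the set gene
  carriers <- c(sprintf("s%03d", 1:5), "s041")
  calls <- cnv_calls(carriers, "2", 0.45e6, 0.65e6, "DEL", 25)
  res <- geneset_carrier_fisher(samples, calls, genes,
                                list(myset = "GSET"), "myset", "DEL")
  expect_equal(res$n_case_carriers, 5)
  expect_equal(res$n_control_carriers, 1)
  expect_equal(res$or, (5 * 59) / (35 * 1))
  # DUPs at the same locus are not deletion carriers: degenerate table
  # errors are surfaced with the gene-set id
  expect_error(geneset_carrier_fisher(samples, calls, genes,
                                      list(myset = "GSET"), "myset", "DUP"),
               "myset")
})

test_that("call-size comparison detects stochastically larger case calls", {
  set.seed(61)
  n <- 200
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%03d", 1:(2 * n)), dataset_id = "d",
    array_group = "GSA", sex = "M",
    status = rep(c("case", "control"), each = n), lrr_sd = 0.1,
    baf_drift = 0.002, gcwf = 0, n_cnv_raw = 1L, stringsAsFactors = FALSE))
  len_case <- round(rlnorm(n, log(4e5), 0.4))
  len_ctrl <- round(rlnorm(n, log(2e5), 0.4))
  calls <- cnv_calls(samples$sample_id, "1", 1e5,
                     1e5 + c(len_case, len_ctrl), "DEL", 20)
  expect_lt(compare_call_sizes(calls, samples)$p, 0.01)

  only_case <- calls[1:n, ]
  expect_error(compare_call_sizes(only_case, samples), "both case and control")
})

test_that("leave-one-out reruns per dataset and attenuates carried signal", {
  set.seed(71)
  spec3 <- rbind(default_strata_spec(), default_strata_spec()[1:2, ])
  spec3$dataset_id <- rep(c("d1", "d2", "d3"), c(2, 2, 2))
  spec3$ancestry_cluster <- rep(1:3, each = 2)
  spec3$n_case <- 40L; spec3$n_control <- 40L
  cfg <- sim_config(seed = 7, strata_spec = spec3, planted_loci = NULL)
  sim <- simulate_cohort(cfg)
  # plant the entire deletion signal into dataset d3's cases
  d3_cases <- sim$samples$sample_id[sim$samples$dataset_id == "d3" &
                                      sim$samples$status == "case"]
  extra <- cnv_calls(d3_cases[1:25], "1", 2e6, 2.3e6, "DEL", 60)
  calls <- rbind(sim$calls, extra)

  runner <- function(samples, calls, strata) {
    carrier <- compute_burden(calls, samples, spec = burden_spec("del", "DEL"))
    tab <- cmh_test(carrier_counts(
      calls, data.frame(locus_id = "L", chrom = "1", start = 2e6, end = 2.3e6),
      strata$assignment, "DEL", mode = "window"))
    data.frame(or = tab$or_mh)
  }
  res <- leave_one_out(sim$samples, calls, runner)
  expect_equal(nrow(res), 3)
  or_wo_signal <- res$or[res$excluded_dataset == "d3"]
  or_wo_null <- res$or[res$excluded_dataset == "d1"]
  expect_true(is.na(or_wo_signal) || or_wo_signal < 2)
  expect_gt(or_wo_null, 5)
  expect_error(leave_one_out(sim$samples[sim$samples$dataset_id == "d1", ],
                             calls, runner), ">= 2 datasets")
})

test_that("catalog matching needs same type and 50% coverage", {
  catalog <- data.frame(locus_id = "ndd1", chrom = "1", start = 1e6,
                        end = 1.4e6, cnv_type = "DEL",
                        stringsAsFactors = FALSE)
  calls <- cnv_calls(c("full", "partial", "wrongtype"), "1",
                     c(0.9e6, 1.0e6, 0.9e6),
                     c(1.5e6, 1.12e6, 1.5e6),
                     c("DEL", "DEL", "DUP"), 30)
  hits <- match_known_cnvs(calls, catalog)
  expect_equal(hits$sample_id, "full")  # 30% coverage and DUP both miss
  hits30 <- match_known_cnvs(calls, catalog, min_cov = 0.25)
  expect_setequal(hits30$sample_id, c("full", "partial"))
})

test_that("the burden suite flags degenerate metrics but keeps running", {
  fx <- read_fixture(toy_fixture_dir())
  st <- build_strata(fx$samples)
  empty <- fx$calls[0, ]
  out <- run_burden_suite(fx$samples, empty, fx$genes, fx$gene_sets,
                          strata = st)
  expect_true(all(nzchar(out$note)))
  expect_setequal(unique(out$model), c("logistic", "cmh"))
})

test_that("suite effect estimates are centred on OR 1 after label permutation", {
  set.seed(81)
  fx <- read_fixture(toy_fixture_dir())
  calls <- filter_analysis_grade(filter_qualifying(fx$calls))
  log_ors <- replicate(20, {
    s <- fx$samples
    # permute status within each stratum-defining combination
    key <- interaction(s$array_group, s$ancestry_cluster, s$sex)
    for (k in levels(key)) {
      idx <- which(key == k)
      s$status[idx] <- sample(s$status[idx])
    }
    st <- build_strata(s)
    out <- run_burden_suite(s, calls, fx$genes, fx$gene_sets,
                            specs = list(burden_spec("all")), strata = st)
    log(out$or[out$model == "cmh"])
  })
  log_ors <- log_ors[is.finite(log_ors)]
  expect_lt(abs(mean(log_ors)), 3 * sd(log_ors) / sqrt(length(log_ors)))
})
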