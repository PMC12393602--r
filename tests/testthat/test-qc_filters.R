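mk_samples <- function(n, dataset = "d1", array = "GSA", lrr = 0.1,
                       baf = 0.002, gcwf = 0, n_raw = 3, abs_wf = NA_real_) {
  sample_table(data.frame(
    sample_id = sprintf("%s_s%03d", dataset, seq_len(n)),
    dataset_id = dataset, array_group = array,
    sex = rep(c("M", "F"), length.out = n),
    status = rep(c("case", "control"), length.out = n),
    lrr_sd = rep(lrr, length.out = n), baf_drift = rep(baf, length.out = n),
    gcwf = rep(gcwf, length.out = n), n_cnv_raw = rep(n_raw, length.out = n),
    abs_wf = rep(abs_wf, length.out = n), stringsAsFactors = FALSE))
}

test_that("intensity outliers flagged per dataset beyond k SD of the median", {
  # identical metrics: SD = 0, nothing flagged
  expect_length(flag_intensity_outliers(mk_samples(10)), 0)

  # 19 samples at 0.10 plus one at 0.18: median 0.10, SD ~0.018 -> flagged
  s <- mk_samples(20, lrr = c(rep(0.10, 19), 0.18))
  expect_equal(flag_intensity_outliers(s), "d1_s020")

  # extreme on gcwf only is enough ("any of these metrics")
  s2 <- mk_samples(20, gcwf = c(rep(0, 19), 0.5))
  expect_equal(flag_intensity_outliers(s2), "d1_s020")

  # flags are computed within each dataset independently
  both <- rbind(s, mk_samples(20, dataset = "d2"))
  expect_equal(flag_intensity_outliers(both), "d1_s020")

  expect_warning(flag_intensity_outliers(mk_samples(2)), "< 3 samples")
})

test_that("raw call limits are per array group (15 vs 30) with 20 Mb cap", {
  s <- rbind(mk_samples(1, dataset = "o", array = "OmniExpress", n_raw = 16),
             mk_samples(1, dataset = "g", array = "GSA", n_raw = 16),
             mk_samples(1, dataset = "b", array = "610K", n_raw = 10))
  s$total_cnv_bp <- c(5e6, 5e6, 21e6)
  kept <- apply_raw_call_limits(s)
  expect_false("o_s001" %in% kept)  # 16 > 15 on OmniExpress
  expect_true("g_s001" %in% kept)   # 16 <= 30 on GSA
  expect_false("b_s001" %in% kept)  # 21 Mb > 20 Mb

  s$array_group[1] <- "CustomChip"
  expect_error(apply_raw_call_limits(s), "no QC profile.*CustomChip")
})

test_that("raw call limits computed from calls agree with metadata route", {
  s <- mk_samples(2, array = "OmniExpress")
  calls <- cnv_calls(rep(c("d1_s001", "d1_s002"), c(16, 3)), "1",
                     seq(1e5, by = 2e5, length.out = 19),
                     seq(1e5, by = 2e5, length.out = 19) + 5e4,
                     "DEL", 20)
  expect_equal(apply_raw_call_limits(s, calls), "d1_s002")
})

test_that("qualifying filter: >=10 probes, 30kb-20Mb inclusive, autosomes", {
  calls <- cnv_calls(
    sample_id = letters[1:6], chrom = c("1", "1", "1", "1", "X", "2"),
    start = 0, end = c(50e3, 25e3, 30e3, 20e6, 50e3, 21e6),
    cnv_type = "DEL", n_probes = c(9, 20, 10, 50, 20, 50))
  kept <- filter_qualifying(calls)
  # a: 9 probes out; b: 25 kb out; c: exactly 30 kb in; d: exactly 20 Mb in;
  # e: chrX out; f: 21 Mb out
  expect_setequal(kept$sample_id, c("c", "d"))
})

test_that("analysis-grade filter: strictly >100kb and >=15 probes", {
  calls <- cnv_calls(letters[1:3], "1", 0,
                     c(100e3, 150e3, 150e3), "DUP", c(20, 14, 15))
  kept <- filter_analysis_grade(calls)
  expect_equal(kept$sample_id, "c")
})

test_that("qualifying and analysis-grade filters are idempotent and commute", {
  set.seed(99)
  n <- 200
  calls <- cnv_calls(sprintf("s%d", sample(1:40, n, TRUE)),
                     sample(c(1:22, "X"), n, TRUE),
                     start <- sample(1e6, n),
                     start + pmax(1000, round(rlnorm(n, log(9e4), 1))),
                     sample(c("DEL", "DUP"), n, TRUE),
                     sample(1:40, n, TRUE))
  q <- filter_qualifying(calls)
  expect_identical(filter_qualifying(q), q)
  a <- filter_analysis_grade(calls)
  expect_identical(filter_analysis_grade(a), a)
  expect_identical(filter_analysis_grade(filter_qualifying(calls)),
                   filter_qualifying(filter_analysis_grade(calls)))
})

test_that("adjacent merge applies the gap < 20% of merged span rule", {
  # gap 20k over merged span 200k = 10% -> merged
  m <- merge_adjacent_calls(cnv_calls(c("s", "s"), "1",
                                      c(100e3, 220e3), c(200e3, 300e3),
                                      "DEL", c(10, 8)))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end, m$n_probes), c(100e3, 300e3, 18))

  # gap 60k over span 200k = 30% -> untouched
  m2 <- merge_adjacent_calls(cnv_calls(c("s", "s"), "1",
                                       c(100e3, 260e3), c(200e3, 300e3),
                                       "DEL", c(10, 8)))
  expect_equal(nrow(m2), 2)

  # single call unchanged
  single <- cnv_calls("s", "1", 1e5, 2e5, "DEL", 10)
  expect_equal(merge_adjacent_calls(single)$length, 1e5)
})

test_that("merge never crosses samples, chromosomes, or CNV types", {
  calls <- cnv_calls(c("s1", "s2", "s1", "s1"),
                     c("1", "1", "2", "1"),
                     c(100e3, 220e3, 220e3, 220e3),
                     c(200e3, 300e3, 300e3, 300e3),
                     c("DEL", "DEL", "DEL", "DUP"), 10)
  m <- merge_adjacent_calls(calls)
  expect_equal(nrow(m), 4)
  # merge chains to a fixed point and outputs disjoint intervals
  chain <- cnv_calls(rep("s", 3), "1", c(0, 110e3, 215e3),
                     c(100e3, 205e3, 300e3), "DEL", 10)
  mc <- merge_adjacent_calls(chain)
  expect_equal(nrow(mc), 1)
  expect_identical(merge_adjacent_calls(mc), mc)
})

test_that("frequency filter removes loci at >= 1% carriers", {
  mk <- function(n, start = 1e6) {
    cnv_calls(sprintf("s%03d", seq_len(n)), "1", start, start + 2e5,
              "DEL", 20)
  }
  common <- mk(11)            # 11 of 1000 samples >= 10 -> removed
  rare <- mk(9, start = 2e6)  # 9 of 1000 < 10 -> kept
  kept <- filter_by_frequency(rbind(common, rare), n_samples = 1000)
  expect_equal(nrow(kept), 9)
  expect_true(all(kept$start == 2e6))

  # DEL and DUP at the same locus are never pooled
  mixed <- rbind(mk(6), within(mk(6), cnv_type <- "DUP"))
  mixed$sample_id <- sprintf("s%03d", 1:12)
  expect_equal(nrow(filter_by_frequency(mixed, n_samples = 1000)), 12)

  expect_error(filter_by_frequency(common, 1000, max_freq = 0), "\\(0, 1\\]")
  expect_error(filter_by_frequency(common, 1000, max_freq = 1.5), "\\(0, 1\\]")
})

test_that("blacklist exclusion uses half-open overlap semantics", {
  bl <- data.frame(chrom = "1", start = 5e5, end = 6e5)
  calls <- cnv_calls(c("a", "b", "c"), "1",
                     c(450e3, 350e3, 610e3),
                     c(500001, 500e3, 700e3), "DEL", 10)
  kept <- exclude_regions(calls, bl)
  # a overlaps by 1 bp -> removed; b is adjacent (0 bp) -> kept; c clear
  expect_setequal(kept$sample_id, c("b", "c"))
  expect_identical(nrow(exclude_regions(calls, bl[0, ])), 3L)
})

test_that("biobank sample QC enforces intensity and call-count bounds", {
  s <- mk_samples(5, abs_wf = c(0.01, 0.01, 0.06, 0.01, 0.01),
                  lrr = c(0.1, 0.31, 0.1, 0.1, 0.1),
                  baf = c(0.002, 0.002, 0.002, 0.02, 0.002))
  calls <- rbind(
    cnv_calls(rep("d1_s005", 51), "1", seq(0, by = 3e5, length.out = 51),
              seq(0, by = 3e5, length.out = 51) + 1e5, "DEL", 10),
    cnv_calls("d1_s001", "2", 0, 1e5, "DEL", 10))
  kept <- biovu_sample_qc(s, calls)
  expect_setequal(kept, "d1_s001")  # s2 lrr, s3 abswf, s4 baf, s5 51 calls

  # one 21 Mb call excludes its sample (s5 now has no calls and passes)
  big <- rbind(calls[calls$sample_id == "d1_s001", ],
               cnv_calls("d1_s001", "3", 0, 21e6, "DUP", 500))
  expect_setequal(biovu_sample_qc(s, big), "d1_s005")

  s_na <- mk_samples(3)
  expect_error(biovu_sample_qc(s_na, calls), "abs_wf")
})

test_that("count-outlier flag uses the inverse-normal transform", {
  s <- mk_samples(100, n_raw = c(rep(3, 98), 40, 50))
  flagged <- flag_count_outliers(s)
  expect_setequal(flagged, c("d1_s099", "d1_s100"))
})

test_that("QC cascade report is internally consistent on the fixture", {
  fx <- read_fixture(toy_fixture_dir())
  qc <- run_qc_cascade(fx$samples, fx$calls)
  expect_true(all(qc$report$n_in - qc$report$removed == qc$report$retained))
  expect_identical(filter_qualifying(qc$qualifying), qc$qualifying)
})
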