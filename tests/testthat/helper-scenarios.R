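# Shared simulation scenarios. The single 3.19 Mb chromosome yields
# exactly 300 windows of 200 kb advancing by 10 kb.

genome_300w <- function() genome_layout("1", 3.19e6)

# Fully null stratified cohort: 2 strata, 500 samples.
null_cohort_config <- function(seed) {
  sim_config(
    seed = seed,
    genome = genome_300w(),
    strata_spec = data.frame(
      array_group = c("GSA", "OmniExpress"),
      ancestry_cluster = c(1L, 2L),
      sex = c("M", "F"),
      n_case = c(100L, 150L), n_control = c(150L, 100L),
      baseline_call_rate = 1.0, probe_density = 1 / 5000,
      stringsAsFactors = FALSE),
    planted_loci = NULL
  )
}

# Planted duplication: control carrier frequency 0.5%, carrier OR 10,
# 4,000 samples split over 2 strata, sparse background.
power_cohort_config <- function(seed) {
  sim_config(
    seed = seed,
    genome = genome_300w(),
    strata_spec = data.frame(
      array_group = c("GSA", "OmniExpress"),
      ancestry_cluster = c(1L, 2L),
      sex = c("M", "F"),
      n_case = 1000L, n_control = 1000L,
      baseline_call_rate = 0.2, probe_density = 1 / 5000,
      stringsAsFactors = FALSE),
    planted_loci = data.frame(
      locus_id = "planted", chrom = "1", start = 1.5e6, end = 1.8e6,
      cnv_type = "DUP", control_freq = 0.005, odds_ratio = 10,
      stringsAsFactors = FALSE)
  )
}

# Confounded cohort: the second stratum has both a higher case fraction
# and a higher baseline call rate, so pooling inflates every test.
confounded_cohort_config <- function(seed) {
  sim_config(
    seed = seed,
    genome = genome_300w(),
    strata_spec = data.frame(
      array_group = c("GSA", "GSA"),
      ancestry_cluster = c(1L, 2L),
      sex = c("M", "M"),
      n_case = c(200L, 800L), n_control = c(800L, 200L),
      baseline_call_rate = c(1.0, 3.0), probe_density = 1 / 5000,
      stringsAsFactors = FALSE),
    planted_loci = NULL
  )
}

strata_from_sim <- function(sim) {
  build_strata(sim$samples)
}

# Raw CMH vs pooled (single-stratum) p-values over replicate confounded
# cohorts, pooled into aggregate genomic-inflation estimates.
confounding_lambdas <- function(n_rep, seed) {
  win <- make_windows(genome_300w())
  p_cmh <- p_pooled <- list()
  for (r in seq_len(n_rep)) {
    sim <- simulate_cohort(confounded_cohort_config(seed + r))
    st <- strata_from_sim(sim)
    strat <- run_association(sim$calls, win, st$assignment, "DEL",
                             n_perm = 0, seed = 1)
    pool_asg <- st$assignment
    pool_asg$stratum_id <- "pooled"
    pool <- run_association(sim$calls, win, pool_asg, "DEL",
                            n_perm = 0, seed = 1)
    p_cmh[[r]] <- strat$results$p[strat$results$informative]
    p_pooled[[r]] <- pool$results$p[pool$results$informative]
  }
  list(cmh = genomic_lambda(unlist(p_cmh)),
       pooled = genomic_lambda(unlist(p_pooled)))
}

toy_fixture_dir <- function() {
  system.file("extdata", "toy_cohort", package = "rarecnv")
}
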