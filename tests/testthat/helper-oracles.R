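# Independent oracles used across tests. These are deliberately written
# against textbook definitions (or delegated to base R's independent
# implementations), never against the package's internals.

# Per-base brute-force overlap count for small coordinates.
brute_overlap_bp <- function(call_start, call_end, int_start, int_end) {
  if (call_end <= call_start) return(0)
  bases <- call_start:(call_end - 1)
  covered <- rep(FALSE, length(bases))
  for (k in seq_along(int_start)) {
    covered <- covered | (bases >= int_start[k] & bases < int_end[k])
  }
  sum(covered)
}

# Random stratified 2x2xK carrier tables with positive margins.
random_strat_table <- function(n_strata, max_cell = 30) {
  a <- sample.int(max_cell, n_strata)
  b <- sample.int(max_cell, n_strata)
  c0 <- sample.int(max_cell, n_strata)
  d <- sample.int(max_cell, n_strata)
  data.frame(case_carriers = a, case_total = a + b,
             control_carriers = c0, control_total = c0 + d)
}

# mantelhaen.test as the independent CMH reference (2x2xK array layout:
# rows = carrier yes/no, columns = case/control, slices = strata).
mantelhaen_ref <- function(tab) {
  arr <- array(0, dim = c(2, 2, nrow(tab)))
  for (i in seq_len(nrow(tab))) {
    arr[, , i] <- matrix(c(tab$case_carriers[i],
                           tab$case_total[i] - tab$case_carriers[i],
                           tab$control_carriers[i],
                           tab$control_total[i] - tab$control_carriers[i]),
                         nrow = 2)
  }
  mantelhaen.test(arr, correct = FALSE)
}

# Exhaustive min(P) enumeration over all within-stratum case-label
# assignments for a two-stratum toy. Returns per-locus exact adjusted
# p-values (probability that the assignment-wise minimum p is <= the
# observed p) computed from first principles.
exhaustive_minp <- function(carrier, assignment) {
  strata <- split(seq_len(nrow(assignment)), assignment$stratum_id)
  stopifnot(length(strata) == 2)
  loci <- rownames(carrier)
  n_loci <- nrow(carrier)

  piece <- function(idx) {
    st <- assignment$status[idx]
    n <- length(idx); n_case <- sum(st == "case")
    subs <- combn(n, n_case)
    # per locus: a for every choice of case subset
    C <- carrier[, idx, drop = FALSE] * 1
    A <- matrix(0, n_loci, ncol(subs))
    for (j in seq_len(ncol(subs))) A[, j] <- rowSums(C[, subs[, j], drop = FALSE])
    m1 <- rowSums(C)
    N <- n
    E <- n_case * m1 / N
    V <- n_case * (N - n_case) * m1 * (N - m1) / (N^2 * (N - 1))
    obs <- rowSums(C[, st == "case", drop = FALSE])
    list(A = A, E = E, V = V, obs = obs)
  }
  p1 <- piece(strata[[1]]); p2 <- piece(strata[[2]])
  E <- p1$E + p2$E; V <- p1$V + p2$V
  n1 <- ncol(p1$A); n2 <- ncol(p2$A)

  p_of <- function(a_tot) {
    stat <- ifelse(V > 0, (a_tot - E)^2 / V, 0)
    p <- pchisq(stat, 1, lower.tail = FALSE)
    p[V <= 0] <- 1
    p
  }
  p_obs <- p_of(p1$obs + p2$obs)

  # enumerate all n1 x n2 assignment combinations; track the minimum p
  min_p <- matrix(1, n1, n2)
  for (l in seq_len(n_loci)) {
    if (V[l] <= 0) next
    a_grid <- outer(p1$A[l, ], p2$A[l, ], "+")
    stat <- (a_grid - E[l])^2 / V[l]
    min_p <- pmin(min_p, pchisq(stat, 1, lower.tail = FALSE))
  }
  p_adj_exact <- vapply(p_obs, function(p0) mean(min_p <= p0), numeric(1))
  list(p_obs = p_obs, p_adj_exact = p_adj_exact, min_p = as.vector(min_p))
}
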