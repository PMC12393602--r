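# Statistical kernels: stratified Cochran-Mantel-Haenszel (CMH) test with
# the Mantel-Haenszel common odds ratio and Robins-Breslow-Greenland CI,
# Fisher carrier tests, the burden logistic model, the min(P) permutation
# engine, and the genomic inflation factor.
#
# The CMH kernel is written as vectorized arithmetic over loci because the
# permutation engine re-evaluates every locus for every label permutation
# (10^5-10^8 stratified tables per run); stats::mantelhaen.test serves as
# an independent cross-check in the test suite.

#' Validate a stratified carrier count table
#'
#' The exchange format for per-locus carrier counts: one row per
#' (locus, stratum) with the number of case/control samples carrying at
#' least one qualifying CNV at the locus and the stratum arm sizes. This
#' is also the format external cohorts contribute when individual-level
#' data cannot be shared.
#'
#' @param tab data.frame with columns `locus_id`, `cnv_type`,
#'   `stratum_id`, `case_carriers`, `case_total`, `control_carriers`,
#'   `control_total`.
#' @return the validated data.frame.
#' @export
stratified_counts <- function(tab) {
  stopifnot_cols(tab, c("locus_id", "cnv_type", "stratum_id",
                        "case_carriers", "case_total",
                        "control_carriers", "control_total"),
                 "stratified count table")
  bad <- which(tab$case_carriers < 0 | tab$case_carriers > tab$case_total |
                 tab$control_carriers < 0 |
                 tab$control_carriers > tab$control_total)
  if (length(bad)) {
    stop(sprintf("count table row %d (locus %s, stratum %s): carriers outside [0, total]",
                 bad[1], tab$locus_id[bad[1]], tab$stratum_id[bad[1]]),
         call. = FALSE)
  }
  tab
}

# Hypergeometric moments per stratum. a = case carriers, c = control
# carriers; returns the pieces of the CMH statistic and MH odds ratio.
cmh_pieces <- function(a, n_case, c0, n_control) {
  # double arithmetic: products of counts overflow 32-bit integers
  a <- as.numeric(a); n_case <- as.numeric(n_case)
  c0 <- as.numeric(c0); n_control <- as.numeric(n_control)
  b <- n_case - a
  d <- n_control - c0
  N <- n_case + n_control
  m1 <- a + c0
  E <- n_case * m1 / N
  V <- n_case * n_control * m1 * (N - m1) / (N^2 * (N - 1))
  V[N <= 1] <- 0
  list(a = a, b = b, c = c0, d = d, N = N, E = E, V = V,
       R = a * d / N, S = b * c0 / N,
       P = (a + d) / N, Q = (b + c0) / N)
}

#' Cochran-Mantel-Haenszel test for a stratified 2x2 carrier table
#'
#' Computes the 1-df CMH score statistic
#' \deqn{X^2 = (\sum_i (a_i - E[a_i]))^2 / \sum_i Var(a_i)}
#' with hypergeometric moments per stratum, the Mantel-Haenszel common
#' odds ratio \eqn{\sum_i a_i d_i / N_i \, / \, \sum_i b_i c_i / N_i},
#' and its Robins-Breslow-Greenland confidence interval. Strata with no
#' carriers in either arm (or with everyone a carrier) contribute nothing
#' to the statistic and are skipped; if every stratum is degenerate the
#' test is flagged and returns p = 1 with an undefined odds ratio.
#'
#' @param case_carriers per-stratum case carrier counts, or a data.frame
#'   with columns `case_carriers`, `case_total`, `control_carriers`,
#'   `control_total` (e.g. one locus of a [stratified_counts()] table).
#' @param case_total,control_carriers,control_total per-stratum counts
#'   (ignored when a data.frame is given).
#' @param conf_level confidence level for the odds-ratio CI.
#' @param continuity apply a 0.5 continuity correction to the statistic
#'   (off by default: the plain two-sided score form).
#' @return list of class `cmh_result`: `statistic`, `p`, `or_mh`,
#'   `ci_low`, `ci_high`, `n_strata_informative`, `degenerate`.
#' @examples
#' cmh_test(c(5, 8), c(100, 120), c(1, 2), c(200, 180))
#' @export
cmh_test <- function(case_carriers, case_total = NULL,
                     control_carriers = NULL, control_total = NULL,
                     conf_level = 0.95, continuity = FALSE) {
  if (is.data.frame(case_carriers)) {
    tab <- case_carriers
    stopifnot_cols(tab, c("case_carriers", "case_total", "control_carriers",
                          "control_total"), "count table")
    a <- tab$case_carriers; n1 <- tab$case_total
    c0 <- tab$control_carriers; n2 <- tab$control_total
  } else {
    a <- case_carriers; n1 <- case_total
    c0 <- control_carriers; n2 <- control_total
  }
  if (any(a < 0 | a > n1 | c0 < 0 | c0 > n2)) {
    stop("carrier counts must lie in [0, total] per stratum", call. = FALSE)
  }
  pc <- cmh_pieces(a, n1, c0, n2)
  informative <- pc$V > 0
  if (!any(informative)) {
    return(structure(list(statistic = 0, p = 1, or_mh = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          n_strata_informative = 0L, degenerate = TRUE),
                     class = "cmh_result"))
  }
  num <- abs(sum(pc$a - pc$E))
  if (continuity) num <- max(0, num - 0.5)
  stat <- num^2 / sum(pc$V)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)

  sR <- sum(pc$R); sS <- sum(pc$S)
  if (sS == 0 && sR == 0) {
    or <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else if (sS == 0) {
    or <- Inf; ci <- c(NA_real_, Inf)
  } else {
    or <- sR / sS
    if (sR == 0) {
      ci <- c(0, NA_real_)
    } else {
      v <- sum(pc$P * pc$R) / (2 * sR^2) +
        sum(pc$P * pc$S + pc$Q * pc$R) / (2 * sR * sS) +
        sum(pc$Q * pc$S) / (2 * sS^2)
      z <- qnorm(1 - (1 - conf_level) / 2)
      ci <- exp(log(or) + c(-1, 1) * z * sqrt(v))
    }
  }
  structure(list(statistic = stat, p = p, or_mh = or,
                 ci_low = ci[1], ci_high = ci[2],
                 n_strata_informative = sum(informative),
                 degenerate = FALSE),
            class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf("CMH: X^2 = %.4g, p = %.4g, OR_MH = %.4g [%.4g, %.4g] (%d informative strata)\n",
              x$statistic, x$p, x$or_mh, x$ci_low, x$ci_high,
              x$n_strata_informative))
  invisible(x)
}

#' Sample odds ratio and Fisher's exact test for one 2x2 table
#'
#' @param a,b,c,d cell counts: case carriers, case non-carriers, control
#'   carriers, control non-carriers.
#' @return list with `or` (the sample odds ratio `a*d / (b*c)`; `Inf` when
#'   `b*c == 0`) and `p` (two-sided exact hypergeometric p-value).
#' @examples
#' fisher_or(5, 5197, 1, 8666)  # OR 8.34
#' @export
fisher_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all-zero 2x2 table", call. = FALSE)
  or <- if (b * c == 0 && a * d == 0) {
    NA_real_  # no contrast in either direction
  } else if (b * c == 0) {
    Inf
  } else {
    (a * d) / (b * c)
  }
  p <- fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  list(or = or, p = p)
}

#' Fit the covariate-adjusted burden logistic regression
#'
#' Fits `status ~ burden + GROUP + lrr_sd + n_cnv_raw` by maximum
#' likelihood, where `GROUP` is the categorical stratum label (the unique
#' array-group x ancestry-cluster x sex combination). Returns the burden
#' coefficient as an odds ratio with a Wald confidence interval and
#' p-value. Perfect separation or a constant burden metric raises an
#' explicit non-identifiability error rather than returning a huge
#' estimate.
#'
#' @param samples a sample table.
#' @param burden numeric burden metric, one value per row of `samples`
#'   (or named by sample id).
#' @param assignment stratum assignment (`sample_id`, `stratum_id`), e.g.
#'   `build_strata(...)$assignment`; samples outside any stratum are
#'   excluded from the fit.
#' @param conf_level Wald CI level.
#' @return list of class `burden_fit`: `or`, `ci_low`, `ci_high`, `p`,
#'   `statistic` (Wald z), `n`, `log_or`, `se`.
#' @export
fit_burden_logistic <- function(samples, burden, assignment,
                                conf_level = 0.95) {
  if (!is.null(names(burden))) burden <- burden[samples$sample_id]
  if (length(burden) != nrow(samples)) {
    stop("burden vector is not aligned to samples", call. = FALSE)
  }
  idx <- match(samples$sample_id, assignment$sample_id)
  keep <- !is.na(idx)
  df <- data.frame(
    y = as.integer(samples$status[keep] == "case"),
    burden = as.numeric(burden[keep]),
    GROUP = factor(assignment$stratum_id[idx[keep]]),
    lrr_sd = samples$lrr_sd[keep],
    n_cnv_raw = samples$n_cnv_raw[keep]
  )
  if (nrow(df) == 0) stop("no samples fall inside a stratum", call. = FALSE)
  if (sd(df$burden) == 0) {
    stop("burden metric is constant; effect not identifiable", call. = FALSE)
  }
  form <- if (nlevels(droplevels(df$GROUP)) >= 2) {
    y ~ burden + GROUP + lrr_sd + n_cnv_raw
  } else {
    y ~ burden + lrr_sd + n_cnv_raw
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", msg)) {
        invokeRestart("muffleWarning")  # handled via fit$converged below
      }
    }
  )
  beta <- coef(fit)["burden"]
  se <- sqrt(diag(vcov(fit))["burden"])
  if (separated || !fit$converged || !is.finite(se) || se > 50 ||
      abs(beta) > 25) {
    stop("burden effect not identifiable (separation or degenerate fit)",
         call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = unname(exp(beta)),
                 ci_low = unname(exp(beta - z * se)),
                 ci_high = unname(exp(beta + z * se)),
                 p = unname(2 * pnorm(-abs(beta / se))),
                 statistic = unname(beta / se),
                 n = nrow(df),
                 log_or = unname(beta), se = unname(se)),
            class = "burden_fit")
}

# ---- min(P) permutation engine ---------------------------------------

# Precompute per-locus CMH ingredients that are invariant under
# within-stratum label permutation: total E, total V, and the fixed
# contribution of external (count-only) strata.
minp_precompute <- function(carrier, assignment, external = NULL) {
  loci <- rownames(carrier)
  if (is.null(loci)) loci <- as.character(seq_len(nrow(carrier)))
  miss <- setdiff(assignment$sample_id, colnames(carrier))
  if (length(miss)) {
    stop("carrier matrix lacks column(s) for sample(s): ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  carrier <- carrier[, assignment$sample_id, drop = FALSE]
  storage.mode(carrier) <- "double"

  n_loci <- nrow(carrier)
  E_tot <- numeric(n_loci); V_tot <- numeric(n_loci)
  A_obs <- numeric(n_loci)
  strata_idx <- split(seq_len(nrow(assignment)), assignment$stratum_id)
  for (idx in strata_idx) {
    st <- assignment$status[idx]
    n_case <- sum(st == "case"); n_ctrl <- sum(st == "control")
    N <- n_case + n_ctrl
    m1 <- rowSums(carrier[, idx, drop = FALSE])
    E_tot <- E_tot + n_case * m1 / N
    if (N > 1) {
      V_tot <- V_tot + n_case * n_ctrl * m1 * (N - m1) / (N^2 * (N - 1))
    }
    A_obs <- A_obs + rowSums(carrier[, idx[st == "case"], drop = FALSE])
  }
  if (!is.null(external) && nrow(external)) {
    external <- stratified_counts(external)
    unknown <- setdiff(unique(external$locus_id), loci)
    if (length(unknown)) {
      stop("external counts name unknown locus/loci: ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    }
    li <- match(external$locus_id, loci)
    pc <- cmh_pieces(external$case_carriers, external$case_total,
                     external$control_carriers, external$control_total)
    for (k in seq_along(li)) {
      A_obs[li[k]] <- A_obs[li[k]] + pc$a[k]
      E_tot[li[k]] <- E_tot[li[k]] + pc$E[k]
      V_tot[li[k]] <- V_tot[li[k]] + pc$V[k]
    }
  }
  list(carrier = carrier, loci = loci, strata_idx = strata_idx,
       assignment = assignment, E_tot = E_tot, V_tot = V_tot, A_obs = A_obs)
}

minp_stat_to_p <- function(A, E, V) {
  stat <- (A - E)^2
  ok <- V > 0
  stat[ok] <- stat[ok] / V[ok]
  stat[!ok] <- 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[!ok] <- 1
  list(stat = stat, p = p, informative = ok)
}

#' Min(P) permutation null for stratified carrier association
#'
#' Permutes case/control labels independently within every stratum
#' (preserving stratum case counts), recomputes the per-locus CMH
#' p-values for each iteration, and records the minimum p-value across
#' loci. The empirical genome-wide significance threshold is the
#' `alpha`-quantile order statistic of those minima (k-th smallest with
#' `k = max(1, floor(alpha * n_perm))`), and per-locus family-wise error
#' rate adjusted p-values use the `(r + 1) / (n_perm + 1)` convention.
#' Count-only external strata have no permutable labels; their
#' contributions are held fixed across iterations.
#'
#' @param carrier 0/1 matrix (loci x samples, dimnames required) marking
#'   samples carrying at least one qualifying CNV at each locus.
#' @param assignment stratum assignment data.frame with `sample_id`,
#'   `stratum_id`, `status`.
#' @param n_perm number of label permutations; `0` returns observed
#'   results only.
#' @param alpha family-wise error rate defining the threshold quantile.
#' @param seed RNG seed (the engine is bit-reproducible given the seed).
#' @param external optional [stratified_counts()] table of frozen
#'   external-cohort counts, keyed to the carrier matrix's locus ids.
#' @return list of class `minp_null`: `observed` (data.frame `locus_id`,
#'   `statistic`, `p`, `informative`), `min_p` (length `n_perm`),
#'   `threshold`, `p_adjusted`, `alpha`, `n_perm`, `seed`.
#' @export
minp_permutation <- function(carrier, assignment, n_perm = 1000,
                             alpha = 0.05, seed = 1, external = NULL) {
  if (nrow(carrier) == 0) stop("no loci in carrier matrix", call. = FALSE)
  if (n_perm > 0 && n_perm < 100) {
    warning("n_perm < 100 gives a very coarse permutation null")
  }
  pre <- minp_precompute(carrier, assignment, external)
  obs <- minp_stat_to_p(pre$A_obs, pre$E_tot, pre$V_tot)
  observed <- data.frame(locus_id = pre$loci, statistic = obs$stat,
                         p = obs$p, informative = obs$informative,
                         stringsAsFactors = FALSE)
  if (n_perm == 0) {
    return(structure(list(observed = observed, min_p = NULL,
                          threshold = NA_real_, p_adjusted = NULL,
                          alpha = alpha, n_perm = 0L, seed = seed),
                     class = "minp_null"))
  }
  n_samples <- nrow(pre$assignment)
  min_p <- with_seed(seed, {
    # case-indicator matrix, one column per permutation, filled per stratum
    P <- matrix(0, n_samples, n_perm)
    for (idx in pre$strata_idx) {
      n_case <- sum(pre$assignment$status[idx] == "case")
      if (n_case == 0 || n_case == length(idx)) {
        P[idx, ] <- as.numeric(n_case > 0)
        next
      }
      for (j in seq_len(n_perm)) {
        P[idx[sample.int(length(idx), n_case)], j] <- 1
      }
    }
    A <- pre$carrier %*% P
    S <- (A - pre$E_tot)^2
    ok <- pre$V_tot > 0
    if (!any(ok)) {
      rep(1, n_perm)
    } else {
      S <- S[ok, , drop = FALSE] / pre$V_tot[ok]
      pchisq(apply(S, 2, max), df = 1, lower.tail = FALSE)
    }
  })
  k <- max(1L, floor(alpha * n_perm))
  threshold <- sort(min_p)[k]
  p_adjusted <- vapply(observed$p,
                       function(p0) (1 + sum(min_p <= p0)) / (n_perm + 1),
                       numeric(1))
  structure(list(observed = observed, min_p = min_p, threshold = threshold,
                 p_adjusted = p_adjusted, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "minp_null")
}

#' Double p-values for two rounds of association testing
#'
#' A Bonferroni-style correction for running the association scan once
#' per CNV class (deletions and duplications): `min(2p, 1)`.
#'
#' @param p numeric p-values in (0, 1].
#' @return the doubled, capped p-values.
#' @export
adjust_two_rounds <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  pmin(2 * p, 1)
}

#' Genomic inflation factor lambda
#'
#' Median of the chi-square (1 df) quantiles implied by the observed
#' p-values, divided by the null median (~0.4549). Lambda near 1
#' indicates calibrated tests; lambda substantially above 1 indicates
#' systematic inflation such as uncorrected population stratification.
#'
#' @param p p-values in (0, 1]; `NA`s are dropped.
#' @return the inflation factor (positive scalar).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}
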