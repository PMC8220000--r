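#' Composite signature score
#'
#' Per-gene z-standardization across samples, then the mean z over the
#' signature genes present in the matrix. Constant (zero-variance) genes are
#' excluded with a warning; signature genes absent from the matrix are
#' reported via `message()`.
#'
#' @param cohort A `cohort` object (or a gene x sample matrix).
#' @param genes Character vector of signature gene symbols.
#' @return Named per-sample numeric score.
#' @export
signature_score <- function(cohort, genes) {
  expr <- if (inherits(cohort, "cohort")) cohort$expression else cohort
  present <- intersect(genes, rownames(expr))
  assert_that(length(present) >= 1,
              "no signature gene overlaps the expression matrix")
  if (length(present) < length(genes))
    message(sprintf("%d signature gene(s) absent from the matrix",
                    length(genes) - length(present)))
  x <- expr[present, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance signature gene(s)",
                    sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    assert_that(nrow(x) >= 1, "all signature genes have zero variance")
  }
  z <- (x - rowMeans(x)) / sds
  colMeans(z)
}

#' Median dichotomization of a per-sample score
#'
#' `high` strictly above the median; ties at the median go `low`
#' (deterministic rule).
#'
#' @param scores Per-sample numeric scores (>= 2 samples).
#' @return Character vector of `"high"`/`"low"` labels (names preserved).
#' @export
dichotomize_median <- function(scores) {
  assert_that(length(scores) >= 2, "need >= 2 samples")
  med <- median(scores)
  labels <- ifelse(scores > med, "high", "low")
  if (all(labels == "low"))
    warning("all samples at or below the median: everyone labeled 'low'")
  labels
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood for a single continuous covariate by
#' Newton ascent (converged when |gradient| < 1e-8, at most 50 iterations),
#' with Efron (default) or Breslow handling of tied event times. The
#' standard error comes from the inverse observed information; `z = beta/se`
#' and the p-value is two-sided standard normal. Monotone likelihoods
#' (perfect separation, |beta| diverging) and non-convergence are flagged so
#' callers can exclude the fit from concordance calls.
#'
#' @param x Per-sample covariate (e.g. log2 expression of one gene).
#' @param time,event Survival time (days) and event indicator (1 = event).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit` list: `beta`, `se`, `hr`, `ci95_low`, `ci95_high`,
#'   `z`, `p`, `n`, `n_events`, `converged`, `flagged`.
#' @export
cox_univariate <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  assert_that(length(x) == length(time) && length(time) == length(event),
              "x, time, event must have equal length")
  assert_that(sum(event) >= 2, "need at least 2 events")
  assert_that(sd(x) > 0, "covariate is constant")
  # center for numerical stability (beta is invariant to location shifts)
  xc <- x - mean(x)
  ord <- order(time, -event)  # events precede same-time censorings
  xo <- xc[ord]; to <- time[ord]; do <- event[ord]
  n <- length(xo)
  # group tied event times; with to sorted ascending, the risk set at event
  # time t is the suffix starting at the first occurrence of t
  ev_times <- unique(to[do == 1])  # ascending (to is sorted)
  ev_groups <- split(which(do == 1), match(to[do == 1], ev_times))
  first_idx <- match(ev_times, to)
  d_k <- lengths(ev_groups)
  singles <- d_k == 1L
  single_i <- unlist(ev_groups[singles], use.names = FALSE)
  single_first <- first_idx[singles]
  tied_groups <- ev_groups[!singles]
  tied_first <- first_idx[!singles]
  sum_x_events <- sum(xo[do == 1])

  loglik_terms <- function(beta) {
    r <- exp(beta * xo)
    # risk-set sums at each position i: sum over j with t_j >= t_i
    s0 <- rev(cumsum(rev(r)))
    s1 <- rev(cumsum(rev(r * xo)))
    s2 <- rev(cumsum(rev(r * xo^2)))
    ll <- beta * sum_x_events
    grad <- sum_x_events
    info <- 0
    # untied events (vectorized); Efron and Breslow coincide at d = 1
    if (length(single_i)) {
      S0 <- s0[single_first]; S1 <- s1[single_first]; S2 <- s2[single_first]
      mu <- S1 / S0
      ll <- ll - sum(log(S0))
      grad <- grad - sum(mu)
      info <- info + sum(S2 / S0 - mu^2)
    }
    for (k in seq_along(tied_groups)) {
      idx <- tied_groups[[k]]
      first <- tied_first[k]
      d <- length(idx)
      S0 <- s0[first]; S1 <- s1[first]; S2 <- s2[first]
      if (ties == "breslow") {
        ll <- ll - d * log(S0)
        mu <- S1 / S0
        grad <- grad - d * mu
        info <- info + d * (S2 / S0 - mu^2)
      } else {
        D0 <- sum(r[idx]); D1 <- sum(r[idx] * xo[idx])
        D2 <- sum(r[idx] * xo[idx]^2)
        f <- (seq_len(d) - 1) / d
        A0 <- S0 - f * D0; A1 <- S1 - f * D1; A2 <- S2 - f * D2
        ll <- ll - sum(log(A0))
        mu <- A1 / A0
        grad <- grad - sum(mu)
        info <- info + sum(A2 / A0 - mu^2)
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- 0; converged <- FALSE; flagged <- FALSE
  for (iter in seq_len(50L)) {
    t3 <- loglik_terms(beta)
    if (!is.finite(t3$grad) || !is.finite(t3$info) || t3$info <= 0) {
      flagged <- TRUE; break
    }
    if (abs(t3$grad) < 1e-8) { converged <- TRUE; break }
    step <- t3$grad / t3$info
    step <- sign(step) * min(abs(step), 5)  # damp huge early steps
    beta <- beta + step
    if (abs(beta) > 50) { flagged <- TRUE; break }  # monotone likelihood
  }
  if (!converged) flagged <- TRUE
  info <- loglik_terms(beta)$info
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  z <- beta / se
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci95_low = exp(beta - 1.96 * se),
                 ci95_high = exp(beta + 1.96 * se),
                 z = z, p = 2 * pnorm(-abs(z)), n = n, n_events = sum(do),
                 converged = converged, flagged = flagged),
            class = "cox_fit")
}

#' Per-gene Cox screen across cohorts
#'
#' Fits [cox_univariate()] for each gene in each cohort (expression as a
#' continuous covariate). Genes constant in a cohort, or fits flagged for
#' separation/non-convergence, yield NA rows (excluded from concordance).
#'
#' @param cohorts List of `cohort` objects.
#' @param genes Genes to screen (default: all genes of the first cohort).
#' @param ties Tie handling, passed to [cox_univariate()].
#' @return Data frame: one row per gene x cohort with the `cox_fit` fields.
#' @export
cox_screen <- function(cohorts, genes = NULL, ties = "efron") {
  genes <- genes %||% rownames(cohorts[[1]]$expression)
  out <- vector("list", length(cohorts) * length(genes))
  i <- 0L
  for (co in cohorts) {
    for (g in genes) {
      i <- i + 1L
      row <- data.frame(gene = g, cohort_id = co$cohort_id,
                        beta = NA_real_, se = NA_real_, hr = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_,
                        z = NA_real_, p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE)
      if (g %in% rownames(co$expression) &&
          sd(co$expression[g, ]) > 0 && sum(co$survival$event) >= 2) {
        fit <- cox_univariate(co$expression[g, ], co$survival$time_days,
                              co$survival$event, ties = ties)
        row[c("beta", "se", "hr", "ci95_low", "ci95_high", "z", "p")] <-
          fit[c("beta", "se", "hr", "ci95_low", "ci95_high", "z", "p")]
        row$flagged <- fit$flagged
      }
      out[[i]] <- row
    }
  }
  do.call(rbind, out)
}

#' Multi-cohort concordance rule
#'
#' A gene is called reproducibly prognostic when at least `k_min` cohorts
#' have p < `alpha` AND the signs of their Cox coefficients agree. Flagged
#' or NA fits never count toward significance.
#'
#' @param fits Data frame from [cox_screen()] (columns `gene`, `cohort_id`,
#'   `beta`, `p`, optionally `flagged`).
#' @param alpha Per-cohort significance level (default 0.05).
#' @param k_min Minimum number of concordant significant cohorts (default 2).
#' @return Data frame: `gene`, `n_significant_cohorts` (largest same-sign
#'   significant count), `direction` (sign of the concordant coefficients,
#'   0 when none), `reproducible`.
#' @export
concordance_call <- function(fits, alpha = 0.05, k_min = 2L) {
  fits <- as.data.frame(fits)
  if (!"flagged" %in% names(fits)) fits$flagged <- FALSE
  res <- lapply(split(fits, fits$gene), function(d) {
    ok <- !d$flagged & is.finite(d$p) & d$p < alpha & is.finite(d$beta)
    n_pos <- sum(ok & d$beta > 0)
    n_neg <- sum(ok & d$beta < 0)
    n_best <- max(n_pos, n_neg)
    data.frame(gene = d$gene[1],
               n_significant_cohorts = n_best,
               direction = if (n_best == 0) 0 else if (n_pos >= n_neg) 1 else -1,
               reproducible = n_best >= k_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic comparing survival between two groups.
#'
#' @param labels Per-sample group labels (exactly two distinct values).
#' @param time,event Survival time and event indicator.
#' @return List with `chi2`, `p`, `observed` and `expected` events per group.
#' @export
logrank_test <- function(labels, time, event) {
  groups <- sort(unique(labels))
  assert_that(length(groups) == 2, "log-rank needs exactly two groups")
  assert_that(sum(event) >= 1, "need at least one event")
  g1 <- labels == groups[1]
  ev_times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = setNames(c(O1, sum(event) - O1), groups),
       expected = setNames(c(E1, sum(event) - E1), groups))
}

# Exact two-sided Mann-Whitney p by enumeration over all assignments of the
# pooled values to group A (valid under ties); used when both groups <= 8.
mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(2 * min(p_le, p_ge), 1)
}

# Normal approximation with tie correction.
mwu_normal_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  2 * pnorm(-abs(z))
}

#' Per-gene rank-based differential expression
#'
#' Two-sided Mann-Whitney U per gene: exact enumeration when both groups
#' have at most `exact_max` samples, otherwise a normal approximation with
#' tie and continuity correction. Direction is the sign of the median
#' difference (`"up"` = group B median above group A); all-tied genes get
#' p = 1.
#'
#' @param group_a,group_b Gene x sample matrices sharing row names (e.g.
#'   healthy HSCs vs AML blasts).
#' @param alpha Significance level (default 0.05).
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return Data frame: `gene`, `median_a`, `median_b`, `p`, `significant`,
#'   `direction`.
#' @export
diff_expression <- function(group_a, group_b, alpha = 0.05, exact_max = 8L) {
  genes <- intersect(rownames(group_a), rownames(group_b))
  assert_that(length(genes) >= 1, "no shared genes between groups")
  assert_that(ncol(group_a) >= 2 && ncol(group_b) >= 2,
              "need >= 2 samples per group")
  res <- lapply(genes, function(g) {
    a <- group_a[g, ]; b <- group_b[g, ]
    p <- if (length(unique(c(a, b))) == 1) 1
    else if (length(a) <= exact_max && length(b) <= exact_max) mwu_exact_p(a, b)
    else mwu_normal_p(a, b)
    ma <- median(a); mb <- median(b)
    data.frame(gene = g, median_a = ma, median_b = mb, p = p,
               significant = p < alpha,
               direction = if (mb > ma) "up" else if (mb < ma) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rounded fold-change summary
#'
#' `mean_a / mean_b`, rounded half-up to `decimals` places (the convention
#' used when reporting tumor-mass fold changes).
#'
#' @param mean_a Numerator mean.
#' @param mean_b Denominator mean (must be positive).
#' @param decimals Decimal places (default 1).
#' @return The rounded ratio.
#' @export
fold_change_summary <- function(mean_a, mean_b, decimals = 1L) {
  assert_that(is_number(mean_b) && mean_b > 0,
              "denominator mean must be positive")
  ratio <- mean_a / mean_b
  scale <- 10^decimals
  sign(ratio) * floor(abs(ratio) * scale + 0.5) / scale  # round half-up
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3, both non-constant).
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need equal-length vectors with n >= 3")
  assert_that(sd(x) > 0 && sd(y) > 0, "constant input")
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}
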