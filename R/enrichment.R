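#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the over-representation p-value
#' for observing `k` annotated genes in a query of size `n` when `K` of the
#' `N` universe genes carry the annotation. Computed by summing exact terms
#' in log space via `lchoose` for numerical stability.
#'
#' @param k Hits in the query.
#' @param n Query size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return The upper-tail probability in [0, 1].
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  assert_that(is_count(k) && is_count(n) && is_count(K) && is_count(N),
              "k, n, K, N must be non-negative integers")
  assert_that(k <= n && n <= N && K <= N && k <= K,
              "inconsistent counts: need k <= min(n, K), n <= N, K <= N")
  if (k == 0) return(1)
  i <- seq(k, min(n, K))
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  min(exp(m + log(sum(exp(log_terms - m)))), 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  assert_that(all(is.finite(p_values) & p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q <- pmin(rev(cummin(rev(p_values[o] * m / seq_len(m)))), 1)
  q[order(o)]
}

#' Hypergeometric over-representation analysis
#'
#' One upper-tail hypergeometric test per gene set, with Benjamini-Hochberg
#' correction across sets and significance at `q < alpha`.
#'
#' @param query Character vector of query genes (e.g. a selected interactome).
#' @param universe Character vector of all assayed genes.
#' @param sets A `gene_set_collection`.
#' @param alpha FDR significance level (default 0.05).
#' @return Data frame with columns `set_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `q_value`, `significant`.
#' @export
over_representation <- function(query, universe, sets, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  N <- length(universe)
  n <- length(query)
  assert_that(n >= 1, "query has no overlap with the universe")
  K <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  p <- mapply(hypergeometric_upper_tail, k = k, n = n, K = K, N = N)
  q <- benjamini_hochberg(p)
  data.frame(set_name = names(sets), k = k, n = n, K = K, N = N,
             p_value = p, q_value = q, significant = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Enrichment score of a gene set occupying positions `pos` (sorted ascending)
# of an N-long ranking, with hit weights w (|score|^exponent at those
# positions). The running sum increments by w/sum(w) at hits and decrements
# by 1/(N - m) at misses; the ES is the signed maximum deviation from zero,
# which is attained immediately after or immediately before a hit.
es_from_positions <- function(pos, w, N) {
  m <- length(pos)
  sw <- sum(w)
  if (sw == 0) w <- rep(1, m) else w <- w  # all-zero scores: unweighted hits
  sw <- sum(w)
  miss <- 1 / (N - m)
  cw <- cumsum(w) / sw
  after <- cw - (pos - seq_len(m)) * miss
  before <- c(0, cw[-m]) - (pos - seq_len(m)) * miss
  hi <- max(after)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on a fixed descending
#' ranking: hit increments proportional to |score|^`weight_exponent`
#' (normalized over the set), miss increments 1/(N - set size); the
#' enrichment score (ES) is the signed maximum deviation. The null is
#' gene-label permutation within the fixed ranking. NES = ES divided by the
#' mean |null ES| of matching sign; nominal p is the same-sign permutation
#' tail fraction with +1 smoothing; FDR q follows the sign-pooled NES
#' procedure. Significance at `fdr_q < 0.25`, the conventional GSEA cutoff.
#'
#' @param ranked Data frame with columns `gene`, `score` (any order; ranked
#'   descending by score internally), or a named numeric vector of scores.
#' @param sets A `gene_set_collection`; sets disjoint from the ranking are
#'   skipped with a warning.
#' @param weight_exponent 1 (weighted, default) or 0 (classic KS).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param fdr_cutoff Significance threshold on the FDR q-value (default 0.25).
#' @return Data frame with `set_name`, `size`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`, `significant`, `leading_edge` (slash-separated gene list).
#' @export
gsea_preranked <- function(ranked, sets, weight_exponent = 1,
                           n_perm = 1000L, seed = 1L, fdr_cutoff = 0.25) {
  if (is.data.frame(ranked)) {
    scores <- setNames(ranked$score, ranked$gene)
  } else scores <- ranked
  assert_that(all(is.finite(scores)), "gene scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  genes <- names(scores)
  N <- length(genes)
  w_all <- abs(scores)^weight_exponent

  keep <- vapply(sets, function(s) any(s %in% genes), TRUE)
  if (!all(keep))
    warning(sprintf("skipping %d set(s) disjoint from the ranked universe",
                    sum(!keep)))
  sets <- sets[keep]
  assert_that(length(sets) > 0, "no gene set overlaps the ranked universe")

  set.seed(seed)
  n_sets <- length(sets)
  es <- numeric(n_sets)
  sizes <- integer(n_sets)
  leading <- character(n_sets)
  null_es <- vector("list", n_sets)
  for (si in seq_len(n_sets)) {
    pos <- sort(which(genes %in% sets[[si]]))
    m <- length(pos)
    sizes[si] <- m
    es[si] <- es_from_positions(pos, w_all[pos], N)
    # leading edge: hits at or before (after: at or after) the ES extremum
    cw <- cumsum(w_all[pos]) / max(sum(w_all[pos]), .Machine$double.eps)
    run_after <- cw - (pos - seq_len(m)) / (N - m)
    if (es[si] >= 0) {
      peak <- which.max(run_after)
      leading[si] <- paste(genes[pos[seq_len(peak)]], collapse = "/")
    } else {
      run_before <- c(0, cw[-m]) - (pos - seq_len(m)) / (N - m)
      trough <- which.min(run_before)
      leading[si] <- paste(genes[pos[seq(trough, m)]], collapse = "/")
    }
    null_es[[si]] <- vapply(seq_len(n_perm), function(b) {
      rp <- sort(sample.int(N, m))
      es_from_positions(rp, w_all[rp], N)
    }, 0)
  }

  nes <- numeric(n_sets)
  nominal_p <- numeric(n_sets)
  null_nes <- vector("list", n_sets)
  for (si in seq_len(n_sets)) {
    nb <- null_es[[si]]
    same <- if (es[si] >= 0) nb[nb >= 0] else nb[nb < 0]
    denom_pos <- mean(nb[nb >= 0])
    denom_neg <- mean(abs(nb[nb < 0]))
    if (!is.finite(denom_pos) || denom_pos == 0) denom_pos <- 1
    if (!is.finite(denom_neg) || denom_neg == 0) denom_neg <- 1
    scale_for <- function(e) ifelse(e >= 0, e / denom_pos, e / denom_neg)
    nes[si] <- scale_for(es[si])
    null_nes[[si]] <- scale_for(nb)
    nominal_p[si] <- (1 + sum(abs(same) >= abs(es[si]))) / (1 + length(same))
  }

  # Sign-pooled FDR: compare each observed NES with the pooled null NES of
  # the same sign, normalizing by the observed-NES tail fraction.
  pooled <- unlist(null_nes)
  fdr_q <- vapply(seq_len(n_sets), function(si) {
    v <- nes[si]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(pooled[pooled >= 0] >= v)
      den <- mean(nes[nes >= 0] >= v)
    } else {
      num <- mean(pooled[pooled < 0] <= v)
      den <- mean(nes[nes < 0] <= v)
    }
    min(num / max(den, .Machine$double.eps), 1)
  }, 0)

  data.frame(set_name = names(sets), size = sizes, es = es, nes = nes,
             nominal_p = nominal_p, fdr_q = fdr_q,
             significant = is.finite(fdr_q) & fdr_q < fdr_cutoff,
             leading_edge = leading, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank genes for preranked enrichment
#'
#' Fold-change mode: mean log2 expression difference (high minus low group).
#' Correlation mode: Pearson correlation of each gene with a per-sample
#' reference score (e.g. a signature score); zero-variance genes get r = 0
#' with a warning. Descending order, ties broken by gene symbol.
#'
#' @param expression Gene x sample numeric matrix.
#' @param groups Factor/character of per-sample labels (`"high"`/`"low"`),
#'   for fold-change mode.
#' @param reference_score Per-sample numeric score, for correlation mode.
#' @return Data frame with columns `gene`, `score`, sorted descending.
#' @export
rank_genes <- function(expression, groups = NULL, reference_score = NULL) {
  assert_that(xor(is.null(groups), is.null(reference_score)),
              "provide exactly one of groups or reference_score")
  if (!is.null(groups)) {
    assert_that(all(groups %in% c("high", "low")),
                "groups must be 'high'/'low'")
    assert_that(sum(groups == "high") >= 2 && sum(groups == "low") >= 2,
                "need >= 2 samples per group")
    score <- rowMeans(expression[, groups == "high", drop = FALSE]) -
      rowMeans(expression[, groups == "low", drop = FALSE])
  } else {
    assert_that(ncol(expression) >= 3, "need >= 3 samples for correlation")
    centered <- expression - rowMeans(expression)
    sdg <- sqrt(rowSums(centered^2))
    y <- reference_score - mean(reference_score)
    sy <- sqrt(sum(y^2))
    score <- as.vector(centered %*% y) / (sdg * sy)
    if (any(sdg == 0)) {
      warning(sprintf("%d zero-variance gene(s): correlation set to 0",
                      sum(sdg == 0)))
      score[sdg == 0] <- 0
    }
  }
  out <- data.frame(gene = rownames(expression), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  out
}
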