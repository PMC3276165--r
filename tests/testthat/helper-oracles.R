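# Independent brute-force oracles used to validate the HMM and the
# evaluation statistics.  These deliberately share no code with the
# package's implementation paths.

# State posteriors of the copying HMM by full path enumeration.
# obs may contain NA (missing emits 1).  Vectorized over the K^M paths.
oracle_gamma <- function(obs, templ, p_switch, lambda) {
  M <- nrow(templ); K <- ncol(templ)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  w <- rep(1 / K, nrow(paths))
  for (j in seq_len(M)) {
    if (j > 1) {
      p <- p_switch[j - 1]
      w <- w * ((paths[, j] == paths[, j - 1]) * (1 - p) + p / K)
    }
    if (!is.na(obs[j])) {
      tj <- templ[j, paths[, j]]
      w <- w * ifelse(tj == obs[j], 1 - lambda, lambda)
    }
  }
  g <- matrix(0, M, K)
  for (j in seq_len(M))
    g[j, ] <- vapply(seq_len(K), function(k) sum(w[paths[, j] == k]),
                     numeric(1))
  g / rowSums(g)
}

# Marginal likelihood of one haplotype under the copying model, by the
# same enumeration.
oracle_hap_lik <- function(hap, templ, p_switch, lambda) {
  M <- nrow(templ); K <- ncol(templ)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  w <- rep(1 / K, nrow(paths))
  for (j in seq_len(M)) {
    if (j > 1) {
      p <- p_switch[j - 1]
      w <- w * ((paths[, j] == paths[, j - 1]) * (1 - p) + p / K)
    }
    tj <- templ[j, paths[, j]]
    w <- w * ifelse(tj == hap[j], 1 - lambda, lambda)
  }
  sum(w)
}

# Enumerated posterior over unordered phase configurations of a fully
# typed genotype vector: P(h1, h2) prop to L(h1) * L(h2) over the
# genotype-consistent pairs.  Returns probabilities named by the h1
# allele string (both orderings share mass symmetrically).
oracle_phase_posterior <- function(geno, templ, p_switch, lambda) {
  M <- length(geno)
  cfgs <- as.matrix(expand.grid(rep(list(0:1), M)))
  ok <- apply(cfgs, 1, function(h1) all(geno - h1 >= 0 & geno - h1 <= 1))
  cfgs <- cfgs[ok, , drop = FALSE]
  w <- apply(cfgs, 1, function(h1) {
    h2 <- geno - h1
    oracle_hap_lik(h1, templ, p_switch, lambda) *
      oracle_hap_lik(h2, templ, p_switch, lambda)
  })
  stats::setNames(w / sum(w), apply(cfgs, 1, paste, collapse = ""))
}

# Naive per-site Hamming distance.
oracle_hamming <- function(a, b, mask = rep(TRUE, length(a))) {
  d <- 0L
  for (j in seq_along(a)) if (mask[j] && a[j] != b[j]) d <- d + 1L
  d
}

# Direct-formula squared Pearson correlation.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}

# Per-SNP Hudson F_ST, ratio of averages, re-implemented with loops.
oracle_fst <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  num <- 0; den <- 0
  for (j in seq_len(nrow(a))) {
    p1 <- mean(a[j, ]); p2 <- mean(b[j, ])
    if (p1 == p2 && p1 %in% c(0, 1)) next
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  max(num / den, 0)
}
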