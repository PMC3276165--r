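# "Surrogate family" template selection: for each study haplotype, the
# k (phasing) or k_hap (imputation) candidate haplotypes with the
# smallest Hamming distance over the overlapping typed sites.  Haplotypes
# tied at the boundary distance are resolved by a uniform random draw
# from the run RNG, so the non-boundary part of every selection is
# deterministic given the distances.

#' Hamming distance between two haplotypes
#'
#' @param hap_a,hap_b integer 0/1 vectors of equal length.
#' @param mask logical vector marking the overlapping (typed, non-missing)
#'   sites to compare; defaults to all sites.
#' @return Integer count of masked positions where the alleles differ.
#' @export
hamming_distance <- function(hap_a, hap_b, mask = NULL) {
  if (length(hap_a) != length(hap_b))
    stop("haplotypes have different lengths")
  if (is.null(mask)) mask <- rep(TRUE, length(hap_a))
  if (length(mask) != length(hap_a)) stop("mask length mismatch")
  sum(hap_a[mask] != hap_b[mask])
}

# Distances from one query to every column of an allele matrix.
hamming_to_panel <- function(alleles, query, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(query))
  q <- as.integer(query)
  use <- as.logical(mask) & !is.na(q)
  q[is.na(q)] <- 0L
  .hamming_query_cpp(alleles, q, use)
}

#' Select the k nearest haplotypes by Hamming distance
#'
#' All haplotypes with distance strictly below the count-th order
#' statistic are always selected; the remaining slots are filled by a
#' uniform random draw from the haplotypes exactly at the boundary
#' distance.  If `count` exceeds the panel size it is clamped with a
#' warning.
#'
#' @param query integer 0/1 vector (NA allowed; such sites are excluded
#'   from the comparison).
#' @param alleles integer matrix (sites x haplotypes) to select from.
#' @param count number of haplotypes requested.
#' @param mask optional logical site mask.
#' @param distances optional precomputed distance vector (skips the
#'   Hamming computation).
#' @return List with `indices` (column indices of the selected
#'   haplotypes) and `distances` (their Hamming distances).
#' @export
select_k_nearest <- function(query, alleles, count, mask = NULL,
                             distances = NULL) {
  H <- if (is.null(distances)) ncol(alleles) else length(distances)
  if (count > H) {
    warning("requested ", count, " haplotypes but only ", H,
            " available; clamping")
    count <- H
  }
  d <- if (is.null(distances)) hamming_to_panel(alleles, query, mask) else distances
  thr <- sort(d, partial = count)[count]
  below <- which(d < thr)
  at <- which(d == thr)
  need <- count - length(below)
  chosen <- if (need >= length(at)) at else at[sample.int(length(at), need)]
  idx <- c(below, chosen)
  list(indices = idx, distances = d[idx])
}

#' Phasing template candidates for one individual
#'
#' Ranks the candidate pool (reference haplotypes plus the other study
#' individuals' current haplotypes) by Hamming distance to each of the
#' individual's two current haplotypes, takes the k/2 nearest per
#' haplotype (boundary ties randomized), unions them, and tops up to k
#' from the pooled ranking by the smaller of the two distances.
#'
#' @param hap1,hap2 the individual's two current haplotypes over typed
#'   sites.
#' @param pool integer matrix (typed sites x candidates); must already
#'   exclude the individual's own haplotypes.
#' @param k number of templates requested; if the pool is smaller the
#'   whole pool is used.
#' @return List with `indices` into the pool columns.
#' @export
phasing_candidates <- function(hap1, hap2, pool, k) {
  H <- ncol(pool)
  if (H <= k) return(list(indices = seq_len(H)))
  d1 <- hamming_to_panel(pool, hap1)
  d2 <- hamming_to_panel(pool, hap2)
  half <- k %/% 2L
  s1 <- select_k_nearest(hap1, pool, half, distances = d1)$indices
  s2 <- select_k_nearest(hap2, pool, k - half, distances = d2)$indices
  idx <- union(s1, s2)
  if (length(idx) < k) {
    rest <- setdiff(seq_len(H), idx)
    dmin <- pmin(d1, d2)[rest]
    top <- select_k_nearest(NULL, NULL, k - length(idx), distances = dmin)$indices
    idx <- c(idx, rest[top])
  }
  list(indices = idx)
}
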