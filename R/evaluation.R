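# Cross-validation accuracy harness: masking protocols, dosage R^2 with
# the R^2 = 0 convention for undefined correlations, MAF binning, and
# Hudson F_ST for ordering reference panels by divergence.

#' Allele dosage of a probability triple
#'
#' The posterior mean genotype `sum_x P(G = x) * x = P1 + 2 * P2`.
#'
#' @param triple numeric vector or 3-column matrix of
#'   `P(G=0), P(G=1), P(G=2)` summing to 1 within tolerance.
#' @return Dosage in \[0, 2\] (vector if `triple` is a matrix).
#' @export
dosage <- function(triple) {
  m <- if (is.matrix(triple)) triple else matrix(triple, ncol = 3)
  if (any(m < 0)) stop("negative probability in genotype triple")
  if (any(abs(rowSums(m) - 1) > 1e-3))
    stop("genotype triple does not sum to 1")
  drop(m[, 2] + 2 * m[, 3])
}

#' Per-SNP imputation R-squared
#'
#' Squared Pearson correlation between true genotypes and imputed allele
#' dosages.  When the correlation is undefined (either vector constant),
#' returns 0, reflecting that such a SNP carries no association power.
#' Individuals with missing truth are dropped pairwise.
#'
#' @param true_genotypes vector in 0/1/2 (NA allowed).
#' @param dosages matching dosage vector in \[0, 2\].
#' @return R-squared in \[0, 1\].
#' @export
snp_r2 <- function(true_genotypes, dosages) {
  if (length(true_genotypes) != length(dosages))
    stop("genotype and dosage vectors differ in length")
  ok <- !is.na(true_genotypes) & !is.na(dosages)
  g <- true_genotypes[ok]; d <- dosages[ok]
  if (length(g) < 2L) {
    warning("fewer than 2 complete pairs; returning R^2 = 0")
    return(0)
  }
  if (stats::var(g) == 0 || stats::var(d) == 0) return(0)
  stats::cor(g, d)^2
}

# Build the per-SNP report data frame from truth/dosage matrices.
report_from_matrices <- function(sites, truth, dos, metadata = list()) {
  r2 <- vapply(seq_len(nrow(sites)), function(j)
    suppressWarnings(snp_r2(truth[j, ], dos[j, ])), numeric(1))
  rep <- data.frame(id = sites$id, position = sites$position,
                    maf = genotype_maf(truth), r2 = r2,
                    stringsAsFactors = FALSE)
  structure(list(snps = rep, mean_r2 = mean(rep$r2), metadata = metadata),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$snps), " masked SNPs, mean R^2 = ",
      round(x$mean_r2, 4), "\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validation over a phased panel
#'
#' Masks the non-typed SNPs in one individual at a time, imputes them
#' from the haplotypes of all other individuals (the phase of the held-out
#' individual's typed genotypes is also masked), and scores each masked
#' SNP by [snp_r2()] across individuals once everyone has been imputed
#' exactly once.
#'
#' @param panel a [haplotype_panel()] of phased individuals (columns
#'   2i-1, 2i belong to individual i).
#' @param typed_mask logical or integer index of the sites treated as
#'   typed in the study; the rest are masked and imputed.
#' @param map a [genetic_map()].
#' @param params a [model_params()]; `k_hap` is clamped to the available
#'   reference haplotypes.
#' @param imputer function `(study, reference, map, params) ->
#'   imputation_result` (defaults to a single-chunk [run_mcmc()]).
#' @return An `eval_report`: per-SNP `id`, `position`, `maf` (in the
#'   validation panel), `r2`, plus `mean_r2` and metadata.
#' @export
leave_one_out <- function(panel, typed_mask, map, params = model_params(),
                          imputer = NULL) {
  if (is.logical(typed_mask)) typed_mask <- which(typed_mask)
  if (!length(typed_mask)) stop("typed_mask selects no sites")
  H <- ncol(panel$alleles)
  if (H < 4L || H %% 2L) stop("panel must contain at least 2 phased individuals")
  N <- H %/% 2L
  if (is.null(imputer))
    imputer <- function(study, reference, map, params)
      run_mcmc(study, reference, map, params)
  masked_idx <- setdiff(seq_len(nrow(panel$sites)), typed_mask)
  truth_all <- panel$alleles[, seq(1, H, 2)] + panel$alleles[, seq(2, H, 2)]
  dos <- matrix(NA_real_, length(masked_idx), N)
  for (i in seq_len(N)) {
    cols <- c(2L * i - 1L, 2L * i)
    reference <- subset_panel(panel, haplotypes = setdiff(seq_len(H), cols))
    stopifnot(!any(cols %in% setdiff(seq_len(H), cols)))
    g <- panel$alleles[typed_mask, cols[1]] + panel$alleles[typed_mask, cols[2]]
    study <- genotype_matrix(panel$sites[typed_mask, , drop = FALSE],
                             matrix(g, ncol = 1), panel$haplotype_ids[cols[1]])
    res <- imputer(study, reference, map, params)
    m <- match(panel$sites$position[masked_idx], res$untyped_sites$position)
    dos[, i] <- res$dosage[m, 1]
  }
  report_from_matrices(panel$sites[masked_idx, , drop = FALSE],
                       truth_all[masked_idx, , drop = FALSE], dos,
                       metadata = list(protocol = "leave_one_out",
                                       k_hap = params$k_hap,
                                       n_reference_haplotypes = H - 2L))
}

#' Indices masked in each pass of the every-Nth-SNP protocol
#'
#' Pass j masks the SNPs at indices congruent to j modulo n, so the n
#' passes cover every SNP exactly once.
#'
#' @param n_snps total SNP count.
#' @param n stride (e.g. 25 or 13).
#' @return List of n integer index vectors (empty passes possible when
#'   `n > n_snps`).
#' @export
nth_mask_indices <- function(n_snps, n) {
  if (n < 2L) stop("stride n must be at least 2")
  lapply(seq_len(n), function(j) seq_len(n_snps)[(seq_len(n_snps) - j) %% n == 0])
}

#' Every-Nth-SNP sliding-window masking
#'
#' Masks and imputes every n-th typed SNP, repeating in a sliding window
#' so that every SNP is imputed exactly once from the remaining typed
#' SNPs and the reference panel.  Truth is the observed study genotype at
#' the masked SNP.
#'
#' @param study a [genotype_matrix()].
#' @param n stride.
#' @param reference a [haplotype_panel()].
#' @param map a [genetic_map()].
#' @param params a [model_params()].
#' @param imputer function `(study, reference, map, params) ->
#'   imputation_result` (defaults to a single-chunk [run_mcmc()]).
#' @return An `eval_report` over all study SNPs.
#' @export
every_nth_mask <- function(study, n, reference, map,
                           params = model_params(), imputer = NULL) {
  if (is.null(imputer))
    imputer <- function(study, reference, map, params)
      run_mcmc(study, reference, map, params)
  M <- nrow(study$sites)
  passes <- nth_mask_indices(M, n)
  dos <- matrix(NA_real_, M, ncol(study$genotypes))
  for (mask in passes) {
    if (!length(mask)) next
    typed <- setdiff(seq_len(M), mask)
    sub <- genotype_matrix(study$sites[typed, , drop = FALSE],
                           study$genotypes[typed, , drop = FALSE],
                           study$individual_ids)
    res <- imputer(sub, reference, map, params)
    m <- match(study$sites$position[mask], res$untyped_sites$position)
    bad <- is.na(m)
    if (any(bad))
      warning(sum(bad), " masked SNP(s) absent from the reference; no dosage")
    dos[mask[!bad], ] <- res$dosage[m[!bad], , drop = FALSE]
  }
  report_from_matrices(study$sites, study$genotypes, dos,
                       metadata = list(protocol = "every_nth_mask",
                                       stride = n, k_hap = params$k_hap))
}

#' MAF-binned mean R-squared
#'
#' Assigns SNPs to half-open MAF bins `(lo, hi]` of the given width and
#' averages R-squared within bins.  Empty bins are absent from the
#' output rather than reported as zero.
#'
#' @param report an `eval_report`.
#' @param bin_width bin width dividing 0.5 (default 0.05).
#' @param min_maf SNPs with MAF below this are excluded (default 0,
#'   i.e. keep all; 0.01 reproduces the harness's usual filter for
#'   unreliable ultra-rare SNPs).
#' @return data.frame with `lo`, `hi`, `n`, `mean_r2` per non-empty bin.
#' @export
maf_binned_summary <- function(report, bin_width = 0.05, min_maf = 0) {
  if (abs(0.5 / bin_width - round(0.5 / bin_width)) > 1e-9)
    stop("bin_width must divide 0.5")
  snps <- report$snps
  snps <- snps[!is.na(snps$maf) & snps$maf >= min_maf, , drop = FALSE]
  edges <- seq(0, 0.5, by = bin_width)
  bin <- cut(snps$maf, breaks = edges, include.lowest = FALSE, right = TRUE)
  keep <- !is.na(bin)
  agg <- tapply(snps$r2[keep], bin[keep], mean)
  cnt <- table(bin[keep])
  nonempty <- which(cnt > 0)
  data.frame(lo = edges[nonempty], hi = edges[nonempty + 1L],
             n = as.integer(cnt[nonempty]),
             mean_r2 = as.numeric(agg[nonempty]))
}

#' Hudson F_ST between two haplotype panels
#'
#' Per-SNP Hudson estimator from haplotype allele frequencies and sample
#' sizes, averaged as a ratio of averages across the shared SNPs.  SNPs
#' monomorphic in both panels are skipped.  Negative estimates (possible
#' for the unbiased estimator when the panels are effectively identical)
#' are truncated to 0, since only the ordering is used downstream.
#'
#' @param panelA,panelB [haplotype_panel()]s sharing sites (matched by
#'   position).
#' @return F_ST estimate in \[0, 1\].
#' @export
pairwise_fst <- function(panelA, panelB) {
  m <- match(panelA$sites$position, panelB$sites$position)
  keep <- !is.na(m)
  if (!any(keep)) stop("panels share no sites")
  a <- panelA$alleles[keep, , drop = FALSE]
  b <- panelB$alleles[m[keep], , drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  p1 <- rowMeans(a); p2 <- rowMeans(b)
  # skip only sites monomorphic for the SAME allele in both panels;
  # fixed differences are maximally informative
  poly <- !(p1 == p2 & p1 %in% c(0, 1))
  if (!any(poly)) stop("no shared polymorphic SNPs")
  p1 <- p1[poly]; p2 <- p2[poly]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  max(sum(num) / sum(den), 0)
}

#' Order panels by increasing F_ST to a target panel
#'
#' @param target a [haplotype_panel()].
#' @param panels named list of [haplotype_panel()]s.
#' @return data.frame of panel names and F_ST, sorted increasing; the
#'   order in which panels would be cumulatively added to the target's
#'   reference set.
#' @export
fst_ordering <- function(target, panels) {
  fst <- vapply(panels, function(p) pairwise_fst(target, p), numeric(1))
  out <- data.frame(panel = names(panels), fst = fst,
                    stringsAsFactors = FALSE)
  out[order(out$fst), , drop = FALSE]
}

#' Score an imputation result against known truth
#'
#' Builds a per-SNP accuracy report for a simulated experiment whose
#' true genotypes at the untyped sites are known.
#'
#' @param result an `imputation_result` from [run_mcmc()] or
#'   [impute_genotypes()].
#' @param truth integer genotype matrix (all sites x individuals).
#' @param sites the full site table the truth rows refer to.
#' @param metadata optional metadata list stored on the report.
#' @return An `eval_report` over the untyped sites (MAF computed in the
#'   study truth).
#' @export
score_imputation <- function(result, truth, sites, metadata = list()) {
  m <- match(result$untyped_sites$position, sites$position)
  report_from_matrices(result$untyped_sites,
                       truth[m, , drop = FALSE],
                       result$dosage, metadata = metadata)
}

#' Mean accuracy across a k_hap grid
#'
#' Reruns imputation of one simulated experiment for each `k_hap` value
#' and reports the mean R-squared at the masked (untyped) sites, overall
#' and at low-frequency SNPs (MAF below `low_maf` in the study truth).
#'
#' @param experiment output of [simulate_imputation_study()] (or any list
#'   with `reference`, `study`, `truth`, `sites`, `map`).
#' @param khaps integer vector of k_hap values (clamped to panel size).
#' @param params base [model_params()]; `k_hap` is overridden per run.
#' @param low_maf MAF threshold defining the low-frequency class
#'   (default 0.05; sites monomorphic in the study are excluded).
#' @param seed optional seed applied before each run for comparability.
#' @return data.frame with `k_hap`, `mean_r2`, `mean_r2_low`, `n_snps`,
#'   `n_low`.
#' @export
khap_curve <- function(experiment, khaps, params = model_params(),
                       low_maf = 0.05, seed = NULL) {
  out <- lapply(khaps, function(kh) {
    p <- params; p$k_hap <- as.integer(kh)
    if (!is.null(seed)) set.seed(seed)
    res <- run_mcmc(experiment$study, experiment$reference,
                    experiment$map, p)
    rep <- score_imputation(res, experiment$truth, experiment$sites,
                            metadata = list(k_hap = kh))
    maf <- rep$snps$maf
    low <- !is.na(maf) & maf > 0 & maf < low_maf
    data.frame(k_hap = kh, mean_r2 = rep$mean_r2,
               mean_r2_low = mean(rep$snps$r2[low]),
               n_snps = nrow(rep$snps), n_low = sum(low))
  })
  do.call(rbind, out)
}

#' Preset k_hap grid
#'
#' The conventional evaluation grid, clamped to the panel size, plus the
#' all-haplotypes point.
#'
#' @param panel_size number of reference haplotypes.
#' @return Increasing integer vector of k_hap values.
#' @export
khap_grid <- function(panel_size) {
  g <- c(15, 30, 60, 90, 120, 150, 200, 250, 300, 350, 400, 500,
         seq(600, 2000, by = 100), 2020)
  sort(unique(c(g[g < panel_size], panel_size)))
}
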