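# In-code fixtures shared across tests.

# A 1 cM/Mb map over [1, 1e6].
test_map <- function() genetic_map(c(1, 1e6), c(0, 1))

# Random panel of M sites x H haplotypes at random positions.
random_panel <- function(M, H, max_pos = 1e6) {
  pos <- sort(sample.int(max_pos, M))
  sites <- variant_sites(paste0("rs", seq_len(M)), pos,
                         rep("A", M), rep("C", M))
  haplotype_panel(sites, matrix(sample(0:1, M * H, TRUE), M, H))
}

# Two-haplotype-class panel in complete LD: nA copies of the all-0
# haplotype and nB copies of the all-1 haplotype over M sites.
two_class_panel <- function(M, nA, nB, max_pos = 1e5) {
  pos <- round(seq(1000, max_pos, length.out = M))
  sites <- variant_sites(paste0("s", seq_len(M)), pos,
                         rep("A", M), rep("C", M))
  haplotype_panel(sites, cbind(matrix(0L, M, nA), matrix(1L, M, nB)))
}

# Stub imputer for protocol tests: records the typed sites of each pass
# and returns the reference allele frequency as a flat dosage.
recording_imputer <- function(log_env) {
  function(study, reference, map, params) {
    log_env$typed <- c(log_env$typed, list(study$sites$position))
    untyped <- setdiff(seq_len(nrow(reference$sites)),
                       match(study$sites$position,
                             reference$sites$position))
    freq <- rowMeans(reference$alleles[untyped, , drop = FALSE])
    n <- ncol(study$genotypes)
    structure(list(untyped_sites = reference$sites[untyped, , drop = FALSE],
                   dosage = matrix(rep(2 * freq, n), ncol = n)),
              class = "imputation_result")
  }
}
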