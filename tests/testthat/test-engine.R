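test_that("phase initialization is genotype-consistent and seed-reproducible", {
  # all-homozygous individual: deterministic haplotypes
  g <- matrix(c(0L, 2L, 0L, 2L), 4, 1)
  expect_equal(initialize_phase(g), cbind(g[, 1] %/% 2L, g[, 1] %/% 2L))

  set.seed(12)
  geno <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(.3, .3, .3, .1)), 20, 3)
  set.seed(5); h <- initialize_phase(geno)
  for (i in 1:3) {
    s <- h[, 2 * i - 1] + h[, 2 * i]
    ok <- !is.na(geno[, i])
    expect_equal(s[ok], geno[ok, i])
  }
  set.seed(5); h2 <- initialize_phase(geno)
  expect_identical(h, h2)
})

test_that("chunking tiles the region with clipped buffers", {
  ch <- make_chunks(0, 12e6, 5e6, 250e3)
  expect_length(ch, 3L)
  expect_equal(lapply(ch, `[[`, "core"),
               list(c(0, 5e6), c(5e6, 10e6), c(10e6, 12e6)))
  expect_equal(ch[[2]]$buffer, c(4.75e6, 10.25e6))
  expect_equal(ch[[1]]$buffer, c(0, 5.25e6))

  expect_length(make_chunks(100, 2e6), 1L)
  expect_equal(make_chunks(100, 2e6)[[1]]$core, c(100, 2e6))
  expect_error(make_chunks(5, 5), "exceed")

  set.seed(61)
  for (r in 1:25) {
    a <- sample.int(1e6, 1); b <- a + sample.int(3e7, 1)
    size <- sample.int(7e6, 1)
    ch <- lapply(make_chunks(a, b, size, 1e5), `[[`, "core")
    expect_equal(ch[[1]][1], a)
    expect_equal(ch[[length(ch)]][2], b)
    for (i in seq_along(ch)[-1])
      expect_equal(ch[[i]][1], ch[[i - 1]][2])  # disjoint, gap-free tiling
  }
})

test_that("a perfectly matching homozygous reference pair forces the
          imputed genotype", {
  set.seed(71)
  M <- 40
  panel <- random_panel(M, 10, max_pos = 2e5)
  target <- panel$alleles[, 1]
  # reference contains an identical pair carrying the target haplotype
  ref <- subset_panel(panel, haplotypes = c(1, 1, 2:10))
  typed <- seq(1, M, by = 2)
  study <- genotype_matrix(panel$sites[typed, , drop = FALSE],
                           matrix(2L * target[typed], ncol = 1))
  map <- test_map()
  params <- model_params(k = 4, k_hap = 2, iterations = 6, burnin = 2,
                         lambda = 1e-4)
  res <- run_mcmc(study, ref, map, params)
  untyped <- setdiff(seq_len(M), typed)
  want <- target[untyped] + 1L  # 0 -> P(G=0), 1 -> P(G=2)
  tri <- cbind(res$probs$p0[, 1], res$probs$p1[, 1], res$probs$p2[, 1])
  hit <- tri[cbind(seq_along(untyped), ifelse(target[untyped] == 1, 3, 1))]
  expect_true(all(hit > 0.99))
  expect_equal(rowSums(tri), rep(1, length(untyped)), tolerance = 1e-9)
  expect_true(all(res$dosage >= 0 & res$dosage <= 2))
})

test_that("averaging identical post-burn-in sweeps equals a single sweep", {
  # with a fully homozygous study the phase chain is deterministic and
  # k_hap = panel size removes selection ties, so every sweep's triples
  # are identical and the average must equal one sweep.
  set.seed(81)
  M <- 30
  panel <- random_panel(M, 8, max_pos = 1e5)
  target <- panel$alleles[, 3]
  typed <- seq(2, M, by = 2)
  study <- genotype_matrix(panel$sites[typed, , drop = FALSE],
                           matrix(2L * target[typed], ncol = 1))
  map <- test_map()
  long <- model_params(k = 80, k_hap = 8, iterations = 5, burnin = 1)
  short <- model_params(k = 80, k_hap = 8, iterations = 5, burnin = 4)
  set.seed(1); a <- run_mcmc(study, panel, map, long)
  set.seed(2); b <- run_mcmc(study, panel, map, short)
  expect_equal(a$probs, b$probs, tolerance = 1e-12)
})

test_that("requesting more templates than the panel holds clamps k_hap", {
  set.seed(91)
  panel <- random_panel(20, 6, max_pos = 1e5)
  study <- genotype_matrix(panel$sites[1:10, , drop = FALSE],
                           matrix(panel$alleles[1:10, 1] +
                                    panel$alleles[1:10, 2], ncol = 1))
  params <- model_params(k_hap = 500, iterations = 2, burnin = 1)
  expect_message(res <- run_mcmc(study, panel, test_map(), params), "clamp")
  expect_equal(res$k_hap_used, 6L)
})

test_that("stitching keeps each core site exactly once", {
  set.seed(102)
  cfg <- sim_config(n_populations = 1, haplotypes_per_population = 16,
                    region_length = 6e5, snp_density = 0.3,
                    split_depth = 0, switch_rate = 0.02)
  sim <- simulate_panels(cfg)
  ref <- subset_panel(sim$combined, haplotypes = 1:12)
  held <- subset_panel(sim$combined, haplotypes = 13:16)
  typed <- sort(sample.int(nrow(ref$sites), 60))
  st <- make_study(held, 2, typed)
  params <- model_params(k = 10, k_hap = 12, iterations = 3, burnin = 1)
  res <- impute_genotypes(st$study, ref, sim$map, params,
                          region = c(0, 6e5), chunk_size = 2e5,
                          buffer = 5e4, seed = 4)
  got <- sort(c(res$untyped_sites$position, res$typed_sites$position))
  expect_equal(got, sort(ref$sites$position))  # every site exactly once
  expect_length(unique(got), length(got))
})

test_that("equal seeds give identical end-to-end results", {
  set.seed(112)
  cfg <- sim_config(n_populations = 1, haplotypes_per_population = 20,
                    region_length = 2e5, snp_density = 0.5, split_depth = 0)
  sim <- simulate_panels(cfg)
  ref <- subset_panel(sim$combined, haplotypes = 1:14)
  held <- subset_panel(sim$combined, haplotypes = 15:20)
  typed <- sort(sample.int(nrow(ref$sites), 30))
  st <- make_study(held, 3, typed)
  params <- model_params(k = 8, k_hap = 10, iterations = 4, burnin = 1)
  r1 <- impute_genotypes(st$study, ref, sim$map, params, seed = 77)
  r2 <- impute_genotypes(st$study, ref, sim$map, params, seed = 77)
  expect_identical(r1, r2)
})

test_that("imputation beats the frequency-only baseline, more so with a
          larger reference", {
  set.seed(123)
  cfg <- sim_config(n_populations = 1, haplotypes_per_population = 170,
                    region_length = 3e5, snp_density = 1.5,
                    split_depth = 0, switch_rate = 0.02)
  sim <- simulate_panels(cfg)
  H <- ncol(sim$combined$alleles)
  held <- subset_panel(sim$combined, haplotypes = (H - 19):H)
  avail <- subset_panel(sim$combined, haplotypes = 1:(H - 20))
  typed <- ascertain_array(avail, target_density = 0.4, maf_floor = 0.05)
  st <- make_study(held, 10, typed)
  untyped <- setdiff(seq_len(nrow(avail$sites)), typed)
  truth_untyped <- st$truth[untyped, , drop = FALSE]
  params <- model_params(k = 20, iterations = 8, burnin = 3)
  mean_r2_for <- function(nref) {
    ref <- subset_panel(avail, haplotypes = seq_len(nref))
    p <- params; p$k_hap <- nref
    res <- run_mcmc(st$study, ref, sim$map, p)
    m <- match(avail$sites$position[untyped], res$untyped_sites$position)
    r2 <- vapply(seq_along(untyped), function(j)
      suppressWarnings(snp_r2(truth_untyped[j, ], res$dosage[m[j], ])),
      numeric(1))
    mean(r2)
  }
  set.seed(9); small <- mean_r2_for(30)
  set.seed(9); large <- mean_r2_for(150)
  # the frequency-only baseline (dosage = 2*MAF for everyone) is
  # constant, so its per-SNP R^2 is 0 by convention
  expect_gt(small, 0.1)
  expect_gt(large, small)
})
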