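test_that("zero split depth gives undifferentiated populations", {
  set.seed(7)
  cfg <- sim_config(n_populations = 2, haplotypes_per_population = 80,
                    region_length = 1e5, snp_density = 3, split_depth = 0)
  sim <- simulate_panels(cfg)
  expect_lt(pairwise_fst(sim$panels[[1]], sim$panels[[2]]), 0.01)
})

test_that("a degenerate mosaic reproduces founders exactly", {
  set.seed(17)
  cfg <- sim_config(n_populations = 1, haplotypes_per_population = 30,
                    region_length = 5e4, snp_density = 2,
                    switch_rate = 0, mismatch_rate = 0, n_founders = 5)
  sim <- simulate_panels(cfg)
  founders <- sim$founders[[1]]
  keys <- apply(founders, 2, paste, collapse = "")
  for (h in seq_len(ncol(sim$panels[[1]]$alleles)))
    expect_true(paste(sim$panels[[1]]$alleles[, h], collapse = "") %in% keys)
})

test_that("F_ST grows monotonically with split depth", {
  set.seed(27)
  fst <- vapply(c(0.05, 0.15, 0.4), function(Fd) {
    cfg <- sim_config(n_populations = 2, haplotypes_per_population = 100,
                      region_length = 5e5, snp_density = 3,
                      split_depth = c(0.001, Fd))
    sim <- simulate_panels(cfg)
    pairwise_fst(sim$panels[[1]], sim$panels[[2]])
  }, numeric(1))
  expect_true(all(diff(fst) > 0))
})

test_that("array-like ascertainment favors common SNPs within the floor", {
  set.seed(37)
  cfg <- sim_config(n_populations = 1, haplotypes_per_population = 100,
                    region_length = 2e5, snp_density = 3, split_depth = 0)
  sim <- simulate_panels(cfg)
  panel <- sim$panels[[1]]
  maf <- panel_maf(panel)
  sel <- ascertain_array(panel, target_density = 0.3, maf_floor = 0.05)
  expect_true(all(maf[sel] >= 0.05))
  expect_true(!is.unsorted(sel))
  w <- suppressWarnings(stats::wilcox.test(maf[sel], maf,
                                           alternative = "greater"))
  expect_lt(w$p.value, 0.01)
  # flat weights and no floor with full density keep every polymorphic site
  all_sel <- ascertain_array(panel, target_density = 1e6, maf_floor = 0,
                             weight_by_maf = FALSE)
  expect_equal(all_sel, which(maf > 0))
  expect_error(ascertain_array(panel, maf_floor = 0.6), "floor")
})

test_that("discovery ascertainment follows the allele-count curve per
          population with a union rule", {
  set.seed(47)
  cfg <- sim_config(n_populations = 3, haplotypes_per_population = 50,
                    region_length = 5e4, snp_density = 3)
  sim <- simulate_panels(cfg)
  always <- discovery_model(1, 1)
  seg <- which(Reduce(`|`, lapply(sim$panels,
                                  function(p) rowSums(p$alleles) > 0)))
  expect_equal(ascertain_discovery(sim$panels, always), seg)
  never <- discovery_model(1, 0)
  expect_length(ascertain_discovery(sim$panels, never), 0L)

  # hard threshold at 5 copies is deterministic: union of count >= 5
  step <- discovery_model(c(4, 5), c(0, 1))
  want <- which(Reduce(`|`, lapply(sim$panels,
                                   function(p) rowSums(p$alleles) >= 5)))
  expect_equal(ascertain_discovery(sim$panels, step), want)

  # probabilistic curve: retained fraction within 3 SE of expectation
  half <- discovery_model(1, 0.5)
  pkeep <- 1 - Reduce(`*`, lapply(sim$panels, function(p)
    ifelse(rowSums(p$alleles) > 0, 0.5, 1)))
  exp_n <- sum(pkeep); sd_n <- sqrt(sum(pkeep * (1 - pkeep)))
  got <- length(ascertain_discovery(sim$panels, half))
  expect_lt(abs(got - exp_n), 3 * sd_n)
  expect_error(discovery_model(c(1, 2), c(0.9, 0.1)), "non-decreasing")
})

test_that("study construction pairs held-out haplotypes consistently", {
  set.seed(57)
  panel <- random_panel(30, 2)
  st <- make_study(panel, 1, typed_sites = 1:10)
  expect_equal(sort(as.vector(st$hap_pairs)), 1:2)
  expect_equal(st$study$genotypes[, 1],
               panel$alleles[1:10, 1] + panel$alleles[1:10, 2])

  panel2 <- random_panel(30, 20)
  st2 <- make_study(panel2, 6, typed_sites = seq(1, 30, 3))
  expect_length(unique(as.vector(st2$hap_pairs)), 12L)
  expect_equal(st2$truth,
               st2$truth_haplotypes[, seq(1, 11, 2)] +
                 st2$truth_haplotypes[, seq(2, 12, 2)])
  expect_error(make_study(panel2, 11, 1:5), "available")
})

test_that("simulated experiments round-trip through the file formats", {
  set.seed(67)
  cfg <- sim_config(n_populations = 2, haplotypes_per_population = 30,
                    region_length = 1e5, snp_density = 1)
  exp <- simulate_imputation_study(cfg, n_study = 4,
                                   target_density = 0.5)
  prefix <- tempfile()
  write_experiment(exp, prefix)
  ref <- read_hap_legend(paste0(prefix, ".hap"), paste0(prefix, ".legend"))
  expect_identical(ref$alleles, exp$reference$alleles)
  st <- read_gen(paste0(prefix, ".gen"))
  expect_identical(st$genotypes, unname(exp$study$genotypes))
  map <- read_genetic_map(paste0(prefix, ".map"))
  expect_equal(interpolate_cm(map, 5e4), interpolate_cm(exp$map, 5e4),
               tolerance = 1e-6)
  # study haplotypes are held out of the reference panel
  expect_equal(ncol(exp$reference$alleles), (30 - 2 * 4) + 30)
  held_ids <- paste0("pop1_hap", (30 - 2 * 4 + 1):30)
  expect_length(intersect(exp$reference$haplotype_ids, held_ids), 0L)
})

test_that("the default simulate-ascertain-impute-evaluate loop recovers
          common variants", {
  set.seed(87)
  cfg <- sim_config(n_populations = 2, haplotypes_per_population = 60,
                    region_length = 2e5, snp_density = 2)
  exp <- simulate_imputation_study(cfg, n_study = 8, target_density = 0.4)
  params <- model_params(k = 20, k_hap = 60, iterations = 8, burnin = 3)
  res <- run_mcmc(exp$study, exp$reference, exp$map, params)
  untyped <- setdiff(seq_len(nrow(exp$sites)), exp$typed_sites)
  truth <- exp$truth[untyped, , drop = FALSE]
  m <- match(exp$sites$position[untyped], res$untyped_sites$position)
  maf <- genotype_maf(truth)
  common <- which(maf >= 0.1)
  r2 <- vapply(common, function(j)
    suppressWarnings(snp_r2(truth[j, ], res$dosage[m[j], ])), numeric(1))
  expect_gt(mean(r2), 0.5)
})
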