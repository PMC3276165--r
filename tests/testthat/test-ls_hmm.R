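test_that("transition schedule follows the Ne-scaled map distances", {
  map <- test_map()
  sch <- build_transitions(map, c(1000, 1000, 5000)[c(1, 3)], 20000, 4)
  d <- (interpolate_cm(map, 5000) - interpolate_cm(map, 1000)) / 100
  expect_equal(sch$rho, 4 * 20000 * d)
  expect_equal(sch$p_switch, 1 - exp(-sch$rho / 4))

  # zero genetic distance: stay probability 1
  sch0 <- build_transitions(genetic_map(c(1, 1e6), c(0, 0)),
                            c(100, 900), 20000, 5)
  expect_equal(sch0$p_switch, 0)

  # huge rho: all transition probabilities tend to 1/K
  schI <- build_transitions(map, c(1, 1e6), 1e9, 3)
  p <- schI$p_switch
  expect_equal(p / 3, 1 / 3, tolerance = 1e-9)          # off-diagonal
  expect_equal((1 - p) + p / 3, 1 / 3, tolerance = 1e-9)  # diagonal

  # full transition matrix rows sum to 1 for random rho and K
  set.seed(3)
  for (r in 1:20) {
    K <- sample(2:10, 1); p <- stats::runif(1)
    Tm <- matrix(p / K, K, K); diag(Tm) <- (1 - p) + p / K
    expect_equal(rowSums(Tm), rep(1, K))
  }
  expect_error(build_transitions(map, c(500, 100), 20000, 4), "sorted")
})

test_that("haploid forward-backward handles degenerate template sets", {
  map <- test_map()
  pos <- c(1000, 2000, 3000)
  params <- model_params(lambda = 0.01)

  sch1 <- build_transitions(map, pos, 20000, 1)
  fb1 <- haploid_forward_backward(c(0L, 1L, 0L),
                                  matrix(1L, 3, 1), sch1, params)
  expect_equal(fb1$gamma, matrix(1, 3, 1))

  sch2 <- build_transitions(map, pos, 20000, 2)
  tpl <- matrix(c(0L, 1L, 1L), 3, 2)  # two identical templates
  fb2 <- haploid_forward_backward(c(0L, NA, 1L), tpl, sch2, params)
  expect_equal(fb2$gamma, matrix(0.5, 3, 2))
})

test_that("haploid smoothing matches path enumeration on random instances", {
  set.seed(202)
  map <- test_map()
  for (r in 1:60) {
    M <- sample(2:5, 1); K <- sample(2:4, 1)
    templ <- matrix(sample(0:1, M * K, TRUE), M, K)
    obs <- sample(c(0L, 1L, NA), M, TRUE)
    pos <- sort(sample.int(5e4, M))
    sch <- build_transitions(map, pos, 20000, K)
    params <- model_params(lambda = 0.01)
    fb <- haploid_forward_backward(obs, templ, sch, params)
    expect_equal(fb$gamma, oracle_gamma(obs, templ, sch$p_switch, 0.01),
                 tolerance = 1e-10)
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-9))
  }
})

test_that("forward log-likelihood is invariant to template ordering", {
  set.seed(9)
  map <- test_map()
  M <- 20; K <- 6
  templ <- matrix(sample(0:1, M * K, TRUE), M, K)
  obs <- sample(0:1, M, TRUE)
  sch <- build_transitions(map, sort(sample.int(1e5, M)), 20000, K)
  fb <- haploid_forward_backward(obs, templ, sch)
  perm <- sample(K)
  fbp <- haploid_forward_backward(obs, templ[, perm], sch)
  expect_equal(fb$loglik, fbp$loglik, tolerance = 1e-12)
})

test_that("untyped-site imputation is exact against the enumeration oracle", {
  set.seed(303)
  map <- test_map()
  for (r in 1:40) {
    Mtot <- sample(3:5, 1); K <- sample(2:4, 1)
    U <- sample(1:2, 1); U <- min(U, Mtot - 2)
    allpos <- sort(sample.int(5e4, Mtot))
    ui <- sort(sample(Mtot, U)); ti <- setdiff(seq_len(Mtot), ui)
    templ <- matrix(sample(0:1, Mtot * K, TRUE), Mtot, K)
    obs <- sample(0:1, length(ti), TRUE)
    sch <- build_transitions(map, allpos[ti], 20000, K)
    params <- model_params(lambda = 0.02)
    fb <- haploid_forward_backward(obs, templ[ti, , drop = FALSE], sch, params)
    p1 <- impute_untyped(fb, templ[ui, , drop = FALSE], allpos[ui],
                         allpos[ti], map, 20000)
    # oracle: enumerate with the untyped sites as missing columns
    obs_all <- rep(NA_integer_, Mtot); obs_all[ti] <- obs
    schA <- build_transitions(map, allpos, 20000, K)
    og <- oracle_gamma(obs_all, templ, schA$p_switch, 0.02)
    exp_p1 <- 0.02 + 0.96 * rowSums(og[ui, , drop = FALSE] *
                                      (templ[ui, , drop = FALSE] == 1))
    expect_equal(p1, exp_p1, tolerance = 1e-10)
    expect_true(all(p1 >= 0 & p1 <= 1))
  }
})

test_that("untyped imputation is forced by unanimous or balanced templates", {
  map <- test_map()
  set.seed(8)
  pos <- c(1000, 2000, 3000)
  sch <- build_transitions(map, pos, 20000, 4)
  params <- model_params(lambda = 0.01)
  tpl <- matrix(sample(0:1, 12, TRUE), 3, 4)
  fb <- haploid_forward_backward(c(0L, 1L, 0L), tpl, sch, params)
  # every template carries allele 1 at the untyped site
  expect_equal(impute_untyped(fb, matrix(1L, 1, 4), 2500, pos, map, 20000),
               1 - 0.01, tolerance = 1e-12)
  # balanced templates with uniform gamma (all-missing observation)
  fbm <- haploid_forward_backward(rep(NA_integer_, 3), tpl, sch, params)
  expect_equal(impute_untyped(fbm, matrix(c(0L, 1L, 0L, 1L), 1, 4),
                              2500, pos, map, 20000), 0.5)
  # position outside the map still extrapolates but stays a probability
  expect_error(impute_untyped(fb, matrix(1L, 2, 4), c(2500), pos, map, 20000),
               "rows")
})

test_that("a single exactly matching template dominates as lambda -> 0", {
  # at tight linkage the exactly matching template dominates the mosaic
  map <- test_map()
  set.seed(31)
  M <- 10
  pos <- sort(sample(100:400, M + 1))
  ui <- 5L; ti <- setdiff(seq_len(M + 1), ui)
  target <- sample(0:1, M + 1, TRUE)
  templ <- cbind(target, matrix(sample(0:1, (M + 1) * 3, TRUE), M + 1, 3))
  params <- model_params(lambda = 1e-9)
  sch <- build_transitions(map, pos[ti], 20000, 4)
  fb <- haploid_forward_backward(target[ti], templ[ti, ], sch, params)
  p1 <- impute_untyped(fb, templ[ui, , drop = FALSE], pos[ui], pos[ti],
                       map, 20000)
  expect_equal(p1, target[ui], tolerance = 1e-3)
})

test_that("diploid phase sampling is forced at homozygous sites", {
  map <- test_map()
  set.seed(14)
  pos <- c(1000, 1500, 2200, 4000)
  sch <- build_transitions(map, pos, 20000, 3)
  tpl <- matrix(sample(0:1, 12, TRUE), 4, 3)
  g <- c(0L, 2L, 0L, 2L)
  set.seed(1)
  pr <- diploid_sample_phase(g, tpl, sch)
  expect_equal(pr$h1, g %/% 2L)
  expect_equal(pr$h2, g %/% 2L)
})

test_that("one heterozygous site with opposite templates phases 50/50", {
  map <- test_map()
  sch <- build_transitions(map, c(1000, 2000), 20000, 2)
  tpl <- cbind(c(0L, 0L), c(1L, 1L))
  set.seed(42)
  n <- 4000
  ones <- 0
  for (s in seq_len(n)) {
    pr <- diploid_sample_phase(c(0L, 1L), tpl, sch)
    expect_equal(pr$h1 + pr$h2, c(0L, 1L))
    ones <- ones + pr$h1[2]
  }
  expect_lt(abs(ones / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("diploid sampler frequencies match the enumerated phase posterior", {
  set.seed(606)
  map <- test_map()
  pos <- c(1000, 2000, 3000)
  K <- 3
  templ <- cbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  geno <- c(1L, 1L, 1L)
  sch <- build_transitions(map, pos, 20000, K)
  lam <- lambda_mismatch(K)
  post <- oracle_phase_posterior(geno, templ, sch$p_switch, lam)
  n <- 20000
  cnt <- stats::setNames(numeric(length(post)), names(post))
  for (s in seq_len(n)) {
    pr <- diploid_sample_phase(geno, templ, sch)
    key <- paste(pr$h1, collapse = "")
    cnt[key] <- cnt[key] + 1
  }
  emp <- cnt / n
  se <- sqrt(post * (1 - post) / n)
  expect_true(all(abs(emp - post) < 3.5 * se))
  chi <- sum((cnt - n * post)^2 / (n * post))
  expect_gt(stats::pchisq(chi, length(post) - 1, lower.tail = FALSE), 0.001)
})
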