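test_that("kl_distance matches hand-computed value, is symmetric and metric-like", {
  a <- c(0.5, 0.3, 0.2); b <- c(0.2, 0.3, 0.5)
  # term-by-term: 2 * 0.3 * log(2.5)
  expect_equal(kl_distance(a, b), 2 * 0.3 * log(2.5), tolerance = 1e-12)
  expect_equal(kl_distance(a, a), 0)
  expect_error(kl_distance(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5)), "positive")
  set.seed(11)
  for (i in 1:20) {
    x <- replace_zeros(as.numeric(random_simplex(1, 8)))
    y <- replace_zeros(as.numeric(random_simplex(1, 8)))
    expect_equal(kl_distance(x, y), kl_distance(y, x), tolerance = 1e-12)
    expect_gte(kl_distance(x, y), 0)
  }
})

test_that("mixture_signature handles vertices, midpoints, stays on simplex", {
  means <- rbind(c(1, 0), c(0, 1))
  expect_equal(mixture_signature(c(1, 0), means), c(1, 0))
  expect_equal(mixture_signature(c(0.5, 0.5), means), c(0.5, 0.5))
  set.seed(3)
  means <- random_simplex(4, 7)
  for (i in 1:10) {
    alpha <- as.numeric(random_simplex(1, 4))
    expect_equal(sum(mixture_signature(alpha, means)), 1, tolerance = 1e-12)
  }
  expect_error(mixture_signature(c(0.5, 0.5), random_simplex(3, 4)), "species")
})

test_that("alpha_to_pi applies the lipid conversion formula", {
  expect_equal(alpha_to_pi(c(0.5, 0.5), c(1.0, 0.5)), c(1/3, 2/3))
  # equal lipid fractions leave alpha unchanged
  a <- c(0.2, 0.3, 0.5)
  expect_equal(alpha_to_pi(a, c(0.7, 0.7, 0.7)), a, tolerance = 1e-12)
  expect_error(alpha_to_pi(c(0.5, 0.5), c(1, 0)), "lipid")
})

test_that("pure-diet predators recover the vertex", {
  lib <- make_flat_library(3L)
  cc <- gen_calibration(lib$fa, spread = 0.3, seed = 9)
  for (k in seq_along(lib$species)) {
    mu <- prey_means(lib)[k, ]
    pred <- apply_calibration(mu, cc, "prey_to_predator")
    names(pred) <- lib$fa
    est <- estimate_diet(pred, lib, cc = cc, seed = k)
    target <- as.numeric(seq_along(lib$species) == k)
    expect_lt(max(abs(est$alpha - target)), 1e-3)
    expect_true(est$converged)
  }
})

test_that("two-species noiseless mixture matches the grid-search oracle", {
  lib <- make_flat_library(2L)
  means <- prey_means(lib)
  truth <- c(0.6, 0.4)
  pred <- mixture_signature(truth, means)
  names(pred) <- lib$fa
  est <- estimate_diet(pred, lib, seed = 1)
  expect_lt(max(abs(est$pi - truth)), 1e-3)   # equal lipids: pi == alpha
  oracle <- grid_search_diet(replace_zeros(pred), means, resolution = 0.001)
  expect_lte(est$optimum_distance, oracle$value + 1e-10)
})

test_that("optimizer beats the 0.01 grid on random <=3 species predators", {
  set.seed(21)
  for (trial in 1:6) {
    k <- sample(2:3, 1)
    lib <- make_flat_library(k, n_spec = 4L)
    means <- prey_means(lib)
    pred <- replace_zeros(as.numeric(random_simplex(1, length(lib$fa))))
    names(pred) <- lib$fa
    est <- estimate_diet(pred, lib, seed = trial)
    oracle <- grid_search_diet(replace_zeros(pred), means, resolution = 0.01)
    expect_lte(est$optimum_distance, oracle$value + 1e-10)
  }
})

test_that("lipid overrides shift pi but not alpha", {
  lib <- make_flat_library(2L, lipid = c(alpha_sp = 1, bravo_sp = 1))
  means <- prey_means(lib)
  pred <- mixture_signature(c(0.5, 0.5), means)
  names(pred) <- lib$fa
  base <- estimate_diet(pred, lib, seed = 1)
  over <- estimate_diet(pred, lib, seed = 1,
                        lipid_overrides = c(bravo_sp = 0.5))
  expect_equal(over$alpha, base$alpha, tolerance = 1e-9)
  expect_equal(unname(over$pi), alpha_to_pi(unname(base$alpha), c(1, 0.5)),
               tolerance = 1e-9)
  expect_error(estimate_diet(pred, lib, lipid_overrides = c(zzz = 0.5)),
               "unknown species")
})

test_that("batch_estimate summarizes, is deterministic, flags degenerate spread", {
  lib <- make_flat_library(2L)
  means <- prey_means(lib)
  pred <- mixture_signature(c(0.7, 0.3), means)
  info <- data.frame(id = c("b1", "b2"), class = c("AF", "AF"),
                     year = c(2013L, 2013L))
  sig <- rbind(pred, pred); colnames(sig) <- lib$fa
  ps <- predator_set(info, sig)
  dt <- batch_estimate(ps, lib, seed = 4)
  expect_equal(nrow(dt$estimates), 2L)
  # duplicated predators: identical estimates, SE = 0
  expect_equal(dt$estimates$alpha_sp[1], dt$estimates$alpha_sp[2],
               tolerance = 1e-9)
  expect_equal(dt$summary$se_pct, c(0, 0), tolerance = 1e-6)
  dt2 <- batch_estimate(ps, lib, seed = 4)
  expect_identical(dt$estimates, dt2$estimates)

  one <- predator_set(info[1, ], sig[1, , drop = FALSE])
  d1 <- batch_estimate(one, lib, seed = 4)
  expect_equal(d1$summary$mean_pct,
               100 * as.numeric(diet_matrix(d1)), tolerance = 1e-12)
})

test_that("cohort mean estimated diet tracks the generating mean", {
  # no class/year structure so the generating mean is the scenario baseline
  sc <- make_small_scenario(seed = 5, n_predators = 40L,
                            class_tilt = list(), year_effect_sd = 0,
                            predator_noise_sd = 0.01)
  lib <- gen_prey_library(sc)
  cc <- gen_calibration(sc$fa, sc$cc_spread, seed = sc$seed)
  coh <- gen_predator_cohort(sc, lib, cc)
  dt <- batch_estimate(coh$predators, lib, cc = cc, seed = 31)
  est <- diet_matrix(dt)
  n <- nrow(est)
  # MC SE of the generating mean: Dirichlet sampling spread of the true
  # diets plus the estimation-error spread
  dir_sd <- sqrt(sc$diet_mean * (1 - sc$diet_mean) /
                   (sc$diet_concentration + 1))
  est_sd <- apply(est - coh$true_diet, 2L, sd)
  mc_se <- sqrt(dir_sd^2 + est_sd^2) / sqrt(n)
  diff <- abs(colMeans(est) - sc$diet_mean)
  expect_true(all(diff <= 2 * mc_se))
})
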