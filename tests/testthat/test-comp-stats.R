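test_that("chi_square_distance matches the closed form and is a metric", {
  P <- rbind(c(1, 0), c(0, 1))
  expect_equal(chi_square_distance(P)[1, 2], 2)
  P2 <- rbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(chi_square_distance(P2)[1, 2], 0)
  expect_error(chi_square_distance(rbind(c(1, 0), c(1, 0))), "column")
  named <- rbind(c(1, 0), c(0.5, 0))
  colnames(named) <- c("a", "b")
  expect_error(chi_square_distance(named), "b")
  # triangle inequality on random matrices
  set.seed(19)
  for (i in 1:10) {
    D <- chi_square_distance(random_simplex(5, 3))
    for (a in 1:5) for (b in 1:5) for (cc in 1:5) {
      expect_lte(D[a, b], D[a, cc] + D[cc, b] + 1e-12)
    }
  }
})

test_that("permanova handles the degenerate all-identical case", {
  P <- matrix(rep(c(0.4, 0.6), 6), 6, byrow = TRUE)
  dat <- data.frame(class = rep(c("AF", "AM"), 3))
  res <- permanova(chi_square_distance(P), dat, ~ class, n_perm = 99,
                   seed = 1)
  expect_equal(res$SS[1], 0, tolerance = 1e-12)
  expect_equal(res$pseudo_F[1], 0)
  expect_gt(res$p_perm[1], 0.9)
})

test_that("exact permutation p matches an independent enumeration oracle", {
  set.seed(23)
  for (trial in 1:3) {
    P <- random_simplex(6, 3)
    groups <- rep(c("g1", "g2"), each = 3)
    D <- chi_square_distance(P)
    res <- permanova(D, data.frame(class = groups), ~ class, exact = TRUE)
    oracle <- oneway_perm_oracle(D, groups)
    expect_equal(res$pseudo_F[1], oracle$F, tolerance = 1e-10)
    expect_equal(res$p_perm[1], oracle$p, tolerance = 1e-12)
  }
  # unbalanced design with 7 observations
  P <- random_simplex(7, 4)
  groups <- c("a", "a", "b", "b", "b", "c", "c")
  D <- chi_square_distance(P)
  res <- permanova(D, data.frame(class = groups), ~ class, exact = TRUE)
  oracle <- oneway_perm_oracle(D, groups)
  expect_equal(res$pseudo_F[1], oracle$F, tolerance = 1e-10)
  expect_equal(res$p_perm[1], oracle$p, tolerance = 1e-12)
})

test_that("SS partition and pseudo-F agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(29)
  P <- random_simplex(24, 5)
  dat <- data.frame(class = factor(rep(c("AF", "AM", "SF", "SM"), 6)),
                    year = factor(rep(2013:2015, 8)))
  D <- chi_square_distance(P)
  mine <- permanova(D, dat, ~ class + year, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(D) ~ class + year, data = dat,
                        permutations = 199, by = "terms")
  expect_equal(mine$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(mine$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(mine$df[1:3], ref$Df[1:3])
})

test_that("df bookkeeping: 13 year levels give df 12, residual completes n-1", {
  set.seed(31)
  n <- 60
  P <- random_simplex(n, 5)
  dat <- data.frame(class = factor(sample(c("AF", "AM", "SF", "SM"), n,
                                          replace = TRUE)),
                    year = factor(sample(rep(2004:2016, length.out = n))))
  stopifnot(nlevels(dat$year) == 13L)
  res <- permanova(chi_square_distance(P), dat, ~ year + class,
                   n_perm = 99, seed = 2)
  expect_equal(res$df[res$term == "year"], 12L)
  expect_equal(res$df[res$term == "class"], 3L)
  expect_equal(sum(res$df[res$term != "Total"]), n - 1L)
})

test_that("permanova validates inputs and is seed-reproducible", {
  P <- random_simplex(8, 3)
  D <- chi_square_distance(P)
  dat <- data.frame(class = rep("AF", 8))
  expect_error(permanova(D, dat, ~ class, n_perm = 99), "single level")
  dat2 <- data.frame(class = rep(c("AF", "AM"), 4))
  dat2$copy <- dat2$class
  expect_error(permanova(D, dat2, ~ class + copy, n_perm = 99), "confounded")
  r1 <- permanova(D, dat2, ~ class, n_perm = 199, seed = 77)
  r2 <- permanova(D, dat2, ~ class, n_perm = 199, seed = 77)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm[1], 1 / 200)
})

test_that("holm_adjust implements the step-down closed form", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.01, 0.2, 0.3, 0.4, 0.5))[1], 0.05)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  # agrees with the reference implementation; never below raw
  set.seed(37)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("per-prey permanova flags structured prey and handles constants", {
  set.seed(41)
  n <- 40
  classes <- rep(c("AF", "AM"), n / 2)
  # ringed-like prey strongly class-structured, others exchangeable noise
  p1 <- ifelse(classes == "AF", 0.6, 0.3) + rnorm(n, sd = 0.03)
  p2 <- runif(n, 0.1, 0.3)
  p3 <- rep(0.1, n)                      # constant
  rest <- pmax(1 - p1 - p2 - p3, 0.01)
  P <- cbind(ringed = p1, bearded = p2, constant = p3, other = rest)
  P <- P / rowSums(P)
  P[, "constant"] <- 0.1                 # exactly constant column
  dat <- data.frame(class = classes)
  res <- per_prey_permanova(P, dat, ~ class, n_perm = 199, seed = 5)
  expect_equal(nrow(res), 4L)
  r <- res[res$species == "ringed", ]
  expect_equal(r$p_holm, min(res$p_holm))
  expect_lte(r$p_raw, 0.01)
  cst <- res[res$species == "constant", ]
  expect_equal(cst$pseudo_F, 0)
  expect_equal(cst$p_holm, 1)
  expect_true(all(res$p_holm >= res$p_raw))
})

test_that("pairwise class tests localize a displaced class", {
  set.seed(43)
  n_per <- 8
  classes <- rep(c("AF", "AM", "SF", "SM"), each = n_per)
  p <- ifelse(classes == "AM", 0.25, 0.55) + rnorm(length(classes), sd = 0.03)
  P <- cbind(ringed = p, rest = 1 - p)
  res <- pairwise_class_tests(P, classes, "ringed", n_perm = 199, seed = 3)
  expect_equal(nrow(res), 6L)
  involved <- res$class_a == "AM" | res$class_b == "AM"
  expect_true(max(res$p_raw[involved]) < min(res$p_raw[!involved]))
  # identical class distributions: nothing significant
  P0 <- cbind(ringed = rep(c(0.5, 0.52), 16), rest = rep(c(0.5, 0.48), 16))
  res0 <- pairwise_class_tests(P0, classes, "ringed", n_perm = 199, seed = 3)
  expect_true(all(res0$p_holm > 0.5))
  expect_warning(
    pairwise_class_tests(P[-(1:7), ], classes[-(1:7)], "ringed",
                         n_perm = 99, seed = 1), "AF")
})

test_that("annual_mean_trend ranks annual means against year", {
  years <- rep(2013:2015, each = 4)
  # annual means (3, 1, 2)/6 against years 1:3 -> r_s = -0.5
  p <- rep(c(3, 1, 2) / 6, each = 4)
  P <- cbind(focal = p, rest = 1 - p)
  res <- annual_mean_trend(P, years)
  expect_equal(res$r_s[res$species == "focal"], -0.5)
  # strictly increasing means -> r_s = 1
  p2 <- rep(c(0.1, 0.2, 0.3), each = 4)
  P2 <- cbind(focal = p2, rest = 1 - p2)
  expect_equal(annual_mean_trend(P2, years)$r_s[1], 1)
  expect_error(annual_mean_trend(P, rep(2013, 12)), "3 distinct years")
})

test_that("ice covariate permanova: df 1, tracks a strong year effect", {
  set.seed(47)
  years <- rep(2004:2011, each = 5)
  ice <- data.frame(year = 2004:2011, ifd50 = seq(80, 150, 10),
                    ifd15 = seq(60, 130, 10), melt_season = seq(100, 170, 10))
  # diet proportion follows the ifd50 trend
  p <- 0.3 + 0.003 * (ice$ifd50[match(years, ice$year)] - 80) +
    rnorm(length(years), sd = 0.02)
  P <- cbind(focal = p, rest = 1 - p)
  dat <- data.frame(class = rep(c("AF", "AM", "SF", "SM", "AF"), 8),
                    year = years)
  res <- ice_covariate_permanova(P, dat, ice, "ifd50", n_perm = 199,
                                 seed = 7)
  expect_equal(res$df[res$term == "ice"], 1L)
  expect_lte(res$p_perm[res$term == "ice"], 0.05)
  # constant covariate carries zero SS
  ice0 <- ice; ice0$ifd50 <- 100
  res0 <- ice_covariate_permanova(P, dat, ice0, "ifd50", n_perm = 99,
                                  seed = 7)
  expect_equal(res0$SS[res0$term == "ice"], 0)
  expect_error(ice_covariate_permanova(P, dat, ice[-1, ], "ifd50"),
               "2004")
})
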