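test_that("mean-value normalization divides by the series mean", {
  expect_equal(normalize_series(c(2, 4, 6)), c(0.5, 1.0, 1.5))
  expect_equal(normalize_series(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(normalize_series(c(48.28, 41.47)), c(1.0759, 0.9241),
               tolerance = 5e-5)
  expect_equal(mean(normalize_series(stats::runif(20, 1, 9))), 1,
               tolerance = 1e-12)
  expect_error(normalize_series(c(1, -2)), "positive")
  expect_error(normalize_series(c(1, NA)), "positive|finite")
})

test_that("relational coefficients follow the Deng formula by hand", {
  y_o <- c(0.5, 1.0, 1.5)
  subs <- list(f1 = c(0.5, 1.0, 1.5), f2 = c(1.5, 1.0, 0.5))
  rc <- relational_coefficients(y_o, subs, grey_config(rho = 0.5))
  expect_equal(rc$delta_min, 0)
  expect_equal(rc$delta_max, 1)
  expect_equal(unname(rc$coefficients[, "f1"]), c(1, 1, 1))
  expect_equal(unname(rc$coefficients[, "f2"]), c(1 / 3, 1, 1 / 3),
               tolerance = 1e-15)
  expect_true(all(rc$coefficients > 0 & rc$coefficients <= 1))
})

test_that("identical parent and subfactor degenerate to coefficients of 1", {
  rc <- relational_coefficients(c(0.5, 1, 1.5),
                                list(f1 = c(0.5, 1, 1.5)))
  expect_equal(unname(rc$coefficients[, 1]), c(1, 1, 1))
})

test_that("coefficient inputs are checked", {
  expect_error(relational_coefficients(c(1, 2), list(f1 = c(1, 2, 3))),
               "length mismatch")
  expect_error(
    relational_coefficients(c(1, 2), matrix(numeric(0), nrow = 2)),
    "empty subfactor set")
  expect_error(relational_coefficients(c(1, 2), list(c(1, 2))), "named")
})

test_that("degrees are means of coefficients; ranks break ties by name", {
  expect_equal(relational_degree(cbind(f1 = c(1, 1, 1))), c(f1 = 1))
  expect_equal(relational_degree(cbind(f2 = c(1 / 3, 1, 1 / 3))),
               c(f2 = 5 / 9), tolerance = 1e-15)
  expect_equal(rank_degrees(c(f1 = 1.0, f2 = 0.5556)), c(f1 = 1L, f2 = 2L))
  expect_equal(rank_degrees(c(b = 0.7, a = 0.7)), c(b = 2L, a = 1L))
  expect_equal(rank_degrees(c(only = 0.4)), c(only = 1L))
})

test_that("the full model reproduces the hand-computed example", {
  res <- gra(c(2, 4, 6), list(f1 = c(1, 2, 3), f2 = c(3, 2, 1)),
             grey_config(rho = 0.5))
  expect_equal(res$degrees, c(f1 = 1, f2 = 5 / 9), tolerance = 1e-15)
  expect_equal(res$ranks, c(f1 = 1L, f2 = 2L))
  # intermediates retained for audit
  expect_equal(dim(res$delta), c(3, 2))
  expect_equal(res$delta_min, 0)
  expect_equal(res$delta_max, 1)
})

test_that("a subfactor proportional to the parent always has degree 1", {
  parent <- c(3.2, 8.1, 4.4, 9.9)
  res <- gra(parent, list(scaled = 7.3 * parent, other = c(1, 9, 2, 4)))
  expect_equal(unname(res$degrees["scaled"]), 1)
  expect_equal(unname(res$ranks["scaled"]), 1L)
})

test_that("the configuration guards the resolution coefficient", {
  expect_error(grey_config(rho = 0), "positive")
  expect_error(grey_config(rho = -0.5), "positive")
  expect_error(grey_config(rho = 1.5), "allow_large_rho")
  expect_equal(grey_config(rho = 1.5, allow_large_rho = TRUE)$rho, 1.5)
  expect_error(grey_config(delta_scope = "bogus"))
})

test_that("scale invariance: per-series positive rescaling leaves degrees", {
  for (seed in 1:25) {
    inst <- random_gra_instance(seed)
    base <- gra(inst$parent, inst$subs)
    set.seed(seed + 1000)
    c0 <- stats::runif(1, 0.01, 50)
    d <- stats::runif(length(inst$subs), 0.01, 50)
    scaled_subs <- Map(function(s, di) s * di, inst$subs, as.list(d))
    scaled <- gra(c0 * inst$parent, scaled_subs)
    expect_equal(scaled$degrees, base$degrees, tolerance = 1e-12)
  }
})

test_that("jointly permuting all series leaves every degree unchanged", {
  for (seed in 1:25) {
    inst <- random_gra_instance(seed)
    base <- gra(inst$parent, inst$subs)
    set.seed(seed + 2000)
    perm <- sample(length(inst$parent))
    permuted <- gra(inst$parent[perm], lapply(inst$subs, `[`, perm))
    expect_equal(permuted$degrees, base$degrees, tolerance = 1e-12)
  }
})

test_that("degrees are nondecreasing in the resolution coefficient", {
  rhos <- c(0.05, 0.2, 0.5, 0.8, 1)
  for (seed in 1:25) {
    inst <- random_gra_instance(seed)
    degs <- sapply(rhos, function(r)
      gra(inst$parent, inst$subs, grey_config(rho = r))$degrees)
    diffs <- t(apply(degs, 1, diff))
    expect_true(all(diffs >= -1e-12))
  }
})

test_that("with a zero minimum difference, degrees stay in [rho/(1+rho), 1]", {
  for (seed in 1:25) {
    inst <- random_gra_instance(seed)
    # including the parent itself as a subfactor forces delta_min = 0
    subs <- c(inst$subs, list(self = inst$parent))
    res <- gra(inst$parent, subs, grey_config(rho = 0.5))
    expect_equal(res$delta_min, 0)
    expect_true(all(res$degrees >= 1 / 3 - 1e-12))
    expect_true(all(res$degrees <= 1 + 1e-12))
    expect_equal(unname(res$degrees["self"]), 1)
  }
})

test_that("vectorized implementation matches the naive loop oracle", {
  for (seed in 1:30) {
    inst <- random_gra_instance(seed)
    for (scope in c("global", "per_subfactor")) {
      res <- gra(inst$parent, inst$subs,
                 grey_config(rho = 0.4, delta_scope = scope))
      oracle <- gra_naive(inst$parent, inst$subs, rho = 0.4, scope = scope)
      expect_equal(res$degrees, oracle, tolerance = 1e-12)
    }
  }
})

test_that("per-subfactor extrema give every subfactor a coefficient of 1", {
  inst <- random_gra_instance(99)
  res <- gra(inst$parent, inst$subs,
             grey_config(delta_scope = "per_subfactor"))
  # each column attains its own delta_min, where its coefficient is exactly 1
  expect_equal(unname(apply(res$coefficients, 2, max)),
               rep(1, length(inst$subs)), tolerance = 1e-12)
  expect_length(res$delta_min, length(inst$subs))
})
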