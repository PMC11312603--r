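test_that("fractional ranks follow the weighted midpoint convention", {
  expect_equal(fractional_rank(c(1, 2, 3, 4)), c(0.125, 0.375, 0.625, 0.875))
  # ordering of the input does not matter
  expect_equal(fractional_rank(c(10, 40, 20, 30)), c(0.125, 0.875, 0.375, 0.625))
  # ties share the midpoint rank of their block
  expect_equal(fractional_rank(c(1, 1, 5, 9)), c(0.25, 0.25, 0.625, 0.875))
  # weights move the midpoints: poorer record with triple weight
  expect_equal(fractional_rank(c(1, 2), weights = c(3, 1)), c(0.375, 0.875))
  expect_error(fractional_rank(c(1, 2), weights = c(0, 0)), "zero")
  expect_error(fractional_rank(numeric(0)), "empty")
})

test_that("ranks are non-decreasing in the living standard", {
  for (s in 1:20) {
    withr::with_seed(s, {
      x <- sample(round(rlnorm(50, 3, 1)))  # rounding induces ties
      w <- runif(50, 0.2, 2)
    })
    r <- fractional_rank(x, w)
    expect_true(all(diff(r[order(x)]) >= 0))
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("the two-record hand computation gives an index of one half", {
  # poorer unserved, richer served: mu 0.5, ranks (0.25, 0.75), cov 0.125
  est <- concentration_index(c(0, 1), living_standard = c(100, 200))
  expect_equal(est$value, 0.5)
  expect_equal(est$mu, 0.5)
})

test_that("the index is zero for a constant outcome and flips under rank reversal", {
  withr::with_seed(1, ls <- rlnorm(100, 8, 1))
  expect_identical(concentration_index(rep(1, 100), living_standard = ls)$value, 0)
  withr::with_seed(2, y <- rbinom(100, 1, 0.2 + 0.006 * seq_len(100)))
  up <- concentration_index(y, living_standard = ls)$value
  down <- concentration_index(y, living_standard = -ls)$value
  expect_equal(up, -down)
})

test_that("the index is invariant to outcome scaling and rank shifts", {
  withr::with_seed(4, {
    ls <- rlnorm(150, 8, 1)
    y <- rexp(150) * (1 + rank(ls) / 150)
    w <- runif(150, 0.5, 2)
  })
  r <- fractional_rank(ls, w)
  base <- concentration_index(y, rank = r, weights = w)$value
  expect_equal(concentration_index(17.3 * y, rank = r, weights = w)$value, base)
  # the textbook i/N rank is a constant shift of the midpoint rank; covariance
  # is shift-invariant, so the estimate is identical
  expect_equal(concentration_index(y, rank = r + 1 / (2 * 150), weights = w)$value,
               base)
})

test_that("duplicating a record equals doubling its weight, exactly", {
  withr::with_seed(5, {
    ls <- rlnorm(60, 8, 1)
    y <- rbinom(60, 1, 0.4)
  })
  y[1] <- 1
  w <- rep(1, 60)
  w2 <- w; w2[7] <- 2
  dup <- concentration_index(c(y, y[7]), weights = rep(1, 61),
                             living_standard = c(ls, ls[7]))$value
  wtd <- concentration_index(y, weights = w2, living_standard = ls)$value
  expect_equal(dup, wtd)
})

test_that("binary outcomes respect the 1 - mu magnitude bound", {
  for (s in 1:25) {
    withr::with_seed(100 + s, {
      n <- sample(20:300, 1)
      ls <- rlnorm(n, 8, 1)
      y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    })
    if (mean(y) == 0) next
    est <- concentration_index(y, living_standard = ls)
    expect_lte(abs(est$value), 1 - est$mu + 1e-12)
    expect_lte(est$ci95[["lower"]], est$value)
    expect_gte(est$ci95[["upper"]], est$value)
  }
})

test_that("the delta-method standard error tracks the sampling spread", {
  # simulate many small samples from one law; the robust SE should be on the
  # scale of the realized spread of the estimates (factor-of-1.3 agreement)
  ests <- ses <- numeric(300)
  for (s in seq_along(ests)) {
    withr::with_seed(2000 + s, {
      ls <- runif(150)
      y <- rbinom(150, 1, 0.2 + 0.4 * ls)
    })
    e <- concentration_index(y, living_standard = ls)
    ests[s] <- e$value; ses[s] <- e$se
  }
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.3)
})

test_that("concentration curves have the right endpoints, monotonicity and shape", {
  withr::with_seed(6, {
    ls <- rlnorm(80, 8, 1)
    y <- rbinom(80, 1, 0.5)
  })
  y[1] <- 1
  cv <- concentration_curve(y, ls)
  pts <- cv$points
  expect_equal(pts$p[1], 0); expect_equal(pts$L[1], 0)
  expect_equal(pts$p[nrow(pts)], 1); expect_equal(pts$L[nrow(pts)], 1)
  expect_true(all(diff(pts$p) >= 0) && all(diff(pts$L) >= 0))

  # everyone served equally: the curve is the diagonal
  cv_eq <- concentration_curve(rep(1, 10), 1:10)
  expect_equal(cv_eq$points$L, cv_eq$points$p)

  # only the richest of four served
  cv4 <- concentration_curve(c(0, 0, 0, 1), c(1, 2, 3, 4))
  expect_equal(cv4$points$p, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cv4$points$L, c(0, 0, 0, 0, 1))

  expect_error(concentration_curve(c(0, 0), c(1, 2)), "positive")
})

test_that("covariance formula and curve geometry agree within 2/n", {
  for (s in 1:30) {
    withr::with_seed(300 + s, {
      n <- sample(10:500, 1)
      ls <- rlnorm(n, 8, 1)
      y <- random_nonneg_outcome(n)
      w <- if (s %% 2 == 0) runif(n, 0.5, 2) else rep(1, n)
    })
    if (sum(y) == 0) next
    ci_cov <- concentration_index(y, weights = w, living_standard = ls)$value
    ci_area <- ci_from_curve(concentration_curve(y, ls, w))
    expect_lte(abs(ci_cov - ci_area), 2 / n)
  }
})

test_that("stratified indices recompute ranks within each stratum", {
  ds <- simple_ds(300, seed = 9, wave = "wave")
  whole <- concentration_index(dataset_records(ds)$exam,
                               living_standard = dataset_records(ds)$pce)
  tab <- ci_by_group(ds)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$ci, whole$value)
  expect_equal(tab$lower, whole$ci95[["lower"]])

  # two strata with opposite built-in gradients give opposite-sign estimates
  up <- simple_table(2000, seed = 11)
  down <- simple_table(2000, seed = 12)
  down$exam <- withr::with_seed(13,
    rbinom(2000, 1, 0.5 - 0.3 * rank(down$pce) / 2000))
  up$residence <- "urban"; down$residence <- "rural"
  both <- analytic_dataset(dplyr::bind_rows(up, down), simple_roles(),
                           quiet = TRUE)
  tab2 <- ci_by_group(both, group = "residence")
  expect_gt(tab2$ci[tab2$group == "urban"], 0)
  expect_lt(tab2$ci[tab2$group == "rural"], 0)

  # cells under the size floor are computed but flagged
  small <- simple_ds(20, seed = 14)
  expect_equal(ci_by_group(small)$flag, "small stratum")
})
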