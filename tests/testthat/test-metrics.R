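test_that("determination coefficient and MAE behave as defined", {
  obs <- c(1, 2, 3, 5)
  expect_equal(r2(obs, 2 * obs + 1), 1)
  expect_equal(r2(obs, -obs), 1)        # sign-blind by squaring
  calc <- c(1.2, 1.9, 3.4, 4.8)
  cov_based <- (sum((obs - mean(obs)) * (calc - mean(calc))))^2 /
    (sum((obs - mean(obs))^2) * sum((calc - mean(calc))^2))
  expect_equal(r2(obs, calc), cov_based, tolerance = 1e-12)
  expect_error(r2(obs, rep(1, 4)), "zero variance")

  expect_equal(mae(obs, obs), 0)
  expect_equal(mae(c(1, 2), c(0, 3)), 1)
  withr::with_seed(1L, {
    o <- rnorm(20); c_ <- rnorm(20)
    expect_equal(mae(o, c_), sum(abs(o - c_)) / 20)
  })
})

test_that("IIC balances the residual sides and zeroes one-sided errors", {
  # symmetric residuals (-a,-a,+a,+a): IIC equals r
  obs <- c(1, 2, 3, 4)
  calc <- obs + c(-0.2, 0.2, -0.2, 0.2)
  expect_equal(iic(obs, calc), cor(obs, calc))
  # all residuals >= 0, one positive: IIC = 0
  expect_equal(iic(obs, obs - c(0.3, 0.1, 0.2, 0.4)), 0)
  # perfect fit: ratio defined as 1, IIC = r = 1
  expect_equal(iic(obs, obs), 1)
  # oracle equivalence on hand pairs
  o5 <- c(0.1, 0.9, 1.7, 2.2, 3.4)
  c5 <- c(0.3, 0.7, 1.9, 2.6, 3.1)
  expect_equal(iic(o5, c5), iic_brute(o5, c5), tolerance = 1e-12)
})

test_that("CII is bounded by one and equals one on collinear data", {
  obs <- seq(1, 5, length.out = 8)
  expect_equal(cii(obs, 3 * obs - 2), 1)
  withr::with_seed(101L, {
    vals <- replicate(120, {
      n <- sample(5:50, 1)
      cii(rnorm(n), rnorm(n))
    })
    expect_lte(max(vals), 1)
  })
})

test_that("IIC and CII match brute-force oracles on random small sets", {
  withr::with_seed(202L, {
    for (i in 1:200) {
      n <- sample(3:12, 1)
      o <- rnorm(n)
      c_ <- 0.8 * o + rnorm(n, sd = 0.5)
      expect_lt(abs(cii(o, c_) - cii_brute(o, c_)), 1e-12)
      expect_lt(abs(iic(o, c_) - iic_brute(o, c_)), 1e-12)
    }
  })
})

test_that("IIC magnitude never exceeds |r|; CII is correlation-invariant", {
  withr::with_seed(303L, {
    for (i in 1:50) {
      o <- rnorm(10)
      c_ <- 0.5 * o + rnorm(10)
      expect_lte(abs(iic(o, c_)), abs(cor(o, c_)) + 1e-12)
      # affine rescaling of the calculated values leaves CII unchanged
      expect_equal(cii(o, c_), cii(o, 3.7 * c_ - 11), tolerance = 1e-10)
    }
  })
})

test_that("leave-one-out Q2 matches explicit refitting and is below R2", {
  x <- c(0.5, 1.1, 1.9, 3.2, 4.1, 5.3, 6.0)
  y <- 0.3 + 0.7 * x
  expect_equal(q2_loo(y, x), 1)
  withr::with_seed(404L, {
    for (i in 1:25) {
      x <- rnorm(12)
      y <- 1 + 2 * x + rnorm(12, sd = 0.6)
      q2 <- q2_loo(y, x)
      expect_equal(q2, q2_loo_refit(y, x), tolerance = 1e-10)
      # determination-coefficient form of R2 (PRESS >= SSE)
      fit <- fit_line(y, x)
      sse <- sum((y - fit[["c0"]] - fit[["c1"]] * x)^2)
      r2_det <- 1 - sse / sum((y - mean(y))^2)
      expect_lte(q2, r2_det + 1e-12)
    }
  })
  expect_error(q2_loo(c(1, 2, 3), rep(2, 3)), "degenerate")
})

test_that("Q2F family follows its three denominators", {
  y_tr <- c(0, 1, 2, 3, 4)
  obs <- c(0.5, 1.5, 2.5, 3.1)
  expect_equal(unname(q2f_family(obs, obs, y_tr)), c(1, 1, 1))

  calc <- c(0.7, 1.2, 2.9, 2.8)
  got <- q2f_family(obs, calc, y_tr)
  sse <- sum((obs - calc)^2)
  expect_equal(got[["q2f1"]], 1 - sse / sum((obs - mean(y_tr))^2))
  expect_equal(got[["q2f2"]], 1 - sse / sum((obs - mean(obs))^2))
  expect_equal(got[["q2f3"]],
               1 - (sse / 4) / (sum((y_tr - mean(y_tr))^2) / 5))
  # Q2F1 >= Q2F2: the training-mean denominator is never smaller
  withr::with_seed(505L, {
    for (i in 1:30) {
      o <- rnorm(8); c_ <- o + rnorm(8, sd = 0.4); tr <- rnorm(15)
      q <- q2f_family(o, c_, tr)
      expect_gte(q[["q2f1"]], q[["q2f2"]] - 1e-12)
    }
  })
})

test_that("averaged rm2 is one at identity and bounded by r2", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(rm2_average(obs, obs), 1)
  withr::with_seed(606L, {
    for (i in 1:30) {
      o <- rnorm(9, mean = 2)
      c_ <- o + rnorm(9, sd = 0.3)
      expect_lte(rm2_average(o, c_), r2(o, c_) + 1e-12)
      expect_lte(rm2_average(o, c_), 1)
    }
  })
  # hand example against independent arithmetic
  o <- c(0.2, 1.1, 1.8, 3.0, 3.9)
  c_ <- c(0.4, 0.9, 2.1, 2.7, 4.2)
  rm_dir <- function(y, x) {
    r2v <- cor(y, x)^2
    k <- sum(x * y) / sum(x^2)
    r02 <- 1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
    r2v * (1 - sqrt(abs(r2v - r02)))
  }
  expect_equal(rm2_average(o, c_), mean(c(rm_dir(o, c_), rm_dir(c_, o))),
               tolerance = 1e-12)
})

test_that("Fisher F follows r2 (n-2) / (1 - r2) and is monotone in r2", {
  # r2 = 0.5, n = 72 -> F = 70
  withr::with_seed(707L, {
    target <- NULL
    # construct a 72-point set with exactly r2 = 0.5 via rotation trick
    x <- rnorm(72)
    e <- rnorm(72)
    e <- residuals(lm(e ~ x))
    x_ <- (x - mean(x)) / sd(x)
    e_ <- e / sqrt(sum(e^2) / 71)
    y <- x_ + e_          # cor(y, x)^2 == 0.5 by construction
    expect_equal(r2(y, x_), 0.5, tolerance = 1e-10)
    expect_equal(f_ratio(y, x_), 70, tolerance = 1e-8)
  })
  expect_true(is.na(f_ratio(c(1, 2, 3), c(2, 4, 6))))
  # monotone in r2 at fixed n
  o <- c(1, 2, 3, 4, 5, 6)
  tight <- o + c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  loose <- o + c(1.5, -1.5, 1.5, -1.5, 1.5, -1.5)
  expect_gt(f_ratio(o, tight), f_ratio(o, loose))
})

test_that("the target function rewards balanced training and the index", {
  expect_equal(target_function(0.8, 0.8, 0), 1.6)
  expect_equal(target_function(0.9, 0.5, 1, 0.3), 1.3)
  expect_equal(target_function(0.4, 0.7, 0.5),
               target_function(0.7, 0.4, 0.5))
})
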