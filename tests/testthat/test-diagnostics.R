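test_that("identity-line R^2 matches hand-computed cases", {
  expect_equal(yx_r2(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(yx_r2(c(1, 2, 3), c(2, 2, 2)), 0.0)   # SSE = SST
  expect_equal(yx_r2(c(1, 2, 3), c(3, 2, 1)), -3.0)  # SSE 8, SST 2
  expect_error(yx_r2(c(2, 2, 2), c(1, 2, 3)), "SST")
})

test_that("OLS fit matches the closed-form normal equations", {
  f <- ols_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)
  f2 <- ols_fit(c(1, 4), c(3, 9))  # two points: interpolating line
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)
  expect_equal(f2$r2, 1)
  expect_error(ols_fit(c(2, 2, 2), c(1, 2, 3)), "constant x")

  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 1.5 * x + rnorm(n)
    f <- ols_fit(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # normal-equations oracle
    expect_equal(f$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("Q scores are MedAD-normalized absolute residuals", {
  qs <- q_scores(c(1, 2, 3, 100), c(0, 0, 0, 0))
  expect_equal(qs$med_ad, 2.5)
  expect_equal(qs$q, c(0.4, 0.8, 1.2, 40))
  # all residuals equal c > 0: all scores are 1
  expect_equal(q_scores(c(5, 6, 7), c(2, 3, 4))$q, c(1, 1, 1))
  # invariance under common rescaling of the residuals
  expect_equal(q_scores(c(10, 20, 30, 1000), rep(0, 4))$q, qs$q)
  # MedAD = 0 with some nonzero residual: those points always filtered
  qz <- q_scores(c(1, 1, 1, 5), c(1, 1, 1, 1))
  expect_equal(qz$q, c(0, 0, 0, Inf))
  expect_equal(q_scores(c(1, 2), c(1, 2))$q, c(0, 0))
})

test_that("Q filtering is a strict single-pass threshold", {
  # residual magnitudes (1, 2, 3, 100) -> Q = (0.4, 0.8, 1.2, 40)
  pts <- data.frame(measured_g = c(2, 3, 4, 101),
                    estimated_g = c(1, 1, 1, 1))
  fq <- filter_q(pts, threshold = 6)
  expect_equal(nrow(fq$kept), 3)
  expect_equal(nrow(fq$removed), 1)
  expect_equal(fq$removed$measured_g, 101)
  expect_equal(fq$removed$q, 40)
  # all Q <= threshold: identity
  pts2 <- data.frame(measured_g = c(5, 6, 7), estimated_g = c(2, 3, 4))
  fq2 <- filter_q(pts2)
  expect_equal(nrow(fq2$removed), 0)
  expect_equal(fq2$kept$measured_g, pts2$measured_g)
})

test_that("Cook's distances equal brute-force leave-one-out refits", {
  # exact collinearity: no residual, no influence
  cd0 <- cooks_distance(1:10, 2 * (1:10) + 1)
  expect_equal(cd0$d, rep(0, 10))

  set.seed(5)
  for (i in 1:15) {
    n <- sample(8:60, 1)
    x <- exp(rnorm(n)); y <- x * exp(rnorm(n, 0, 0.4))
    cd <- cooks_distance(x, y)
    expect_equal(cd$d, loo_cooks(x, y), tolerance = 1e-10)
    expect_true(all(cd$d >= 0))
  }
})

test_that("duplicating a point dilutes its deletion influence", {
  set.seed(6)
  x <- c(rnorm(12), 5)  # one high-leverage point
  y <- 2 * x + rnorm(13, 0, 0.5)
  d_unique <- cooks_distance(x, y)$d[13]
  xd <- c(x, x[13]); yd <- c(y, y[13])
  d_dup <- cooks_distance(xd, yd)$d[c(13, 14)]
  expect_true(all(d_dup < d_unique))
})

test_that("influence filtering removes a planted outlier and lowers refit SSE", {
  set.seed(7)
  x <- seq(1, 10, length.out = 20)
  y <- x + rnorm(20, 0, 0.05)
  pts <- data.frame(measured_g = c(y, 60), estimated_g = c(x, 30))
  fi <- filter_influential(pts)
  expect_equal(nrow(fi$removed), 1)
  expect_equal(fi$removed$estimated_g, 30)

  # all D below the cutoff: identity
  pts2 <- data.frame(measured_g = y, estimated_g = x)
  fi2 <- filter_influential(pts2, rule = list(rule = "fixed", cutoff = 10))
  expect_equal(nrow(fi2$removed), 0)

  # refitting on the kept points can only reduce their SSE
  for (i in 1:10) {
    p <- random_pair(30)
    pts3 <- data.frame(measured_g = p$measured, estimated_g = p$estimated)
    fi3 <- filter_influential(pts3)
    if (nrow(fi3$removed) == 0) next
    full <- ols_fit(pts3$estimated_g, pts3$measured_g)
    kept <- fi3$kept
    sse_full_on_kept <- sum((kept$measured_g -
                               (full$intercept + full$slope * kept$estimated_g))^2)
    refit <- ols_fit(kept$estimated_g, kept$measured_g)
    expect_lte(sum(refit$residuals^2), sse_full_on_kept + 1e-12)
  }
})

test_that("top-k influence rule removes exactly the k largest distances", {
  set.seed(8)
  p <- random_pair(25)
  pts <- data.frame(measured_g = p$measured, estimated_g = p$estimated)
  d <- cooks_distance(pts$estimated_g, pts$measured_g)$d
  fi <- filter_influential(pts, rule = list(rule = "top_k", k = 3))
  expect_equal(nrow(fi$removed), 3)
  expect_setequal(fi$removed$cooks_d, sort(d, decreasing = TRUE)[1:3])
})

test_that("RMSE and MAE follow their closed forms and Jensen ordering", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(mae(c(3, 4), c(0, 0)), 3.5)
  set.seed(9)
  for (i in 1:30) {
    p <- random_pair(sample(3:50, 1))
    expect_gte(rmse(p$measured, p$estimated), mae(p$measured, p$estimated))
  }
})

test_that("log-scale IQR screen flags only extreme weights", {
  set.seed(10)
  w <- exp(rnorm(200, 2, 0.5))
  expect_false(any(iqr_outlier_screen(w)$outlier))
  w2 <- c(w, median(w) * 1e6)
  sc <- iqr_outlier_screen(w2)
  expect_true(sc$outlier[201])
  expect_equal(sum(sc$outlier), 1)
  # quartile convention: linear interpolation (quantile type 7)
  expect_equal(sc$q1, unname(quantile(log(w2), 0.25, type = 7)))
  expect_error(iqr_outlier_screen(c(1, 0)), "> 0")
})

test_that("identity-line R^2 never exceeds the regression R^2", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_pair(sample(4:60, 1))
    f <- ols_fit(p$estimated, p$measured)
    expect_lte(yx_r2(p$measured, p$estimated), f$r2 + 1e-12)
  }
})

test_that("concordance statistics are permutation-invariant", {
  set.seed(12)
  p <- random_pair(40)
  perm <- sample(40)
  expect_equal(yx_r2(p$measured, p$estimated),
               yx_r2(p$measured[perm], p$estimated[perm]))
  expect_equal(rmse(p$measured, p$estimated),
               rmse(p$measured[perm], p$estimated[perm]))
  expect_equal(sort(q_scores(p$measured, p$estimated)$q),
               sort(q_scores(p$measured[perm], p$estimated[perm])$q))
  expect_equal(sort(cooks_distance(p$estimated, p$measured)$d),
               sort(cooks_distance(p$estimated[perm], p$measured[perm])$d))
})
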