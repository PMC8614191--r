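test_that("standardize yields exact z-scores and is idempotent", {
  df <- data.frame(x = c(1, 2, 3), y = c(10, 0, 5))
  z <- standardize(df)
  expect_equal(z$x, c(-1, 0, 1))
  for (cl in names(z)) {
    expect_equal(mean(z[[cl]]), 0, tolerance = 1e-9)
    expect_equal(sd(z[[cl]]), 1, tolerance = 1e-9)
  }
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(data.frame(x = c(1, 1, 1))), "constant")
  expect_error(standardize(df[1:2, ]), "3 rows")
})

test_that("OLS statistics match closed forms", {
  x <- c(-1.2, 0.3, 0.8, -0.5, 0.6, 0, 1.1, -1.1)
  df <- data.frame(y = 2 * x, x = x)
  f <- ols_fit("y", "x", df)
  expect_equal(unname(f$estimates[["x"]]), 2, tolerance = 1e-12)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)

  # intercept-only Gaussian AIC against the hand formula
  set.seed(2); y <- rnorm(30)
  f0 <- ols_fit("y", character(0), data.frame(y = y))
  n <- 30; rss <- sum((y - mean(y))^2)
  expect_equal(f0$aic, n * log(2 * pi * rss / n) + n + 2 * 2, tolerance = 1e-10)
  expect_equal(f0$aic, AIC(lm(y ~ 1)), tolerance = 1e-10)

  # pure-noise regression: adjusted R2 centred on 0 over many seeds
  adj <- vapply(1:300, function(i) {
    set.seed(i)
    d <- data.frame(y = rnorm(92), x = rnorm(92))
    ols_fit("y", "x", d)$adj_r2
  }, 0)
  expect_lt(abs(mean(adj)), 0.02)

  dd <- data.frame(y = rnorm(10), x1 = 1:10, x2 = 2 * (1:10))
  expect_error(ols_fit("y", c("x1", "x2"), dd), "singular")
})

test_that("star codes follow the p-value bins and are monotone", {
  expect_equal(star_code(c(0.0005, 0.005, 0.03, 0.07, 0.5)),
               c("***", "**", "*", "#", ""))
  expect_error(star_code(1.3), "0, 1")
  p <- sort(runif(50))
  codes <- star_code(p)
  rank <- c("***" = 4, "**" = 3, "*" = 2, "#" = 1)
  vals <- ifelse(codes == "", 0, rank[codes])
  expect_true(all(diff(vals) <= 0))
})

test_that("noise-free support recovery: the true predictor is found exactly", {
  set.seed(9)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  names(X) <- c("T1", paste0("D", 1:5))
  X$y <- 2 * X$T1
  rep <- stepwise_aic("y", c("T1", paste0("D", 1:5)), X)
  expect_equal(rep$selected, "T1")
  expect_equal(unname(rep$estimates[["T1"]]), 2, tolerance = 1e-9)
})

test_that("stepwise endpoint equals exhaustive best-subset AIC on orthogonal designs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200; p <- 6
    raw <- matrix(rnorm(n * p), n)
    X <- qr.Q(qr(raw))[, 1:p] * sqrt(n)        # orthogonal, unit-variance columns
    colnames(X) <- paste0("V", 1:p)
    beta <- c(0.4, -0.3, 0.25, 0, 0, 0)
    d <- as.data.frame(X)
    d$y <- X %*% beta + rnorm(n, 0, 1)
    rep <- stepwise_aic("y", colnames(X), d)
    # oracle: enumerate all 64 subsets
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
    aics <- apply(subsets, 1, function(keep) {
      ols_fit("y", colnames(X)[as.logical(keep)], d)$aic
    })
    best <- colnames(X)[as.logical(subsets[which.min(aics), ])]
    expect_setequal(rep$selected, best)
    expect_equal(rep$aic, min(aics), tolerance = 1e-10)
    # descent property: the endpoint never exceeds the full-model AIC
    expect_lte(rep$aic, rep$trace$aic[1] + 1e-12)
    expect_true(all(diff(rep$trace$aic) <= 1e-12))
  }
})

test_that("stepwise endpoint matches stats::step on generic designs", {
  for (seed in 1:4) {
    set.seed(100 + seed)
    n <- 92; p <- 8
    d <- as.data.frame(matrix(rnorm(n * p), n))
    names(d) <- paste0("V", 1:p)
    d$y <- 0.5 * d$V1 - 0.4 * d$V3 + rnorm(n, 0, 0.8)
    rep <- stepwise_aic("y", paste0("V", 1:p), d)
    full <- lm(y ~ ., data = d)
    ref <- stats::step(full, direction = "both", trace = 0)
    expect_setequal(rep$selected,
                    setdiff(names(coef(ref)), "(Intercept)"))
  }
})

test_that("report assembly leaves unselected predictors blank", {
  set.seed(5)
  n <- 50
  d <- as.data.frame(matrix(rnorm(n * 15), n))
  names(d) <- predictor_order()
  d$a <- 0.8 * d$AREA + rnorm(n, 0, 0.3)
  reports <- lapply(c("CA", "ripa"), function(sc) stepwise_aic("a", data = d, scale_name = sc))
  tab <- build_report(reports)
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("response", "scale", predictor_order(), "Adj_R2_pct"))
  expect_match(tab$AREA[1], "^0\\.\\d+\\*")
  unselected <- setdiff(predictor_order(), reports[[1]]$selected)
  for (u in unselected[1:3]) expect_equal(tab[[u]][1], "")
})

test_that("adjusted R2 and selection are invariant to affine predictor rescaling", {
  set.seed(6)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 0.6 * d$x1 - 0.5 * d$x2 + rnorm(n, 0, 0.5)
  r1 <- stepwise_aic("y", c("x1", "x2", "x3"), standardize(d, c("x1", "x2", "x3")))
  d2 <- d; d2$x1 <- 1000 * d2$x1 + 7; d2$x2 <- 0.01 * d2$x2 - 3
  r2 <- stepwise_aic("y", c("x1", "x2", "x3"), standardize(d2, c("x1", "x2", "x3")))
  expect_equal(r1$selected, r2$selected)
  expect_equal(r1$adj_r2_pct, r2$adj_r2_pct, tolerance = 1e-9)
  expect_equal(r1$estimates, r2$estimates, tolerance = 1e-9)
})
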