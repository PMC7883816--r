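test_that("the penalized fit has its known limits", {
  set.seed(6)
  n <- 200; p <- 5
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% c(2, -1, 0.5, 0, 0)) + rnorm(n)
  # vanishing penalty: least squares on the standardized design
  f0 <- lasso_path_fit(X, y, lambda_grid = c(1e-7, 1e-8), seed = 2,
                       rule = "lambda.min")
  ols <- coef(lm(scale(y, scale = FALSE) ~ 0 + scale(X)))
  expect_equal(unname(f0$beta), unname(ols), tolerance = 1e-6)
  # penalty above the null threshold: everything shrunk to zero
  Xs <- scale(X); yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc))) / n
  fmax <- lasso_path_fit(X, y, lambda_grid = c(lmax * 1.2, lmax * 1.1), seed = 2)
  expect_true(all(fmax$beta == 0))
})

test_that("the penalized objective matches a proximal-gradient oracle", {
  set.seed(17)
  n <- 50; p <- 10
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% c(1.5, -1, rep(0, 8))) + rnorm(n, 0, 0.5)
  Xs <- scale(X); yc <- y - mean(y)
  for (lambda in c(0.05, 0.2)) {
    f <- lasso_path_fit(X, y, lambda_grid = c(lambda * 1.5, lambda), seed = 3)
    g <- glmnet::glmnet(Xs, yc, lambda = lambda, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    b_pkg <- as.numeric(g$beta)
    b_orc <- oracle_lasso_fista(Xs, yc, lambda)
    expect_lt(abs(lasso_objective(Xs, yc, b_pkg, lambda) -
                  lasso_objective(Xs, yc, b_orc, lambda)), 1e-8)
  }
})

test_that("de-biasing reduces exactly to least squares on an orthogonal design", {
  set.seed(8)
  n <- 200; p <- 5
  raw <- scale(matrix(rnorm(n * p), n), scale = FALSE)
  Q <- qr.Q(qr(raw))                       # orthonormal, mean-zero columns
  X <- Q * sqrt(n - 1)                     # unit-sd columns, X'X = (n-1) I
  colnames(X) <- paste0("x", 1:p)
  y <- drop(X %*% c(1, -0.5, 0.25, 0, 0)) + rnorm(n, 0, 0.5)
  fit <- lasso_path_fit(X, y, seed = 5)
  db <- debias(X, y, fit)
  ols <- drop(crossprod(X, y - mean(y))) / (n - 1)
  expect_equal(db$beta_hat, unname(ols), tolerance = 1e-6)
  ols_fit <- lm(y ~ X)
  se_cl <- sqrt(diag(vcov(ols_fit)))[-1]
  expect_equal(db$se, unname(se_cl), tolerance = 0.05)
})

test_that("de-biased estimates are equivariant to column reordering", {
  set.seed(23)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% c(1, -1, rep(0, 6))) + rnorm(n, 0, 0.5)
  db1 <- debias(X, y, lasso_path_fit(X, y, seed = 4))
  perm <- c(3, 1, 8, 2, 7, 4, 6, 5)
  Xp <- X[, perm]
  db2 <- debias(Xp, y, lasso_path_fit(Xp, y, seed = 4))
  expect_equal(db2$beta_hat[match(colnames(X), colnames(Xp))], db1$beta_hat,
               tolerance = 1e-6)   # solver path noise only
})

test_that("interval width shrinks like 1/sqrt(n)", {
  set.seed(41)
  widths <- vapply(c(50, 100, 200, 400), function(n) {
    X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("x", 1:6)))
    y <- drop(X %*% c(1, -1, 0.5, 0, 0, 0)) + rnorm(n, 0, 0.7)
    db <- debias(X, y, lasso_path_fit(X, y, seed = n))
    mean(db$ci_high - db$ci_low)
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(c(50, 100, 200, 400))))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("per-target union design yields comparable two-condition estimates", {
  set.seed(19)
  n <- 32
  tfx <- rnorm(2 * n, 2, 1)
  tg <- 5 + 0.5 * tfx + rnorm(2 * n, 0, 0.3)
  expr <- rbind(TF1 = tfx, G1 = tg)
  colnames(expr) <- paste0("s", 1:(2 * n))
  labels <- data.frame(sample = colnames(expr),
                       condition = rep(c("normal", "tumor"), each = n))
  grn <- data.frame(target = "G1", tf = "TF1")
  it <- estimate_intensities(expr, labels, grn, grn, seed = 7)
  expect_equal(nrow(it), 2)
  expect_equal(it$beta[1], 0.5, tolerance = 0.15)
  expect_equal(it$beta[2], 0.5, tolerance = 0.15)
  expect_false(ci_disjoint(c(it$ci_low[1], it$ci_high[1]),
                           c(it$ci_low[2], it$ci_high[2])))
  # a link confirmed only in the normal network is still estimated in both
  it2 <- estimate_intensities(expr, labels, grn, grn[0, ], seed = 7)
  expect_equal(sort(it2$condition), c("normal", "tumor"))
})

test_that("a planted intensity change yields disjoint intervals reliably", {
  set.seed(33)
  n <- 32
  hits <- vapply(1:50, function(k) {
    tf_n <- rnorm(n, 2, 1); tf_t <- rnorm(n, 2, 1)
    y_n <- 5 + 0.6 * tf_n + rnorm(n, 0, 0.3)
    y_t <- 5 + 0 * tf_t + rnorm(n, 0, 0.3)
    expr <- rbind(TF1 = c(tf_n, tf_t), G1 = c(y_n, y_t))
    colnames(expr) <- paste0("s", 1:(2 * n))
    labels <- data.frame(sample = colnames(expr),
                         condition = rep(c("normal", "tumor"), each = n))
    grn <- data.frame(target = "G1", tf = "TF1")
    it <- estimate_intensities(expr, labels, grn, grn, seed = k)
    ci_disjoint(c(it$ci_low[it$condition == "normal"],
                  it$ci_high[it$condition == "normal"]),
                c(it$ci_low[it$condition == "tumor"],
                  it$ci_high[it$condition == "tumor"]))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
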