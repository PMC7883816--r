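#' Cross-validated LASSO fit
#'
#' Initial sparse estimator for the de-biasing step: coordinate-descent
#' LASSO on internally standardized columns and centered response, with the
#' penalty level chosen by k-fold cross-validation. The default is the
#' one-standard-error rule: the prediction-optimal (min-CV) penalty is too
#' dense and unstable as an inference starting point, and measurably
#' degrades the coverage of the downstream de-biased intervals. The
#' intercept is unpenalized (handled by centering). For a single regressor
#' the cross-validated LASSO degenerates gracefully to the univariate
#' problem.
#'
#' @param X sample x regressor matrix (raw scale; standardized internally).
#' @param y response vector.
#' @param lambda_grid optional penalty grid; defaults to glmnet's.
#' @param cv_folds folds for cross-validation.
#' @param seed seed for fold assignment.
#' @param rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @return list with `beta` (on the standardized scale), `lambda`,
#'   `intercept` (of the centered problem, 0 by construction) and the
#'   standardization constants.
#' @export
lasso_path_fit <- function(X, y, lambda_grid = NULL, cv_folds = 5, seed = 1,
                           rule = c("lambda.1se", "lambda.min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 8) stop_dysreg("need at least 8 samples")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  const <- scl == 0
  if (any(const)) {
    warning("constant regressor column(s): coefficient forced to 0")
    scl[const] <- 1
  }
  Xs <- scale(X, center = ctr, scale = scl)
  Xs[, const] <- 0
  yc <- y - mean(y)
  p <- ncol(Xs)
  if (p == 1) {
    b <- if (const[1]) 0 else sum(Xs[, 1] * yc) / sum(Xs[, 1]^2)
    beta <- setNames(b, colnames(X))
    return(list(beta = beta, lambda = 0, center = ctr, scale = scl,
                y_center = mean(y)))
  }
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    cvfit <- glmnet::cv.glmnet(Xs, yc, lambda = lambda_grid, foldid = foldid,
                               standardize = FALSE, intercept = FALSE)
  })
  beta <- as.numeric(coef(cvfit, s = rule))[-1]
  names(beta) <- colnames(X)
  beta[const] <- 0
  list(beta = beta, lambda = cvfit[[rule]], center = ctr, scale = scl,
       y_center = mean(y))
}

# Node-wise inverse-covariance approximation (van de Geer et al. style):
# row j of M comes from the LASSO of X_j on the remaining columns at
# lambda_node, scaled by tau_j^2 = ||X_j - X_-j g||^2 / n + lambda_node ||g||_1.
nodewise_M <- function(Xs, lambda_node) {
  n <- nrow(Xs); p <- ncol(Xs)
  M <- matrix(0, p, p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    if (p == 2) {
      # single predictor: soft-thresholded univariate coefficient
      xo <- Xs[, others]
      r <- sum(xo * Xs[, j]) / n
      denom <- sum(xo^2) / n
      g <- sign(r) * max(abs(r) - lambda_node, 0) / denom
    } else {
      fit <- glmnet::glmnet(Xs[, others, drop = FALSE], Xs[, j],
                            lambda = lambda_node, standardize = FALSE,
                            intercept = FALSE)
      g <- as.numeric(fit$beta)
    }
    resid <- Xs[, j] - Xs[, others, drop = FALSE] %*% g
    tau2 <- sum(resid^2) / n + lambda_node * sum(abs(g))
    row <- numeric(p)
    row[j] <- 1
    row[others] <- -g
    M[j, ] <- row / tau2
  }
  M
}

#' De-biased LASSO estimates with standard errors
#'
#' One-step correction of the LASSO: `b = beta + M X'(y - X beta) / n`,
#' where M approximates the inverse regressor covariance via node-wise
#' sparse regressions. Per-coefficient standard errors are
#' `sigma_hat * sqrt((M S M')_jj / n)` with `S = X'X/n`; the noise scale is
#' the residual estimate with degrees of freedom corrected by the LASSO
#' support size (falling back to a scaled-residual estimate when the
#' support is too large).
#'
#' @param X sample x regressor matrix (raw scale).
#' @param y response vector.
#' @param fit result of [lasso_path_fit()] on the same data.
#' @param lambda_node node-wise penalty; default `c * sqrt(log(p)/n)`.
#' @param c_node multiplier for the default node-wise penalty.
#' @param level confidence level for the reported intervals.
#' @param M optional precomputed node-wise matrix (from a previous call on
#'   the same fixed design); recomputed when NULL.
#' @return data.frame: `term`, `beta_hat`, `se`, `ci_low`, `ci_high`, plus
#'   attributes `sigma_hat`, `lambda_node`, `M`.
#' @export
debias <- function(X, y, fit, lambda_node = NULL, c_node = 1.0, level = 0.95,
                   M = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  Xs[, fit$scale == 1 & apply(X, 2, sd) == 0] <- 0
  yc <- y - fit$y_center
  beta <- fit$beta
  z <- qnorm(1 - (1 - level) / 2)
  resid <- yc - Xs %*% beta
  s <- sum(beta != 0)
  if (n > s + 1) {
    sigma_hat <- sqrt(sum(resid^2) / (n - s))
  } else {
    warning("support too large for df correction; using scaled-residual sigma")
    sigma_hat <- sqrt(sum(resid^2) / n) / max(1e-8, sqrt(1 - s / n))
  }
  if (p == 1) {
    # univariate: de-biasing reduces to ordinary least squares
    sxx <- sum(Xs[, 1]^2)
    if (sxx == 0) {
      b <- 0; se <- NA_real_
    } else {
      b <- sum(Xs[, 1] * yc) / sxx
      se <- sigma_hat / sqrt(sxx)
    }
    out <- data.frame(term = colnames(X) %||% "x1", beta_hat = b, se = se,
                      ci_low = b - z * se, ci_high = b + z * se)
    attr(out, "sigma_hat") <- sigma_hat
    attr(out, "lambda_node") <- 0
    return(out)
  }
  if (is.null(lambda_node)) lambda_node <- c_node * sqrt(log(p) / n)
  if (is.null(M)) M <- nodewise_M(Xs, lambda_node)
  b <- as.numeric(beta + M %*% crossprod(Xs, resid) / n)
  S <- crossprod(Xs) / n
  v <- diag(M %*% S %*% t(M))
  se <- sigma_hat * sqrt(v / n)
  out <- data.frame(term = colnames(X) %||% paste0("x", seq_len(p)),
                    beta_hat = b, se = se,
                    ci_low = b - z * se, ci_high = b + z * se)
  attr(out, "sigma_hat") <- sigma_hat
  attr(out, "lambda_node") <- lambda_node
  attr(out, "M") <- M
  out
}

#' Estimate per-link regulatory intensities in both conditions
#'
#' For every target, the regressor set is the union of its confirmed TFs
#' across the two conditional networks; one de-biased sparse regression per
#' condition is fitted on that common design, so coefficients are directly
#' comparable between conditions. Links whose target has an empty union set
#' are skipped.
#'
#' @param expr gene x sample log2 expression matrix (both conditions).
#' @param labels data.frame from [read_labels_tsv()].
#' @param grn_normal,grn_tumor conditional networks
#'   (from [build_conditional_grn()], or plain edge data.frames).
#' @param seed global seed; per-target CV seeds derive from it.
#' @param c_node node-wise penalty multiplier (see [debias()]).
#' @return data.frame of class `intensity_table`: one row per
#'   (target, tf, condition) with `beta`, `se`, `ci_low`, `ci_high`,
#'   `lambda`, `sigma`, `n_samples`, `n_regressors`.
#' @export
estimate_intensities <- function(expr, labels, grn_normal, grn_tumor,
                                 seed = 1, c_node = 1.0) {
  edges_of <- function(g) if (inherits(g, "conditional_grn")) g$edges else g
  en <- edges_of(grn_normal); et <- edges_of(grn_tumor)
  union_edges <- unique(rbind(en[, c("target", "tf")], et[, c("target", "tf")]))
  samples <- intersect(colnames(expr), labels$sample)
  cond <- setNames(labels$condition, labels$sample)[samples]
  out <- list()
  for (tg in unique(union_edges$target)) {
    tfs <- union_edges$tf[union_edges$target == tg]
    tfs <- intersect(tfs, rownames(expr))
    if (!length(tfs) || !(tg %in% rownames(expr))) next
    for (cc in c("normal", "tumor")) {
      sm <- samples[cond == cc]
      X <- t(expr[tfs, sm, drop = FALSE])
      y <- expr[tg, sm]
      fit <- lasso_path_fit(X, y, seed = derive_seed(seed, paste0(tg, cc)))
      db <- debias(X, y, fit, c_node = c_node)
      out[[paste(tg, cc)]] <- data.frame(
        target = tg, tf = db$term, condition = cc,
        beta = db$beta_hat, se = db$se,
        ci_low = db$ci_low, ci_high = db$ci_high,
        lambda = fit$lambda, sigma = attr(db, "sigma_hat"),
        n_samples = length(sm), n_regressors = length(tfs))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(target = character(), tf = character(),
                      condition = character(), beta = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(), lambda = numeric(),
                      sigma = numeric(), n_samples = integer(),
                      n_regressors = integer())
  rownames(res) <- NULL
  class(res) <- c("intensity_table", "data.frame")
  res
}
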