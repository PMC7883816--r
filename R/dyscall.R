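# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used for moment-matching the prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Empirical-Bayes hyperparameters (d0, s0^2) by matching moments of
# log sample variances, the classic moderated-t construction.
estimate_ebayes_hyperparams <- function(s2, d) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  n <- length(e)
  ev <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(d / 2)
  if (is.na(ev) || ev <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated t-test for differential expression
#'
#' Per-gene two-group comparison on log2 expression with empirical-Bayes
#' variance moderation: hyperparameters `(d0, s0^2)` are estimated by
#' matching moments of the log sample variances across genes, each gene's
#' posterior variance is `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t
#' has `d0 + d` degrees of freedom. P-values are BH-adjusted across all
#' genes.
#'
#' @param expr gene x sample log2 expression matrix.
#' @param groups vector over samples with values `"normal"` / `"tumor"`.
#' @param paired if TRUE, samples are matched by position within each group
#'   (requires a `pairing` attribute or equal-ordered groups) and the test is
#'   on per-pair differences.
#' @param lfc_threshold absolute log2-fold-change cutoff for the DEG flag.
#' @param p_threshold BH-adjusted p cutoff for the DEG flag.
#' @param d0_override force the prior degrees of freedom (0 gives the
#'   ordinary t-test; Inf full shrinkage); mainly for testing.
#' @return data.frame: `gene`, `logFC` (tumor - normal), `s2`, `t_mod`, `p`,
#'   `p_adj`, `is_deg`, `direction`.
#' @export
moderated_t_test <- function(expr, groups, paired = FALSE,
                             lfc_threshold = 1, p_threshold = 0.05,
                             d0_override = NULL) {
  stopifnot(ncol(expr) == length(groups))
  i1 <- which(groups == "tumor")
  i0 <- which(groups == "normal")
  if (paired) {
    if (length(i1) != length(i0)) stop_dysreg("paired test needs equal group sizes")
    if (length(i1) < 3) stop_dysreg("need at least 3 pairs")
    D <- expr[, i1, drop = FALSE] - expr[, i0, drop = FALSE]
    logFC <- rowMeans(D)
    s2 <- apply(D, 1, var)
    d <- ncol(D) - 1
    v <- 1 / ncol(D)
  } else {
    if (length(i1) < 3 || length(i0) < 3) stop_dysreg("need at least 3 samples per group")
    m1 <- rowMeans(expr[, i1, drop = FALSE])
    m0 <- rowMeans(expr[, i0, drop = FALSE])
    logFC <- m1 - m0
    ss1 <- apply(expr[, i1, drop = FALSE], 1, var) * (length(i1) - 1)
    ss0 <- apply(expr[, i0, drop = FALSE], 1, var) * (length(i0) - 1)
    d <- length(i1) + length(i0) - 2
    s2 <- (ss1 + ss0) / d
    v <- 1 / length(i1) + 1 / length(i0)
  }
  eps <- .Machine$double.eps
  if (any(s2 <= eps)) {
    warning("zero-variance gene(s): variance floored at machine epsilon")
    s2 <- pmax(s2, eps)
  }
  hp <- if (is.null(d0_override)) estimate_ebayes_hyperparams(s2, d)
        else list(d0 = d0_override,
                  s0sq = estimate_ebayes_hyperparams(s2, d)$s0sq)
  if (is.infinite(hp$d0)) {
    s2_post <- rep(hp$s0sq, length(s2))
    df_tot <- Inf
  } else {
    s2_post <- (hp$d0 * hp$s0sq + d * s2) / (hp$d0 + d)
    df_tot <- hp$d0 + d
  }
  t_mod <- logFC / sqrt(s2_post * v)
  p <- 2 * pt(abs(t_mod), df = df_tot, lower.tail = FALSE)
  p_adj <- p.adjust(p, "BH")
  res <- data.frame(gene = rownames(expr) %||% paste0("gene", seq_len(nrow(expr))),
                    logFC = logFC, s2 = s2,
                    t_mod = t_mod, p = p, p_adj = p_adj,
                    is_deg = abs(logFC) > lfc_threshold & p_adj < p_threshold,
                    direction = ifelse(logFC > 0, "up", "down"),
                    row.names = NULL)
  attr(res, "hyperparams") <- hp
  res
}

#' Are two confidence intervals disjoint?
#'
#' Strict convention: intervals sharing an endpoint overlap.
#'
#' @param ci_a,ci_b length-2 numeric vectors `(low, high)`.
#' @return logical.
#' @export
ci_disjoint <- function(ci_a, ci_b) {
  stopifnot(ci_a[1] <= ci_a[2], ci_b[1] <= ci_b[2])
  ci_a[2] < ci_b[1] || ci_b[2] < ci_a[1]
}

#' Is an intensity change consistent with the target's expression change?
#'
#' True iff the product of the intensity change and the target's log fold
#' change is strictly positive (a zero in either is inconsistent).
#'
#' @param delta_beta tumor-minus-normal intensity change.
#' @param target_logFC target's log2 fold change (tumor - normal).
#' @return logical.
#' @export
direction_consistent <- function(delta_beta, target_logFC) {
  stopifnot(is.finite(delta_beta), is.finite(target_logFC))
  delta_beta * target_logFC > 0
}

#' Identify gene dysregulations
#'
#' Integrates the three criteria over an intensity table: (1) the link's 95%
#' confidence intervals are disjoint between conditions, (2) the target is
#' differentially expressed, (3) the intensity-change direction matches the
#' target's expression-change direction. Results are ordered by decreasing
#' absolute intensity change.
#'
#' @param intensities an `intensity_table` from [estimate_intensities()].
#' @param degs DEG table from [moderated_t_test()].
#' @return data.frame: one row per dysregulation with full provenance
#'   (`tf`, `target`, per-condition beta and CI, `delta_beta`,
#'   `target_logFC`, `target_p_adj`).
#' @export
identify_dysregulations <- function(intensities, degs) {
  nn <- intensities[intensities$condition == "normal", ]
  tt <- intensities[intensities$condition == "tumor", ]
  key <- function(d) paste(d$tf, d$target)
  common <- intersect(key(nn), key(tt))
  nn <- nn[match(common, key(nn)), ]
  tt <- tt[match(common, key(tt)), ]
  dg <- degs[match(nn$target, degs$gene), ]
  skip <- is.na(dg$gene)
  if (any(skip))
    warning(sum(skip), " link(s) skipped: target missing from DEG table")
  delta <- tt$beta - nn$beta
  pass <- !skip &
    (tt$ci_high < nn$ci_low | nn$ci_high < tt$ci_low) &
    dg$is_deg &
    delta * dg$logFC > 0
  pass[is.na(pass)] <- FALSE
  out <- data.frame(
    tf = nn$tf[pass], target = nn$target[pass],
    beta_normal = nn$beta[pass], ci_n_lo = nn$ci_low[pass],
    ci_n_hi = nn$ci_high[pass],
    beta_tumor = tt$beta[pass], ci_t_lo = tt$ci_low[pass],
    ci_t_hi = tt$ci_high[pass],
    delta_beta = delta[pass],
    target_logFC = dg$logFC[pass], target_p_adj = dg$p_adj[pass])
  out <- out[order(-abs(out$delta_beta)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
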