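#' Greedy-selection configuration
#'
#' @param train_frac fraction of samples in each training split.
#' @param n_reps random splits per candidate evaluation.
#' @param delta_c_stop minimum median C-index improvement to accept a
#'   candidate.
#' @param seed global seed.
#' @param max_dysregs optional hard cap on signature size.
#' @return list of class `greedy_config`.
#' @export
greedy_config <- function(train_frac = 0.6, n_reps = 100, delta_c_stop = 0.001,
                          seed = 1, max_dysregs = Inf) {
  stopifnot(train_frac > 0, train_frac < 1, delta_c_stop > 0)
  structure(list(train_frac = train_frac, n_reps = n_reps,
                 delta_c_stop = delta_c_stop, seed = seed,
                 max_dysregs = max_dysregs),
            class = "greedy_config")
}

# Covariate matrix for a gene set (+ optional clinical covariates),
# aligned to the clinical table's samples.
signature_design <- function(genes, expr, clin, clinical_covs = TRUE) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop_dysreg("genes missing from expression: ",
                                paste(miss, collapse = ", "))
  X <- t(expr[genes, clin$sample, drop = FALSE])
  colnames(X) <- genes
  if (clinical_covs)
    X <- cbind(X, age = clin$age, gender = clin$gender, stage = clin$stage)
  X
}

# Median test-set C-index of a gene set over shared train/test splits.
cv_median_c <- function(genes, expr, clin, splits, clinical_covs = TRUE) {
  X <- signature_design(genes, expr, clin, clinical_covs)
  cs <- vapply(splits, function(tr) {
    te <- setdiff(seq_len(nrow(X)), tr)
    f <- tryCatch(fit_cox(clin$os_time[tr], clin$os_event[tr],
                          X[tr, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    lp_te <- drop(scale(X[te, , drop = FALSE], center = f$centers,
                        scale = FALSE) %*% f$coef)
    tryCatch(concordance_index(lp_te, clin$os_time[te], clin$os_event[te]),
             error = function(e) NA_real_)
  }, numeric(1))
  median(cs, na.rm = TRUE)
}

#' Greedy forward selection of a dysregulation signature
#'
#' The primary dysregulation is the candidate whose full-data overall
#' survival model (its two genes plus clinical covariates) has the largest
#' in-sample concordance. Each iteration then evaluates every remaining
#' candidate by adding its genes and measuring the median test-set
#' concordance over `n_reps` random train/test splits (split seeds shared
#' across candidates within an iteration, a paired comparison); the best
#' candidate joins if it improves the current median by at least
#' `delta_c_stop`, otherwise selection stops.
#'
#' @param candidates data.frame of dysregulations (`tf`, `target`).
#' @param expr gene x sample expression matrix.
#' @param clinical clinical table; rows matched to `colnames(expr)`.
#' @param cfg a [greedy_config()].
#' @param restrict optional character vector of genes (e.g. from a GMT set);
#'   only candidates with at least one member gene in the set are eligible.
#' @return list of class `signature_model`: `dysregs` (ordered data.frame of
#'   included dysregulations), `genes`, `coef` (full-data fit with clinical
#'   covariates), `centers`, `history` (per-iteration medians), `c_index`
#'   (full-data, in-sample).
#' @export
greedy_build <- function(candidates, expr, clinical, cfg = greedy_config(),
                         restrict = NULL) {
  if (!is.null(restrict)) {
    keep <- candidates$tf %in% restrict | candidates$target %in% restrict
    candidates <- candidates[keep, , drop = FALSE]
  }
  if (!nrow(candidates)) stop_dysreg("no eligible candidates")
  clin <- clinical[match(intersect(colnames(expr), clinical$sample),
                         clinical$sample), ]
  n <- nrow(clin)
  # primary: largest full-data in-sample C-index
  full_c <- vapply(seq_len(nrow(candidates)), function(i) {
    g <- unique(c(candidates$tf[i], candidates$target[i]))
    f <- tryCatch(fit_cox(clin$os_time, clin$os_event,
                          signature_design(g, expr, clin)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) NA_real_ else f$c_index
  }, numeric(1))
  if (all(is.na(full_c))) stop_dysreg("no candidate model converged")
  primary <- which.max(full_c)
  included <- primary
  genes <- unique(c(candidates$tf[primary], candidates$target[primary]))
  history <- data.frame(iteration = integer(), c_current = numeric(),
                        c_new = numeric(), accepted = logical(),
                        candidate = integer())
  iter <- 0L
  repeat {
    iter <- iter + 1L
    remaining <- setdiff(seq_len(nrow(candidates)), included)
    if (!length(remaining) || length(included) >= cfg$max_dysregs) break
    splits <- with_seed(derive_seed(cfg$seed, paste0("iter", iter)), {
      lapply(seq_len(cfg$n_reps), function(r)
        sample(n, max(2, round(cfg$train_frac * n))))
    })
    c_current <- cv_median_c(genes, expr, clin, splits)
    cand_c <- vapply(remaining, function(i) {
      g <- unique(c(genes, candidates$tf[i], candidates$target[i]))
      cv_median_c(g, expr, clin, splits)
    }, numeric(1))
    if (all(is.na(cand_c))) break
    best <- remaining[which.max(cand_c)]
    c_new <- max(cand_c, na.rm = TRUE)
    accepted <- is.finite(c_current) && (c_new - c_current >= cfg$delta_c_stop)
    history <- rbind(history, data.frame(
      iteration = iter, c_current = c_current, c_new = c_new,
      accepted = accepted, candidate = best))
    if (!accepted) break
    included <- c(included, best)
    genes <- unique(c(genes, candidates$tf[best], candidates$target[best]))
  }
  final <- fit_cox(clin$os_time, clin$os_event,
                   signature_design(genes, expr, clin))
  structure(list(dysregs = candidates[included, , drop = FALSE],
                 genes = genes, coef = final$coef, centers = final$centers,
                 c_index = final$c_index, history = history,
                 clinical_covs = TRUE),
            class = "signature_model")
}

#' Risk scores and grouping from a signature model
#'
#' The score is the fitted linear predictor with covariates centered at the
#' training means, so zero means "average predicted risk in the training
#' cohort". Grouping is either by the scored cohort's median (samples at
#' the median go to the low group) or by score sign (benefit mode:
#' positive vs negative).
#'
#' @param model a `signature_model` (or any list with `coef`, `centers`,
#'   `genes`, `clinical_covs`).
#' @param expr gene x sample expression matrix.
#' @param clinical clinical table for the scored samples.
#' @param grouping `"median"` or `"sign"`.
#' @return data.frame: `sample`, `score`, `group`.
#' @export
risk_score <- function(model, expr, clinical, grouping = c("median", "sign")) {
  grouping <- match.arg(grouping)
  clin <- clinical[match(intersect(colnames(expr), clinical$sample),
                         clinical$sample), ]
  X <- signature_design(model$genes, expr, clin,
                        clinical_covs = isTRUE(model$clinical_covs))
  X <- X[, names(model$coef), drop = FALSE]
  score <- drop(scale(X, center = model$centers, scale = FALSE) %*% model$coef)
  group <- if (grouping == "median") {
    ifelse(score <= median(score), "low", "high")
  } else {
    ifelse(score > 0, "positive", "negative")
  }
  data.frame(sample = clin$sample, score = score, group = group,
             row.names = NULL)
}

#' Kaplan-Meier comparison with log-rank test and hazard ratio
#'
#' Product-limit curves per group, the standard log-rank statistic, and the
#' hazard ratio (with Wald 95% CI) from a one-covariate proportional-hazards
#' fit on the group indicator (second level vs first).
#'
#' @param groups factor or character vector of group labels.
#' @param time,event survival outcome.
#' @return list of class `km_comparison`: `km` (survfit object), `chisq`,
#'   `p`, `hr`, `hr_ci`, `hr_ref` (the reference level).
#' @export
km_logrank_hr <- function(groups, time, event) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_dysreg("need at least two groups")
  ev_per <- tapply(event, groups, sum)
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  p <- pchisq(sd$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  hr <- hr_ci <- NA
  flagged <- any(ev_per == 0)
  if (!flagged) {
    cf <- survival::coxph(survival::Surv(time, event) ~ groups)
    hr <- exp(coef(cf)[1])
    se <- sqrt(diag(cf$var))[1]
    hr_ci <- exp(coef(cf)[1] + c(-1.96, 1.96) * se)
  } else {
    warning("group with zero events: hazard ratio undefined")
  }
  structure(list(km = survival::survfit(survival::Surv(time, event) ~ groups),
                 chisq = sd$chisq, p = p, hr = unname(hr),
                 hr_ci = unname(hr_ci), hr_ref = levels(groups)[1],
                 flagged = flagged),
            class = "km_comparison")
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' At each evaluation time t, cases are samples with an observed event by t
#' and controls are samples still at risk after t; each pair is weighted by
#' the inverse probability of remaining uncensored (cases at their event
#' time, controls at t), with the censoring survival curve estimated by
#' Kaplan-Meier on the censoring indicator. With no censoring all weights
#' are one and AUC(t) is exactly the empirical ROC AUC of the
#' event-by-t outcome.
#'
#' @param scores risk scores (higher = earlier event expected).
#' @param time,event survival outcome.
#' @param eval_times evaluation times within follow-up.
#' @return data.frame: `t`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(scores, time, event, eval_times) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {             # right-continuous censoring survival
    s <- summary(cens_fit, times = t, extend = TRUE)$surv
    pmax(s, 1e-8)
  }
  Gminus <- function(t) {        # left limit G(t-)
    s <- vapply(t, function(ti) {
      idx <- cens_fit$time < ti
      if (!any(idx)) 1 else min(cens_fit$surv[idx][cens_fit$n.event[idx] >= 0])
    }, numeric(1))
    pmax(s, 1e-8)
  }
  out <- lapply(eval_times, function(t0) {
    case <- which(time <= t0 & event == 1)
    ctrl <- which(time > t0)
    if (!length(case) || !length(ctrl)) {
      warning("no cases or no controls at t = ", t0)
      return(data.frame(t = t0, auc = NA_real_, n_cases = length(case),
                        n_controls = length(ctrl)))
    }
    wi <- 1 / Gminus(time[case])
    wj <- rep(1 / G(t0), length(ctrl))
    cmp <- outer(scores[case], scores[ctrl], `>`) +
      0.5 * outer(scores[case], scores[ctrl], `==`)
    wmat <- outer(wi, wj)
    data.frame(t = t0, auc = sum(wmat * cmp) / sum(wmat),
               n_cases = length(case), n_controls = length(ctrl))
  })
  do.call(rbind, out)
}

#' Repeated-split cross-validation of a fixed gene signature
#'
#' Per repetition: fit the overall-survival model (genes plus clinical
#' covariates) on a random training fraction, then on the held-out samples
#' compute the concordance, time-dependent AUC at the evaluation times, and
#' the log-rank significance of the median-split groups. Reports median and
#' quartiles across repetitions.
#'
#' @param genes signature gene list.
#' @param expr,clinical data as in [greedy_build()].
#' @param cfg a [greedy_config()] (train fraction, repetitions, seed).
#' @param eval_times times for the AUC columns.
#' @return list: `summary` (data.frame of median/Q1/Q3 per metric) and
#'   `reps` (per-repetition metrics; skipped repetitions are NA rows).
#' @export
cross_validate_signature <- function(genes, expr, clinical,
                                     cfg = greedy_config(),
                                     eval_times = c(1, 3, 5)) {
  clin <- clinical[match(intersect(colnames(expr), clinical$sample),
                         clinical$sample), ]
  X <- signature_design(genes, expr, clin)
  n <- nrow(X)
  metrics <- c("c_train", "c_test", paste0("auc_", eval_times), "neglog10_p")
  reps <- matrix(NA_real_, cfg$n_reps, length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in seq_len(cfg$n_reps)) {
    tr <- with_seed(derive_seed(cfg$seed, paste0("cv", r)),
                    sample(n, round(cfg$train_frac * n)))
    te <- setdiff(seq_len(n), tr)
    f <- tryCatch(fit_cox(clin$os_time[tr], clin$os_event[tr],
                          X[tr, , drop = FALSE]), error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    lp_te <- drop(scale(X[te, , drop = FALSE], center = f$centers,
                        scale = FALSE) %*% f$coef)
    ct <- tryCatch(concordance_index(lp_te, clin$os_time[te], clin$os_event[te]),
                   error = function(e) NA_real_)
    if (is.na(ct)) next
    auc <- time_dependent_auc(lp_te, clin$os_time[te], clin$os_event[te],
                              eval_times)$auc
    grp <- ifelse(lp_te <= median(lp_te), "low", "high")
    km <- tryCatch(km_logrank_hr(grp, clin$os_time[te], clin$os_event[te]),
                   error = function(e) NULL)
    reps[r, ] <- c(f$c_index, ct, auc,
                   if (is.null(km)) NA_real_ else -log10(max(km$p, 1e-300)))
  }
  qs <- apply(reps, 2, quantile, probs = c(0.5, 0.25, 0.75), na.rm = TRUE)
  summary <- data.frame(metric = metrics, median = qs[1, ],
                        q1 = qs[2, ], q3 = qs[3, ], row.names = NULL)
  list(summary = summary, reps = as.data.frame(reps))
}

#' Treatment-benefit transfer analysis
#'
#' Fits an overall-survival model on the genes alone (no clinical
#' covariates) in the untreated samples, scores the treated samples with
#' it, splits them by score sign, and compares the sign groups by
#' Kaplan-Meier / log-rank / hazard ratio and time-dependent AUC.
#'
#' @param genes signature gene list.
#' @param expr gene x sample expression matrix covering both subsets.
#' @param clinical clinical table with an `adjc` flag (and optional
#'   `adjc_type`).
#' @param adjc_type optional restriction of the treated subset to one
#'   therapy type.
#' @param eval_times times for the AUC.
#' @return list of class `benefit_result`: `scores` (treated samples),
#'   `km` (a `km_comparison`, negative vs positive), `auc`, `degenerate`
#'   flag, `n_untreated`, `n_treated`.
#' @export
benefit_transfer <- function(genes, expr, clinical, adjc_type = NULL,
                             eval_times = c(1, 3, 5)) {
  if (!"adjc" %in% names(clinical)) stop_dysreg("clinical table lacks 'adjc'")
  clin <- clinical[match(intersect(colnames(expr), clinical$sample),
                         clinical$sample), ]
  untreated <- clin[clin$adjc == 0, ]
  treated <- clin[clin$adjc == 1, ]
  if (!is.null(adjc_type))
    treated <- treated[treated$adjc_type == adjc_type, ]
  if (!nrow(untreated)) stop_dysreg("no untreated samples to train on")
  if (!nrow(treated)) stop_dysreg("no treated samples to score")
  f <- fit_cox(untreated$os_time, untreated$os_event,
               signature_design(genes, expr, untreated, clinical_covs = FALSE))
  if (!f$converged) stop_dysreg("training model did not converge")
  model <- list(coef = f$coef, centers = f$centers, genes = genes,
                clinical_covs = FALSE)
  sc <- risk_score(model, expr[, treated$sample, drop = FALSE], treated,
                   grouping = "sign")
  degenerate <- length(unique(sc$group)) < 2
  km <- NULL; auc <- NULL
  if (degenerate) {
    warning("all treated scores have the same sign: comparison degenerate")
  } else {
    grp <- factor(sc$group, levels = c("positive", "negative"))
    km <- km_logrank_hr(grp, treated$os_time, treated$os_event)
    auc <- time_dependent_auc(sc$score, treated$os_time, treated$os_event,
                              eval_times)
  }
  structure(list(scores = sc, km = km, auc = auc, degenerate = degenerate,
                 n_untreated = nrow(untreated), n_treated = nrow(treated)),
            class = "benefit_result")
}
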