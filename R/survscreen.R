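#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around the partial-likelihood maximizer (Efron tie
#' handling) returning the in-sample Harrell concordance alongside the
#' coefficients. Non-convergent or separated fits are flagged rather than
#' raised, so screening loops can drop them pairwise.
#'
#' @param time,event survival outcome (event 0/1).
#' @param X sample x covariate numeric matrix.
#' @param min_events minimum observed events required for a fit.
#' @return list of class `cox_fit`: `coef`, `lp` (linear predictor centered
#'   at covariate means), `c_index`, `converged`, `n_events`.
#' @export
fit_cox <- function(time, event, X, min_events = 10) {
  X <- as.matrix(X)
  keep <- complete.cases(X) & is.finite(time)
  X <- X[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event) < min_events) stop_dysreg("need at least ", min_events, " events")
  if (any(apply(X, 2, var) == 0)) stop_dysreg("constant covariate")
  y <- survival::Surv(time, event)
  fit <- tryCatch(
    survival::coxph.fit(X, y, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = NULL, method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  bad <- is.null(fit) || anyNA(fit$coefficients) ||
    !all(is.finite(fit$coefficients)) || any(abs(fit$coefficients) > 1e3)
  if (bad) {
    # diverging likelihood (e.g. a perfectly ranking covariate): the final
    # iterate's risk ordering is still well defined, so its concordance is
    # reported, but the fit stays flagged and screens exclude it
    lp <- fit$linear.predictors %||% NULL
    ci <- if (!is.null(lp) && all(is.finite(lp)) && var(lp) > 0)
      concordance_index(lp, time, event) else NA_real_
    return(structure(list(coef = rep(NA_real_, ncol(X)), lp = lp,
                          c_index = ci, converged = FALSE,
                          n_events = sum(event)), class = "cox_fit"))
  }
  lp <- drop(scale(X, center = TRUE, scale = FALSE) %*% fit$coefficients)
  structure(list(coef = setNames(fit$coefficients, colnames(X)), lp = lp,
                 c_index = concordance_index(lp, time, event),
                 converged = TRUE, n_events = sum(event),
                 centers = colMeans(X)),
            class = "cox_fit")
}

#' Harrell's concordance index
#'
#' Among usable pairs (the strictly shorter time has an observed event),
#' the fraction where the higher risk score goes with the shorter time;
#' risk ties count 0.5.
#'
#' @param risk risk scores (higher = worse).
#' @param time,event survival outcome.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  usable <- outer(time, time, `<`) & (event == 1)   # row i shorter, with event
  den <- sum(usable)
  if (den == 0) stop_dysreg("no usable pairs for concordance")
  conc <- sum(usable & outer(risk, risk, `>`))
  ties <- sum(usable & outer(risk, risk, `==`))
  (conc + 0.5 * ties) / den
}

#' Sample control gene pairs for the prognostic screen
#'
#' The four randomized control strategies: (i) `random_pair` — two genes
#' from the preprocessed gene list; (ii) `deg_nondeg_pair` — one DEG and
#' one non-DEG; (iii) `refgrn_edge` — a reference-network edge;
#' (iv) `refgrn_edge_deg_target` — a reference-network edge whose target is
#' a DEG. Draws are without replacement within one repetition.
#'
#' @param strategy one of the four names above.
#' @param n_pairs pairs to draw.
#' @param gene_pool character vector of genes.
#' @param deg_set character vector of DEGs.
#' @param refgrn reference edge data.frame.
#' @param seed RNG seed.
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
sample_controls <- function(strategy = c("random_pair", "deg_nondeg_pair",
                                         "refgrn_edge", "refgrn_edge_deg_target"),
                            n_pairs, gene_pool, deg_set = NULL, refgrn = NULL,
                            seed = 1) {
  strategy <- match.arg(strategy)
  with_seed(seed, {
    switch(strategy,
      random_pair = {
        if (length(gene_pool) < 2 * n_pairs) stop_dysreg("gene pool too small")
        g <- sample(gene_pool, 2 * n_pairs)
        data.frame(gene1 = g[seq_len(n_pairs)], gene2 = g[n_pairs + seq_len(n_pairs)])
      },
      deg_nondeg_pair = {
        non <- setdiff(gene_pool, deg_set)
        deg <- intersect(deg_set, gene_pool)
        if (length(deg) < n_pairs || length(non) < n_pairs)
          stop_dysreg("DEG or non-DEG pool too small")
        data.frame(gene1 = sample(deg, n_pairs), gene2 = sample(non, n_pairs))
      },
      refgrn_edge = {
        if (nrow(refgrn) < n_pairs) stop_dysreg("reference network too small")
        i <- sample(nrow(refgrn), n_pairs)
        data.frame(gene1 = refgrn$tf[i], gene2 = refgrn$target[i])
      },
      refgrn_edge_deg_target = {
        sub <- refgrn[refgrn$target %in% deg_set, , drop = FALSE]
        if (nrow(sub) < n_pairs) stop_dysreg("too few edges with DEG targets")
        i <- sample(nrow(sub), n_pairs)
        data.frame(gene1 = sub$tf[i], gene2 = sub$target[i])
      })
  })
}

# Four model types: endpoint x with/without clinical covariates.
screen_model_types <- function() {
  list(ExpClin_OS = list(endpoint = "os", clinical = TRUE),
       Exp_OS = list(endpoint = "os", clinical = FALSE),
       ExpClin_RFS = list(endpoint = "rfs", clinical = TRUE),
       Exp_RFS = list(endpoint = "rfs", clinical = FALSE))
}

# C-index of the two-gene (+ clinical) Cox model for one gene pair.
pair_c_index <- function(g1, g2, expr, clin, endpoint, with_clinical) {
  if (!(g1 %in% rownames(expr)) || !(g2 %in% rownames(expr)) || g1 == g2)
    return(NA_real_)
  X <- cbind(e1 = expr[g1, clin$sample], e2 = expr[g2, clin$sample])
  if (with_clinical)
    X <- cbind(X, age = clin$age, gender = clin$gender, stage = clin$stage)
  tm <- clin[[paste0(endpoint, "_time")]]
  ev <- clin[[paste0(endpoint, "_event")]]
  f <- tryCatch(fit_cox(tm, ev, X), error = function(e) NULL)
  if (is.null(f) || !f$converged) NA_real_ else f$c_index
}

#' Screen dysregulations for prognostic effect against randomized controls
#'
#' For each of the four Cox model types, every dysregulation's two genes
#' (plus clinical covariates where the type says so) are fitted and the
#' in-sample concordance recorded. Per repetition and control strategy, an
#' equal number of control pairs is drawn, fitted identically, and a
#' one-sided rank-sum test asks whether the dysregulation concordances are
#' larger. The dysregulation arm is fixed; only controls are redrawn.
#'
#' @param dysregs data.frame with `tf` and `target` columns.
#' @param expr gene x sample log2 expression matrix (prognostic cohort).
#' @param clinical clinical data.frame (see [read_clinical_tsv()]); rows are
#'   matched to `colnames(expr)` by the `sample` column.
#' @param refgrn reference edge data.frame (control strategies iii/iv).
#' @param deg_set character vector of DEGs (strategies ii/iv).
#' @param n_reps repetitions per strategy.
#' @param seed global seed.
#' @param min_fits minimum converged fits per arm for a repetition to count.
#' @return list of class `screen_result`: for each model type a list per
#'   strategy with the p-value vector and its median; plus the per-arm
#'   concordance vectors and a skip log.
#' @export
prognostic_screen <- function(dysregs, expr, clinical, refgrn, deg_set,
                              n_reps = 100, seed = 1, min_fits = 10) {
  if (!nrow(dysregs)) stop_dysreg("no dysregulations to screen")
  clin <- clinical[match(intersect(colnames(expr), clinical$sample),
                         clinical$sample), ]
  have_rfs <- all(c("rfs_time", "rfs_event") %in% names(clin)) &&
    !anyNA(clin$rfs_time)
  types <- screen_model_types()
  if (!have_rfs) types <- types[c("ExpClin_OS", "Exp_OS")]
  strategies <- c("random_pair", "deg_nondeg_pair", "refgrn_edge",
                  "refgrn_edge_deg_target")
  gene_pool <- rownames(expr)
  n_pairs <- nrow(dysregs)
  res <- list()
  skipped <- list()
  for (ty in names(types)) {
    ep <- types[[ty]]$endpoint; wc <- types[[ty]]$clinical
    dys_c <- mapply(pair_c_index, dysregs$tf, dysregs$target,
                    MoreArgs = list(expr = expr, clin = clin, endpoint = ep,
                                    with_clinical = wc))
    res[[ty]] <- list(dys_c_index = unname(dys_c))
    for (st in strategies) {
      pvals <- rep(NA_real_, n_reps)
      for (r in seq_len(n_reps)) {
        ctl <- sample_controls(st, n_pairs, gene_pool, deg_set, refgrn,
                               seed = derive_seed(seed, paste(ty, st, r)))
        ctl_c <- mapply(pair_c_index, ctl$gene1, ctl$gene2,
                        MoreArgs = list(expr = expr, clin = clin,
                                        endpoint = ep, with_clinical = wc))
        a <- dys_c[!is.na(dys_c)]; b <- ctl_c[!is.na(ctl_c)]
        if (length(a) < min_fits || length(b) < min_fits) {
          skipped[[length(skipped) + 1]] <- list(type = ty, strategy = st, rep = r)
          next
        }
        pvals[r] <- wilcox.test(a, b, alternative = "greater",
                                exact = FALSE)$p.value
      }
      res[[ty]][[st]] <- list(p = pvals, median_p = median(pvals, na.rm = TRUE))
    }
  }
  structure(list(results = res, skipped = skipped, n_reps = n_reps),
            class = "screen_result")
}
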