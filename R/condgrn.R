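#' Shadow-selection configuration
#'
#' @param n_trees trees per random forest.
#' @param max_rounds maximum shadow rounds.
#' @param alpha two-sided binomial-test level, Bonferroni-corrected across
#'   the features still undecided at each test.
#' @param seed RNG seed; the whole procedure is deterministic given it.
#' @param tentative_policy what to do with features still undecided at
#'   termination: `"drop"` (conservative default) or
#'   `"keep_if_above_median_shadow"`.
#' @param importance ranger importance mode; permutation importance is
#'   z-scored over trees (scaled), which keeps chance in-sample correlates
#'   from outcompeting the shadow maximum.
#' @param min_shadows minimum number of shadow columns per round (shadows
#'   are replicated when fewer features remain).
#' @return list of class `shadow_config`.
#' @export
shadow_config <- function(n_trees = 500, max_rounds = 100, alpha = 0.05,
                          seed = 1, tentative_policy = c("drop", "keep_if_above_median_shadow"),
                          importance = "permutation", min_shadows = 5) {
  stopifnot(max_rounds >= 10, alpha > 0, alpha < 1, n_trees >= 10)
  structure(list(n_trees = n_trees, max_rounds = max_rounds, alpha = alpha,
                 seed = seed, tentative_policy = match.arg(tentative_policy),
                 importance = importance, min_shadows = min_shadows),
            class = "shadow_config")
}

#' Shadow-feature relevance selection for one response
#'
#' Boruta-style iteration: every round appends an independently permuted
#' (shadow) copy of each remaining feature, fits a regression random forest,
#' and records a hit for features whose importance exceeds the round's
#' maximum shadow importance. After each round a two-sided binomial test at
#' `alpha` (Bonferroni-corrected across undecided features) confirms features
#' with significantly many hits and rejects features with significantly few;
#' rejected features leave the design. Terminates when no feature is
#' undecided or at `max_rounds`.
#'
#' @param X sample x feature numeric matrix (candidate TF expression).
#' @param y response vector (target expression), aligned with rows of X.
#' @param cfg a [shadow_config()].
#' @return data.frame with one row per feature: `tf`, `status`
#'   (confirmed/rejected/tentative), `hit_count`, `n_rounds`, `z_final`
#'   (importance z-summary from the last round the feature participated in).
#' @export
shadow_select <- function(X, y, cfg = shadow_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) < 8) stop_dysreg("shadow_select requires at least 8 samples")
  if (length(y) != nrow(X)) stop_dysreg("y must align with rows of X")
  p <- ncol(X)
  status <- setNames(rep("tentative", p), colnames(X))
  hits <- setNames(rep(0L, p), colnames(X))
  rounds <- setNames(rep(0L, p), colnames(X))
  zfin <- setNames(rep(NA_real_, p), colnames(X))

  if (var(y) == 0) {
    warning("constant response: all features rejected")
    return(data.frame(tf = colnames(X), status = "rejected", hit_count = 0L,
                      n_rounds = 0L, z_final = NA_real_))
  }
  const <- apply(X, 2, var) == 0
  status[const] <- "rejected"

  with_seed(cfg$seed, {
    for (r in seq_len(cfg$max_rounds)) {
      active <- names(status)[status != "rejected"]
      undec <- names(status)[status == "tentative"]
      if (!length(undec)) break
      Xa <- X[, active, drop = FALSE]
      # shadow pool held at the original feature count so the max-shadow
      # yardstick keeps its multiplicity even after mass rejection
      n_sh <- max(p, cfg$min_shadows)
      sh_src <- rep_len(seq_along(active), n_sh)
      Xs <- apply(Xa[, sh_src, drop = FALSE], 2, sample)
      colnames(Xs) <- paste0(".shadow", seq_len(n_sh))
      fit <- ranger::ranger(x = cbind(Xa, Xs), y = y,
                            num.trees = cfg$n_trees, importance = cfg$importance,
                            scale.permutation.importance =
                              cfg$importance == "permutation",
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      sh_imp <- imp[colnames(Xs)]
      fe_imp <- imp[active]
      thr <- max(sh_imp)
      zfin[active] <- (fe_imp - mean(sh_imp)) /
        ifelse(sd(sh_imp) > 0, sd(sh_imp), 1)
      hit <- fe_imp > thr
      hits[active[hit]] <- hits[active[hit]] + 1L
      rounds[active] <- rounds[active] + 1L

      # two-sided binomial decisions, Bonferroni-corrected across all
      # original features (constant correction keeps late rounds honest)
      for (f in undec) {
        p_hi <- pbinom(hits[f] - 1L, rounds[f], 0.5, lower.tail = FALSE)
        p_lo <- pbinom(hits[f], rounds[f], 0.5)
        if (2 * p_hi < cfg$alpha / p) status[f] <- "confirmed"
        else if (2 * p_lo < cfg$alpha / p) status[f] <- "rejected"
      }
    }
    # tentative handling at termination
    if (cfg$tentative_policy == "keep_if_above_median_shadow" &&
        any(status == "tentative")) {
      tent <- names(status)[status == "tentative"]
      status[tent][zfin[tent] > 0] <- "confirmed"
      status[status == "tentative"] <- "rejected"
    }
  })
  data.frame(tf = colnames(X), status = unname(status[colnames(X)]),
             hit_count = unname(hits[colnames(X)]),
             n_rounds = unname(rounds[colnames(X)]),
             z_final = unname(zfin[colnames(X)]))
}

#' Build a conditional regulatory network for one condition
#'
#' Runs [shadow_select()] once per target over its candidate TFs from the
#' reference network, restricted to the samples of one condition. Per-target
#' seeds are derived from the global seed and the target id, so results do
#' not depend on execution order.
#'
#' @param expr gene x sample log2 expression matrix for one condition.
#' @param refgrn reference edge data.frame (`tf`, `target`, ...).
#' @param cfg a [shadow_config()]; `cfg$seed` is the global seed.
#' @param tentative one of `"drop"`, `"keep_if_above_median_shadow"`;
#'   overrides `cfg$tentative_policy` when given.
#' @return list of class `conditional_grn`: `edges` (data.frame
#'   `target, tf, status, hit_frac`), `condition` (attribute left to caller)
#'   and per-target decision log.
#' @export
build_conditional_grn <- function(expr, refgrn, cfg = shadow_config(),
                                  tentative = NULL) {
  if (!is.null(tentative)) cfg$tentative_policy <- tentative
  genes <- rownames(expr)
  miss_tf <- setdiff(unique(refgrn$tf), genes)
  miss_tg <- setdiff(unique(refgrn$target), genes)
  if (length(miss_tf) || length(miss_tg))
    warning("dropping ", length(miss_tf), " TFs and ", length(miss_tg),
            " targets absent from the expression matrix")
  grn <- refgrn[refgrn$tf %in% genes & refgrn$target %in% genes, , drop = FALSE]
  if (ncol(expr) < 20)
    warning("fewer than 20 samples in this condition; selection may be unstable")
  targets <- unique(grn$target)
  logs <- vector("list", length(targets))
  names(logs) <- targets
  edges <- list()
  for (tg in targets) {
    tfs <- setdiff(unique(grn$tf[grn$target == tg]), tg)
    if (!length(tfs)) next
    cfg_t <- cfg
    cfg_t$seed <- derive_seed(cfg$seed, tg)
    dec <- shadow_select(t(expr[tfs, , drop = FALSE]), expr[tg, ], cfg_t)
    logs[[tg]] <- dec
    conf <- dec$tf[dec$status == "confirmed"]
    if (length(conf))
      edges[[tg]] <- data.frame(
        target = tg, tf = conf,
        status = "confirmed",
        hit_frac = dec$hit_count[match(conf, dec$tf)] /
          pmax(dec$n_rounds[match(conf, dec$tf)], 1L))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(target = character(), tf = character(),
               status = character(), hit_frac = numeric())
  rownames(edges) <- NULL
  # invariant: conditional edges are a subset of the reference network
  stopifnot(all(paste(edges$tf, edges$target) %in% paste(grn$tf, grn$target)))
  structure(list(edges = edges, decisions = logs), class = "conditional_grn")
}
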