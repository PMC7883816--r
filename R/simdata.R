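#' Generate a planted regulatory network with condition-specific coefficients
#'
#' Each target receives `links_per_target` distinct TFs; link coefficients
#' are drawn uniformly from the union of -(0.8, 0.3) and (0.3, 0.8). A chosen fraction of links is
#' dysregulated: `beta_tumor = beta_normal + s * effect_size` (random sign
#' s), at most one dysregulated link per target, and the target's tumor
#' intercept is shifted by `s * effect_size * tf_mean` in the same
#' direction, so the target is differentially expressed with matching sign
#' and the direction-consistency criterion is attainable by construction.
#'
#' @param n_tf,n_target network size.
#' @param links_per_target regulators per target.
#' @param frac_dysregulated fraction of links planted as dysregulated.
#' @param effect_size intensity change of a dysregulated link.
#' @param tf_mean mean TF expression (log2 scale).
#' @param seed RNG seed.
#' @return list of class `synthetic_truth`: `tfs`, `targets`, `links`
#'   (data.frame with `tf`, `target`, `beta_normal`, `beta_tumor`,
#'   `dysregulated`), per-condition target intercepts, `deg` flags,
#'   `tf_mean`.
#' @export
generate_grn <- function(n_tf = 50, n_target = 200, links_per_target = 3,
                         frac_dysregulated = 0.0333, effect_size = 0.8,
                         tf_mean = 2, seed = 1) {
  stopifnot(n_tf > 0, n_target > 0, links_per_target > 0,
            frac_dysregulated >= 0, frac_dysregulated <= 1)
  if (links_per_target > n_tf) stop_dysreg("links_per_target exceeds n_tf")
  with_seed(seed, {
    tfs <- sprintf("TF%02d", seq_len(n_tf))
    targets <- sprintf("G%03d", seq_len(n_target))
    links <- do.call(rbind, lapply(targets, function(tg) {
      data.frame(tf = sample(tfs, links_per_target), target = tg)
    }))
    nl <- nrow(links)
    links$beta_normal <- sample(c(-1, 1), nl, TRUE) * runif(nl, 0.3, 0.8)
    links$beta_tumor <- links$beta_normal
    links$dysregulated <- FALSE
    n_dys <- round(frac_dysregulated * nl)
    icpt_n <- setNames(runif(n_target, 6, 10), targets)
    icpt_t <- icpt_n
    deg <- setNames(rep(FALSE, n_target), targets)
    if (n_dys > 0) {
      dys_targets <- sample(targets, n_dys)   # at most one dysregulated link per target
      for (tg in dys_targets) {
        i <- sample(which(links$target == tg), 1)
        s <- sample(c(-1, 1), 1)
        links$beta_tumor[i] <- links$beta_normal[i] + s * effect_size
        links$dysregulated[i] <- TRUE
        icpt_t[tg] <- icpt_n[tg] + s * effect_size * tf_mean
        deg[tg] <- TRUE
      }
    }
    structure(list(tfs = tfs, targets = targets, links = links,
                   intercept_normal = icpt_n, intercept_tumor = icpt_t,
                   deg = deg, tf_mean = tf_mean, effect_size = effect_size),
              class = "synthetic_truth")
  })
}

#' Simulate paired two-condition expression from a planted network
#'
#' TF expression is i.i.d. Normal(`tf_mean`, 1) per sample; each target is
#' its condition intercept plus the condition-specific linear combination of
#' its TFs plus Normal(0, `noise_sd`) noise. Samples come in matched
#' normal/tumor pairs (`P01N`/`P01T`, ...).
#'
#' @param truth a `synthetic_truth` from [generate_grn()].
#' @param n_per_condition paired samples per condition.
#' @param noise_sd target noise standard deviation.
#' @param seed RNG seed.
#' @return list: `expr` (gene x sample matrix), `labels` (data.frame
#'   `sample`, `condition`, `pair`).
#' @export
simulate_expression <- function(truth, n_per_condition = 32, noise_sd = 0.5,
                                seed = 1) {
  stopifnot(n_per_condition >= 8)
  if (noise_sd < 0) stop_dysreg("noise_sd must be non-negative")
  with_seed(seed, {
    n <- n_per_condition
    ids_n <- sprintf("P%03dN", seq_len(n))
    ids_t <- sprintf("P%03dT", seq_len(n))
    genes <- c(truth$tfs, truth$targets)
    expr <- matrix(NA_real_, length(genes), 2 * n,
                   dimnames = list(genes, c(ids_n, ids_t)))
    for (cc in c("normal", "tumor")) {
      ids <- if (cc == "normal") ids_n else ids_t
      tfx <- matrix(rnorm(length(truth$tfs) * n, truth$tf_mean, 1),
                    length(truth$tfs), n,
                    dimnames = list(truth$tfs, ids))
      expr[truth$tfs, ids] <- tfx
      beta <- if (cc == "normal") truth$links$beta_normal else truth$links$beta_tumor
      icpt <- if (cc == "normal") truth$intercept_normal else truth$intercept_tumor
      for (tg in truth$targets) {
        li <- which(truth$links$target == tg)
        lp <- drop(beta[li] %*% tfx[truth$links$tf[li], , drop = FALSE])
        expr[tg, ids] <- icpt[tg] + lp + rnorm(n, 0, noise_sd)
      }
    }
    labels <- data.frame(sample = c(ids_n, ids_t),
                         condition = rep(c("normal", "tumor"), each = n),
                         pair = c(ids_t, ids_n))
    list(expr = expr, labels = labels)
  })
}

#' Simulate survival and clinical covariates from expression
#'
#' Event times are exponential with log-hazard linear in the chosen genes'
#' (centered) expression, plus an optional treatment-by-risk interaction for
#' benefit-mode cohorts. Censoring is independent uniform on `(0, cmax)`
#' with `cmax` calibrated so the realized censoring fraction matches
#' `censor_rate`. Age, gender and stage are drawn from simple distributions
#' and optionally wired into the hazard.
#'
#' @param expr gene x sample matrix (typically the tumor samples).
#' @param hazard_coefs named numeric vector of per-gene log-hazard
#'   coefficients (a subset of `rownames(expr)`).
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @param base_rate baseline exponential rate.
#' @param clinical_coefs optional named vector with elements of
#'   `age`, `gender`, `stage` entering the log-hazard.
#' @param adjc_frac fraction of samples flagged as having received adjuvant
#'   chemotherapy.
#' @param treatment_benefit multiplier applied to the gene linear predictor
#'   for treated samples (1 = no interaction).
#' @param rfs_rate_factor baseline-rate multiplier for the recurrence
#'   endpoint (same linear predictor).
#' @param seed RNG seed.
#' @return clinical data.frame in the pipeline schema: `sample`, `os_time`,
#'   `os_event`, `rfs_time`, `rfs_event`, `age`, `gender`, `stage`, `adjc`,
#'   `adjc_type`.
#' @export
simulate_survival <- function(expr, hazard_coefs, censor_rate = 0.3,
                              base_rate = 0.1, clinical_coefs = NULL,
                              adjc_frac = 0.4, treatment_benefit = 1,
                              rfs_rate_factor = 1.5, seed = 1) {
  if (censor_rate < 0 || censor_rate >= 1) stop_dysreg("censor_rate must be in [0, 1)")
  miss <- setdiff(names(hazard_coefs), rownames(expr))
  if (length(miss)) stop_dysreg("hazard genes not in expression: ",
                                paste(miss, collapse = ", "))
  with_seed(seed, {
    n <- ncol(expr)
    age <- round(rnorm(n, 65, 10))
    gender <- sample(c(0, 1), n, TRUE)
    stage <- sample(1:4, n, TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    adjc <- rbinom(n, 1, adjc_frac)
    adjc_type <- ifelse(adjc == 1,
                        sample(c("5FU", "combined"), n, TRUE), "none")
    lp_gene <- if (length(hazard_coefs)) {
      xg <- expr[names(hazard_coefs), , drop = FALSE]
      drop(hazard_coefs %*% (xg - rowMeans(xg)))
    } else rep(0, n)
    lp_gene <- lp_gene * ifelse(adjc == 1, treatment_benefit, 1)
    lp_clin <- rep(0, n)
    if (!is.null(clinical_coefs)) {
      if (!is.na(clinical_coefs["age"] %||% NA))
        lp_clin <- lp_clin + clinical_coefs[["age"]] * (age - mean(age))
      if (!is.na(clinical_coefs["gender"] %||% NA))
        lp_clin <- lp_clin + clinical_coefs[["gender"]] * gender
      if (!is.na(clinical_coefs["stage"] %||% NA))
        lp_clin <- lp_clin + clinical_coefs[["stage"]] * (stage - mean(stage))
    }
    lp <- lp_gene + lp_clin
    draw_endpoint <- function(rate0) {
      t_ev <- rexp(n, rate = rate0 * exp(lp))
      if (censor_rate == 0) {
        list(time = t_ev, event = rep(1L, n))
      } else {
        # calibrate uniform censoring horizon to the realized event times
        f <- function(cmax) mean(pmin(t_ev / cmax, 1)) - censor_rate
        cmax <- uniroot(f, c(min(t_ev) * 1e-3, max(t_ev) * 1e3))$root
        cens <- runif(n, 0, cmax)
        list(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
      }
    }
    os <- draw_endpoint(base_rate)
    rfs <- draw_endpoint(base_rate * rfs_rate_factor)
    data.frame(sample = colnames(expr),
               os_time = os$time, os_event = os$event,
               rfs_time = rfs$time, rfs_event = rfs$event,
               age = age, gender = gender, stage = stage,
               adjc = adjc, adjc_type = adjc_type)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Profiles: `tiny` (10 TFs x 30 targets, n = 16 pairs; unit-test scale),
#' `default` (50 TFs x 200 targets, n = 32 pairs, 20 planted
#' dysregulations), `benefit` (default network plus a treated/untreated
#' split with planted benefit). Files conform to the pipeline's TSV
#' schemas; repeated calls with the same profile and seed are
#' byte-identical.
#'
#' @param profile one of `"tiny"`, `"default"`, `"benefit"`.
#' @param seed RNG seed.
#' @param outdir output directory (created if needed).
#' @return invisible list: paths written plus the in-memory `truth`,
#'   `expr`, `labels`, `clinical`.
#' @export
make_fixture <- function(profile = c("tiny", "default", "benefit"),
                         seed = 1, outdir = tempfile("fixture")) {
  profile <- match.arg(profile)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pars <- switch(profile,
    tiny    = list(n_tf = 10, n_target = 30, n = 16, n_dys = 4),
    default = list(n_tf = 50, n_target = 200, n = 32, n_dys = 20),
    benefit = list(n_tf = 50, n_target = 200, n = 32, n_dys = 20))
  truth <- generate_grn(pars$n_tf, pars$n_target, links_per_target = 3,
                        frac_dysregulated = pars$n_dys / (pars$n_target * 3),
                        seed = derive_seed(seed, "grn"))
  sim <- simulate_expression(truth, pars$n, seed = derive_seed(seed, "expr"))
  # hazard signal on the genes of a few planted dysregulations
  dys <- truth$links[truth$links$dysregulated, ]
  sig_genes <- unique(c(head(dys$tf, 3), head(dys$target, 3)))
  coefs <- setNames(rep(c(0.8, -0.8), length.out = length(sig_genes)), sig_genes)
  tumor_ids <- sim$labels$sample[sim$labels$condition == "tumor"]
  clin <- simulate_survival(
    sim$expr[, tumor_ids, drop = FALSE], coefs,
    treatment_benefit = if (profile == "benefit") 1.5 else 1,
    seed = derive_seed(seed, "surv"))
  refgrn <- data.frame(tf = truth$links$tf, target = truth$links$target,
                       score = 0, p_promoter = NA_real_)
  paths <- list(
    expr = file.path(outdir, "expr.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    clinical = file.path(outdir, "clinical.tsv"),
    refgrn = file.path(outdir, "refgrn.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_expression_tsv(round(sim$expr, 6), paths$expr)
  write.table(sim$labels, paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  clin_out <- clin
  clin_out$os_time <- round(clin_out$os_time, 6)
  clin_out$rfs_time <- round(clin_out$rfs_time, 6)
  write.table(clin_out, paths$clinical, sep = "\t", quote = FALSE, row.names = FALSE)
  write_grn_tsv(refgrn, paths$refgrn)
  jsonlite::write_json(list(
    profile = profile, seed = seed,
    links = truth$links, deg = as.list(truth$deg),
    hazard_coefs = as.list(coefs),
    intercept_normal = as.list(truth$intercept_normal),
    intercept_tumor = as.list(truth$intercept_tumor)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, expr = sim$expr,
                 labels = sim$labels, clinical = clin))
}
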