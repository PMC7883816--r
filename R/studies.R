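# Reproducible simulation studies: each function sets up a synthetic
# experiment with known ground truth, runs the corresponding pipeline stage,
# and returns the operating characteristics. These back both the test suite
# and scripts/acceptance.R.

#' End-to-end dysregulation recovery on the default fixture
#'
#' For each seed: generate the default planted network (50 TFs, 200
#' targets, 20 dysregulated links, 32 sample pairs), run conditional-network
#' pruning, intensity estimation, differential expression and the
#' three-criterion call, and score the called set against the planted truth.
#'
#' @param n_seeds number of independent fixture seeds.
#' @param seed base seed.
#' @param n_trees forest size for the pruning stage (fixture-scale default
#'   100; see the methods vignette).
#' @param max_rounds shadow-round cap at fixture scale (decisions for at
#'   most 3 candidate regulators per target settle within ~20 rounds; the
#'   conservative tentative policy drops stragglers either way).
#' @param profile fixture profile passed to [make_fixture()].
#' @return data.frame per seed: `precision`, `recall`, `f1`, `n_called`.
#' @export
recovery_study <- function(n_seeds = 10, seed = 1, n_trees = 100,
                           max_rounds = 25, profile = "default") {
  res <- lapply(seq_len(n_seeds), function(k) {
    sk <- derive_seed(seed, paste0("recovery", k))
    fx <- make_fixture(profile, seed = sk)
    expr <- fx$expr; labels <- fx$labels; truth <- fx$truth
    refgrn <- data.frame(tf = truth$links$tf, target = truth$links$target)
    cfg <- shadow_config(n_trees = n_trees, max_rounds = max_rounds,
                         seed = derive_seed(sk, "boruta"))
    spl <- split(labels$sample, labels$condition)
    gn <- suppressWarnings(
      build_conditional_grn(expr[, spl$normal], refgrn, cfg))
    gt <- suppressWarnings(
      build_conditional_grn(expr[, spl$tumor], refgrn, cfg))
    it <- suppressWarnings(
      estimate_intensities(expr, labels, gn, gt, seed = derive_seed(sk, "int")))
    deg <- moderated_t_test(expr, labels$condition)
    dys <- identify_dysregulations(it, deg)
    truth_keys <- paste(truth$links$tf, truth$links$target)[truth$links$dysregulated]
    called <- paste(dys$tf, dys$target)
    tp <- length(intersect(called, truth_keys))
    prec <- if (length(called)) tp / length(called) else 0
    rec <- tp / length(truth_keys)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(seed = sk, precision = prec, recall = rec, f1 = f1,
               n_called = length(called))
  })
  do.call(rbind, res)
}

#' Family-wise error calibration of reference-network target selection
#'
#' Null simulation: random motifs scanned against promoters of pure
#' background sequence. Records, per TF and repetition, whether at least one
#' promoter was (falsely) selected; under the selection rule the per-TF
#' family-wise false-discovery frequency should stay below the nominal
#' level.
#'
#' @param n_tf number of random motifs.
#' @param n_promoters promoters per repetition.
#' @param prom_len promoter length.
#' @param motif_width motif width (needs to be large enough that the score
#'   grid resolves the promoter-level threshold).
#' @param n_reps repetitions.
#' @param cfg a [scan_config()].
#' @param seed RNG seed (motifs and repetitions derive from it).
#' @param rep_seed optional separate seed for the promoter repetitions;
#'   lets a two-stage check rerun the same motifs on fresh promoters.
#' @return list: `rate` (per-TF family-wise frequency), `mc_se` (Monte-Carlo
#'   standard error of a rate at the nominal level), `n_reps`.
#' @export
fwer_null_study <- function(n_tf = 20, n_promoters = 200, prom_len = 1000,
                            motif_width = 14, n_reps = 300,
                            cfg = scan_config(), seed = 1, rep_seed = NULL) {
  motifs <- with_seed(derive_seed(seed, "motifs"), {
    lapply(seq_len(n_tf), function(i) {
      m <- matrix(rgamma(motif_width * 4, 0.5), motif_width, 4)
      m <- m / rowSums(m)
      colnames(m) <- c("A", "C", "G", "T")
      list(tf_name = paste0("TF", i), width = motif_width, mat = m,
           background = rep(0.25, 4))
    })
  })
  with_seed(rep_seed %||% derive_seed(seed, "reps"), {
    bg <- rep(0.25, 4)
    # per-motif scoring matrices and exact p-value tables, computed once
    prep <- lapply(motifs, function(mo) {
      lom <- log_odds_matrix(mo, bg, cfg$pseudocount)
      im <- discretize_scores(lom, cfg$step)
      im_rc <- revcomp_matrix(im)
      list(fwd = matrix(as.numeric(im), motif_width, 4),
           rev = matrix(as.numeric(im_rc), motif_width, 4),
           tab_f = exact_score_pvalues(im, bg),
           tab_r = exact_score_pvalues(im_rc, bg))
    })
    false_hit <- matrix(FALSE, n_reps, n_tf)
    for (r in seq_len(n_reps)) {
      seqs <- matrix(sample.int(4L, n_promoters * prom_len, replace = TRUE),
                     prom_len, n_promoters)   # one promoter per column
      for (i in seq_len(n_tf)) {
        pp <- prep[[i]]
        bs <- pwm_best_scores_cpp(seqs, pp$fwd, pp$rev)
        p_site <- pmin(score_pvalue(pp$tab_f, as.integer(round(bs[, 1]))),
                       score_pvalue(pp$tab_r, as.integer(round(bs[, 2]))))
        sel <- fwer_select_targets(p_site, as.integer(bs[, 3]), n_promoters,
                                   cfg$fwer_alpha)
        false_hit[r, i] <- any(sel$selected)
      }
    }
    list(rate = colMeans(false_hit),
         mc_se = sqrt(cfg$fwer_alpha * (1 - cfg$fwer_alpha) / n_reps),
         n_reps = n_reps)
  })
}

#' Shadow-selection recovery and null calibration
#'
#' Planted arm: `y = x1 + x2 - x3 + noise` among irrelevant standard-normal
#' candidates. Null arm: the same design with an independent response.
#'
#' @param n_seeds seeds per arm.
#' @param n samples.
#' @param p candidate features.
#' @param noise_sd noise level of the planted response.
#' @param seed base seed.
#' @param cfg a [shadow_config()] template (per-seed seeds are derived).
#' @return data.frame per seed and arm: `recall` (planted arm),
#'   `false_confirms`, `n_confirmed`.
#' @export
shadow_recovery_study <- function(n_seeds = 20, n = 100, p = 100,
                                  noise_sd = 0.5, seed = 1,
                                  cfg = shadow_config()) {
  run_one <- function(k, null_arm) {
    sk <- derive_seed(seed, paste0("shadow", k, null_arm))
    with_seed(sk, {
      X <- matrix(rnorm(n * p), n)
      colnames(X) <- paste0("x", seq_len(p))
      y <- if (null_arm) rnorm(n) else
        X[, 1] + X[, 2] - X[, 3] + rnorm(n, 0, noise_sd)
      cfg$seed <- derive_seed(sk, "sel")
      dec <- shadow_select(X, y, cfg)
      conf <- dec$tf[dec$status == "confirmed"]
      truth <- if (null_arm) character() else c("x1", "x2", "x3")
      data.frame(arm = if (null_arm) "null" else "planted",
                 recall = if (null_arm) NA_real_ else
                   length(intersect(conf, truth)) / length(truth),
                 false_confirms = length(setdiff(conf, truth)),
                 n_confirmed = length(conf))
    })
  }
  rbind(do.call(rbind, lapply(seq_len(n_seeds), run_one, null_arm = FALSE)),
        do.call(rbind, lapply(seq_len(n_seeds), run_one, null_arm = TRUE)))
}

#' Fixed-design calibration of de-biased LASSO intervals
#'
#' One Gaussian design, repeated response draws from a sparse linear model.
#' Reports empirical 95% CI coverage on the nonzero coefficients and the
#' |z| > 1.96 rate on the zero coefficients.
#'
#' @param n,p design size.
#' @param beta_nonzero values of the nonzero coefficients (placed first).
#' @param sigma noise standard deviation.
#' @param n_reps response draws.
#' @param seed RNG seed.
#' @return list: `coverage`, `null_z_rate`, per-rep matrix of nonzero
#'   estimates.
#' @export
debias_calibration_study <- function(n = 100, p = 150,
                                     beta_nonzero = c(2, -1, 0.5, 1.5, -2),
                                     sigma = 1, n_reps = 200, seed = 1) {
  s <- length(beta_nonzero)
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("x", seq_len(p))
    sds <- apply(X, 2, sd)
    beta_true <- c(beta_nonzero, rep(0, p - s))
    beta_true_std <- beta_true * sds   # estimates are on the standardized scale
    M <- NULL
    cover <- matrix(NA, n_reps, s)
    nullz <- matrix(NA, n_reps, p - s)
    est <- matrix(NA, n_reps, s)
    for (r in seq_len(n_reps)) {
      y <- drop(X %*% beta_true) + rnorm(n, 0, sigma)
      fit <- lasso_path_fit(X, y, seed = derive_seed(seed, paste0("cv", r)))
      db <- debias(X, y, fit, M = M)
      if (is.null(M)) M <- attr(db, "M")
      cover[r, ] <- db$ci_low[1:s] <= beta_true_std[1:s] &
        beta_true_std[1:s] <= db$ci_high[1:s]
      z <- db$beta_hat / db$se
      nullz[r, ] <- abs(z[(s + 1):p]) > 1.96
      est[r, ] <- db$beta_hat[1:s]
    }
    list(coverage = mean(cover), null_z_rate = mean(nullz), estimates = est)
  })
}

# Shared scaffolding for the screen studies: a cohort of null genes plus an
# optional block of prognostic "dysregulation" genes.
screen_sim_cohort <- function(n_dys = 50, n_null_genes = 600, n_samples = 200,
                              planted = TRUE, hazard = 0.5, seed = 1) {
  with_seed(seed, {
    sig_genes <- paste0("S", seq_len(2 * n_dys))
    null_genes <- paste0("N", seq_len(n_null_genes))
    genes <- c(sig_genes, null_genes)
    expr <- matrix(rnorm(length(genes) * n_samples, 8, 1), length(genes),
                   dimnames = list(genes, paste0("P", seq_len(n_samples))))
    dysregs <- data.frame(tf = sig_genes[seq_len(n_dys)],
                          target = sig_genes[n_dys + seq_len(n_dys)])
    coefs <- if (planted)
      setNames(sample(c(-hazard, hazard), length(sig_genes), TRUE), sig_genes)
    else setNames(numeric(0), character(0))
    clinical <- simulate_survival(expr, coefs, censor_rate = 0.3,
                                  seed = derive_seed(seed, "surv"))
    deg_set <- sample(null_genes, min(150, floor(n_null_genes / 3)))
    refgrn <- data.frame(tf = sample(null_genes, 400, TRUE),
                         target = sample(null_genes, 400, TRUE))
    refgrn <- refgrn[refgrn$tf != refgrn$target, ]
    list(expr = expr, clinical = clinical, dysregs = dysregs,
         deg_set = deg_set, refgrn = refgrn)
  })
}

#' Calibration of the prognostic screen
#'
#' Planted mode: the dysregulation pairs' genes carry a true log-hazard
#' effect while all control pools are null, so the screen should reject.
#' Null mode: the dysregulation arm is null too, so one-sided rank-test
#' p-values should center near 0.5.
#'
#' @param planted logical.
#' @param n_dys number of dysregulation pairs.
#' @param n_samples cohort size.
#' @param n_reps control repetitions.
#' @param seed RNG seed.
#' @return the [prognostic_screen()] result.
#' @export
screen_calibration_study <- function(planted = TRUE, n_dys = 50,
                                     n_samples = 200, n_reps = 25, seed = 1) {
  co <- screen_sim_cohort(n_dys = n_dys, n_samples = n_samples,
                          planted = planted, seed = seed)
  prognostic_screen(co$dysregs, co$expr, co$clinical, co$refgrn, co$deg_set,
                    n_reps = n_reps, seed = derive_seed(seed, "screen"))
}

#' Greedy primary selection with one planted prognostic candidate
#'
#' Per seed: 21 candidate gene pairs, exactly one of which carries hazard
#' signal; records whether the greedy stage picks the planted candidate as
#' primary, and the signature's cross-validated history.
#'
#' @param n_seeds seeds.
#' @param n_samples cohort size.
#' @param n_noise number of noise candidates.
#' @param hazard per-gene log-hazard coefficient of the planted pair.
#' @param n_reps splits per greedy iteration.
#' @param seed base seed.
#' @return data.frame per seed: `primary_correct`, `n_included`,
#'   `history_ok` (accepted steps improved by at least the stopping delta).
#' @export
greedy_selection_study <- function(n_seeds = 20, n_samples = 200,
                                   n_noise = 20, hazard = 0.8, n_reps = 25,
                                   seed = 1) {
  res <- lapply(seq_len(n_seeds), function(k) {
    sk <- derive_seed(seed, paste0("greedy", k))
    with_seed(sk, {
      n_cand <- n_noise + 1
      genes <- paste0("g", seq_len(2 * n_cand))
      expr <- matrix(rnorm(2 * n_cand * n_samples, 8, 1), 2 * n_cand,
                     dimnames = list(genes, paste0("P", seq_len(n_samples))))
      cand <- data.frame(tf = genes[seq_len(n_cand)],
                         target = genes[n_cand + seq_len(n_cand)])
      planted <- sample(n_cand, 1)
      coefs <- setNames(c(hazard, -hazard),
                        c(cand$tf[planted], cand$target[planted]))
      clinical <- simulate_survival(expr, coefs, censor_rate = 0.3,
                                    seed = derive_seed(sk, "surv"))
      cfg <- greedy_config(n_reps = n_reps, seed = derive_seed(sk, "greedy"))
      mod <- greedy_build(cand, expr, clinical, cfg)
      acc <- mod$history[mod$history$accepted, , drop = FALSE]
      data.frame(
        primary_correct = identical(
          sort(unique(c(mod$dysregs$tf[1], mod$dysregs$target[1]))),
          sort(unique(c(cand$tf[planted], cand$target[planted])))),
        n_included = nrow(mod$dysregs),
        history_ok = !nrow(acc) ||
          all(acc$c_new - acc$c_current >= cfg$delta_c_stop))
    })
  })
  do.call(rbind, res)
}
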