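sim_cohort <- function(n = 120, seed = 1, hazard = c(g1 = 0.9, g2 = -0.9)) {
  with_seed <- dysreg:::with_seed
  with_seed(seed, {
    genes <- paste0("g", 1:6)
    expr <- matrix(rnorm(6 * n, 8, 1), 6,
                   dimnames = list(genes, paste0("P", 1:n)))
    clinical <- simulate_survival(expr, hazard, censor_rate = 0.25,
                                  seed = seed + 1)
    list(expr = expr, clinical = clinical)
  })
}

test_that("risk scores equal the centered linear predictor and split at the median", {
  co <- sim_cohort(seed = 3)
  model <- list(coef = c(g1 = 0.5, g2 = -0.25, g3 = 0.1),
                centers = c(g1 = 8, g2 = 8, g3 = 8),
                genes = c("g1", "g2", "g3"), clinical_covs = FALSE)
  rs <- risk_score(model, co$expr, co$clinical)
  # independent arithmetic oracle on ten samples
  for (s in co$clinical$sample[1:10]) {
    want <- sum(model$coef * (co$expr[model$genes, s] - model$centers))
    expect_equal(rs$score[rs$sample == s], want)
  }
  expect_lte(abs(sum(rs$group == "low") - sum(rs$group == "high")), 1)
  # ties at the median go to the low group
  model0 <- list(coef = c(g1 = 0), centers = c(g1 = 8), genes = "g1",
                 clinical_covs = FALSE)
  rs0 <- risk_score(model0, co$expr, co$clinical)
  expect_true(all(rs0$score == 0))
  expect_true(all(rs0$group == "low"))
  expect_error(risk_score(list(coef = c(zz = 1), centers = c(zz = 0),
                               genes = "zz", clinical_covs = FALSE),
                          co$expr, co$clinical), "missing")
})

test_that("log-rank statistic matches the hand-computed formula", {
  # small worked instance with censoring
  tm <- c(3, 5, 7, 2, 10, 4, 8, 6)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0)
  gr <- rep(c("a", "b"), each = 4)
  km <- km_logrank_hr(gr, tm, ev)
  expect_equal(km$chisq, oracle_logrank_chisq(gr, tm, ev), tolerance = 1e-10)
  set.seed(7)
  for (i in 1:10) {
    tm <- rexp(30); ev <- rbinom(30, 1, 0.7); gr <- rbinom(30, 1, 0.5)
    if (length(unique(gr)) < 2 || sum(ev) < 2) next
    expect_equal(km_logrank_hr(gr, tm, ev)$chisq,
                 oracle_logrank_chisq(gr, tm, ev), tolerance = 1e-10)
  }
})

test_that("group dominance and equality show up in the hazard ratio", {
  set.seed(12)
  tm <- c(rexp(20, 1), rexp(20, 0.2))   # group a fails sooner
  ev <- rep(1, 40)
  gr <- rep(c("a", "b"), each = 20)
  km <- km_logrank_hr(gr, tm, ev)
  expect_lt(km$p, 0.01)
  expect_lt(km$hr, 1)                   # b vs a: slower failures
  tm2 <- rep(rexp(20), 2)
  km2 <- km_logrank_hr(rep(c("a", "b"), each = 20), tm2, rep(1, 40))
  expect_gt(km2$p, 0.9)
  expect_equal(km2$hr, 1, tolerance = 0.05)
  expect_warning(km_logrank_hr(c("a", "a", "b", "b"), c(1, 2, 3, 4),
                               c(1, 1, 0, 0)), "zero events")
})

test_that("time-dependent AUC reduces to the binary AUC without censoring", {
  set.seed(21)
  n <- 150
  tm <- rexp(n, 0.3); ev <- rep(1, n)
  score <- -tm + rnorm(n, 0, 0.5)
  for (t0 in c(1, 3, 5)) {
    auc <- time_dependent_auc(score, tm, ev, t0)$auc
    expect_equal(auc, oracle_binary_auc(score, tm <= t0))
  }
  # perfect score
  expect_true(all(time_dependent_auc(-tm, tm, ev, c(1, 3))$auc == 1))
  # weights kick in under censoring but stay near the uncensored answer
  cens <- runif(n, 0, 12)
  tm_c <- pmin(tm, cens); ev_c <- as.integer(tm <= cens)
  auc_c <- time_dependent_auc(score, tm_c, ev_c, 3)$auc
  expect_equal(auc_c, oracle_binary_auc(score, tm <= 3), tolerance = 0.05)
  expect_warning(time_dependent_auc(score, tm, ev, max(tm) + 1), "no cases")
})

test_that("greedy selection respects its stopping rule and trivial limits", {
  co <- sim_cohort(n = 150, seed = 5)
  cand1 <- data.frame(tf = "g1", target = "g2")
  m1 <- greedy_build(cand1, co$expr, co$clinical,
                     greedy_config(n_reps = 5, seed = 2))
  expect_equal(nrow(m1$dysregs), 1)
  expect_equal(sort(m1$genes), c("g1", "g2"))

  cand <- data.frame(tf = c("g1", "g3", "g5"), target = c("g2", "g4", "g6"))
  mInf <- greedy_build(cand, co$expr, co$clinical,
                       greedy_config(n_reps = 5, delta_c_stop = Inf, seed = 2))
  expect_equal(nrow(mInf$dysregs), 1)    # stopping-rule limit: primary only

  m <- greedy_build(cand, co$expr, co$clinical,
                    greedy_config(n_reps = 10, seed = 2))
  acc <- m$history[m$history$accepted, ]
  if (nrow(acc))
    expect_true(all(acc$c_new - acc$c_current >= 0.001))
  expect_lte(length(m$genes), 2 * nrow(m$dysregs))
  # the planted prognostic pair is chosen as primary
  expect_setequal(c(m$dysregs$tf[1], m$dysregs$target[1]), c("g1", "g2"))
})

test_that("signature cross-validation is reproducible and sane", {
  co <- sim_cohort(n = 150, seed = 9)
  cfg <- greedy_config(n_reps = 2, seed = 4)
  cv1 <- cross_validate_signature(c("g1", "g2"), co$expr, co$clinical, cfg,
                                  eval_times = c(2, 4))
  cv2 <- cross_validate_signature(c("g1", "g2"), co$expr, co$clinical, cfg,
                                  eval_times = c(2, 4))
  expect_identical(cv1, cv2)
  expect_true(all(cv1$summary$metric ==
                  c("c_train", "c_test", "auc_2", "auc_4", "neglog10_p")))
})

test_that("benefit transfer separates treated samples by planted risk", {
  hrs <- vapply(1:10, function(k) {
    co <- sim_cohort(n = 250, seed = 100 + k)
    bt <- benefit_transfer(c("g1", "g2"), co$expr, co$clinical)
    bt$km$hr    # negative vs positive score group
  }, numeric(1))
  expect_gte(mean(hrs < 1), 0.9)
  # null genes: hazard ratio centers near one
  hr0 <- vapply(1:10, function(k) {
    co <- sim_cohort(n = 250, seed = 200 + k, hazard = c(g1 = 0, g2 = 0)[0])
    bt <- benefit_transfer(c("g3", "g4"), co$expr, co$clinical)
    if (bt$degenerate) NA_real_ else bt$km$hr
  }, numeric(1))
  expect_equal(median(log(hr0), na.rm = TRUE), 0, tolerance = 0.45)
  # an all-untreated cohort cannot be scored
  co <- sim_cohort(n = 60, seed = 3)
  co$clinical$adjc <- 0
  expect_error(benefit_transfer(c("g1", "g2"), co$expr, co$clinical),
               "no treated")
})
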