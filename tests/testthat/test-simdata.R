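test_that("planted networks have the declared shape and sign structure", {
  truth <- generate_grn(n_tf = 12, n_target = 10, links_per_target = 3,
                        frac_dysregulated = 0, seed = 2)
  expect_equal(nrow(truth$links), 30)
  expect_equal(truth$links$beta_normal, truth$links$beta_tumor)
  expect_error(generate_grn(n_tf = 2, links_per_target = 3), "exceeds")

  # dysregulated links change intensity and intercept in the same direction,
  # so the planted fold change matches the intensity change
  for (s in 1:20) {
    tr <- generate_grn(n_tf = 10, n_target = 20, links_per_target = 2,
                       frac_dysregulated = 0.2, effect_size = 0.8, seed = s)
    dys <- tr$links[tr$links$dysregulated, ]
    shift <- tr$intercept_tumor[dys$target] - tr$intercept_normal[dys$target]
    expect_true(all(sign(dys$beta_tumor - dys$beta_normal) == sign(shift)))
    expect_true(all(tr$deg[dys$target]))
    expect_true(all(abs(dys$beta_tumor - dys$beta_normal) == 0.8))
  }
})

test_that("simulated expression reproduces the planted coefficients", {
  truth <- generate_grn(n_tf = 8, n_target = 10, links_per_target = 2,
                        frac_dysregulated = 0.1, seed = 4)
  sim <- simulate_expression(truth, 500, noise_sd = 0.5, seed = 5)
  norm_ids <- sim$labels$sample[sim$labels$condition == "normal"]
  for (i in sample(nrow(truth$links), 5)) {
    tg <- truth$links$target[i]
    tfs <- truth$links$tf[truth$links$target == tg]
    fit <- lm(sim$expr[tg, norm_ids] ~ t(sim$expr[tfs, norm_ids, drop = FALSE]))
    got <- unname(coef(fit)[-1])
    want <- truth$links$beta_normal[truth$links$target == tg]
    expect_lt(max(abs(got - want)), 0.05)
  }
  # noiseless single link is exactly linear
  tr1 <- generate_grn(n_tf = 1, n_target = 1, links_per_target = 1,
                      frac_dysregulated = 0, seed = 1)
  s1 <- simulate_expression(tr1, 10, noise_sd = 0, seed = 2)
  ids <- s1$labels$sample[s1$labels$condition == "normal"]
  resid <- s1$expr["G001", ids] - tr1$intercept_normal["G001"] -
    tr1$links$beta_normal * s1$expr["TF01", ids]
  expect_equal(unname(resid), rep(0, 10), tolerance = 1e-12)
})

test_that("survival simulation calibrates censoring and recovers hazards", {
  set.seed(6)
  genes <- paste0("g", 1:4)
  expr <- matrix(rnorm(4 * 300, 8, 1), 4,
                 dimnames = list(genes, paste0("P", 1:300)))
  clin <- simulate_survival(expr, c(g1 = 1.0), censor_rate = 0.3, seed = 7)
  expect_equal(1 - mean(clin$os_event), 0.3, tolerance = 0.05)
  # univariate Cox recovers the planted coefficient
  coefs <- vapply(1:20, function(k) {
    cl <- simulate_survival(expr, c(g1 = 1.0), censor_rate = 0.3, seed = 50 + k)
    unname(fit_cox(cl$os_time, cl$os_event, cbind(g1 = expr["g1", ]))$coef)
  }, numeric(1))
  expect_equal(median(coefs), 1.0, tolerance = 0.15)
  # no signal: concordance of any gene score stays at chance
  cl0 <- simulate_survival(expr, setNames(numeric(0), character(0)),
                           censor_rate = 0, seed = 8)
  expect_equal(concordance_index(expr["g2", ], cl0$os_time, cl0$os_event),
               0.5, tolerance = 0.08)
  expect_error(simulate_survival(expr, c(g1 = 1), censor_rate = 1), "censor_rate")
  expect_error(simulate_survival(expr, c(zz = 1)), "not in expression")
})

test_that("fixtures are schema-conformant and byte-identical under a seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx1 <- make_fixture("tiny", seed = 9, outdir = d1)
  fx2 <- make_fixture("tiny", seed = 9, outdir = d2)
  for (f in c("expr.tsv", "labels.tsv", "clinical.tsv", "refgrn.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # files round-trip through the pipeline readers
  expr <- read_expression_tsv(file.path(d1, "expr.tsv"))
  labels <- read_labels_tsv(file.path(d1, "labels.tsv"))
  clin <- read_clinical_tsv(file.path(d1, "clinical.tsv"))
  grn <- read_grn_tsv(file.path(d1, "refgrn.tsv"))
  expect_setequal(colnames(expr), labels$sample)
  expect_setequal(clin$sample, labels$sample[labels$condition == "tumor"])
  expect_true(all(grn$tf %in% rownames(expr)))
  expect_equal(nrow(fx1$truth$links), nrow(grn))
})

test_that("planted dysregulations satisfy the call criteria at large n", {
  # large-sample check: intensity and expression changes are jointly
  # recoverable for every planted dysregulation
  truth <- generate_grn(n_tf = 10, n_target = 20, links_per_target = 2,
                        frac_dysregulated = 0.25, seed = 3)
  sim <- simulate_expression(truth, 2000, noise_sd = 0.5, seed = 4)
  deg <- moderated_t_test(sim$expr, sim$labels$condition)
  dys <- truth$links[truth$links$dysregulated, ]
  called_deg <- deg$is_deg[match(dys$target, deg$gene)]
  expect_gte(mean(called_deg), 0.95)
  # per-condition OLS on the true design recovers the planted betas, so the
  # direction of change matches the fold change
  ids_n <- sim$labels$sample[sim$labels$condition == "normal"]
  ids_t <- sim$labels$sample[sim$labels$condition == "tumor"]
  ok <- vapply(seq_len(nrow(dys)), function(i) {
    tg <- dys$target[i]
    tfs <- truth$links$tf[truth$links$target == tg]
    j <- which(tfs == dys$tf[i])
    bn <- coef(lm(sim$expr[tg, ids_n] ~ t(sim$expr[tfs, ids_n, drop = FALSE])))[j + 1]
    bt <- coef(lm(sim$expr[tg, ids_t] ~ t(sim$expr[tfs, ids_t, drop = FALSE])))[j + 1]
    lfc <- deg$logFC[deg$gene == tg]
    sign(bt - bn) == sign(lfc)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
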