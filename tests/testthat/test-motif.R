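meme_text <- c(
  "MEME version 4", "",
  "ALPHABET= ACGT", "",
  "Background letter frequencies",
  "A 0.25 C 0.25 G 0.25 T 0.25", "",
  "MOTIF AAAA_motif",
  "letter-probability matrix: alength= 4 w= 4 nsites= 20",
  "1.0 0.0 0.0 0.0", "1.0 0.0 0.0 0.0", "1.0 0.0 0.0 0.0", "1.0 0.0 0.0 0.0",
  "",
  "MOTIF mixed",
  "letter-probability matrix: alength= 4 w= 3 nsites= 10",
  "0.5 0.5 0.0 0.0", "0.25 0.25 0.25 0.25", "0.0 0.0 0.0 1.0")

test_that("read_meme parses minimal MEME text", {
  path <- withr::local_tempfile(lines = meme_text, fileext = ".meme")
  mo <- read_meme(path)
  expect_length(mo, 2)
  expect_equal(mo[[1]]$width, 4)
  expect_equal(unname(mo[[1]]$mat[, "A"]), rep(1, 4))
  expect_equal(mo[[2]]$tf_name, "mixed")

  bad <- meme_text
  bad[10] <- "0.3 0.1 0.05 0.05"   # sums to 0.5
  pbad <- withr::local_tempfile(lines = bad, fileext = ".meme")
  expect_error(read_meme(pbad), "sum to 1 at line 10")
})

test_that("log-odds scoring has the expected closed-form values", {
  mo <- random_motif(4, seed = 1)
  # uniform position, uniform background: zero score regardless of pseudocount
  mo$mat[2, ] <- 0.25
  lom <- log_odds_matrix(mo, rep(0.25, 4), pseudocount = 0.1)
  expect_equal(unname(lom[2, ]), rep(0, 4))
  # deterministic position, no pseudocount: 2 bits
  mo$mat[1, ] <- c(1, 0, 0, 0)
  lom0 <- log_odds_matrix(mo, rep(0.25, 4), pseudocount = 0)
  expect_equal(unname(lom0[1, "A"]), 2)
  # every row's max is non-negative for small pseudocount
  expect_true(all(apply(log_odds_matrix(random_motif(6, seed = 2),
                                        pseudocount = 0.01), 1, max) >= 0))
  expect_error(log_odds_matrix(mo, c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("exact score p-values match brute-force enumeration", {
  cfg <- scan_config()
  for (s in 1:5) {
    mo <- random_motif(sample(3:5, 1), seed = 100 + s)
    im <- dysreg:::discretize_scores(log_odds_matrix(mo, pseudocount = 0.1),
                                     cfg$step)
    tab <- exact_score_pvalues(im)
    oracle <- oracle_pwm_tail(im)
    grid <- tab$min_score:tab$max_score
    expect_equal(dysreg:::score_pvalue(tab, grid),
                 vapply(grid, oracle, numeric(1)), tolerance = 1e-14)
  }
  # single best word: p at the maximum is 4^-w
  mo <- random_motif(5, seed = 9)
  mo$mat <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 5), 5, 4, byrow = TRUE)
  im <- dysreg:::discretize_scores(log_odds_matrix(mo, pseudocount = 0), 0.01)
  tab <- exact_score_pvalues(im)
  expect_equal(dysreg:::score_pvalue(tab, tab$max_score), 4^-5)
  expect_equal(dysreg:::score_pvalue(tab, tab$min_score), 1)
})

test_that("scan_sequence finds a planted consensus site and skips N windows", {
  mo <- random_motif(10, seed = 3)
  mo$mat <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 10), 10, 4, byrow = TRUE)
  hits <- scan_sequence(strrep("A", 10), mo)   # sequence = exact consensus
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 0)
  expect_equal(hits$strand, "+")
  expect_lt(hits$p, 1e-4)
  expect_equal(nrow(scan_sequence(strrep("N", 50), mo)), 0)
  expect_warning(h <- scan_sequence("ACGT", mo), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("hits on a reverse-complemented sequence swap strands", {
  set.seed(21)
  mo <- random_motif(8, sharp = 0.3, seed = 77)
  cfg <- scan_config(site_p_threshold = 5e-3)   # permissive: more hits to compare
  for (i in 1:5) {
    seq <- random_dna(1, 400)
    h_f <- scan_sequence(seq, mo, cfg)
    h_r <- scan_sequence(revcomp_string(seq), mo, cfg)
    expect_equal(nrow(h_f), nrow(h_r))
    expect_equal(sum(h_f$strand == "+"), sum(h_r$strand == "-"))
    expect_equal(sort(h_f$score), sort(h_r$score))
  }
})

test_that("null scan hit rate matches the site p threshold", {
  set.seed(12)
  mo <- random_motif(10, sharp = 0.5, seed = 55)
  seqs <- random_dna(200, 1000)
  n_hits <- sum(vapply(seqs, function(s) nrow(scan_sequence(s, mo)), numeric(1)))
  n_windows <- 200 * (1000 - 10 + 1) * 2
  # discreteness makes the true rate <= 1e-4; allow a generous binomial band
  expect_lt(n_hits, qbinom(0.9999, n_windows, 1e-4))
  expect_gt(n_hits, qbinom(1e-4, n_windows, 0.4e-4))
})

test_that("promoter-level selection is monotone in alpha and in p", {
  sel <- fwer_select_targets(p_site = c(0.005, 0.5), m = c(1, 1),
                             n_promoters = 1, fwer_alpha = 0.01)
  expect_equal(sel$selected, c(TRUE, FALSE))
  set.seed(8)
  p_site <- runif(50, 0, 1e-4)
  m <- sample(500:2000, 50, TRUE)
  alphas <- c(0.05, 0.01, 0.002)
  sels <- lapply(alphas, function(a)
    fwer_select_targets(p_site, m, 200, a)$selected)
  expect_true(all(!sels[[2]] | sels[[1]]))   # smaller alpha never adds
  expect_true(all(!sels[[3]] | sels[[2]]))
  expect_error(fwer_select_targets(0.5, 10, 0), "positive")
})

test_that("top-k trimming equals sort-and-slice per TF", {
  set.seed(4)
  edges <- data.frame(tf = sample(c("T1", "T2", "T3"), 60, TRUE),
                      target = paste0("g", 1:60),
                      score = round(runif(60), 2),
                      p_promoter = runif(60))
  out <- trim_top_targets(edges, top_k = 5)
  for (tf in unique(edges$tf)) {
    e <- edges[edges$tf == tf, ]
    want <- e[order(-e$score, e$p_promoter, e$target), ][seq_len(min(5, nrow(e))), ]
    got <- out[out$tf == tf, ]
    expect_setequal(got$target, want$target)
    expect_lte(nrow(got), 5)
  }
  expect_equal(trim_top_targets(edges, 5000), edges)
})

test_that("build_reference_grn recovers a planted binding site", {
  set.seed(2)
  proms <- setNames(random_dna(30, 300), paste0("G", 1:30))
  mo <- random_motif(12, seed = 13)
  mo$mat <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 12), 12, 4, byrow = TRUE)
  substr(proms[5], 101, 112) <- strrep("A", 12)
  grn <- build_reference_grn(proms, list(mo), background = "uniform")
  expect_equal(grn$target, "G5")
  expect_lt(grn$p_promoter, 0.01 / 30)
})
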