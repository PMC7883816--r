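# Independent brute-force oracles used across the suite. Each re-derives the
# quantity from its definition, sharing no code with the implementation.

# kNN imputation by explicit search: for gene g missing at sample s, rank all
# donor genes by root-mean-square difference over mutually observed samples
# (>= min_shared shared, observed at s), average the k nearest donors at s.
oracle_knn_impute <- function(values, k, min_shared = 3) {
  out <- values
  for (g in seq_len(nrow(values))) {
    for (s in seq_len(ncol(values))) {
      if (!is.na(values[g, s])) next
      ds <- rep(Inf, nrow(values))
      for (d in seq_len(nrow(values))) {
        if (d == g || is.na(values[d, s])) next
        sh <- which(!is.na(values[g, ]) & !is.na(values[d, ]))
        if (length(sh) < min_shared) next
        ds[d] <- sqrt(mean((values[g, sh] - values[d, sh])^2))
      }
      donors <- order(ds)[seq_len(k)]
      donors <- donors[is.finite(ds[donors])]
      out[g, s] <- mean(values[donors, s])
    }
  }
  out
}

# Exact tail probabilities by enumerating all 4^w words.
oracle_pwm_tail <- function(int_mat, background = rep(0.25, 4)) {
  w <- nrow(int_mat)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(words, 1, function(wd) sum(int_mat[cbind(seq_len(w), wd)]))
  probs <- apply(words, 1, function(wd) prod(background[wd]))
  function(s) sum(probs[scores >= s])
}

# Proximal-gradient (FISTA) LASSO on standardized data, objective
# 1/(2n)||y - Xb||^2 + lambda ||b||_1.
oracle_lasso_fista <- function(X, y, lambda, iters = 20000) {
  n <- nrow(X); p <- ncol(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE, only.values = TRUE)$values)
  b <- numeric(p); z <- b; t_k <- 1
  soft <- function(u, a) sign(u) * pmax(abs(u) - a, 0)
  for (i in seq_len(iters)) {
    grad <- -crossprod(X, y - X %*% z) / n
    b_new <- soft(z - grad / L, lambda / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- b_new + (t_k - 1) / t_new * (b_new - b)
    b <- b_new; t_k <- t_new
  }
  drop(b)
}

lasso_objective <- function(X, y, b, lambda) {
  n <- nrow(X)
  sum((y - X %*% b)^2) / (2 * n) + lambda * sum(abs(b))
}

# Harrell concordance by explicit double loop.
oracle_concordance <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Textbook log-rank statistic: observed minus expected over event times.
oracle_logrank_chisq <- function(groups, time, event) {
  groups <- as.integer(factor(groups))
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t0 in tt) {
    at_risk <- time >= t0
    d <- sum(event == 1 & time == t0)
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == 1)
    d1 <- sum(event == 1 & time == t0 & groups == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Empirical ROC AUC for a binary outcome (ties counted half).
oracle_binary_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

revcomp_string <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

random_motif <- function(w, name = "M", sharp = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rgamma(w * 4, sharp), w, 4)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  list(tf_name = name, width = w, mat = m, background = rep(0.25, 4))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
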