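#' Scan configuration for reference-network construction
#'
#' @param site_p_threshold site-level p-value cutoff for reported hits.
#' @param fwer_alpha per-TF family-wise error level for target selection.
#' @param top_k maximum targets kept per TF after ranking by score.
#' @param pseudocount pseudocount (times background) added to motif
#'   frequencies before log-odds scoring.
#' @param step score discretization step in bits; p-values are computed on
#'   the floored score grid, so reported p-values are conservative.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(site_p_threshold = 1e-4, fwer_alpha = 0.01,
                        top_k = 5000, pseudocount = 0.1, step = 0.01) {
  stopifnot(site_p_threshold > 0, site_p_threshold < 1,
            fwer_alpha > 0, fwer_alpha < 1, top_k >= 1, step > 0)
  structure(list(site_p_threshold = site_p_threshold, fwer_alpha = fwer_alpha,
                 top_k = top_k, pseudocount = pseudocount, step = step),
            class = "scan_config")
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

encode_dna <- function(seq) {
  v <- DNA_CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  if (anyNA(v)) stop_dysreg("sequence contains characters outside A/C/G/T/N")
  unname(v)
}

#' Read motifs in MEME (minimal text) format
#'
#' One motif per `MOTIF` block; the background line is optional and defaults
#' to uniform. Each letter-probability row must have four columns summing to
#' approximately one.
#'
#' @param path MEME file path.
#' @return list of motifs; each a list with `tf_name`, `width`, `mat`
#'   (width x 4 probability matrix over A,C,G,T) and `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toks[c(TRUE, FALSE)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop_dysreg("no MOTIF blocks in ", path)
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]][2]
    lp <- starts[k] + grep("^letter-probability matrix",
                           lines[seq(starts[k], length(lines))])[1] - 1
    if (is.na(lp)) stop_dysreg("motif ", name, ": no letter-probability matrix")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp]))
    if (is.na(w) || w < 3) stop_dysreg("motif ", name, ": invalid width")
    rows <- matrix(0, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_len(w)) {
      ln <- lp + i
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals))
        stop_dysreg("motif ", name, ": malformed matrix row at line ", ln)
      if (abs(sum(vals) - 1) > 0.1)
        stop_dysreg("motif ", name, ": row does not sum to 1 at line ", ln)
      rows[i, ] <- vals / sum(vals)
    }
    motifs[[k]] <- list(tf_name = name, width = w, mat = rows, background = bg)
  }
  motifs
}

#' Log-odds scoring matrix for a motif
#'
#' `score[i, b] = log2((freq[i, b] + pseudocount * bg[b]) /
#' ((1 + pseudocount) * bg[b]))`, finite in every cell for positive
#' pseudocount or strictly positive frequencies.
#'
#' @param motif a motif from [read_meme()].
#' @param background length-4 background probabilities (A,C,G,T).
#' @param pseudocount pseudocount multiplier on the background.
#' @return width x 4 matrix of log2 odds (bits).
#' @export
log_odds_matrix <- function(motif, background = motif$background,
                            pseudocount = 0.1) {
  if (any(background <= 0)) stop_dysreg("background probabilities must be positive")
  background <- background / sum(background)
  num <- sweep(motif$mat, 2, pseudocount * background, `+`)
  log2(sweep(num, 2, (1 + pseudocount) * background, `/`))
}

# Integer (floored) score matrix on the step grid; scanning and the exact
# p-value DP share this discretization so p-values are exact at every
# observed score.
discretize_scores <- function(lom, step) {
  m <- matrix(as.integer(floor(lom / step)), nrow(lom), 4)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

# Reverse-complement scoring matrix: applying it to the forward strand
# scores the reverse strand.
revcomp_matrix <- function(m) m[rev(seq_len(nrow(m))), 4:1, drop = FALSE]

#' Exact tail probabilities of PWM scores under an i.i.d. background
#'
#' Dynamic programming over the discretized score grid: the exact
#' distribution of the total integer score of a random width-w word under
#' the 0-order background, and its upper-tail probabilities.
#'
#' @param int_mat width x 4 integer score matrix (see `step` in
#'   [scan_config()]).
#' @param background length-4 background probabilities.
#' @return list with `min_score`, `max_score` (integer totals) and `tail`,
#'   where `tail[s - min_score + 1] = P(score >= s)`.
#' @export
exact_score_pvalues <- function(int_mat, background = rep(0.25, 4)) {
  background <- background / sum(background)
  lo <- sum(apply(int_mat, 1, min))
  hi <- sum(apply(int_mat, 1, max))
  probs <- numeric(hi - lo + 1)
  # running distribution over totals, offset by running minimum
  run_lo <- 0L
  dist <- 1
  for (i in seq_len(nrow(int_mat))) {
    row <- int_mat[i, ]
    rlo <- min(row); rhi <- max(row)
    new <- numeric(length(dist) + rhi - rlo)
    for (b in 1:4) {
      off <- row[b] - rlo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    run_lo <- run_lo + rlo
  }
  probs[(run_lo - lo + 1):(run_lo - lo + length(dist))] <- dist
  tail <- rev(cumsum(rev(probs)))
  tail <- pmin(tail, 1)
  list(min_score = lo, max_score = hi, tail = tail)
}

# Upper-tail p-value of an integer score total under a DP table.
score_pvalue <- function(tab, s) {
  i <- s - tab$min_score + 1
  p <- rep(1, length(s))
  p[s > tab$max_score] <- 0
  ok <- s >= tab$min_score & s <= tab$max_score
  p[ok] <- tab$tail[i[ok]]
  p
}

#' Scan one sequence with a motif
#'
#' Both strands are scanned; windows containing N are skipped. Hits with
#' site p-value strictly below `cfg$site_p_threshold` are returned sorted by
#' increasing p-value.
#'
#' @param seq DNA string (A/C/G/T/N) or encoded integer vector.
#' @param motif motif from [read_meme()].
#' @param cfg a [scan_config()].
#' @param background background probabilities; defaults to the motif's.
#' @return data.frame with columns `tf`, `offset` (0-based on the forward
#'   strand), `strand`, `score` (bits, grid-floored), `p`.
#' @export
scan_sequence <- function(seq, motif, cfg = scan_config(),
                          background = motif$background) {
  if (is.character(seq)) seq <- encode_dna(seq)
  w <- motif$width
  empty <- data.frame(tf = character(), offset = integer(), strand = character(),
                      score = numeric(), p = numeric())
  if (length(seq) < w) {
    warning("sequence shorter than motif width: no windows scanned")
    return(empty)
  }
  lom <- log_odds_matrix(motif, background, cfg$pseudocount)
  im <- discretize_scores(lom, cfg$step)
  im_rc <- revcomp_matrix(im)
  tab_f <- exact_score_pvalues(im, background)
  tab_r <- exact_score_pvalues(im_rc, background)
  res <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") im else im_rc
    tab <- if (strand == "+") tab_f else tab_r
    sc <- pwm_window_scores_cpp(seq, matrix(as.numeric(m), w, 4))
    ok <- which(!is.na(sc))
    if (!length(ok)) next
    p <- score_pvalue(tab, as.integer(round(sc[ok])))
    keep <- p < cfg$site_p_threshold
    if (!any(keep)) next
    res[[strand]] <- data.frame(
      tf = motif$tf_name, offset = ok[keep] - 1L, strand = strand,
      score = sc[ok][keep] * cfg$step, p = p[keep])
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best hit per promoter for one motif: integer best score and valid window
# count m over both strands, vectorized over a promoter matrix
# (one encoded promoter per column).
best_hits_matrix <- function(seq_mat, motif, cfg, background) {
  lom <- log_odds_matrix(motif, background, cfg$pseudocount)
  im <- discretize_scores(lom, cfg$step)
  im_rc <- revcomp_matrix(im)
  bs <- pwm_best_scores_cpp(seq_mat,
                            matrix(as.numeric(im), motif$width, 4),
                            matrix(as.numeric(im_rc), motif$width, 4))
  tab_f <- exact_score_pvalues(im, background)
  tab_r <- exact_score_pvalues(im_rc, background)
  bf <- as.integer(round(bs[, 1]))
  br <- as.integer(round(bs[, 2]))
  m <- as.integer(bs[, 3])
  ok <- m > 0
  best <- rep(NA_integer_, length(m))
  p_site <- rep(NA_real_, length(m))
  best[ok] <- pmax(bf[ok], br[ok])
  # p of the single best window, each strand looked up in its own table
  p_site[ok] <- pmin(score_pvalue(tab_f, bf[ok]), score_pvalue(tab_r, br[ok]))
  list(best = best, m = m, p_site = p_site)
}

#' Promoter-level selection under per-TF family-wise error control
#'
#' Each promoter's best site p-value is corrected for its number of scanned
#' windows (both strands) by a Sidak step, `p_prom = 1 - (1 - p_site)^m`;
#' targets are selected when `p_prom < fwer_alpha / n_promoters` (Bonferroni
#' across promoters), which bounds the probability of at least one false
#' target per TF by `fwer_alpha` under the null.
#'
#' @param p_site best site p-value per promoter.
#' @param m scanned window count per promoter.
#' @param n_promoters number of promoters in the scanned set.
#' @param fwer_alpha family-wise error level.
#' @return list with logical `selected` and numeric `p_prom`.
#' @export
fwer_select_targets <- function(p_site, m, n_promoters, fwer_alpha = 0.01) {
  if (n_promoters <= 0) stop_dysreg("n_promoters must be positive")
  p_prom <- 1 - (1 - p_site)^m
  list(selected = !is.na(p_prom) & p_prom < fwer_alpha / n_promoters,
       p_prom = p_prom)
}

#' Trim a TF's target list to the top-k by score
#'
#' Targets are ranked by best site score descending; ties are broken by
#' promoter-level p-value ascending, then target id, so output is
#' deterministic.
#'
#' @param edges data.frame with columns `tf`, `target`, `score`, `p_promoter`.
#' @param top_k maximum targets per TF.
#' @return trimmed edge data.frame.
#' @export
trim_top_targets <- function(edges, top_k = 5000) {
  if (!nrow(edges)) return(edges)
  keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$tf), function(idx) {
    e <- edges[idx, ]
    ord <- order(-e$score, e$p_promoter, e$target)
    idx[ord][seq_len(min(top_k, length(idx)))]
  }), use.names = FALSE)
  out <- edges[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the reference regulatory network
#'
#' Scans every promoter with every motif, applies per-TF family-wise error
#' control over promoters, and trims each TF to its top-k targets by score.
#'
#' @param promoters named character vector of promoter sequences (or a
#'   pre-encoded integer matrix with rownames).
#' @param motifs list of motifs from [read_meme()].
#' @param cfg a [scan_config()].
#' @param background `"uniform"`, `"estimate"` (0-order fit to the promoter
#'   set), or a length-4 probability vector.
#' @return data.frame `tf, target, score, p_promoter` — the reference GRN.
#' @export
build_reference_grn <- function(promoters, motifs, cfg = scan_config(),
                                background = "estimate") {
  if (is.character(promoters)) {
    lens <- nchar(promoters)
    if (length(unique(lens)) > 1)
      stop_dysreg("promoters must have equal length for batch scanning")
    seq_mat <- vapply(promoters, encode_dna, integer(lens[1]))
  } else {
    seq_mat <- promoters              # length x promoters, encoded
  }
  if (identical(background, "uniform")) {
    bg <- rep(0.25, 4)
  } else if (identical(background, "estimate")) {
    counts <- tabulate(seq_mat[seq_mat > 0], nbins = 4)
    bg <- counts / sum(counts)
  } else {
    bg <- background / sum(background)
  }
  n_prom <- ncol(seq_mat)
  res <- lapply(motifs, function(mo) {
    bh <- best_hits_matrix(seq_mat, mo, cfg, bg)
    sel <- fwer_select_targets(bh$p_site, bh$m, n_prom, cfg$fwer_alpha)
    idx <- which(sel$selected)
    if (!length(idx)) return(NULL)
    data.frame(tf = mo$tf_name, target = colnames(seq_mat)[idx],
               score = bh$best[idx] * cfg$step,
               p_promoter = sel$p_prom[idx])
  })
  edges <- do.call(rbind, res)
  if (is.null(edges))
    edges <- data.frame(tf = character(), target = character(),
                        score = numeric(), p_promoter = numeric())
  trim_top_targets(edges, cfg$top_k)
}
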