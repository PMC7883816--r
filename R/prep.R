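#' Preprocessing configuration
#'
#' @param min_tpm TPM threshold below which values are treated as missing.
#' @param max_missing_frac a gene is removed when its missing fraction is
#'   strictly greater than this.
#' @param knn_k neighbour count for k-nearest-neighbour imputation.
#' @param already_log set TRUE for array data already in log space; skips the
#'   log2 transform.
#' @return list of class `prep_config`.
#' @export
prep_config <- function(min_tpm = 1, max_missing_frac = 0.2, knn_k = 10,
                        already_log = FALSE) {
  stopifnot(max_missing_frac > 0, max_missing_frac < 1, knn_k >= 1)
  structure(list(min_tpm = min_tpm, max_missing_frac = max_missing_frac,
                 knn_k = knn_k, already_log = already_log),
            class = "prep_config")
}

#' Mask low values and filter genes by missingness
#'
#' For RNA-seq abundances, values below `min_tpm` are treated as missing; a
#' gene is removed when its missing fraction strictly exceeds
#' `max_missing_frac` of the samples.
#'
#' @param values gene x sample numeric matrix of TPM.
#' @param cfg a [prep_config()].
#' @return list with `values` (missing entries as `NA`), `n_removed` and the
#'   removed gene ids.
#' @export
mask_and_filter <- function(values, cfg = prep_config()) {
  if (any(values < 0, na.rm = TRUE)) stop_dysreg("TPM values must be non-negative")
  values[values < cfg$min_tpm] <- NA_real_
  frac <- rowMeans(is.na(values))
  drop <- frac > cfg$max_missing_frac
  if (all(drop)) stop_dysreg("no genes survive filtering")
  list(values = values[!drop, , drop = FALSE],
       n_removed = sum(drop),
       removed = rownames(values)[drop])
}

#' k-nearest-neighbour imputation
#'
#' Each missing entry is replaced by the mean, over the k genes nearest to the
#' target gene, of that sample's values. Gene-gene distance is the root mean
#' squared difference over samples observed in both genes; donors sharing
#' fewer than `min_shared` observed samples with the target, or unobserved in
#' the sample being imputed, are skipped.
#'
#' @param values matrix with `NA` entries.
#' @param k neighbour count.
#' @param min_shared minimum mutually observed samples for a donor.
#' @return list with complete `values` and `n_imputed`.
#' @export
impute_knn <- function(values, k = 10, min_shared = 3) {
  if (k >= nrow(values)) stop_dysreg("k must be smaller than the number of genes")
  obs <- !is.na(values)
  if (any(rowSums(obs) == 0)) stop_dysreg("gene with zero observed values")
  n_imp <- 0L
  out <- values      # distances always computed on the pristine matrix
  need <- which(rowSums(!obs) > 0)
  for (g in need) {
    og <- obs[g, ]
    # mean squared difference over mutually observed samples
    shared <- drop(obs %*% og)
    diffs2 <- sweep(values, 2, values[g, ])^2   # NA where either gene missing
    d2 <- rowMeans(diffs2, na.rm = TRUE)
    d2[g] <- Inf
    d2[shared < min_shared] <- Inf
    d2[!is.finite(d2)] <- Inf
    for (s in which(!og)) {
      cand <- d2
      cand[!obs[, s]] <- Inf
      donors <- order(cand)[seq_len(k)]
      donors <- donors[is.finite(cand[donors])]
      if (!length(donors))
        stop_dysreg("no usable donors for gene ", rownames(values)[g],
                    " in sample ", colnames(values)[s])
      out[g, s] <- mean(values[donors, s])
      n_imp <- n_imp + 1L
    }
  }
  list(values = out, n_imputed = n_imp)
}

#' Log2-transform an expression table
#'
#' Assumes masking has already removed sub-threshold values, so all entries
#' are >= 1 for TPM data and the transform is safe without a pseudocount.
#'
#' @param values complete numeric matrix with positive entries.
#' @return matrix of log2 values.
#' @export
log2_transform <- function(values) {
  if (any(is.na(values))) stop_dysreg("log2_transform requires a complete matrix")
  if (any(values <= 0)) stop_dysreg("non-positive value: log2 undefined")
  log2(values)
}

#' Collapse microarray probes to gene level
#'
#' Probes mapping to more than one gene are removed. When several probes map
#' to the same gene, the probe with the highest mean across samples is
#' retained (ties broken by lexicographic probe id).
#'
#' @param values probe x sample matrix.
#' @param probe_map named list: probe id -> character vector of gene symbols.
#' @return gene x sample matrix.
#' @export
collapse_probes <- function(values, probe_map) {
  if (!length(probe_map)) stop_dysreg("empty probe map")
  if (any(vapply(probe_map, length, 1L) == 0)) stop_dysreg("probe with empty gene set")
  keep <- names(probe_map)[vapply(probe_map, length, 1L) == 1]
  keep <- intersect(keep, rownames(values))
  if (!length(keep)) stop_dysreg("no single-gene probes present in the matrix")
  gene <- unname(vapply(probe_map[keep], `[`, "", 1))
  v <- values[keep, , drop = FALSE]
  pm <- rowMeans(v)
  ord <- order(gene, -pm, keep)         # per gene: highest mean first, then id
  v <- v[ord, , drop = FALSE]
  gene <- gene[ord]
  sel <- !duplicated(gene)
  out <- v[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out
}

#' Quantile normalization across samples
#'
#' Every column is mapped onto the across-sample mean of order statistics, so
#' all columns share identical sorted values while each column's rank order
#' is preserved. Ties are resolved by first occurrence, which makes the
#' operation exactly idempotent.
#'
#' @param m complete gene x sample matrix.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  if (any(is.na(m))) stop_dysreg("quantile_normalize requires a complete matrix")
  if (ncol(m) < 2) {
    warning("single sample: quantile normalization skipped")
    return(m)
  }
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) target[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(m)
  out
}

#' Full RNA-seq / microarray preprocessing
#'
#' Runs the standard chain: (RNA-seq) mask sub-threshold TPM, drop
#' high-missingness genes, kNN-impute, log2; (microarray) collapse probes,
#' impute, optional log2, quantile-normalize.
#'
#' @param values raw feature x sample matrix.
#' @param platform `"rnaseq_tpm"` or `"microarray"`.
#' @param cfg a [prep_config()].
#' @param probe_map probe map for microarray input.
#' @return list with `values` (clean log2 matrix) and a `report` list
#'   (genes dropped, entries imputed).
#' @export
preprocess_expression <- function(values, platform = c("rnaseq_tpm", "microarray"),
                                  cfg = prep_config(), probe_map = NULL) {
  platform <- match.arg(platform)
  report <- list(genes_dropped = 0L, entries_imputed = 0L)
  if (platform == "rnaseq_tpm") {
    mf <- mask_and_filter(values, cfg)
    report$genes_dropped <- mf$n_removed
    im <- impute_knn(mf$values, k = min(cfg$knn_k, nrow(mf$values) - 1L))
    report$entries_imputed <- im$n_imputed
    out <- log2_transform(im$values)
  } else {
    if (!is.null(probe_map)) values <- collapse_probes(values, probe_map)
    if (anyNA(values)) {
      im <- impute_knn(values, k = min(cfg$knn_k, nrow(values) - 1L))
      report$entries_imputed <- im$n_imputed
      values <- im$values
    }
    if (!cfg$already_log) values <- log2_transform(values)
    out <- quantile_normalize(values)
  }
  list(values = out, report = report)
}
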