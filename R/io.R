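#' Read an expression matrix from TSV
#'
#' The expected layout is the one every stage of the pipeline exchanges:
#' feature identifiers in the first column, sample identifiers in the header,
#' tab-separated numeric values.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, rows = features, columns = samples.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop_dysreg("duplicate feature ids in ", path)
  m
}

#' Write an expression matrix to TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_col name of the identifier column (first column).
#' @export
write_expression_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample condition labels (and optional tumor-normal pairing)
#'
#' Two-column TSV `sample  condition`, optional third column `pair` giving,
#' for a tumor sample, the id of its matched normal.
#'
#' @param path path to the labels TSV.
#' @return data.frame with columns `sample`, `condition` and optionally `pair`.
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop_dysreg("labels file must have columns 'sample' and 'condition'")
  if (anyDuplicated(df$sample)) stop_dysreg("duplicate sample ids in labels")
  bad <- setdiff(unique(df$condition), c("normal", "tumor"))
  if (length(bad)) stop_dysreg("unknown condition labels: ", paste(bad, collapse = ", "))
  df
}

#' Read a clinical table
#'
#' Schema: `sample os_time os_event rfs_time rfs_event age gender stage adjc adjc_type`;
#' the RFS and adjuvant-chemotherapy columns are optional.
#'
#' @param path path to the clinical TSV.
#' @return data.frame, one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "os_time", "os_event", "age", "gender", "stage")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_dysreg("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$os_time <= 0)) stop_dysreg("survival times must be positive")
  if (!all(df$os_event %in% c(0, 1))) stop_dysreg("os_event must be 0/1")
  df
}

#' Read/write a TF-target edge list
#'
#' The reference-network format exchanged between stages:
#' `tf  target  score  p_promoter`.
#'
#' @param path TSV path.
#' @return data.frame with columns `tf`, `target`, `score`, `p_promoter`.
#' @export
read_grn_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(df)))
    stop_dysreg("edge list must have columns 'tf' and 'target'")
  df
}

#' @rdname read_grn_tsv
#' @param grn data.frame of edges.
#' @export
write_grn_tsv <- function(grn, path) {
  write.table(grn, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set (GMT) file
#'
#' @param path GMT path: set name, description, then member genes, tab-separated.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_dysreg("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Read promoter sequences from FASTA
#'
#' Headers are taken as gene symbols (first whitespace-separated token).
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_dysreg("no FASTA headers found in ", path)
  idx <- cumsum(hdr)
  names_v <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  seqs <- toupper(seqs)
  names(seqs) <- names_v
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_dysreg("non-ACGTN characters in promoter(s): ",
                paste(head(names_v[bad], 3), collapse = ", "))
  seqs
}
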