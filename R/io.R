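# Readers and writers for the pipeline's plain-text formats. All TSV output
# uses "." as decimal separator and Unix newlines (readr defaults), so
# identical inputs yield byte-identical files.

#' Read / write a count matrix as TSV
#'
#' Genes-by-samples integer counts; first column `gene_id`, one column per
#' sample.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @return `read_counts_tsv()` returns the count tibble; the writer returns
#'   `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  counts_matrix(out) # validate
  out
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  counts_matrix(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read / write a count matrix as Matrix Market (MTX) plus index files
#'
#' Writes `<stem>.mtx` with the sparse counts, `<stem>.rows.txt` (gene ids)
#' and `<stem>.cols.txt` (sample ids), the triplet convention used for
#' expression matrices.
#'
#' @param stem Path stem (without extension).
#' @param counts Count tibble.
#' @return `read_counts_mtx()` returns the count tibble; the writer returns
#'   `stem` invisibly.
#' @export
write_counts_mtx <- function(counts, stem) {
  mat <- counts_matrix(counts)
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), paste0(stem, ".mtx"))
  writeLines(rownames(mat), paste0(stem, ".rows.txt"))
  writeLines(colnames(mat), paste0(stem, ".cols.txt"))
  invisible(stem)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(stem) {
  mat <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  genes <- readLines(paste0(stem, ".rows.txt"))
  smp <- readLines(paste0(stem, ".cols.txt"))
  dimnames(mat) <- list(genes, smp)
  dplyr::bind_cols(tibble(gene_id = genes),
                   as_tibble(mat, .name_repair = "minimal"))
}

#' Read / write a DE table as TSV
#'
#' Columns `gene_id`, `base_mean`, `log2_fold_change`, `p_value`, `adj_p`
#' (extra columns are preserved on write, ignored on read).
#'
#' @param de A DE tibble; `path` a file path.
#' @param path File path.
#' @return The reader returns a `vasc_de` tibble; the writer returns `path`
#'   invisibly.
#' @export
write_de_tsv <- function(de, path) {
  need <- c("gene_id", "base_mean", "log2_fold_change", "p_value", "adj_p")
  if (!all(need %in% names(de))) {
    abort(paste0("DE table must have columns ", paste(need, collapse = ", "), "."))
  }
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  new_vasc_tbl(readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_guess()),
    progress = FALSE), "vasc_de")
}

#' Read / write a ranked gene list (RNK)
#'
#' Two-column headerless TSV (gene, metric), the interchange format of
#' preranked enrichment tools.
#'
#' @param ranking A `vasc_ranking` tibble.
#' @param path File path.
#' @return The reader returns a `vasc_ranking` tibble (re-sorted with the
#'   package tie rule); the writer returns `path` invisibly.
#' @export
write_rnk <- function(ranking, path) {
  rk <- check_ranking(ranking)
  readr::write_tsv(rk, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  rk <- readr::read_tsv(path, col_names = c("gene_id", "metric"),
                        col_types = "cd", progress = FALSE)
  new_vasc_tbl(check_ranking(rk), "vasc_ranking")
}

#' Read a qPCR CT table from CSV
#'
#' Expected columns: `sample_id`, `group`, `gene`, `ct`, `reference_ct`
#' (extra columns pass through).
#'
#' @param path File path.
#' @return A CT tibble suitable for [delta_delta_ct()].
#' @export
read_ct_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character(),
    gene = readr::col_character(), ct = readr::col_double(),
    reference_ct = readr::col_double(), .default = readr::col_guess()),
    progress = FALSE)
}
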