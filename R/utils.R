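# Internal helpers shared across modules.

# Deterministic sub-stream seed derivation: every stochastic stage draws from
# its own seed derived from (global seed, stage label), so adding a stage never
# perturbs another stage's stream. Result always in [1, 2^31 - 2].
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  m <- 2147483587 # large prime below 2^31
  val <- (((abs(seed) %% m) * 48271) %% m + (h * 7919) %% m) %% m
  as.integer(val) + 1L
}

# Validate a counts tibble: first column gene_id, remaining columns numeric
# non-negative counts. Returns the numeric matrix with gene_id rownames.
counts_matrix <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2L) {
    abort("`counts` must be a data frame with a gene_id column and >=1 sample column.")
  }
  if (names(counts)[1] != "gene_id") {
    abort("first column of `counts` must be named 'gene_id'.")
  }
  if (anyDuplicated(counts$gene_id)) abort("gene_id values must be unique.")
  mat <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort("sample columns of `counts` must be numeric.")
  if (anyDuplicated(colnames(mat))) abort("sample ids must be unique.")
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort("counts must be finite and non-negative.")
  }
  rownames(mat) <- counts$gene_id
  mat
}

# Match sample annotation to count matrix columns; returns the condition
# vector aligned with colnames(mat).
sample_conditions <- function(mat, samples) {
  if (!all(c("sample_id", "condition") %in% names(samples))) {
    abort("`samples` must have columns sample_id and condition.")
  }
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples missing a condition label: ",
                 paste(colnames(mat)[is.na(idx)], collapse = ", ")))
  }
  as.character(samples$condition[idx])
}

new_vasc_tbl <- function(x, class) {
  structure(as_tibble(x), class = c(class, class(as_tibble(x))))
}
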