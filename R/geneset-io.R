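#' Parse a GMT-format gene set collection
#'
#' GMT is the tab-separated carrier used by MSigDB: one set per line, fields
#' are set name, description, then one or more gene symbols.
#'
#' @param text GMT content: a single string (possibly with embedded newlines)
#'   or a character vector of lines.
#' @param collection Provenance tag attached to every parsed set (e.g.
#'   `"Curated"`, `"GO"`).
#'
#' @return A gene set catalog: a tibble with columns `set_name`,
#'   `description`, `collection` and a list-column `genes` of character
#'   vectors. Duplicate symbols within a line are dropped, keeping the first
#'   occurrence.
#'
#' @examples
#' parse_gmt("S1\tdesc\tA\tB\tC")
#' @export
parse_gmt <- function(text, collection = NA_character_) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_vasc_tbl(tibble(set_name = character(), description = character(),
                               collection = character(), genes = list()),
                        "vasc_catalog"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed GMT line %d: expected >=3 tab-separated fields, got %d",
                  line_no[bad[1]], lengths(fields)[bad[1]]))
  }
  set_name <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_name)) {
    abort(paste0("duplicate set name(s) in GMT input: ",
                 paste(unique(set_name[duplicated(set_name)]), collapse = ", ")))
  }
  if (any(!nzchar(set_name))) abort("empty set name in GMT input.")
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    unique(g)
  })
  empty <- which(lengths(genes) == 0L)
  if (length(empty) > 0L) {
    abort(sprintf("GMT line %d has no non-empty gene symbols", line_no[empty[1]]))
  }
  cat <- tibble(
    set_name = set_name,
    description = vapply(fields, `[[`, character(1), 2L),
    collection = collection,
    genes = genes
  )
  new_vasc_tbl(cat, "vasc_catalog")
}

#' Read a gene set catalog from a GMT file
#'
#' @param path Path to a GMT file.
#' @inheritParams parse_gmt
#' @return A gene set catalog tibble (see [parse_gmt()]).
#' @export
read_gmt <- function(path, collection = NA_character_) {
  parse_gmt(readLines(path, warn = FALSE), collection = collection)
}

#' Write a gene set catalog to a GMT file
#'
#' @param catalog A gene set catalog tibble as returned by [parse_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  assert_catalog(catalog)
  desc <- catalog$description
  desc[is.na(desc)] <- ""
  lines <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(c(catalog$set_name[i], desc[i], catalog$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

assert_catalog <- function(catalog) {
  need <- c("set_name", "genes")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog))) {
    abort("`catalog` must be a tibble with columns set_name and genes (list-column).")
  }
  if (anyDuplicated(catalog$set_name)) abort("catalog set names must be unique.")
  invisible(catalog)
}

# Canonical form for term matching: case-folded, "_" and " " runs collapse to
# a single space (MSigDB names use underscores, free text uses spaces).
norm_term <- function(x) {
  x <- stringr::str_replace_all(x, "[ _]+", " ")
  stringr::str_to_lower(trimws(x))
}

#' Select gene sets matching a term
#'
#' Retains sets whose name or description contains `term`, case-insensitively
#' and treating underscores and spaces as the same separator — so the term
#' `"smooth muscle"` matches `GO_SMOOTH_MUSCLE_CONTRACTION`.
#'
#' @param catalog A gene set catalog tibble.
#' @param term Non-empty search term.
#' @return The filtered catalog (possibly empty).
#' @export
select_by_term <- function(catalog, term) {
  assert_catalog(catalog)
  if (!is.character(term) || length(term) != 1L || !nzchar(trimws(term))) {
    abort("`term` must be a non-empty string.")
  }
  t <- norm_term(term)
  desc <- if ("description" %in% names(catalog)) catalog$description else
    rep(NA_character_, nrow(catalog))
  hit <- stringr::str_detect(norm_term(catalog$set_name), stringr::fixed(t)) |
    (!is.na(desc) & stringr::str_detect(norm_term(desc), stringr::fixed(t)))
  dplyr::filter(catalog, hit)
}

#' Filter gene sets by size
#'
#' Retains sets whose effective size lies in `[min_size, max_size]` (both
#' bounds inclusive). When a measured-gene `universe` is supplied and
#' `size_on_universe` is `TRUE` (the default, matching enrichment-tool
#' convention), the effective size is the number of set genes present in the
#' universe; otherwise the raw set size is used.
#'
#' @param catalog A gene set catalog tibble.
#' @param min_size,max_size Inclusive size bounds, `1 <= min_size <= max_size`.
#' @param universe Optional character vector of measured gene identifiers.
#' @param size_on_universe Compute sizes after intersection with `universe`?
#' @return The filtered catalog.
#' @export
filter_by_size <- function(catalog, min_size, max_size, universe = NULL,
                           size_on_universe = TRUE) {
  assert_catalog(catalog)
  if (!is.numeric(min_size) || !is.numeric(max_size) ||
      min_size < 1 || min_size > max_size) {
    abort("need 1 <= min_size <= max_size.")
  }
  eff <- if (!is.null(universe) && size_on_universe) {
    vapply(catalog$genes, function(g) sum(g %in% universe), integer(1))
  } else {
    lengths(catalog$genes)
  }
  dplyr::filter(catalog, eff >= min_size & eff <= max_size)
}

#' Read an ortholog symbol map
#'
#' Two-column TSV of (source_symbol, target_symbol) pairs, one pair per line;
#' a symbol may map to several targets. Such tables are typically exported
#' from Ensembl Biomart homology data.
#'
#' @param path Path to the TSV file.
#' @param col_names `TRUE` if the file carries a header row (its names are
#'   ignored), `FALSE` (default) for a bare two-column file.
#' @return A tibble with columns `source` and `target`.
#' @export
read_ortholog_map <- function(path, col_names = FALSE) {
  raw <- readr::read_tsv(path, col_names = c("source", "target"),
                         col_types = readr::cols(.default = readr::col_character()),
                         skip = if (isTRUE(col_names)) 1L else 0L,
                         progress = FALSE)
  validate_ortholog_map(raw)
}

validate_ortholog_map <- function(map) {
  if (!is.data.frame(map) || !all(c("source", "target") %in% names(map))) {
    abort("ortholog map must have columns source and target.")
  }
  if (any(is.na(map$source)) || any(is.na(map$target)) ||
      any(!nzchar(map$source)) || any(!nzchar(map$target))) {
    abort("ortholog map contains empty source or target symbols.")
  }
  as_tibble(map[c("source", "target")])
}

#' Map gene sets across species via an ortholog table
#'
#' Replaces every source symbol by all of its target symbols (one-to-many
#' expansion). Symbols absent from the map are dropped (the tally is reported
#' via a message and the `dropped_symbols` attribute); sets emptied by the
#' mapping are removed.
#'
#' @param catalog A gene set catalog tibble.
#' @param map An ortholog map tibble with columns `source` and `target`
#'   (see [read_ortholog_map()]).
#' @return The mapped catalog; attribute `dropped_symbols` holds the unmapped
#'   symbols per set.
#' @export
map_orthologs <- function(catalog, map) {
  assert_catalog(catalog)
  map <- validate_ortholog_map(map)
  mapped <- lapply(catalog$genes, function(g) {
    hit <- map[map$source %in% g, , drop = FALSE]
    hit <- hit[order(match(hit$source, g)), , drop = FALSE]
    list(genes = unique(hit$target), dropped = setdiff(g, map$source))
  })
  out <- catalog
  out$genes <- lapply(mapped, `[[`, "genes")
  dropped <- lapply(mapped, `[[`, "dropped")
  names(dropped) <- catalog$set_name
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0L) {
    inform(sprintf("map_orthologs: dropped %d unmapped symbol occurrence(s) across %d set(s).",
                   n_drop, sum(lengths(dropped) > 0L)))
  }
  empty <- lengths(out$genes) == 0L
  if (any(empty)) {
    inform(paste0("map_orthologs: removed set(s) emptied by mapping: ",
                  paste(out$set_name[empty], collapse = ", ")))
    out <- dplyr::filter(out, !empty)
  }
  attr(out, "dropped_symbols") <- dropped
  out
}
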