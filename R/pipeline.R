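#' Run the full vascular-injury analysis pipeline
#'
#' Orchestrates the stages end-to-end: obtain counts (from files or the
#' built-in simulator), normalize, run the two-group NB Wald test for each
#' timepoint against the reference condition, score pathways on the
#' size-filtered catalog with decile calls, build the signed -log10(p)
#' ranking, run preranked enrichment, apply the any-timepoint FDR display
#' filter, and write heatmap matrices — all as TSV artifacts plus a JSON run
#' manifest capturing every parameter, seed and input digest. Reruns with an
#' identical config produce byte-identical artifacts.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognized fields (all have defaults unless said otherwise):
#'   \describe{
#'     \item{simulation}{List of [sim_config()] arguments for a
#'       self-contained run. Either this or `counts_tsv` + `samples_tsv`
#'       must be given.}
#'     \item{counts_tsv, samples_tsv}{Paths to a count matrix and a sample
#'       annotation table (columns `sample_id`, `condition`).}
#'     \item{gmt}{Path to a GMT catalog; defaults to the simulated catalog
#'       in simulation runs.}
#'     \item{ortholog_map}{Optional path to a two-column ortholog TSV; the
#'       catalog is mapped through it before filtering.}
#'     \item{term}{Optional term to select sets by ([select_by_term()]).}
#'     \item{reference}{Reference condition label (default `"baseline"`).}
#'     \item{contrasts}{Timepoints to test against the reference (default:
#'       every non-reference condition, in annotation order).}
#'     \item{min_size, max_size}{Pathway size filter bounds (default 20, 80),
#'       applied on the measured-gene universe.}
#'     \item{fraction}{Decile fraction for calls (default 0.10).}
#'     \item{sd_type}{`"sample"` or `"population"` (default `"sample"`).}
#'     \item{weight_exponent, n_perm, q_max, p_floor}{Enrichment parameters
#'       (defaults 1, 1000, 0.05, 1e-300).}
#'     \item{seed}{Global seed (default 1); all stage randomness derives
#'       from it through named sub-streams.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- list()
  if (!is.null(cfg$simulation)) {
    sim <- simulate_counts(do.call(sim_config, cfg$simulation))
    counts <- sim$counts; samples <- sim$samples
    catalog <- if (is.null(cfg$gmt)) sim$catalog else read_gmt(cfg$gmt)
    readr::write_tsv(sim$truth_genes, file.path(out_dir, "truth_genes.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$truth_sets, file.path(out_dir, "truth_sets.tsv"),
                     progress = FALSE)
  } else {
    counts <- read_counts_tsv(cfg$counts_tsv)
    samples <- readr::read_tsv(cfg$samples_tsv, col_types = "cc", progress = FALSE)
    catalog <- read_gmt(cfg$gmt)
    inputs <- list(counts_tsv = unname(tools::md5sum(cfg$counts_tsv)),
                   samples_tsv = unname(tools::md5sum(cfg$samples_tsv)),
                   gmt = unname(tools::md5sum(cfg$gmt)))
  }
  write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(samples, file.path(out_dir, "samples.tsv"), progress = FALSE)

  if (!is.null(cfg$ortholog_map)) {
    catalog <- map_orthologs(catalog, read_ortholog_map(cfg$ortholog_map))
    inputs$ortholog_map <- unname(tools::md5sum(cfg$ortholog_map))
  }
  if (!is.null(cfg$term)) catalog <- select_by_term(catalog, cfg$term)
  catalog <- filter_by_size(catalog, cfg$min_size, cfg$max_size,
                            universe = counts$gene_id)
  if (nrow(catalog) == 0L) abort("stage catalog: no gene set survives the size filter.")
  write_gmt(catalog, file.path(out_dir, "catalog.gmt"))

  conds <- unique(samples$condition)
  if (!cfg$reference %in% conds) {
    abort(sprintf("stage de: reference condition '%s' not among sample conditions.",
                  cfg$reference))
  }
  contrasts <- cfg$contrasts %||% setdiff(conds, cfg$reference)
  if (!all(contrasts %in% conds)) {
    abort("stage de: contrast label(s) missing from sample conditions.")
  }

  sf <- estimate_size_factors(counts)
  scored <- list(); gsea <- list(); de_list <- list()
  for (tp in contrasts) {
    de <- test_two_group(counts, samples, reference = cfg$reference,
                         treated = tp, size_factors = sf)
    write_de_tsv(de, file.path(out_dir, sprintf("de_%s.tsv", tp)))
    de_list[[tp]] <- de

    sc <- rank_and_call(score_pathways(de, catalog, sd_type = cfg$sd_type),
                        fraction = cfg$fraction)
    readr::write_tsv(sc, file.path(out_dir, sprintf("pathway_scores_%s.tsv", tp)),
                     progress = FALSE)
    scored[[tp]] <- sc

    rk <- rank_metric(de, p_floor = cfg$p_floor)
    write_rnk(rk, file.path(out_dir, sprintf("ranking_%s.rnk", tp)))

    gs <- gsea_preranked(rk, catalog, n_perm = cfg$n_perm,
                         weight_exponent = cfg$weight_exponent,
                         seed = sub_seed(cfg$seed, paste0("gsea-", tp)))
    readr::write_tsv(gs, file.path(out_dir, sprintf("gsea_%s.tsv", tp)),
                     progress = FALSE)
    gsea[[tp]] <- gs
  }

  gsea_all <- dplyr::bind_rows(purrr::imap(gsea, ~ dplyr::mutate(as_tibble(.x),
                                                                 timepoint = .y)))
  display <- filter_significant(gsea_all, q_max = cfg$q_max)
  readr::write_tsv(display, file.path(out_dir, "gsea_display.tsv"),
                   progress = FALSE)
  for (v in c("score", "mean_lfc")) {
    hm <- build_heatmap_matrix(scored, value = v)
    readr::write_tsv(hm, file.path(out_dir, sprintf("heatmap_%s.tsv", v)),
                     progress = FALSE)
  }

  manifest <- list(
    package = "vascpath",
    version = as.character(utils::packageVersion("vascpath")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "simulation")],
    simulation = cfg$simulation,
    input_md5 = inputs,
    artifacts = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(list(de = de_list, scores = scored, gsea = gsea,
                 display = display, manifest = manifest))
}

validate_pipeline_config <- function(config) {
  defaults <- list(
    simulation = NULL, counts_tsv = NULL, samples_tsv = NULL, gmt = NULL,
    ortholog_map = NULL, term = NULL, reference = "baseline", contrasts = NULL,
    min_size = 20, max_size = 80, fraction = 0.10, sd_type = "sample",
    weight_exponent = 1, n_perm = 1000, q_max = 0.05, p_floor = 1e-300,
    seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$simulation)) {
    for (f in c("counts_tsv", "samples_tsv", "gmt")) {
      if (is.null(cfg[[f]])) {
        abort(sprintf("config error: need `%s` when no simulation block is given.", f))
      }
      if (!file.exists(cfg[[f]])) {
        abort(sprintf("config error: %s path does not exist: %s", f, cfg[[f]]))
      }
    }
  }
  if (!is.null(cfg$ortholog_map) && !file.exists(cfg$ortholog_map)) {
    abort(sprintf("config error: ortholog_map path does not exist: %s",
                  cfg$ortholog_map))
  }
  if (!cfg$sd_type %in% c("sample", "population")) {
    abort("config error: sd_type must be 'sample' or 'population'.")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
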