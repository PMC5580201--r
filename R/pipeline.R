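#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic dataset first) or
#'   `"analysis"` (read the four input files).
#' @param out_dir Directory for all outputs.
#' @param intensities,snp_map,genes,groups Input paths (analysis mode).
#' @param scan A [scan_config()].
#' @param synthetic A [synthetic_spec()] (simulate mode).
#' @param seed Integer seed; in simulate mode it overrides the synthetic
#'   spec's seed so the whole run is a pure function of (inputs, config).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "analysis"), out_dir,
                            intensities = NULL, snp_map = NULL, genes = NULL,
                            groups = NULL, scan = scan_config(),
                            synthetic = synthetic_spec(), seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, intensities = intensities,
              snp_map = snp_map, genes = genes, groups = groups,
              scan = scan, synthetic = synthetic, seed = as.integer(seed))
  if (mode == "analysis") {
    for (field in c("intensities", "snp_map", "genes", "groups")) {
      p <- cfg[[field]]
      if (is.null(p) || !file.exists(p))
        stop(sprintf("config error: %s file missing (%s)", field,
                     if (is.null(p)) "not set" else p), call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full intensity-scan pipeline
#'
#' Stages: simulate (or load), normalize, scan, pca, report. Writes
#' `results.tsv` (per-gene scan results), `scores.tsv` (PCA scores of the
#' significant-gene feature matrix, or of all eligible genes when nothing
#' is significant), `skipped.tsv` (degenerate genes with reasons) and
#' `manifest.json` (seed, config hash, per-stage timings) under
#' `config$out_dir`. Identical config and seed give identical result files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `results`, `scores`, `manifest` and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  data <- clock("simulate", {
    if (config$mode == "simulate") {
      spec <- config$synthetic
      spec$seed <- config$seed
      generate_dataset(spec)
    } else {
      raw <- read_intensity_table(config$intensities)
      list(raw = raw,
           snp_map = read_snp_map(config$snp_map),
           genes = read_gene_table(config$genes),
           groups = validate_groups(read_group_table(config$groups),
                                    samples = raw$samples),
           truth = NULL)
    }
  })

  norm <- clock("normalize", normalize_intensities(data$raw))

  results <- clock("scan", {
    index <- build_gene_snp_index(data$snp_map, data$genes)
    scan_genome(norm, index, data$groups, config$scan)
  })

  pca <- clock("pca", {
    index <- build_gene_snp_index(data$snp_map, data$genes)
    eligible <- select_eligible_genes(index, config$scan)
    selection <- results$gene_id[results$bh_significant]
    if (length(selection) == 0L) selection <- results$gene_id
    if (length(selection) == 0L) {
      NULL
    } else {
      fm <- gene_feature_matrix(norm, eligible, selection)
      principal_components(
        fm, d = min(nrow(fm), ncol(fm), 5L),
        case_samples = data$groups$sample_id[data$groups$group == "case"])
    }
  })

  manifest <- clock("report", {
    paths <- list(results = file.path(config$out_dir, "results.tsv"),
                  scores = file.path(config$out_dir, "scores.tsv"),
                  skipped = file.path(config$out_dir, "skipped.tsv"),
                  manifest = file.path(config$out_dir, "manifest.json"))
    if (nrow(results) > 0L) write_scan_results(results, paths$results)
    if (!is.null(pca)) {
      sc <- data.frame(sample_id = rownames(pca$scores),
                       round(pca$scores, 10), check.names = FALSE)
      write_tsv_plain(sc, paths$scores)
    }
    write_tsv_plain(attr(results, "skipped"), paths$skipped)
    paths
  })

  man <- list(seed = config$seed, mode = config$mode,
              config_hash = config_hash(config),
              n_genes_tested = nrow(results),
              n_significant = sum(results$bh_significant),
              stages = names(timings), timings_sec = timings)
  jsonlite::write_json(man, manifest$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, pca = pca, manifest = man,
                 paths = manifest))
}

# Deterministic hash of the analysis-relevant configuration: md5 of the
# deparsed config with output locations excluded, so two runs of the same
# analysis into different directories share a hash.
#' @noRd
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}
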