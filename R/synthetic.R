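#' Specification for a synthetic two-group intensity dataset
#'
#' Defaults emulate the study design the package targets: a 6-vs-6
#' two-group comparison on a biallelic genotyping array, with genes carrying
#' enough SNPs to straddle the 15-SNP eligibility threshold, and per-gene
#' effects planted on the case group as a log2 mean shift and/or an
#' inflation of the residual noise standard deviation.
#'
#' @param n_case,n_control Samples per group (each >= 2; defaults 6 and 6).
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param n_genes Number of genes.
#' @param snps_per_gene_range Integer pair (min, max): SNPs per gene, drawn
#'   uniformly. Default c(10, 20) straddles the 15-SNP eligibility cut.
#' @param intergenic_snps_per_gene SNPs placed between consecutive genes.
#' @param baseline_log_mean Mean per-SNP baseline level, log2 fluorescence
#'   units (default 10, i.e. a total intensity around 1024 units).
#' @param snp_level_sd Across-SNP spread of the per-SNP baseline level,
#'   log2 units (default 0.5).
#' @param sample_noise_sd Residual per-cell noise sd, log2 units.
#' @param effect_gene_fraction Fraction of genes carrying a planted effect.
#' @param mean_shift_delta Log2 mean shift added to case samples at effect
#'   genes.
#' @param variance_inflation Multiplier (>= 1) on the case-group noise sd at
#'   effect genes.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_case = 6L, n_control = 6L, n_chromosomes = 5L,
                           n_genes = 100L, snps_per_gene_range = c(10L, 20L),
                           intergenic_snps_per_gene = 5L,
                           baseline_log_mean = 10, snp_level_sd = 0.5,
                           sample_noise_sd = 0.3, effect_gene_fraction = 0.1,
                           mean_shift_delta = 1.0, variance_inflation = 1.0,
                           seed = 1L) {
  spec <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
               n_chromosomes = as.integer(n_chromosomes),
               n_genes = as.integer(n_genes),
               snps_per_gene_range = as.integer(snps_per_gene_range),
               intergenic_snps_per_gene = as.integer(intergenic_snps_per_gene),
               baseline_log_mean = baseline_log_mean,
               snp_level_sd = snp_level_sd,
               sample_noise_sd = sample_noise_sd,
               effect_gene_fraction = effect_gene_fraction,
               mean_shift_delta = mean_shift_delta,
               variance_inflation = variance_inflation,
               seed = as.integer(seed))
  if (spec$n_case < 2L || spec$n_control < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  if (spec$n_chromosomes < 1L || spec$n_genes < 1L)
    stop("need at least one chromosome and one gene", call. = FALSE)
  if (length(spec$snps_per_gene_range) != 2L ||
      any(spec$snps_per_gene_range < 1L) ||
      spec$snps_per_gene_range[1L] > spec$snps_per_gene_range[2L])
    stop("snps_per_gene_range must be an increasing positive pair", call. = FALSE)
  if (spec$intergenic_snps_per_gene < 0L)
    stop("intergenic_snps_per_gene must be >= 0", call. = FALSE)
  if (spec$snp_level_sd < 0 || spec$sample_noise_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (spec$effect_gene_fraction < 0 || spec$effect_gene_fraction > 1)
    stop("effect_gene_fraction must lie in [0, 1]", call. = FALSE)
  if (spec$variance_inflation < 1)
    stop("variance_inflation must be >= 1", call. = FALSE)
  if (is.na(spec$seed)) stop("seed must be an integer", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-group raw-intensity dataset
#'
#' Per SNP `s` and sample `j` the total log2 intensity is
#' `t = baseline_s + e_js`, with `baseline_s ~ N(baseline_log_mean,
#' snp_level_sd^2)` drawn once per SNP and `e_js ~ N(0, sample_noise_sd^2)`.
#' If `s` lies in an effect gene and `j` is a case sample, `mean_shift_delta`
#' is added and the noise sd is multiplied by `variance_inflation`. The
#' emitted total `T = 2^t` is split into allele intensities `A = u * T`,
#' `B = (1 - u) * T` with `u ~ Uniform(0.05, 0.95)` per cell, so `A + B = T`
#' exactly and all intensities are strictly positive. Genes are laid out as
#' non-overlapping intervals with `intergenic_snps_per_gene` markers between
#' consecutive genes. One seed drives a single pseudo-random stream in a
#' fixed draw order, so equal seeds give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `raw` (`raw_intensity_set`), `snp_map`, `genes`,
#'   `groups` and `truth` (data.frame `gene_id`, `mean_shift`,
#'   `variance_inflation` for the planted effect genes).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  samples <- c(sprintf("case_%02d", seq_len(spec$n_case)),
               sprintf("ctrl_%02d", seq_len(spec$n_control)))
  groups <- data.frame(sample_id = samples,
                       group = rep(c("case", "control"),
                                   c(spec$n_case, spec$n_control)),
                       stringsAsFactors = FALSE)
  groups <- validate_groups(groups)

  # Gene layout: round-robin over chromosomes, non-overlapping intervals.
  gene_chrom_idx <- rep(seq_len(spec$n_chromosomes), length.out = spec$n_genes)
  n_snps_gene <- sample(seq(spec$snps_per_gene_range[1L],
                            spec$snps_per_gene_range[2L]),
                        spec$n_genes, replace = TRUE)
  spacing <- 100L        # bp between consecutive SNPs inside a gene
  gap <- 10000L          # bp between a gene and the next feature

  snp_id <- character(0); snp_chrom <- character(0); snp_pos <- integer(0)
  snp_gene <- character(0)  # "" for intergenic
  gene_rows <- vector("list", spec$n_genes)
  cursor <- rep(1L, spec$n_chromosomes)
  marker_counter <- 0L
  for (g in seq_len(spec$n_genes)) {
    ci <- gene_chrom_idx[g]
    chrom <- sprintf("chr%d", ci)
    gid <- sprintf("G%04d", g)
    start <- cursor[ci] + gap
    pos <- start + spacing * (seq_len(n_snps_gene[g]) - 1L)
    end <- pos[length(pos)] + spacing %/% 2L
    ids <- sprintf("SNP%06d", marker_counter + seq_along(pos))
    marker_counter <- marker_counter + length(pos)
    snp_id <- c(snp_id, ids); snp_chrom <- c(snp_chrom, rep(chrom, length(pos)))
    snp_pos <- c(snp_pos, pos); snp_gene <- c(snp_gene, rep(gid, length(pos)))
    if (spec$intergenic_snps_per_gene > 0L) {
      ipos <- end + gap %/% 2L + spacing * seq_len(spec$intergenic_snps_per_gene)
      iids <- sprintf("SNP%06d", marker_counter + seq_along(ipos))
      marker_counter <- marker_counter + length(ipos)
      snp_id <- c(snp_id, iids)
      snp_chrom <- c(snp_chrom, rep(chrom, length(ipos)))
      snp_pos <- c(snp_pos, ipos)
      snp_gene <- c(snp_gene, rep("", length(ipos)))
      cursor[ci] <- ipos[length(ipos)]
    } else {
      cursor[ci] <- end
    }
    gene_rows[[g]] <- data.frame(gene_id = gid, chrom = chrom,
                                 start = start, end = end,
                                 category = "RefSeq", stringsAsFactors = FALSE)
  }
  genes <- validate_gene_set(do.call(rbind, gene_rows))
  snp_map <- validate_snp_map(data.frame(marker_id = snp_id, chrom = snp_chrom,
                                         pos = snp_pos, stringsAsFactors = FALSE))

  # Planted effects.
  n_effect <- round(spec$effect_gene_fraction * spec$n_genes)
  effect_ids <- if (n_effect > 0L) sort(sample(genes$gene_id, n_effect)) else character(0)
  truth <- data.frame(gene_id = effect_ids,
                      mean_shift = rep(spec$mean_shift_delta, length(effect_ids)),
                      variance_inflation = rep(spec$variance_inflation,
                                               length(effect_ids)),
                      stringsAsFactors = FALSE)

  n_snp <- length(snp_id)
  n_samp <- nrow(groups)
  is_case <- groups$group == "case"
  in_effect <- snp_gene %in% effect_ids

  baseline <- stats::rnorm(n_snp, spec$baseline_log_mean, spec$snp_level_sd)
  noise_sd <- matrix(spec$sample_noise_sd, n_snp, n_samp)
  noise_sd[in_effect, is_case] <- spec$sample_noise_sd * spec$variance_inflation
  shift <- matrix(0, n_snp, n_samp)
  shift[in_effect, is_case] <- spec$mean_shift_delta

  t_log <- baseline + shift +
    matrix(stats::rnorm(n_snp * n_samp), n_snp, n_samp) * noise_sd
  total <- 2^t_log
  u <- matrix(stats::runif(n_snp * n_samp, 0.05, 0.95), n_snp, n_samp)
  a <- u * total
  b <- total - a
  dimnames(a) <- dimnames(b) <- list(snp_id, samples)

  list(raw = new_raw_intensity_set(samples, snp_id, a, b),
       snp_map = snp_map, genes = genes, groups = groups, truth = truth)
}

#' Write a synthetic dataset's files
#'
#' Emits the intensity, SNP-map, gene, and group tables in the package's
#' tab-separated formats, plus a planted-truth TSV (`gene_id`, `mean_shift`,
#' `variance_inflation`).
#'
#' @param dataset The list returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(intensities = file.path(dir, "intensities.tsv"),
             snp_map = file.path(dir, "snp_map.tsv"),
             genes = file.path(dir, "genes.tsv"),
             groups = file.path(dir, "groups.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_intensity_table(dataset$raw, paths[["intensities"]])
  write_tsv_plain(dataset$snp_map, paths[["snp_map"]])
  write_tsv_plain(dataset$genes, paths[["genes"]])
  write_tsv_plain(dataset$groups, paths[["groups"]])
  write_tsv_plain(dataset$truth, paths[["truth"]])
  invisible(paths)
}

#' Evaluate recovery of planted effects
#'
#' Compares the Benjamini-Hochberg significant set of a scan against the
#' generator's planted truth. A true positive is a significant effect gene;
#' a false positive is a significant no-effect gene; a false negative is an
#' eligible effect gene not declared significant. Effect genes absent from
#' `results` did not pass the eligibility filter and are excluded from the
#' power denominator.
#'
#' @param results Scan results data.frame (needs `gene_id` and a logical
#'   significance column, by default `bh_significant`).
#' @param truth Planted-truth data.frame with `gene_id`.
#' @param flag_column Which significance column to score against.
#' @return List with `tp`, `fp`, `fn`, `fdr` (= FP / max(1, FP + TP)) and
#'   `power` (= TP / eligible effect genes; `NA` if none were eligible).
#' @export
evaluate_recovery <- function(results, truth, flag_column = "bh_significant") {
  if (!all(c("gene_id", flag_column) %in% names(results)))
    stop("results must contain 'gene_id' and '", flag_column, "'", call. = FALSE)
  if (nrow(results) == 0L && nrow(truth) > 0L)
    stop("results are empty but truth contains effect genes", call. = FALSE)
  sig <- results$gene_id[results[[flag_column]]]
  eligible_effects <- intersect(truth$gene_id, results$gene_id)
  tp <- length(intersect(sig, eligible_effects))
  fp <- length(setdiff(sig, truth$gene_id))
  fn <- length(setdiff(eligible_effects, sig))
  list(tp = tp, fp = fp, fn = fn,
       fdr = fp / max(1L, fp + tp),
       power = if (length(eligible_effects) > 0L)
         tp / length(eligible_effects) else NA_real_)
}
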