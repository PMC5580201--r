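#' Scan configuration
#'
#' @param min_snps Minimum number of array SNPs a gene must contain to be
#'   eligible (default 15).
#' @param alpha False-discovery-rate level for the Benjamini-Hochberg
#'   step-up rule (default 0.05).
#' @return A `scan_config` list.
#' @export
scan_config <- function(min_snps = 15L, alpha = 0.05) {
  min_snps <- as.integer(min_snps)
  if (is.na(min_snps) || min_snps < 2L)
    stop("min_snps must be an integer >= 2", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  structure(list(min_snps = min_snps, alpha = alpha), class = "scan_config")
}

#' Map SNPs to genes by genomic position
#'
#' Containment is inclusive of both gene ends (`start <= pos <= end`); a SNP
#' inside two overlapping genes is listed under both; genes containing no
#' SNP appear with an empty marker list. Markers within each gene are
#' ordered by ascending position.
#'
#' @param snp_map A `snp_map` data.frame (marker_id, chrom, pos).
#' @param genes A `gene_set` data.frame (gene_id, chrom, start, end, category).
#' @return A named list (one element per gene, in input gene order), each a
#'   list with `gene_id`, `chrom`, `start`, `end`, `markers` (character,
#'   position-ordered) and `n_snps`.
#' @export
build_gene_snp_index <- function(snp_map, genes) {
  stopifnot(is.data.frame(snp_map), is.data.frame(genes))
  by_chrom <- split(snp_map[c("marker_id", "pos")], snp_map$chrom)
  by_chrom <- lapply(by_chrom, function(d) d[order(d$pos), , drop = FALSE])
  idx <- vector("list", nrow(genes))
  names(idx) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    d <- by_chrom[[genes$chrom[i]]]
    if (is.null(d)) {
      hits <- character(0)
    } else {
      lo <- findInterval(genes$start[i] - 1L, d$pos) + 1L
      hi <- findInterval(genes$end[i], d$pos)
      hits <- if (hi >= lo) d$marker_id[lo:hi] else character(0)
    }
    idx[[i]] <- list(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                     start = genes$start[i], end = genes$end[i],
                     markers = hits, n_snps = length(hits))
  }
  idx
}

#' Keep only genes meeting the SNP-count eligibility threshold
#'
#' @param index Gene/SNP index from [build_gene_snp_index()].
#' @param config A [scan_config()].
#' @return The subset of `index` with `n_snps >= config$min_snps`.
#' @export
select_eligible_genes <- function(index, config = scan_config()) {
  Filter(function(g) g$n_snps >= config$min_snps, index)
}

#' Build the per-gene case and control vectors
#'
#' Each vector concatenates, over the gene's SNPs in positional order and
#' then over the group's samples in assignment order, the unmasked
#' normalized log2 ratios; masked cells are dropped.
#'
#' @param gene One element of the gene/SNP index.
#' @param norm A `normalized_matrix`.
#' @param groups A `group_assignment` data.frame.
#' @return List with numeric `case` and `control` vectors.
#' @export
build_group_vectors <- function(gene, norm, groups) {
  stopifnot(inherits(norm, "normalized_matrix"))
  gather <- function(sample_ids) {
    v <- as.vector(t(norm$value[gene$markers, sample_ids, drop = FALSE]))
    v[!is.na(v)]
  }
  case <- gather(groups$sample_id[groups$group == "case"])
  control <- gather(groups$sample_id[groups$group == "control"])
  if (length(case) < 2L || length(control) < 2L)
    stop(sprintf("degenerate gene '%s': fewer than 2 usable values in a group",
                 gene$gene_id), call. = FALSE)
  list(case = case, control = control)
}

#' Two-sample tests for equality of variance and mean
#'
#' The variance test is the two-sided F-test on
#' `F = s^2_case / s^2_control` with `(n_case - 1, n_control - 1)` degrees
#' of freedom, with p-value `min(1, 2 * min(Pr(F <= f), Pr(F >= f)))`. The
#' mean test is the two-sided Welch (unequal-variance) t-test.
#'
#' @param case,control Numeric vectors, each of length >= 2.
#' @return List with `p_variance` and `p_mean`.
#' @export
two_sample_tests <- function(case, control) {
  if (length(case) < 2L || length(control) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  v1 <- stats::var(case)
  v2 <- stats::var(control)
  if (v1 == 0 && v2 == 0)
    stop("undefined test: both group variances are zero", call. = FALSE)
  f <- v1 / v2
  df1 <- length(case) - 1L
  df2 <- length(control) - 1L
  p_var <- 2 * min(stats::pf(f, df1, df2),
                   stats::pf(f, df1, df2, lower.tail = FALSE))
  p_var <- min(1, max(p_var, .Machine$double.xmin))
  p_mean <- stats::t.test(case, control, var.equal = FALSE)$p.value
  p_mean <- min(1, max(p_mean, .Machine$double.xmin))
  list(p_variance = p_var, p_mean = p_mean)
}

#' Benjamini-Hochberg step-up multiple-testing correction
#'
#' Implements the step-up rule directly: order the p-values ascending as
#' `P(1) <= ... <= P(m)`; `k` is the largest `i` with
#' `P(i) <= alpha * i / m`; the `k` smallest p-values (ties broken by stable
#' sorted order) are declared significant; `k = 0` when no `i` qualifies.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param alpha FDR level in (0, 1).
#' @return List with `significant` (logical, aligned with `pvalues`) and
#'   `k` (number of rejections).
#' @export
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stop("pvalues must be non-empty", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  m <- length(pvalues)
  ord <- order(pvalues)            # stable: ties keep input order
  sorted <- pvalues[ord]
  passes <- which(sorted <= alpha * seq_len(m) / m)
  k <- if (length(passes) > 0L) max(passes) else 0L
  significant <- logical(m)
  if (k > 0L) significant[ord[seq_len(k)]] <- TRUE
  list(significant = significant, k = as.integer(k))
}

#' Genome-wide per-gene scan
#'
#' For every eligible gene (>= `config$min_snps` SNPs), builds the case and
#' control vectors of normalized log2 ratios, runs the two-sample variance
#' and mean tests, then applies the Benjamini-Hochberg step-up rule
#' separately to the mean-test and variance-test p-value families. Genes
#' with too few usable values or zero variance in both groups are recorded
#' in the skip log (attribute `"skipped"`), not silently dropped.
#'
#' @param norm A `normalized_matrix`.
#' @param index Gene/SNP index (all genes; eligibility is applied here).
#' @param groups A `group_assignment`.
#' @param config A [scan_config()].
#' @return A data.frame with one row per tested gene: `gene_id`, `chrom`,
#'   `start`, `end`, `n_snps`, `p_variance`, `p_mean`,
#'   `bh_significant_mean`, `bh_significant_variance`, and `bh_significant`
#'   (alias of the mean-family flag, the headline significant set). The
#'   `"skipped"` attribute holds a data.frame of skipped genes and reasons.
#' @export
scan_genome <- function(norm, index, groups, config = scan_config()) {
  groups <- validate_groups(as.data.frame(groups), samples = norm$samples)
  eligible <- select_eligible_genes(index, config)
  skipped <- list()
  rows <- list()
  for (gene in eligible) {
    res <- tryCatch({
      vec <- build_group_vectors(gene, norm, groups)
      tst <- two_sample_tests(vec$case, vec$control)
      data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                 start = gene$start, end = gene$end, n_snps = gene$n_snps,
                 p_variance = tst$p_variance, p_mean = tst$p_mean,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = gene$gene_id, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  skip_df <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(gene_id = character(0), reason = character(0))
  if (length(rows) == 0L) {
    warning("no eligible genes produced a test result", call. = FALSE)
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), p_variance = numeric(0),
                      p_mean = numeric(0), bh_significant_mean = logical(0),
                      bh_significant_variance = logical(0),
                      bh_significant = logical(0))
    attr(out, "skipped") <- skip_df
    return(out)
  }
  out <- do.call(rbind, rows)
  out$bh_significant_mean <-
    benjamini_hochberg(out$p_mean, config$alpha)$significant
  out$bh_significant_variance <-
    benjamini_hochberg(out$p_variance, config$alpha)$significant
  out$bh_significant <- out$bh_significant_mean
  attr(out, "skipped") <- skip_df
  out
}
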