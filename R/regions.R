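#' Construct a genomic region
#'
#' @param chrom Chromosome label (opaque string).
#' @param start,end Base-pair coordinates with `start < end`.
#' @return A `region` list.
#' @export
region <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("region start must be < end", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "region")
}

#' Region length in base pairs
#'
#' Defined as `end - start` (the coordinate difference, not the inclusive
#' span `end - start + 1`); SNP containment elsewhere remains inclusive of
#' both endpoints.
#'
#' @param r A [region()].
#' @return Length in bp.
#' @export
region_length <- function(r) {
  stopifnot(inherits(r, "region"))
  r$end - r$start
}

#' Two-sample tests over an arbitrary genomic region
#'
#' Gathers every SNP with `start <= pos <= end` on the region's chromosome,
#' builds the case and control vectors exactly as the gene scan does, and
#' runs the variance and mean tests. Applied to a gene's exact span this
#' reproduces [scan_genome()]'s p-values for that gene bit for bit.
#'
#' @param r A [region()].
#' @param snp_map A `snp_map`.
#' @param norm A `normalized_matrix`.
#' @param groups A `group_assignment`.
#' @return List with `p_variance`, `p_mean` and `n_snps`.
#' @export
region_test <- function(r, snp_map, norm, groups) {
  stopifnot(inherits(r, "region"))
  on_chrom <- snp_map[snp_map$chrom == r$chrom &
                        snp_map$pos >= r$start & snp_map$pos <= r$end, ]
  on_chrom <- on_chrom[order(on_chrom$pos), ]
  if (nrow(on_chrom) == 0L)
    stop(sprintf("degenerate region %s:%s-%s: contains no SNPs",
                 r$chrom, format(r$start, scientific = FALSE),
                 format(r$end, scientific = FALSE)), call. = FALSE)
  pseudo <- list(gene_id = sprintf("%s:%s-%s", r$chrom, r$start, r$end),
                 markers = on_chrom$marker_id, n_snps = nrow(on_chrom))
  vec <- tryCatch(build_group_vectors(pseudo, norm, groups),
                  error = function(e)
                    stop(sprintf("degenerate region %s: %s", pseudo$gene_id,
                                 conditionMessage(e)), call. = FALSE))
  tst <- two_sample_tests(vec$case, vec$control)
  list(p_variance = tst$p_variance, p_mean = tst$p_mean,
       n_snps = nrow(on_chrom))
}

#' Flanking SNP groups around a gene
#'
#' `left` holds the k markers with the largest positions strictly below the
#' gene start on its chromosome; `right` the k markers with the smallest
#' positions strictly above the gene end. Fewer than k available on a side
#' returns what exists with a warning. Markers are returned in ascending
#' positional order.
#'
#' @param gene_region A [region()] covering the gene span.
#' @param snp_map A `snp_map`.
#' @param k Markers per flank (default 5).
#' @return List with character vectors `left` and `right`.
#' @export
flanking_snp_groups <- function(gene_region, snp_map, k = 5L) {
  stopifnot(inherits(gene_region, "region"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  d <- snp_map[snp_map$chrom == gene_region$chrom, ]
  d <- d[order(d$pos), ]
  left_all <- d$marker_id[d$pos < gene_region$start]
  right_all <- d$marker_id[d$pos > gene_region$end]
  left <- utils::tail(left_all, k)
  right <- utils::head(right_all, k)
  if (length(left) < k)
    warning(sprintf("only %d SNP(s) available on the left flank", length(left)),
            call. = FALSE)
  if (length(right) < k)
    warning(sprintf("only %d SNP(s) available on the right flank", length(right)),
            call. = FALSE)
  list(left = left, right = right)
}

#' Mean p-value of the two flanking SNP groups
#'
#' Runs the region-style mean test on each flank's SNP group and returns
#' the arithmetic mean of the two mean-test p-values.
#'
#' @inheritParams flanking_snp_groups
#' @param norm A `normalized_matrix`.
#' @param groups A `group_assignment`.
#' @return The mean of the left and right flank `p_mean` values.
#' @export
mean_flanking_pvalue <- function(gene_region, snp_map, norm, groups, k = 5L) {
  fl <- flanking_snp_groups(gene_region, snp_map, k)
  flank_p <- function(markers, side) {
    if (length(markers) == 0L)
      stop(sprintf("empty %s flank for %s:%s-%s", side, gene_region$chrom,
                   gene_region$start, gene_region$end), call. = FALSE)
    pseudo <- list(gene_id = sprintf("%s-flank", side), markers = markers,
                   n_snps = length(markers))
    vec <- build_group_vectors(pseudo, norm, groups)
    two_sample_tests(vec$case, vec$control)$p_mean
  }
  (flank_p(fl$left, "left") + flank_p(fl$right, "right")) / 2
}

#' Filter CNV segment calls by the declaration rule
#'
#' Retains exactly the calls supported by at least `min_snps` adjacent
#' markers whose region length (`end - start`) is at least `min_length` bp.
#'
#' @param calls Data.frame with columns `chrom`, `start`, `end`, `state`
#'   (`loss`/`gain`) and `n_snps`.
#' @param min_snps Minimum supporting adjacent SNPs (default 3).
#' @param min_length Minimum length in bp (default 1000).
#' @return The retained subset, input order preserved.
#' @export
cnv_declaration_filter <- function(calls, min_snps = 3L, min_length = 1000) {
  stopifnot(all(c("chrom", "start", "end", "n_snps") %in% names(calls)))
  if (any(calls$n_snps < 1L)) stop("n_snps must be >= 1", call. = FALSE)
  if (any(calls$start >= calls$end)) stop("call start must be < end", call. = FALSE)
  keep <- calls$n_snps >= min_snps & (calls$end - calls$start) >= min_length
  calls[keep, , drop = FALSE]
}

#' Overlapping pairs between two region sets
#'
#' Regions overlap iff they share a chromosome and `max(starts) <
#' min(ends)` (strict: touching intervals do not overlap); the overlap
#' length is `min(ends) - max(starts)`.
#'
#' @param query,reference Data.frames with columns `chrom`, `start`, `end`.
#' @return Data.frame with `query_idx`, `reference_idx` and
#'   `overlap_length` (bp), one row per overlapping pair.
#' @export
region_overlap <- function(query, reference) {
  for (d in list(query, reference))
    stopifnot(all(c("chrom", "start", "end") %in% names(d)))
  rows <- list()
  for (i in seq_len(nrow(query))) {
    same <- which(reference$chrom == query$chrom[i])
    if (length(same) == 0L) next
    lo <- pmax(query$start[i], reference$start[same])
    hi <- pmin(query$end[i], reference$end[same])
    hit <- hi > lo
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_idx = i, reference_idx = same[hit],
        overlap_length = (hi - lo)[hit])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_idx = integer(0), reference_idx = integer(0),
                      overlap_length = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pathway coverage arithmetic
#'
#' Coverage is the percentage of the pathway's genes that pass the
#' eligibility filter, truncated (not rounded) at two decimals; the
#' eligible pathway genes are split into the significant and
#' non-significant counts, which always sum to the total.
#'
#' @param pathway_genes Character vector: the pathway's gene ids.
#' @param eligible_genes Character vector: genes with enough SNPs.
#' @param significant_genes Character vector: BH-significant genes (must be
#'   a subset of `eligible_genes`).
#' @return List with `total`, `coverage_pct`, `significant` and
#'   `non_significant`.
#' @export
pathway_coverage <- function(pathway_genes, eligible_genes, significant_genes) {
  if (length(pathway_genes) == 0L)
    stop("pathway gene set must be non-empty", call. = FALSE)
  if (length(setdiff(significant_genes, eligible_genes)) > 0L)
    stop("significant genes must be a subset of eligible genes", call. = FALSE)
  pathway_genes <- unique(pathway_genes)
  total <- length(intersect(pathway_genes, eligible_genes))
  coverage <- floor(100 * total / length(pathway_genes) * 100 + 1e-9) / 100
  sig <- length(intersect(pathway_genes, significant_genes))
  list(total = total, coverage_pct = coverage,
       significant = sig, non_significant = total - sig)
}

#' Haplotype patterns exclusive to one group
#'
#' A pattern is flagged for a group when it occurs in at least one of the
#' two chromosome copies of every sample of that group and in no copy of
#' any sample of the other group — the strongest reading of a
#' group-consistent haplotype. Returns an empty result when no such pattern
#' exists.
#'
#' @param table Data.frame with columns `sample_id`, `hap1`, `hap2`
#'   (equal-length strings over A/C/G/T) and `group` (`case`/`control`).
#' @return Data.frame with columns `pattern` and `group` (possibly 0 rows).
#' @export
haplotype_group_consistency <- function(table) {
  stopifnot(all(c("sample_id", "hap1", "hap2", "group") %in% names(table)))
  haps <- c(table$hap1, table$hap2)
  if (length(unique(nchar(haps))) > 1L)
    stop("all haplotype strings must have equal length", call. = FALSE)
  if (any(grepl("[^ACGT]", haps)))
    stop("haplotype strings must use only A, C, G, T", call. = FALSE)
  per_sample <- Map(function(h1, h2) unique(c(h1, h2)), table$hap1, table$hap2)
  rows <- list()
  for (g in unique(table$group)) {
    own <- per_sample[table$group == g]
    other <- unlist(per_sample[table$group != g], use.names = FALSE)
    candidates <- Reduce(intersect, own)
    hits <- setdiff(candidates, other)
    if (length(hits) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(pattern = sort(hits), group = g,
                                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(pattern = character(0), group = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
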