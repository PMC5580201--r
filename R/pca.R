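#' Build the samples-by-genes feature matrix
#'
#' One feature per selected gene; cell (sample, gene) is the mean of the
#' unmasked normalized log2 ratios over the gene's SNPs for that sample.
#' A gene with every SNP masked for some sample yields an undefined cell and
#' is dropped with a warning, so the returned matrix has no missing cells.
#'
#' @param norm A `normalized_matrix`.
#' @param index Gene/SNP index from [build_gene_snp_index()].
#' @param selection Character vector of gene ids to use as features.
#' @return A samples-by-genes numeric matrix with dimnames.
#' @export
gene_feature_matrix <- function(norm, index, selection) {
  stopifnot(inherits(norm, "normalized_matrix"))
  missing <- setdiff(selection, names(index))
  if (length(missing) > 0L)
    stop("selected genes absent from index: ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  cols <- list()
  dropped <- character(0)
  for (gid in selection) {
    gene <- index[[gid]]
    vals <- norm$value[gene$markers, , drop = FALSE]
    mu <- colMeans(vals, na.rm = TRUE)
    if (any(is.nan(mu))) {
      dropped <- c(dropped, gid)
    } else {
      cols[[gid]] <- mu
    }
  }
  if (length(dropped) > 0L)
    warning(sprintf("%d gene(s) dropped (all SNPs masked for some sample): %s",
                    length(dropped),
                    paste(utils::head(dropped, 3L), collapse = ", ")),
            call. = FALSE)
  if (length(cols) == 0L)
    stop("no usable features after dropping masked genes", call. = FALSE)
  mat <- do.call(cbind, cols)
  rownames(mat) <- norm$samples
  mat
}

#' Principal components of a samples-by-features matrix
#'
#' Columns are centered by their means; the covariance matrix of the
#' centered data (sample covariance, divisor n - 1) is eigen-decomposed via
#' the singular value decomposition; scores are projections on the top-d
#' eigenvectors, eigenvalues sorted non-increasing. The sign of PC1 is fixed
#' so that the mean PC1 score of the case group is non-negative when
#' `case_samples` is supplied; the sign of every other component (and of PC1
#' otherwise) is fixed by making the largest-magnitude loading positive. A
#' constant matrix yields all-zero eigenvalues and scores.
#'
#' @param x Numeric matrix, samples in rows.
#' @param d Components to retain (default all, `min(n_samples, n_features)`).
#' @param case_samples Optional character vector of row names forming the
#'   case group, used for the PC1 sign convention.
#' @return A `pca_result`: list with `scores` (samples x d), `eigenvalues`
#'   (all `min(n, p)` of them, non-increasing), `rotation` (features x d)
#'   and `d`.
#' @export
principal_components <- function(x, d = NULL, case_samples = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  r <- min(n, p)
  if (is.null(d)) d <- r
  if (d < 1L || d > r) stop("d must lie in [1, min(n_samples, n_features)]",
                            call. = FALSE)
  centered <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(centered, nu = 0, nv = r)
  eigenvalues <- numeric(r)
  eigenvalues[seq_along(sv$d)] <- sv$d^2 / (n - 1)
  rotation <- sv$v[, seq_len(d), drop = FALSE]
  scores <- centered %*% rotation
  for (j in seq_len(d)) {
    flip <- FALSE
    if (j == 1L && !is.null(case_samples)) {
      mu_case <- mean(scores[rownames(x) %in% case_samples, 1L])
      flip <- is.finite(mu_case) && mu_case < 0
    } else if (any(rotation[, j] != 0)) {
      flip <- rotation[which.max(abs(rotation[, j])), j] < 0
    }
    if (flip) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), sprintf("PC%d", seq_len(d)))
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 rotation = rotation, d = as.integer(d)),
            class = "pca_result")
}

#' Per-gene PC1 profile across samples
#'
#' Builds the samples-by-SNPs matrix of normalized values for one gene
#' (SNPs with any masked cell are dropped), takes the first principal
#' component, rescales the PC1 scores to unit maximum absolute value, and
#' returns them sorted ascending (the layout of a per-gene loading bar
#' chart), named by sample.
#'
#' @param gene One element of the gene/SNP index.
#' @param norm A `normalized_matrix`.
#' @param groups A `group_assignment` (sets the PC1 sign convention).
#' @return Named numeric vector, one value per sample, ascending.
#' @export
gene_pc1_profile <- function(gene, norm, groups) {
  vals <- t(norm$value[gene$markers, , drop = FALSE])  # samples x snps
  keep <- colSums(is.na(vals)) == 0L
  vals <- vals[, keep, drop = FALSE]
  if (ncol(vals) == 0L)
    stop(sprintf("gene '%s' has no fully unmasked SNP", gene$gene_id),
         call. = FALSE)
  pc <- principal_components(vals, d = 1L,
                             case_samples = groups$sample_id[groups$group == "case"])
  s <- pc$scores[, 1L]
  mx <- max(abs(s))
  if (mx > 0) s <- s / mx
  sort(s)
}
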