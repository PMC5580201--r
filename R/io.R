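#' Read a long-format allele-intensity table
#'
#' Reads a tab-separated file with header columns `marker_id`, `sample_id`,
#' `A`, `B` (one row per marker/sample combination) into a
#' `raw_intensity_set`: two snp-by-sample matrices of non-negative allele
#' fluorescence intensities. The file must contain the complete marker-by-
#' sample grid; missing combinations, duplicates, negative or non-numeric
#' intensities are errors.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @return A `raw_intensity_set` object: list with `samples`, `snps`,
#'   `a_intensity` and `b_intensity` (matrices, rows = SNPs, cols = samples).
#' @export
read_intensity_table <- function(path) {
  df <- read_tsv_checked(path, c("marker_id", "sample_id", "A", "B"))
  for (col in c("A", "B")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric field in column %s at data line %d: '%s'",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  key <- paste(df$marker_id, df$sample_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("duplicate record for marker '%s', sample '%s'",
                 df$marker_id[which(dup)[1L]], df$sample_id[which(dup)[1L]]),
         call. = FALSE)
  }
  snps <- unique(df$marker_id)
  samples <- unique(df$sample_id)
  if (nrow(df) != length(snps) * length(samples)) {
    grid <- paste(rep(snps, each = length(samples)),
                  rep(samples, times = length(snps)), sep = "\r")
    miss <- setdiff(grid, key)[1L]
    parts <- strsplit(miss, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("missing record for marker '%s', sample '%s'",
                 parts[1L], parts[2L]), call. = FALSE)
  }
  a <- matrix(NA_real_, length(snps), length(samples),
              dimnames = list(snps, samples))
  b <- a
  ri <- match(df$marker_id, snps)
  ci <- match(df$sample_id, samples)
  a[cbind(ri, ci)] <- df$A
  b[cbind(ri, ci)] <- df$B
  new_raw_intensity_set(samples, snps, a, b)
}

#' Write a long-format allele-intensity table
#'
#' Inverse of [read_intensity_table()]: one row per marker/sample pair, in
#' marker-major order.
#'
#' @param raw A `raw_intensity_set`.
#' @param path Output path.
#' @export
write_intensity_table <- function(raw, path) {
  stopifnot(inherits(raw, "raw_intensity_set"))
  df <- data.frame(
    marker_id = rep(raw$snps, each = length(raw$samples)),
    sample_id = rep(raw$samples, times = length(raw$snps)),
    A = as.vector(t(raw$a_intensity)),
    B = as.vector(t(raw$b_intensity)),
    stringsAsFactors = FALSE
  )
  write_tsv_plain(df, path)
  invisible(NULL)
}

#' @noRd
new_raw_intensity_set <- function(samples, snps, a, b) {
  if (anyDuplicated(samples)) stop("sample ids are not unique", call. = FALSE)
  if (anyDuplicated(snps)) stop("marker ids are not unique", call. = FALSE)
  stopifnot(identical(dim(a), dim(b)),
            nrow(a) == length(snps), ncol(a) == length(samples))
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("intensities must be finite", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("negative intensity encountered", call. = FALSE)
  structure(list(samples = samples, snps = snps,
                 a_intensity = a, b_intensity = b),
            class = "raw_intensity_set")
}

#' Read a SNP map (marker, chromosome, position)
#'
#' @param path Tab-separated file with header columns `marker_id`, `chrom`,
#'   `pos`; positions are 1-based base-pair coordinates.
#' @return A data.frame with one validated row per marker, of class `snp_map`.
#' @export
read_snp_map <- function(path) {
  df <- read_tsv_checked(path, c("marker_id", "chrom", "pos"))
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad) > 0L)
    stop(sprintf("non-integer position at data line %d: '%s'",
                 bad[1L], df$pos[bad[1L]]), call. = FALSE)
  df$pos <- as.integer(pos)
  validate_snp_map(df)
}

#' @noRd
validate_snp_map <- function(df) {
  if (anyDuplicated(df$marker_id))
    stop("duplicate marker id in SNP map", call. = FALSE)
  if (any(df$pos < 1L))
    stop("SNP positions must be strictly positive", call. = FALSE)
  class(df) <- c("snp_map", "data.frame")
  df
}

#' Read a gene annotation table
#'
#' @param path Tab-separated file with header columns `gene_id`, `chrom`,
#'   `start`, `end`, `category`; coordinates are 1-based and the interval is
#'   treated as inclusive of both ends for SNP containment.
#' @return A data.frame of class `gene_set`.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "start", "end", "category"))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0L)
      stop(sprintf("non-integer coordinate in column %s at data line %d: '%s'",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  validate_gene_set(df)
}

#' @noRd
validate_gene_set <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in gene table", call. = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L)
    stop(sprintf("gene '%s' has start >= end (%d >= %d)",
                 df$gene_id[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]),
         call. = FALSE)
  class(df) <- c("gene_set", "data.frame")
  df
}

#' Read a sample-to-group assignment
#'
#' @param path Tab-separated file with header columns `sample_id`, `group`;
#'   group labels must be `case` or `control` and both groups non-empty.
#' @return A data.frame of class `group_assignment`.
#' @export
read_group_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "group"))
  validate_groups(df)
}

#' @noRd
validate_groups <- function(df, samples = NULL) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in group assignment", call. = FALSE)
  if (!all(df$group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (!all(c("case", "control") %in% df$group))
    stop("both groups must be non-empty", call. = FALSE)
  if (!is.null(samples)) {
    missing <- setdiff(samples, df$sample_id)
    if (length(missing) > 0L)
      stop(sprintf("sample '%s' has no group assignment", missing[1L]),
           call. = FALSE)
  }
  class(df) <- c("group_assignment", "data.frame")
  df
}

#' Write gene-scan results to a tab-separated file
#'
#' Rows are ordered by chromosome (natural order: numeric-aware, so chr2
#' before chr10) and start position, so repeated runs produce identical
#' files. P-values are written with full double precision.
#'
#' @param results A data.frame as returned by [scan_genome()].
#' @param path Output path.
#' @export
write_scan_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L)
    stop("results must be non-empty", call. = FALSE)
  needed <- c("gene_id", "chrom", "start", "end", "n_snps",
              "p_variance", "p_mean", "bh_significant")
  if (!all(needed %in% names(results)))
    stop("results are missing required columns: ",
         paste(setdiff(needed, names(results)), collapse = ", "),
         call. = FALSE)
  ord <- order(chrom_sort_key(results$chrom), results$start)
  out <- results[ord, needed]
  out$p_variance <- format(out$p_variance, digits = 17, scientific = TRUE, trim = TRUE)
  out$p_mean <- format(out$p_mean, digits = 17, scientific = TRUE, trim = TRUE)
  write_tsv_plain(out, path)
  invisible(NULL)
}

#' Read back a scan-results file written by [write_scan_results()]
#' @param path Path to a results TSV.
#' @return A data.frame.
#' @export
read_scan_results <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "start", "end", "n_snps",
                                 "p_variance", "p_mean", "bh_significant"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$n_snps <- as.integer(df$n_snps)
  df$p_variance <- as.numeric(df$p_variance)
  df$p_mean <- as.numeric(df$p_mean)
  df$bh_significant <- as.logical(df$bh_significant)
  df
}

# --- shared TSV helpers ------------------------------------------------------

#' @noRd
read_tsv_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(columns %in% names(df)))
    stop(sprintf("file %s is missing columns: %s", path,
                 paste(setdiff(columns, names(df)), collapse = ", ")),
         call. = FALSE)
  df[columns]
}

#' @noRd
write_tsv_plain <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(NULL)
}

# Numeric-aware chromosome ordering: "chr2" < "chr10"; non-numeric labels
# (chrX, chrMT) sort lexicographically after numeric ones.
#' @noRd
chrom_sort_key <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  key <- ifelse(is.na(num),
                sprintf("1%s", stripped),
                sprintf("0%012.2f", num))
  key
}
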