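#' Normalize allele intensities to log2 ratios
#'
#' For each SNP the total intensity per sample is `T = A + B`; the per-SNP
#' reference is the across-sample median `M = median(T_1, ..., T_N)` taken
#' over all samples (cases and controls together; even sample counts use the
#' arithmetic mean of the two middle values); the normalized value is
#' `log2(T/M)`. Cells with `T = 0` are masked rather than floored or imputed;
#' a SNP whose reference median is 0 is masked entirely. Masked cells are
#' excluded from every downstream vector.
#'
#' @param raw A `raw_intensity_set` (see [read_intensity_table()]).
#' @return A `normalized_matrix`: list with `snps`, `samples`, `value`
#'   (snp-by-sample matrix of log2 ratios; `NA` where masked), `mask`
#'   (logical matrix, `TRUE` = unusable) and `reference` (per-SNP median M,
#'   in the input fluorescence units).
#' @export
normalize_intensities <- function(raw) {
  stopifnot(inherits(raw, "raw_intensity_set"))
  if (length(raw$samples) < 1L || length(raw$snps) < 1L)
    stop("empty intensity set", call. = FALSE)
  total <- raw$a_intensity + raw$b_intensity
  m <- apply(total, 1L, stats::median)
  mask <- total == 0
  snp_dead <- m == 0
  mask[snp_dead, ] <- TRUE
  value <- log2(sweep(total, 1L, m, `/`))
  value[mask] <- NA_real_
  structure(list(snps = raw$snps, samples = raw$samples,
                 value = value, mask = mask, reference = m),
            class = "normalized_matrix")
}

#' Write a normalized matrix as long-format TSV
#'
#' Columns: `marker_id`, `sample_id`, `log2ratio` (empty for masked cells),
#' `masked` (TRUE/FALSE).
#'
#' @param norm A `normalized_matrix`.
#' @param path Output path.
#' @export
write_normalized_table <- function(norm, path) {
  stopifnot(inherits(norm, "normalized_matrix"))
  df <- data.frame(
    marker_id = rep(norm$snps, each = length(norm$samples)),
    sample_id = rep(norm$samples, times = length(norm$snps)),
    log2ratio = as.vector(t(norm$value)),
    masked = as.vector(t(norm$mask)),
    stringsAsFactors = FALSE
  )
  df$log2ratio <- ifelse(df$masked, "",
                         format(df$log2ratio, digits = 17, trim = TRUE))
  write_tsv_plain(df, path)
  invisible(NULL)
}
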