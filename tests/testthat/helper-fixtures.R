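# Small in-code fixture builders shared across test files.

make_raw <- function(a, b, snps = sprintf("M%d", seq_len(nrow(a))),
                     samples = sprintf("S%d", seq_len(ncol(a)))) {
  dimnames(a) <- dimnames(b) <- list(snps, samples)
  snpsignal:::new_raw_intensity_set(samples, snps, a, b)
}

# A normalized_matrix built directly from a value matrix (no masking unless
# NA cells are present), bypassing the intensity layer.
make_norm <- function(value, snps = sprintf("M%d", seq_len(nrow(value))),
                      samples = sprintf("S%d", seq_len(ncol(value)))) {
  dimnames(value) <- list(snps, samples)
  structure(list(snps = snps, samples = samples, value = value,
                 mask = is.na(value), reference = rep(1, nrow(value))),
            class = "normalized_matrix")
}

make_snp_map <- function(marker_id, chrom, pos) {
  snpsignal:::validate_snp_map(
    data.frame(marker_id = marker_id, chrom = chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE))
}

make_genes <- function(gene_id, chrom, start, end, category = "RefSeq") {
  snpsignal:::validate_gene_set(
    data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
               end = as.integer(end), category = category,
               stringsAsFactors = FALSE))
}

make_groups <- function(case, control) {
  snpsignal:::validate_groups(
    data.frame(sample_id = c(case, control),
               group = rep(c("case", "control"),
                           c(length(case), length(control))),
               stringsAsFactors = FALSE))
}

make_regions <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

# Intensity TSV writer for io tests.
write_intensity_lines <- function(rows, path) {
  writeLines(c("marker_id\tsample_id\tA\tB", rows), path)
}

# Brute-force BH oracle: try every i directly, take the largest that passes,
# flag the k smallest.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[ord[i]] <= alpha * i / m) k <- i
  sig <- logical(m)
  if (k > 0L) sig[ord[seq_len(k)]] <- TRUE
  list(significant = sig, k = k)
}
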