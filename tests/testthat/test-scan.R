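test_that("SNP-to-gene containment is inclusive on both gene ends", {
  sm <- make_snp_map(sprintf("M%d", 1:4), "chr1", c(99, 100, 200, 201))
  genes <- make_genes("G1", "chr1", 100, 200)
  idx <- build_gene_snp_index(sm, genes)
  expect_identical(idx$G1$markers, c("M2", "M3"))
  expect_equal(idx$G1$n_snps, 2L)
})

test_that("a SNP inside two overlapping genes is assigned to both", {
  sm <- make_snp_map("M1", "chr1", 150)
  genes <- make_genes(c("G1", "G2"), "chr1", c(100, 140), c(200, 300))
  idx <- build_gene_snp_index(sm, genes)
  expect_identical(idx$G1$markers, "M1")
  expect_identical(idx$G2$markers, "M1")
})

test_that("gene/SNP index matches a brute-force all-pairs containment scan", {
  set.seed(5)
  sm <- make_snp_map(sprintf("M%02d", 1:50),
                     sample(c("chr1", "chr2"), 50, replace = TRUE),
                     sample(1:1000, 50))
  starts <- sample(1:800, 5)
  genes <- make_genes(sprintf("G%d", 1:5),
                      sample(c("chr1", "chr2"), 5, replace = TRUE),
                      starts, starts + sample(50:200, 5))
  idx <- build_gene_snp_index(sm, genes)
  for (g in seq_len(nrow(genes))) {
    hits <- character(0)
    for (s in seq_len(nrow(sm))) {
      if (sm$chrom[s] == genes$chrom[g] &&
          sm$pos[s] >= genes$start[g] && sm$pos[s] <= genes$end[g])
        hits <- c(hits, sm$marker_id[s])
    }
    hits <- hits[order(sm$pos[match(hits, sm$marker_id)])]
    expect_identical(idx[[genes$gene_id[g]]]$markers, hits)
  }
})

test_that("eligibility keeps exactly the genes at or above the SNP threshold", {
  idx <- list(G14 = list(gene_id = "G14", n_snps = 14L),
              G15 = list(gene_id = "G15", n_snps = 15L),
              G16 = list(gene_id = "G16", n_snps = 16L))
  kept <- select_eligible_genes(idx, scan_config(min_snps = 15))
  expect_setequal(names(kept), c("G15", "G16"))
  expect_length(select_eligible_genes(list(), scan_config()), 0L)

  # synthetic dataset straddling the threshold: filter equals a recount
  ds <- generate_dataset(synthetic_spec(n_genes = 40,
                                        snps_per_gene_range = c(10L, 20L),
                                        seed = 21))
  full <- build_gene_snp_index(ds$snp_map, ds$genes)
  kept <- select_eligible_genes(full, scan_config())
  counts <- vapply(full, function(g) g$n_snps, integer(1))
  expect_setequal(names(kept), names(counts)[counts >= 15L])
})

test_that("group vectors concatenate SNP-major, dropping masked cells", {
  set.seed(9)
  value <- matrix(rnorm(15 * 12), 15, 12,
                  dimnames = list(sprintf("M%d", 1:15), sprintf("S%d", 1:12)))
  norm <- make_norm(value)
  groups <- make_groups(sprintf("S%d", 1:6), sprintf("S%d", 7:12))
  gene <- list(gene_id = "G1", markers = norm$snps, n_snps = 15L)
  vec <- build_group_vectors(gene, norm, groups)
  expect_length(vec$case, 90L)
  expect_length(vec$control, 90L)
  # independent nested-loop gather
  gather <- c()
  for (m in norm$snps) for (s in sprintf("S%d", 1:6)) gather <- c(gather, value[m, s])
  expect_equal(vec$case, gather)

  value[3, 2] <- NA  # one masked case cell
  vec2 <- build_group_vectors(gene, make_norm(value), groups)
  expect_length(vec2$case, 89L)
  expect_length(vec2$control, 90L)
})

test_that("degenerate genes (too few usable values) raise a named error", {
  value <- matrix(rnorm(8), 2, 4)
  value[, 1] <- NA  # case group loses a sample entirely
  value[1, 2] <- NA
  value[2, 2] <- NA
  norm <- make_norm(value)
  groups <- make_groups(c("S1", "S2"), c("S3", "S4"))
  gene <- list(gene_id = "Gbad", markers = norm$snps, n_snps = 2L)
  expect_error(build_group_vectors(gene, norm, groups), "degenerate gene 'Gbad'")
})

test_that("two-sample tests match their distributional definitions", {
  # perfect symmetry: identical vectors
  r <- two_sample_tests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_mean, 1)
  expect_equal(r$p_variance, 1)

  # F = 1/4 on (2, 2) df; compare the doubled tail against quadrature of the
  # F density (independent oracle for the distribution function)
  r <- two_sample_tests(c(1, 2, 3), c(2, 4, 6))
  f_stat <- var(c(1, 2, 3)) / var(c(2, 4, 6))
  expect_equal(f_stat, 1 / 4)
  lower <- integrate(function(x) df(x, 2, 2), 0, f_stat, rel.tol = 1e-10)$value
  upper <- integrate(function(x) df(x, 2, 2), f_stat, Inf, rel.tol = 1e-10)$value
  expect_equal(r$p_variance, min(1, 2 * min(lower, upper)), tolerance = 1e-8)

  # Welch t against the standard implementation
  set.seed(31)
  x <- rnorm(20); y <- rnorm(25, 0.5, 2)
  r <- two_sample_tests(x, y)
  expect_equal(r$p_mean, t.test(x, y)$p.value)
  expect_equal(r$p_variance, var.test(x, y)$p.value)

  # two-sided symmetry under swapping
  s <- two_sample_tests(y, x)
  expect_equal(s$p_mean, r$p_mean)
  expect_equal(s$p_variance, r$p_variance)

  expect_error(two_sample_tests(c(1, 1, 1), c(2, 2, 2)), "both group variances")
  expect_error(two_sample_tests(1, c(1, 2)), "at least 2")
})

test_that("Benjamini-Hochberg step-up follows the hand-worked example", {
  # thresholds 0.0125, 0.025, 0.0375, 0.05 -> k = 2
  r <- benjamini_hochberg(c(0.01, 0.02, 0.04, 0.8), 0.05)
  expect_equal(r$k, 2L)
  expect_identical(r$significant, c(TRUE, TRUE, FALSE, FALSE))

  r <- benjamini_hochberg(rep(1, 5), 0.05)
  expect_equal(r$k, 0L)
  expect_false(any(r$significant))

  m <- 8
  r <- benjamini_hochberg(rep(0.05 / m, m), 0.05)
  expect_equal(r$k, m)
  expect_true(all(r$significant))

  expect_error(benjamini_hochberg(numeric(0)), "non-empty")
  expect_error(benjamini_hochberg(c(0.5, 0), 0.05), "0, 1")
  expect_error(benjamini_hochberg(0.5, 1.5), "alpha")
})

test_that("BH matches a brute-force threshold-enumeration oracle", {
  set.seed(77)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)
    if (runif(1) < 0.3) p[sample(m, 1)] <- p[sample(m, 1)]  # inject ties
    alpha <- runif(1, 0.01, 0.2)
    mine <- benjamini_hochberg(p, alpha)
    oracle <- bh_oracle(p, alpha)
    expect_identical(mine$k, as.integer(oracle$k))
    expect_identical(mine$significant, oracle$significant)
    # consistency with the standard adjusted-p formulation
    expect_identical(mine$significant, p.adjust(p, "BH") <= alpha)
  }
})

test_that("BH rejections are non-decreasing in alpha", {
  set.seed(13)
  p <- runif(100)^2
  ks <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.2),
               function(a) benjamini_hochberg(p, a)$k, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("scan flags a strongly shifted gene as the smallest mean-test p", {
  ds <- generate_dataset(synthetic_spec(
    n_genes = 50, snps_per_gene_range = c(15L, 18L), sample_noise_sd = 0.2,
    effect_gene_fraction = 1 / 50, mean_shift_delta = 2.0, seed = 17))
  expect_equal(nrow(ds$truth), 1L)
  norm <- normalize_intensities(ds$raw)
  idx <- build_gene_snp_index(ds$snp_map, ds$genes)
  res <- scan_genome(norm, idx, ds$groups)
  expect_identical(res$gene_id[which.min(res$p_mean)], ds$truth$gene_id)
  expect_true(res$bh_significant[res$gene_id == ds$truth$gene_id])
  expect_identical(res$bh_significant, res$bh_significant_mean)
})

test_that("scan under the null keeps the significant count small", {
  ds <- generate_dataset(synthetic_spec(n_genes = 200,
                                        snps_per_gene_range = c(15L, 18L),
                                        effect_gene_fraction = 0, seed = 19))
  norm <- normalize_intensities(ds$raw)
  idx <- build_gene_snp_index(ds$snp_map, ds$genes)
  res <- scan_genome(norm, idx, ds$groups)
  expect_equal(nrow(res), 200L)
  expect_true(all(res$p_mean > 0 & res$p_mean <= 1))
  expect_lt(sum(res$bh_significant), 10L)
  expect_equal(nrow(attr(res, "skipped")), 0L)
})

test_that("mean-test p-values are approximately uniform under the complete null", {
  pooled <- unlist(lapply(1:3, function(r) {
    ds <- generate_dataset(synthetic_spec(n_genes = 700,
                                          snps_per_gene_range = c(15L, 18L),
                                          effect_gene_fraction = 0,
                                          seed = 3000 + r))
    norm <- normalize_intensities(ds$raw)
    idx <- build_gene_snp_index(ds$snp_map, ds$genes)
    scan_genome(norm, idx, ds$groups)$p_mean
  }))
  expect_gte(length(pooled), 2000L)
  d <- suppressWarnings(ks.test(pooled, "punif")$statistic)
  expect_lt(unname(d), 0.05)
})

test_that("a scan with zero eligible genes returns empty with a warning", {
  sm <- make_snp_map("M1", "chr1", 50)
  genes <- make_genes("G1", "chr1", 10, 100)
  idx <- build_gene_snp_index(sm, genes)
  norm <- make_norm(matrix(rnorm(4), 1, 4), snps = "M1",
                    samples = sprintf("S%d", 1:4))
  groups <- make_groups(c("S1", "S2"), c("S3", "S4"))
  expect_warning(res <- scan_genome(norm, idx, groups), "no eligible")
  expect_equal(nrow(res), 0L)
})
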