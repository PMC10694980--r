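test_that("load_phased_vcf parses shapes, drops multiallelics, honours regions", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  p <- load_phased_vcf(vcf)
  # 6 records minus the multiallelic one
  expect_equal(dim(p), c(6L, 5L))
  expect_equal(p$sample_ids, c("s1", "s2", "s3"))
  expect_equal(p$pos, c(100L, 200L, 300L, 400L, 150L))
  # phased GT mapping: s2 at v1 is 0|1
  expect_equal(unname(p$alleles[3:4, 1]), c(0L, 1L))
  # missing GT -> NA
  expect_true(all(is.na(p$alleles[1:2, 4])))
  # region subsetting keeps 2 of the chr1 SNPs
  pr <- load_phased_vcf(vcf, region = "chr1:150-350")
  expect_equal(dim(pr), c(6L, 2L))
  expect_equal(pr$pos, c(200L, 300L))
  # empty region is an empty panel, not an error
  expect_equal(ncol(load_phased_vcf(vcf, region = "chr1:1-50")$alleles), 0L)
})

test_that("unphased genotypes are rejected unless acknowledged", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), phased = FALSE)
  expect_error(load_phased_vcf(vcf), "unphased")
  p <- load_phased_vcf(vcf, allow_unphased = TRUE)
  expect_equal(dim(p), c(6L, 5L))
})

test_that("VCF round-trip preserves alleles, positions and sample order", {
  sim <- simulate_panel(sim_config(n_source = 6L, n_control = 6L,
                                   n_recipient = 4L,
                                   chrom_lengths = c(chrA = 2e5),
                                   snp_density = 0.5, seed = 7L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(sim$panel, path)
  back <- load_phased_vcf(path)
  expect_identical(unname(back$alleles), unname(sim$panel$alleles))
  expect_identical(back$pos, sim$panel$pos)
  expect_identical(back$sample_ids, sim$panel$sample_ids)
})

test_that("filter_variants applies strict MAF and missingness rules", {
  # 8 haplotypes; sites engineered for known MAF / missingness
  a <- rbind(
    c(0, 0, 0, 0, 1, 0, NA, 0),
    c(1, 0, 0, 0, 1, 0, NA, 0),
    c(0, 1, 0, 0, 1, 0, 0,  0),
    c(1, 0, 0, 0, 1, 0, 0,  0),
    c(0, 0, 0, 1, 1, 0, 0,  0),
    c(1, 0, 0, 0, 1, 1, 0,  0),
    c(0, 0, 0, 0, 1, 0, 0,  0),
    c(1, 1, 0, 0, 1, 0, 0,  1))
  p <- toy_panel(a)
  # brute-force per-site rule application
  keep_oracle <- logical(8)
  for (j in 1:8) {
    col <- a[, j]
    maf <- min(mean(col, na.rm = TRUE), 1 - mean(col, na.rm = TRUE))
    keep_oracle[j] <- maf > 0.05 && mean(is.na(col)) < 0.1
  }
  f <- filter_variants(p, variant_filter_config(0.05, 0.1))
  expect_equal(f$variant_ids, p$variant_ids[keep_oracle])
  # MAF exactly 0.04 under maf_min 0.05 is removed (strict >)
  a2 <- matrix(0L, nrow = 50, ncol = 1)
  a2[1:2] <- 1L  # MAF 0.04
  expect_warning(f2 <- filter_variants(toy_panel(a2)), "removed")
  expect_equal(ncol(f2$alleles), 0L)
  # monomorphic site removed for any maf_min > 0
  a3 <- cbind(matrix(0L, 8, 1), c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L))
  f3 <- filter_variants(toy_panel(a3), variant_filter_config(0.01, 0.5))
  expect_equal(ncol(f3$alleles), 1L)
})

test_that("filter_variants is idempotent", {
  sim <- simulate_panel(sim_config(n_source = 10L, n_control = 10L,
                                   n_recipient = 6L,
                                   chrom_lengths = c(c1 = 1e5),
                                   snp_density = 1, seed = 3L))
  f1 <- filter_variants(sim$panel)
  f2 <- filter_variants(f1)
  expect_identical(f2$variant_ids, f1$variant_ids)
  expect_identical(unname(f2$alleles), unname(f1$alleles))
})

test_that("make_windows tiles chromosomes exactly", {
  p <- toy_panel(matrix(rep(c(0L, 1L), 4), nrow = 2),
                 pos = c(5000L, 15000L, 24000L, 34900L))
  w <- make_windows(p, size_bp = 10000L, chrom_lengths = c(chr1 = 35000))
  expect_equal(nrow(w), 4L)
  expect_equal(w$start, c(1L, 10001L, 20001L, 30001L))
  expect_equal(w$end, c(10001L, 20001L, 30001L, 40001L))
  expect_equal(w$n_snps, rep(1L, 4))
  # empty window is masked, not dropped
  p2 <- toy_panel(matrix(0L, 2, 2), pos = c(100L, 25000L))
  w2 <- make_windows(p2, 10000L, min_snps = 1L)
  expect_true(w2$masked[2])
  expect_equal(w2$n_snps, c(1L, 0L, 1L))
})

test_that("window spans partition each chromosome (property)", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 200L
    pos <- sort(sample.int(9e4, n))
    p <- toy_panel(matrix(0L, 2, n), pos = pos)
    w <- make_windows(p, size_bp = 7000L)
    # brute-force per-window counts
    cnt <- vapply(seq_len(nrow(w)),
                  function(i) sum(pos >= w$start[i] & pos < w$end[i]), 0L)
    expect_equal(w$n_snps, cnt)
    expect_equal(sum(w$n_snps), n)           # every variant in exactly one
    expect_equal(w$start[-1L], w$end[-nrow(w)])  # no gap, no overlap
  }
})
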