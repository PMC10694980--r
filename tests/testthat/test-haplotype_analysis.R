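region_set <- function(a, groups, pos = NULL) {
  p <- toy_panel(a, pos = pos)
  pm <- data.frame(sample_id = p$sample_ids, group = groups)
  list(panel = p, popmap = pm)
}

test_that("informative_snps keeps only large frequency contrasts", {
  # sites: fixed difference (dp=1), dp=0.5, dp=0.9
  a <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 0L),
             c(1L, 1L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(1L, 0L, 1L))
  rs <- region_set(a, rep(c("A", "B"), each = 2))
  pA <- allele_frequencies(rs$panel, rs$popmap, "A")
  pB <- allele_frequencies(rs$panel, rs$popmap, "B")
  # dp by hand: site1 = 1, site2 = 0.25, site3 = 1
  expect_equal(abs(pA - pB), c(1, 0.25, 1))
  oracle <- which(abs(pA - pB) > 0.8)
  got <- informative_snps(rs$panel, rs$popmap, "A", "B", 0.8)
  expect_identical(got, oracle)
  expect_identical(got, c(1L, 3L))
  expect_length(informative_snps(rs$panel, rs$popmap, "A", "B", 0.2), 3L)
})

test_that("build_haplotype_set collapses, labels and counts correctly", {
  h <- c(0L, 1L, 0L)
  a <- rbind(h, h, h, c(1L, 0L, 1L), h, c(1L, 0L, 1L), c(0L, NA, 0L), h)
  rs <- region_set(a, c("A", "A", "B", "B"), pos = c(10L, 20L, 30L))
  hs <- build_haplotype_set(rs$panel, rs$popmap, "chr1", 1, 100)
  expect_equal(rownames(hs$alleles), c("hap_1", "hap_2"))
  expect_equal(unname(hs$total), c(5L, 2L))      # "010" x5, "101" x2
  expect_equal(hs$n_excluded, 1L)
  expect_equal(unname(hs$counts[, "A"]), c(3L, 1L))
  expect_equal(unname(hs$counts[, "B"]), c(2L, 1L))
  # per-group counts sum to 2 x non-missing individuals
  expect_equal(sum(hs$counts), 2L * 4L - 1L)
  # all-identical region gives a single haplotype
  a2 <- matrix(0L, 4, 2)
  rs2 <- region_set(a2, c("A", "B"), pos = c(10L, 20L))
  hs2 <- build_haplotype_set(rs2$panel, rs2$popmap, "chr1", 1, 100)
  expect_equal(nrow(hs2$alleles), 1L)
  expect_equal(unname(hs2$total), 4L)
  expect_error(build_haplotype_set(rs2$panel, rs2$popmap, "chr1", 900, 999),
               "no SNPs")
})

test_that("heatmap_matrix recodes against the reference group's major allele", {
  # reference group A fixed 0 at both sites; group B carries the complement
  a <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  rs <- region_set(a, c("A", "B"), pos = c(10L, 20L))
  hs <- build_haplotype_set(rs$panel, rs$popmap, "chr1", 1, 100)
  m <- heatmap_matrix(hs, "A")  # rows may be reordered; index by label
  lab_a <- rownames(hs$counts)[hs$counts[, "A"] > 0]
  lab_b <- rownames(hs$counts)[hs$counts[, "B"] > 0]
  expect_true(all(m[lab_a, ] == "major"))
  expect_true(all(m[lab_b, ] == "minor"))
  # hand recode oracle on a mixed toy
  a3 <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 0L), c(1L, 0L))
  rs3 <- region_set(a3, c("A", "B"), pos = c(10L, 20L))
  hs3 <- build_haplotype_set(rs3$panel, rs3$popmap, "chr1", 1, 100)
  m3 <- heatmap_matrix(hs3, "A")
  # A haplotypes: "01" x2 -> site majors: 0 at s1, 1 at s2
  expect_equal(unname(m3["hap_1", ]), c("major", "major"))  # "01"
  expect_error(heatmap_matrix(hs3, "Z"), "unknown")
})

test_that("haplotype_network is a deterministic exact MST", {
  # 2 haplotypes at Hamming distance 3
  a <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  rs <- region_set(a, c("A", "B"), pos = c(10L, 20L, 30L))
  hs <- build_haplotype_set(rs$panel, rs$popmap, "chr1", 1, 100)
  nw <- haplotype_network(hs)
  expect_equal(nrow(nw$edges), 1L)
  expect_equal(nw$edges$weight, 3L)
  # 3 haplotypes, distances 1/1/2: MST keeps the two weight-1 edges
  a2 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 1L), c(0L, 0L),
              c(0L, 1L))
  rs2 <- region_set(a2, c("A", "B", "C"), pos = c(10L, 20L))
  hs2 <- build_haplotype_set(rs2$panel, rs2$popmap, "chr1", 1, 100)
  nw2 <- haplotype_network(hs2)
  expect_equal(sort(nw2$edges$weight), c(1L, 1L))
  expect_equal(nrow(nw2$nodes), 3L)
  # MST total weight equals the exhaustive minimum at n = 7 (Pruefer
  # enumeration; the n = 8 case runs in the acceptance suite)
  set.seed(17)
  a8 <- unique(matrix(sample(0:1, 8 * 12, replace = TRUE), nrow = 8))[1:7, ]
  a8 <- rbind(a8, a8[1, ])               # duplicate collapses -> 7 distinct
  stopifnot(nrow(a8) == 8L)
  p8 <- toy_panel(a8, pos = seq_len(12) * 10L)
  pm8 <- data.frame(sample_id = p8$sample_ids, group = "G")
  hs8 <- build_haplotype_set(p8, pm8, "chr1", 1, 1000)
  nw8 <- haplotype_network(hs8)
  expect_equal(nrow(nw8$edges), nrow(hs8$alleles) - 1L)
  d <- as.matrix(dist(hs8$alleles, method = "manhattan"))
  expect_equal(sum(nw8$edges$weight), mst_weight_oracle(d))
})

test_that("tag_snps finds perfectly separating sites and call_Qq uses them", {
  # 4 haplotypes over 6 sites; haps 1-2 form the Q lineage
  q <- c(0L, 0L, 1L, 0L, 1L, 0L)
  o1 <- c(1L, 0L, 0L, 1L, 0L, 0L)
  o2 <- c(1L, 1L, 0L, 0L, 0L, 1L)
  a <- rbind(q, q, o1, o1, o2, o2, q, o1)
  p <- toy_panel(a, pos = (1:6) * 10L)
  pm <- data.frame(sample_id = p$sample_ids,
                   group = c("TL", "TL", "EUW", "DLW"))
  hs <- build_haplotype_set(p, pm, "chr1", 1, 100)
  qlab <- hs$hap_of_row[1]           # label of the q string
  tg <- tag_snps(hs, qlab, n_tags = 2L, seed = 3L)
  # separating sites are 1 (0 vs 1), 3 (1 vs 0), 5 (1 vs 0)
  expect_true(all(tg$cols %in% c(1L, 3L, 5L)))
  expect_identical(tag_snps(hs, qlab, n_tags = 2L, seed = 3L)$cols, tg$cols)
  calls <- call_Qq(p, tg)
  expect_equal(calls$genotype, c("QQ", "qq", "qq", "Qq"))
  # any perfect tag set yields identical calls
  for (s in 1:5) {
    tg2 <- tag_snps(hs, qlab, n_tags = 2L, seed = s)
    expect_equal(call_Qq(p, tg2)$genotype, calls$genotype)
  }
  # no separating site -> explicit error
  expect_error(tag_snps(hs, rownames(hs$alleles)[c(1, 2)], n_tags = 3L),
               "tag SNP")
})

test_that("Q/q calls match simulator truth for carriers", {
  cfg <- sim_config(n_source = 10L, n_control = 10L, n_recipient = 10L,
                    chrom_lengths = c(c1 = 1e6), mut_rate = 0,
                    n_founders = 2L,
                    tracts = data.frame(chrom = "c1", start = 4e5, end = 7e5,
                                        carrier_fraction = 0.5),
                    seed = 31L)
  sim <- simulate_panel(cfg)
  tr <- sim$truth$carriers[[1]]
  info <- informative_snps(sim$panel, sim$popmap, "source", "control", 0.8)
  info <- intersect(info, tr$snp_cols)
  expect_gte(length(info), 3)  # this fixed world has informative SNPs
  hs <- build_haplotype_set(sim$panel, sim$popmap, "c1", 4e5, 7e5,
                            snps = info)
  qlab <- major_hap <- names(which.max(hs$counts[, "source"]))
  tg <- tag_snps(hs, qlab, n_tags = 2L, seed = 1L)
  calls <- call_Qq(sim$panel, tg)
  # truth: recipient haplotype is Q iff it carries the tract from a donor
  # whose regional haplotype equals the source major haplotype
  hap_is_q <- hs$hap_of_row == qlab
  truth_nq <- tapply(hap_is_q, rep(seq_along(sim$panel$sample_ids), each = 2),
                     sum)
  got <- calls$genotype
  expect_equal(got, c("qq", "Qq", "QQ")[truth_nq + 1L])
})
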