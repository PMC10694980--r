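# Toy fixtures shared across test files; everything is built in code.

# Panel from an explicit haplotype x variant matrix.
toy_panel <- function(alleles, pos = NULL, chrom = NULL, samples = NULL) {
  alleles <- as.matrix(alleles)
  n_var <- ncol(alleles)
  if (is.null(pos)) pos <- seq_len(n_var) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", n_var)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(alleles) / 2L))
  haplotype_panel(alleles, chrom, pos, samples)
}

two_group_popmap <- function(panel, n_a, labels = c("A", "B")) {
  data.frame(sample_id = panel$sample_ids,
             group = rep(labels, c(n_a, length(panel$sample_ids) - n_a)))
}

# Minimal hand-written VCF: 3 samples x 5 phased biallelic SNPs plus one
# multiallelic record and one record with a missing genotype.
write_toy_vcf <- function(path, phased = TRUE) {
  sep <- if (phased) "|" else "/"
  g <- function(a, b) paste0(a, sep, b)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", 100, "v1", "A", "G", ".", "PASS", ".", "GT",
          g(0, 0), g(0, 1), g(1, 1), sep = "\t"),
    paste("chr1", 200, "v2", "C", "T", ".", "PASS", ".", "GT",
          g(0, 1), g(1, 1), g(0, 0), sep = "\t"),
    paste("chr1", 250, "vmulti", "C", "T,G", ".", "PASS", ".", "GT",
          g(0, 2), g(1, 1), g(0, 0), sep = "\t"),
    paste("chr1", 300, "v3", "G", "A", ".", "PASS", ".", "GT",
          g(1, 1), g(0, 0), g(0, 1), sep = "\t"),
    paste("chr1", 400, "v4", "T", "C", ".", "PASS", ".", "GT",
          paste0(".", sep, "."), g(0, 0), g(1, 0), sep = "\t"),
    paste("chr2", 150, "v5", "A", "C", ".", "PASS", ".", "GT",
          g(0, 0), g(0, 0), g(1, 1), sep = "\t"))
  writeLines(lines, path)
  path
}

# Shared heavy simulation for the acceptance tests: one 2 x 10 Mb
# three-population world with three planted 400 kb tracts, scanned once.
.acc_cache <- new.env(parent = emptyenv())
acceptance_scan <- function() {
  if (is.null(.acc_cache$res)) {
    cfg <- sim_config(
      n_source = 50L, n_control = 50L, n_recipient = 40L,
      chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
      tracts = data.frame(chrom = c("chr1", "chr1", "chr2"),
                          start = c(2e6, 6e6, 3e6),
                          end = c(2.4e6, 6.4e6, 3.4e6),
                          carrier_fraction = 0.6),
      seed = 1L)
    sim <- simulate_panel(cfg)
    tab <- ribd_scan(sim$panel, sim$popmap, "recipient", "source", "control",
                     chrom_lengths = cfg$chrom_lengths)
    .acc_cache$res <- list(cfg = cfg, sim = sim, tab = tab)
  }
  .acc_cache$res
}
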