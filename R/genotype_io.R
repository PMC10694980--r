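#' Load a phased VCF into a haplotype panel
#'
#' Reads a VCF 4.x file (plain or gzip) with GT fields and returns a
#' [haplotype_panel()]. Multiallelic records are dropped (the panel stores
#' strictly biallelic 0/1 alleles); missing genotypes become `NA`. Genotypes
#' must be phased (`|` separator) unless `allow_unphased = TRUE`, in which
#' case `/`-separated genotypes are accepted and the caller takes
#' responsibility for the arbitrary haplotype assignment.
#'
#' @param path VCF file path.
#' @param region optional `"chrom:start-end"` string (1-based inclusive);
#'   variants outside it are discarded. A region with zero variants yields an
#'   empty panel, not an error.
#' @param allow_unphased accept `/` genotype separators (default FALSE).
#' @return a `haplotype_panel`.
#' @export
load_phased_vcf <- function(path, region = NULL, allow_unphased = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  # drop multiallelic records (ALT with more than one allele)
  n_alt <- S4Vectors::elementNROWS(rr$ALT)
  keep <- n_alt <= 1L
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]
  pos <- pos[keep]
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- chrom == reg$chrom & pos >= reg$start & pos <= reg$end
    gt <- gt[keep, , drop = FALSE]
    chrom <- chrom[keep]
    pos <- pos[keep]
  }
  samples <- colnames(gt)
  n_var <- nrow(gt)
  if (!allow_unphased && n_var > 0L && any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes present; pass allow_unphased = TRUE to accept")
  # GT strings "a|b" -> two haplotype rows per sample
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_var)
  if (n_var > 0L) {
    for (s in seq_along(samples)) {
      g <- gt[, s]
      sp <- strsplit(g, "[|/]")
      a1 <- vapply(sp, function(x) x[1L], "")
      a2 <- vapply(sp, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")
      alleles[2L * s - 1L, ] <- suppressWarnings(as.integer(a1))
      alleles[2L * s, ] <- suppressWarnings(as.integer(a2))
    }
    alleles[alleles > 1L] <- NA_integer_  # defensive: stray multiallelic codes
  }
  ids <- rownames(gt)
  # VariantAnnotation names rows "chr:pos_REF/ALT"; keep them if unique
  if (is.null(ids) || anyDuplicated(ids))
    ids <- if (n_var) paste0(chrom, ":", pos) else character(0)
  haplotype_panel(alleles, chrom, pos, samples, ids)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("malformed region (expect chrom:start-end): ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with REF=A, ALT=G placeholder alleles and phased GT
#' fields; round-trips exactly through [load_phased_vcf()].
#'
#' @param panel a [haplotype_panel()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$sample_ids), collapse = "\t"), con)
  a <- panel$alleles
  ac <- matrix(as.character(a), nrow = nrow(a))
  ac[is.na(ac)] <- "."
  odd <- ac[seq(1L, nrow(ac), by = 2L), , drop = FALSE]
  evn <- ac[seq(2L, nrow(ac), by = 2L), , drop = FALSE]
  gts <- matrix(paste(odd, evn, sep = "|"), nrow = nrow(odd))
  for (j in seq_along(panel$variant_ids)) {
    writeLines(paste(c(panel$chrom[j], panel$pos[j], panel$variant_ids[j],
                       "A", "G", ".", "PASS", ".", "GT", gts[, j]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Variant filter configuration
#'
#' QC thresholds applied by [filter_variants()]: minor-allele frequency must
#' exceed `maf_min` (strict, "more than"), the missing fraction must be below
#' `max_missing` (strict), and only biallelic sites are kept.
#'
#' @param maf_min minimum minor-allele frequency, in `[0, 0.5]` (default 0.05).
#' @param max_missing maximum missing-genotype fraction, in `[0, 1]`
#'   (default 0.1).
#' @param biallelic_only drop sites that are not strictly biallelic
#'   (default TRUE; panels loaded by this package are already biallelic).
#' @return a `variant_filter_config` list.
#' @export
variant_filter_config <- function(maf_min = 0.05, max_missing = 0.1,
                                  biallelic_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  structure(list(maf_min = maf_min, max_missing = max_missing,
                 biallelic_only = biallelic_only),
            class = "variant_filter_config")
}

#' Apply variant QC filters to a panel
#'
#' Keeps sites with minor-allele frequency strictly greater than
#' `cfg$maf_min` (computed over non-missing alleles) and missing fraction
#' strictly below `cfg$max_missing`. Site order is preserved; the per-rule
#' removal counts are attached as attribute `"removed"`.
#'
#' @param panel a [haplotype_panel()].
#' @param cfg a [variant_filter_config()].
#' @return the filtered `haplotype_panel` (possibly with zero variants).
#' @export
filter_variants <- function(panel, cfg = variant_filter_config()) {
  if (!n_variants(panel)) stop("filter_variants: empty input panel")
  a <- panel$alleles
  n_ok <- colSums(!is.na(a))
  miss_frac <- 1 - n_ok / nrow(a)
  alt <- colSums(a == 1L, na.rm = TRUE)
  p_alt <- ifelse(n_ok > 0, alt / n_ok, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  fail_maf <- is.na(maf) | maf <= cfg$maf_min
  fail_miss <- miss_frac >= cfg$max_missing
  keep <- !fail_maf & !fail_miss
  out <- subset_panel(panel, variants = keep)
  attr(out, "removed") <- c(maf = sum(fail_maf),
                            missing = sum(fail_miss & !fail_maf),
                            multiallelic = 0L)
  if (!n_variants(out))
    warning("all ", n_variants(panel), " sites removed by filters")
  out
}

#' Tile a genome into fixed-size windows
#'
#' Windows are half-open `[start, end)`, tiled from position 1 of each
#' chromosome to cover every variant (and the full `chrom_lengths` when
#' supplied). Windows holding fewer than `min_snps` variants are flagged
#' `masked` rather than dropped, so window grids from different statistics
#' stay alignable.
#'
#' @param panel a [haplotype_panel()].
#' @param size_bp window size in bp (default 10000, the scan bin size).
#' @param min_snps minimum SNP support for an unmasked window (default 1).
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   default: the last variant position per chromosome.
#' @return data.frame with columns `chrom`, `start`, `end`, `first`, `last`
#'   (variant index span; NA when empty), `n_snps`, `masked`.
#' @export
make_windows <- function(panel, size_bp = 10000L, min_snps = 1L,
                         chrom_lengths = NULL) {
  stopifnot(size_bp > 0)
  chroms <- unique(panel$chrom)
  if (!is.null(chrom_lengths)) chroms <- union(chroms, names(chrom_lengths))
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    idx <- which(panel$chrom == ch)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else if (length(idx)) max(panel$pos[idx]) else 0
    n_win <- max(1L, ceiling(len / size_bp))
    start <- 1L + (seq_len(n_win) - 1L) * as.integer(size_bp)
    end <- start + as.integer(size_bp)
    # bin each variant: window w covers positions [1 + (w-1)*size, 1 + w*size)
    if (length(idx)) {
      w <- ((panel$pos[idx] - 1L) %/% size_bp) + 1L
      cnt <- tabulate(w, nbins = n_win)
      first <- rep(NA_integer_, n_win)
      last <- rep(NA_integer_, n_win)
      nz <- which(cnt > 0L)
      cum <- cumsum(cnt)
      last[nz] <- idx[cum[nz]]
      first[nz] <- idx[cum[nz] - cnt[nz] + 1L]
    } else {
      cnt <- integer(n_win); first <- last <- rep(NA_integer_, n_win)
    }
    out[[k]] <- data.frame(chrom = ch, start = start, end = end,
                           first = first, last = last, n_snps = cnt,
                           masked = cnt < min_snps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
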