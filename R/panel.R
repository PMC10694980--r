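#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` is the substrate of every scan in the package: a matrix
#' of phased alleles with one row per haplotype (two consecutive rows per
#' sample) and one column per biallelic SNP, plus chromosome/position metadata.
#' Alleles are coded 0 (reference), 1 (alternate), `NA` (missing).
#'
#' @param alleles integer matrix, `(2 * n_samples) x n_variants`, entries in
#'   `{0, 1, NA}`. Haplotypes of sample `s` occupy rows `2s - 1` and `2s`.
#' @param chrom character vector of chromosome labels, one per variant.
#' @param pos integer vector of 1-based physical positions (bp), strictly
#'   increasing within each chromosome.
#' @param sample_ids character vector of sample identifiers.
#' @param variant_ids optional character vector of unique variant identifiers;
#'   defaults to `chrom:pos`.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, chrom, pos, sample_ids,
                            variant_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_var <- ncol(alleles)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != n_var || length(pos) != n_var)
    stop("chrom/pos length must equal the number of variant columns")
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("allele matrix must have two rows per sample")
  if (is.null(variant_ids))
    variant_ids <- if (n_var) paste0(chrom, ":", pos) else character(0)
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && any(bad != 0L & bad != 1L))
    stop("alleles must be 0, 1 or NA")
  if (n_var > 1L) {
    same <- chrom[-1L] == chrom[-n_var]
    if (any(same & pos[-1L] <= pos[-n_var]))
      stop("positions must be strictly increasing within each chromosome")
  }
  hap_ids <- paste0(rep(sample_ids, each = 2L), c("_1", "_2"))
  dimnames(alleles) <- list(hap_ids, variant_ids)
  structure(list(alleles = alleles, chrom = chrom, pos = pos,
                 sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d samples (%d haplotypes) x %d variants\n",
              length(x$sample_ids), nrow(x$alleles), length(x$variant_ids)))
  for (ch in unique(x$chrom)) {
    i <- x$chrom == ch
    cat(sprintf("  %s: %d SNPs, %d..%d bp\n", ch, sum(i),
                min(x$pos[i]), max(x$pos[i])))
  }
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

n_variants <- function(panel) length(panel$variant_ids)

#' Subset a panel by variant index or by genomic region
#'
#' @param panel a [haplotype_panel()].
#' @param variants integer or logical index over variant columns.
#' @param chrom,start,end optional region filter (1-based, `start`..`end - 1`
#'   inclusive, i.e. half-open `[start, end)`); applied after `variants`.
#' @return a `haplotype_panel`; may contain zero variants (empty-panel signal).
#' @export
subset_panel <- function(panel, variants = NULL, chrom = NULL,
                         start = NULL, end = NULL) {
  keep <- seq_along(panel$variant_ids)
  if (!is.null(variants)) keep <- keep[variants]
  if (!is.null(chrom)) {
    keep <- keep[panel$chrom[keep] == chrom]
    if (!is.null(start)) keep <- keep[panel$pos[keep] >= start]
    if (!is.null(end)) keep <- keep[panel$pos[keep] < end]
  }
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  panel$chrom[keep], panel$pos[keep],
                  panel$sample_ids, panel$variant_ids[keep])
}

#' Read a sample-to-population map
#'
#' Expects a two-column TSV `sample_id<TAB>group` (no header, or a header line
#' starting with `sample`).
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_population_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("sample_id", "group"),
                          colClasses = "character")
  df <- as.data.frame(dt)
  if (nrow(df) && tolower(df$sample_id[1]) %in% c("sample", "sample_id"))
    df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in population map")
  rownames(df) <- NULL
  df
}

#' @rdname read_population_map
#' @param popmap data.frame with columns `sample_id`, `group`.
#' @export
write_population_map <- function(popmap, path) {
  data.table::fwrite(popmap[, c("sample_id", "group")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

# Haplotype row indices of a group; errors on unknown labels or samples
# missing from the map.
hap_rows <- function(panel, popmap, group) {
  ids <- popmap$sample_id[popmap$group == group]
  if (!length(ids)) stop("unknown or empty group label: ", group)
  s <- match(ids, panel$sample_ids)
  s <- s[!is.na(s)]
  if (!length(s)) stop("no panel samples belong to group ", group)
  sort(c(2L * s - 1L, 2L * s))
}

# Genotype dosage matrix (samples x variants), counting ALT alleles; a sample
# with one missing haplotype gets NA for that site.
dosage_matrix <- function(panel) {
  a <- panel$alleles
  odd <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE]
  evn <- a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  d <- odd + evn
  rownames(d) <- panel$sample_ids
  d
}
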