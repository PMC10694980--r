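#' Informative SNPs: large allele-frequency contrasts between two groups
#'
#' Keeps sites where `|p_groupA - p_groupB| > min_abs_diff` (strict), with
#' frequencies computed over non-missing alleles.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap population map.
#' @param groupA,groupB group labels.
#' @param min_abs_diff threshold (default 0.8).
#' @return integer vector of variant column indices.
#' @export
informative_snps <- function(panel, popmap, groupA, groupB,
                             min_abs_diff = 0.8) {
  pA <- allele_frequencies(panel, popmap, groupA)
  pB <- allele_frequencies(panel, popmap, groupB)
  which(!is.na(pA) & !is.na(pB) & abs(pA - pB) > min_abs_diff)
}

#' Build the distinct-haplotype table of a region
#'
#' Haplotypes with any missing allele over the region's (filtered) SNPs are
#' excluded (and counted); the remaining allele strings are collapsed into
#' distinct haplotypes with per-group counts. Labels `hap_1, hap_2, ...`
#' follow descending total frequency, ties broken by first occurrence.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap population map.
#' @param chrom,start,end region (half-open bp interval).
#' @param snps optional variant column indices (e.g. from
#'   [informative_snps()]); intersected with the region.
#' @return a `regional_haplotype_set`: `alleles` (distinct haplotype x SNP
#'   0/1 matrix, rows `hap_1...`), `counts` (haplotype x group matrix),
#'   `total` (named vector), `hap_of_row` (panel haplotype row -> label, NA
#'   for excluded), `snp_cols`, `pos`, `n_excluded`.
#' @export
build_haplotype_set <- function(panel, popmap, chrom, start, end,
                                snps = NULL) {
  cols <- which(panel$chrom == chrom & panel$pos >= start & panel$pos < end)
  if (!is.null(snps)) cols <- intersect(cols, snps)
  if (!length(cols)) stop("region contains no SNPs after filtering")
  a <- panel$alleles[, cols, drop = FALSE]
  complete <- rowSums(is.na(a)) == 0L
  if (!any(complete)) stop("no haplotype without missing data in the region")
  strings <- rep(NA_character_, nrow(a))
  strings[complete] <- apply(a[complete, , drop = FALSE], 1L, paste,
                             collapse = "")
  tot <- table(strings[complete])
  ord <- order(-as.integer(tot),
               match(names(tot), strings))  # ties: first occurrence
  uniq <- names(tot)[ord]
  labels <- paste0("hap_", seq_along(uniq))
  hap_of_row <- labels[match(strings, uniq)]
  grp_of_row <- popmap$group[match(rep(panel$sample_ids, each = 2L),
                                   popmap$sample_id)]
  groups <- unique(popmap$group)
  counts <- matrix(0L, nrow = length(uniq), ncol = length(groups),
                   dimnames = list(labels, groups))
  tab <- table(factor(hap_of_row, levels = labels),
               factor(grp_of_row, levels = groups))
  counts[] <- as.integer(tab)
  amat <- do.call(rbind, lapply(strsplit(uniq, ""), as.integer))
  dimnames(amat) <- list(labels, panel$variant_ids[cols])
  structure(list(alleles = amat, counts = counts,
                 total = stats::setNames(rowSums(counts), labels),
                 hap_of_row = hap_of_row, snp_cols = cols,
                 pos = panel$pos[cols], chrom = chrom,
                 n_excluded = sum(!complete)),
            class = "regional_haplotype_set")
}

#' @export
print.regional_haplotype_set <- function(x, ...) {
  cat(sprintf("regional_haplotype_set: %d distinct haplotypes over %d SNPs (%d haplotype copies excluded for missing data)\n",
              nrow(x$alleles), ncol(x$alleles), x$n_excluded))
  invisible(x)
}

# Most frequent haplotype of a group, ties by hap label order (= first
# occurrence in the frequency-ranked table).
major_haplotype <- function(hset, group) {
  cnt <- hset$counts[, group]
  rownames(hset$counts)[which.max(cnt)]
}

#' Major/minor-coded haplotype matrix relative to a reference group
#'
#' The per-site major allele is defined within `reference_group` (weighted by
#' haplotype frequencies in that group; ties favour the reference allele 0).
#' Rows are haplotypes ordered by dominant group (population-map group
#' order), then descending frequency; columns follow physical position.
#'
#' @param hset a `regional_haplotype_set`.
#' @param reference_group group label defining major alleles.
#' @return character matrix with entries `"major"` / `"minor"`.
#' @export
heatmap_matrix <- function(hset, reference_group) {
  if (!reference_group %in% colnames(hset$counts))
    stop("unknown reference group: ", reference_group)
  w <- hset$counts[, reference_group]
  if (!sum(w)) stop("reference group has no complete haplotype in the region")
  # frequency-weighted ALT count per site within the reference group
  alt_w <- colSums(hset$alleles * w)
  major_allele <- ifelse(alt_w > sum(w) / 2, 1L, 0L)
  m <- ifelse(sweep(hset$alleles, 2L, major_allele, "==") , "major", "minor")
  dom <- colnames(hset$counts)[apply(hset$counts, 1L, which.max)]
  ord <- order(match(dom, colnames(hset$counts)), -hset$total)
  m[ord, , drop = FALSE]
}

#' Minimum-spanning haplotype network
#'
#' Kruskal MST over pairwise Hamming distances between distinct haplotypes;
#' candidate edges are processed in deterministic (weight, smaller index
#' pair) order. Node sizes are the haplotype frequencies.
#'
#' @param hset a `regional_haplotype_set` with >= 2 haplotypes.
#' @return list of class `haplotype_network`: `nodes` (`hap`, `freq`),
#'   `edges` (`from`, `to`, `weight` = Hamming distance >= 1).
#' @export
haplotype_network <- function(hset) {
  n <- nrow(hset$alleles)
  if (n < 2L) stop("need >= 2 distinct haplotypes")
  d <- hamming_matrix(hset$alleles)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- matrix(0L, nrow = n - 1L, ncol = 3L)
  k <- 0L
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      edges[k, ] <- c(i, j, d[i, j])
      if (k == n - 1L) break
    }
  }
  labs <- rownames(hset$alleles)
  structure(list(
    nodes = data.frame(hap = labs, freq = as.integer(hset$total)),
    edges = data.frame(from = labs[edges[seq_len(k), 1L]],
                       to = labs[edges[seq_len(k), 2L]],
                       weight = edges[seq_len(k), 3L])),
    class = "haplotype_network")
}

hamming_matrix <- function(m) {
  # pairwise Hamming distances between 0/1 rows via cross products
  x <- m
  ones <- x %*% t(x)
  zeros <- (1 - x) %*% t(1 - x)
  ncol(m) - ones - zeros
}

#' Select tag SNPs that perfectly separate the Q haplotypes
#'
#' A tag site is one where every haplotype in `q_haplotypes` carries one
#' allele and every other haplotype carries the other. `n_tags` such sites
#' are chosen by seeded random draw; if fewer exist, an error lists the best
#' (least-violated) separating sites.
#'
#' @param hset a `regional_haplotype_set`.
#' @param q_haplotypes character vector of introgressed haplotype labels
#'   (a nonempty strict subset of the haplotypes).
#' @param n_tags number of tag sites (default 2).
#' @param seed integer seed for the random draw.
#' @return list: `cols` (panel variant column indices), `pos`,
#'   `q_allele` (allele the Q haplotypes carry at each tag site).
#' @export
tag_snps <- function(hset, q_haplotypes, n_tags = 2L, seed = 1L) {
  labs <- rownames(hset$alleles)
  if (!length(q_haplotypes) || !all(q_haplotypes %in% labs) ||
      length(q_haplotypes) >= length(labs))
    stop("q_haplotypes must be a nonempty strict subset of the haplotypes")
  inq <- labs %in% q_haplotypes
  aq <- hset$alleles[inq, , drop = FALSE]
  ao <- hset$alleles[!inq, , drop = FALSE]
  q_fixed0 <- colSums(aq) == 0L
  q_fixed1 <- colSums(aq) == nrow(aq)
  o_fixed0 <- colSums(ao) == 0L
  o_fixed1 <- colSums(ao) == nrow(ao)
  sep <- (q_fixed0 & o_fixed1) | (q_fixed1 & o_fixed0)
  if (sum(sep) < n_tags) {
    viol <- pmin(colSums(aq == 0L), colSums(aq == 1L)) +
      pmin(colSums(ao == 0L), colSums(ao == 1L))
    best <- order(viol)[seq_len(min(5L, length(viol)))]
    stop("no ", n_tags, " perfectly separating tag SNPs exist; ",
         "best candidate sites (panel columns): ",
         paste(hset$snp_cols[best], collapse = ", "))
  }
  set.seed(seed)
  pick <- sort(sample(which(sep), n_tags))
  list(cols = hset$snp_cols[pick], pos = hset$pos[pick],
       q_allele = ifelse(q_fixed1[pick], 1L, 0L))
}

#' Call Q/q introgression genotypes from tag SNPs
#'
#' Each of an individual's two haplotypes is labelled Q iff it matches the Q
#' allele at every tag site; the genotype is the unordered pair. Individuals
#' with a missing allele at any tag site are no-calls (`NA`).
#'
#' @param panel a [haplotype_panel()].
#' @param tags tag-SNP list from [tag_snps()] (or a list with `cols` and
#'   `q_allele`).
#' @return data.frame: `individual`, `genotype` in `QQ`/`Qq`/`qq`/`NA`.
#' @export
call_Qq <- function(panel, tags) {
  if (length(tags$cols) != length(tags$q_allele))
    stop("inconsistent tag pattern length")
  a <- panel$alleles[, tags$cols, drop = FALSE]
  is_q <- rowSums(sweep(a, 2L, tags$q_allele, "==")) == length(tags$cols)
  is_q[rowSums(is.na(a)) > 0L] <- NA
  odd <- is_q[seq(1L, length(is_q), by = 2L)]
  evn <- is_q[seq(2L, length(is_q), by = 2L)]
  nq <- odd + evn
  geno <- c("qq", "Qq", "QQ")[nq + 1L]
  data.frame(individual = panel$sample_ids, genotype = geno)
}
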