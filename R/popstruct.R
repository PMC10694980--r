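#' Per-site reference-allele frequencies within a group
#'
#' Missing alleles are excluded from the denominator; sites where the group
#' has no non-missing allele return `NA` (the all-missing flag).
#'
#' @param panel a [haplotype_panel()].
#' @param popmap population map data.frame (`sample_id`, `group`).
#' @param group group label.
#' @return numeric vector of reference-allele (code 0) frequencies, one per
#'   variant.
#' @export
allele_frequencies <- function(panel, popmap, group) {
  rows <- hap_rows(panel, popmap, group)
  a <- panel$alleles[rows, , drop = FALSE]
  n_ok <- colSums(!is.na(a))
  n_ref <- colSums(a == 0L, na.rm = TRUE)
  unname(ifelse(n_ok > 0L, n_ref / n_ok, NA_real_))
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites among sites non-missing in both units. In
#' `unit = "sample"` mode the per-site contribution is
#' `|dosage_i - dosage_j| / 2`, which reduces to the haplotype p-distance for
#' haploid data. Pairs with zero jointly non-missing sites get `NA`.
#'
#' @param panel a [haplotype_panel()].
#' @param unit `"sample"` (genotype dosage) or `"haplotype"`.
#' @return list of class `distance_matrix`: `labels`, `d` (symmetric, zero
#'   diagonal, entries in `[0, 1]` or `NA`).
#' @export
p_distance_matrix <- function(panel, unit = c("sample", "haplotype")) {
  unit <- match.arg(unit)
  if (unit == "sample") {
    m <- dosage_matrix(panel) / 2     # per-site mismatch contribution in [0,1]
    labels <- panel$sample_ids
  } else {
    m <- panel$alleles
    labels <- rownames(panel$alleles)
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 units")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    for (j in (i + 1L):n) {
      ok <- !is.na(xi) & !is.na(m[j, ])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(abs(xi[ok] - m[j, ][ok])) else NA_real_
    }
  }
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative estimated
#' branch lengths are clamped to zero with a warning.
#'
#' @param dm a `distance_matrix` (from [p_distance_matrix()]) or a plain
#'   symmetric matrix with dimnames.
#' @return an \pkg{ape} `phylo` object; use [ape::write.tree()] for Newick.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3L) stop("need at least 3 labels for an unrooted NJ tree")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (anyNA(d)) stop("distance matrix contains undefined (NA) entries")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Principal component analysis of genotype dosages
#'
#' PLINK-style variance-standardized PCA: ALT dosages (0/1/2) are centered by
#' `2 * p_alt` per site and scaled by `sqrt(2 p (1 - p))`; missing dosages are
#' imputed to the site mean (zero after centering). Scores are the left
#' singular vectors scaled by singular values.
#'
#' @param panel a [haplotype_panel()].
#' @param n_components number of components to return (default 10, capped at
#'   the matrix rank bound).
#' @param scale variance-standardize (default TRUE); FALSE gives covariance
#'   PCA on centered dosages.
#' @return list: `scores` (samples x components), `explained` (variance per
#'   component, nonincreasing), `constant` (logical: all-constant input flag).
#' @export
pca_panel <- function(panel, n_components = 10L, scale = TRUE) {
  g <- dosage_matrix(panel)
  if (nrow(g) < 2L || ncol(g) < 2L) stop("need >= 2 samples and >= 2 variants")
  mu <- colMeans(g, na.rm = TRUE)
  x <- sweep(g, 2L, mu)
  x[is.na(x)] <- 0
  if (scale) {
    p <- mu / 2
    sdv <- sqrt(2 * p * (1 - p))
    use <- sdv > 0
    x <- sweep(x[, use, drop = FALSE], 2L, sdv[use], "/")
  } else {
    use <- apply(x, 2L, function(v) any(v != 0))
    x <- x[, use, drop = FALSE]
  }
  if (!ncol(x))
    return(list(scores = matrix(0, nrow(g), 0), explained = numeric(0),
                constant = TRUE))
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(panel$sample_ids, paste0("PC", seq_len(k)))
  list(scores = scores, explained = sv$d^2 / (nrow(x) - 1L),
       constant = FALSE)
}
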