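#' Windowed Hudson Fst between two groups
#'
#' Ratio-of-averages Hudson estimator per window:
#' `Fst = sum(N) / sum(D)` over usable sites, with
#' `N = (pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` and
#' `D = pA(1-pB) + pB(1-pA)`, where `p` is the reference-allele frequency and
#' `n` the non-missing allele count in each group at the site. Sites with
#' fewer than 2 non-missing alleles in either group, or with `D = 0` (both
#' groups fixed for the same allele), are skipped. Windows with no usable
#' site are masked. The reported `fst` column is clamped to `[-0.05, 1]`;
#' `fst_raw` keeps the unclamped ratio.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap population map.
#' @param groupA,groupB group labels (each needs >= 2 haplotypes).
#' @param windows window data.frame from [make_windows()].
#' @return `windows` with added columns `fst_raw`, `fst`, `n_sites_fst`, and
#'   `masked` updated to flag windows without usable sites.
#' @export
window_fst <- function(panel, popmap, groupA, groupB, windows) {
  rows_a <- hap_rows(panel, popmap, groupA)
  rows_b <- hap_rows(panel, popmap, groupB)
  if (length(rows_a) < 2L || length(rows_b) < 2L)
    stop("both groups need >= 2 haplotypes")
  nd <- fst_site_terms(panel, rows_a, rows_b)
  agg <- window_aggregate(windows, panel, nd$usable,
                          list(N = nd$N, D = nd$D))
  fst_raw <- ifelse(agg$n > 0 & agg$D != 0, agg$N / agg$D, NA_real_)
  windows$fst_raw <- fst_raw
  windows$fst <- pmin(pmax(fst_raw, -0.05), 1)
  windows$n_sites_fst <- agg$n
  windows$masked <- windows$masked | agg$n == 0L
  windows
}

# Per-site Hudson N and D terms; usable = both groups informative and D > 0
# or N nonzero (sites fixed identical in both groups carry no information).
fst_site_terms <- function(panel, rows_a, rows_b) {
  fr <- function(rows) {
    a <- panel$alleles[rows, , drop = FALSE]
    n <- colSums(!is.na(a))
    p <- ifelse(n > 0, colSums(a == 0L, na.rm = TRUE) / n, NA_real_)
    list(p = p, n = n)
  }
  A <- fr(rows_a); B <- fr(rows_b)
  pA <- A$p; pB <- B$p; nA <- A$n; nB <- B$n
  N <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  D <- pA * (1 - pB) + pB * (1 - pA)
  usable <- !is.na(N) & !is.na(D) & nA >= 2L & nB >= 2L & D > 0
  list(N = ifelse(usable, N, 0), D = ifelse(usable, D, 0), usable = usable)
}

# Sum named per-site vectors into windows using the first/last index spans.
window_aggregate <- function(windows, panel, usable, terms) {
  n_win <- nrow(windows)
  sums <- lapply(terms, function(t) numeric(n_win))
  n_use <- integer(n_win)
  for (w in seq_len(n_win)) {
    if (is.na(windows$first[w])) next
    span <- windows$first[w]:windows$last[w]
    u <- span[usable[span]]
    n_use[w] <- length(u)
    if (length(u))
      for (nm in names(terms)) sums[[nm]][w] <- sum(terms[[nm]][u])
  }
  c(sums, list(n = n_use))
}

#' Locus-specific branch length for population 1
#'
#' `LSBL_1 = (Fst_12 + Fst_13 - Fst_23) / 2` per window: the component of
#' differentiation specific to population 1's branch in the three-population
#' decomposition. Negative values are meaningful and are not clamped.
#'
#' @param fst_12,fst_13,fst_23 per-window Fst vectors on identical grids.
#' @return per-window LSBL for population 1.
#' @export
lsbl <- function(fst_12, fst_13, fst_23) {
  if (length(fst_12) != length(fst_13) || length(fst_12) != length(fst_23))
    stop("window grids differ in length")
  (fst_12 + fst_13 - fst_23) / 2
}

#' Windowed expected heterozygosity and its genome-wide Z score
#'
#' Per-site expected heterozygosity is `Het = 2 p (1 - p)` with `p` the
#' reference-allele frequency in the group; the window value is the mean over
#' sites with a defined frequency. `zhet` standardizes the window values by
#' the overall (genome-wide, unmasked) mean and standard deviation, so low
#' values flag swept regions.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap population map.
#' @param group group label (>= 2 haplotypes).
#' @param windows window data.frame from [make_windows()].
#' @return `windows` with added columns `het`, `zhet`, `n_sites_het`;
#'   `masked` updated. If the het standard deviation is zero, `zhet` is all
#'   `NA` with a warning.
#' @export
window_zhet <- function(panel, popmap, group, windows) {
  rows <- hap_rows(panel, popmap, group)
  if (length(rows) < 2L) stop("group needs >= 2 haplotypes")
  a <- panel$alleles[rows, , drop = FALSE]
  n <- colSums(!is.na(a))
  p <- ifelse(n > 0, colSums(a == 0L, na.rm = TRUE) / n, NA_real_)
  het_site <- 2 * p * (1 - p)
  usable <- !is.na(het_site)
  agg <- window_aggregate(windows, panel, usable, list(H = het_site))
  het <- ifelse(agg$n > 0, agg$H / agg$n, NA_real_)
  windows$het <- het
  windows$n_sites_het <- agg$n
  windows$masked <- windows$masked | agg$n == 0L
  ok <- !windows$masked & !is.na(het)
  s <- stats::sd(het[ok])
  if (!length(which(ok)) || is.na(s) || s == 0) {
    warning("degenerate het distribution; zhet undefined")
    windows$zhet <- NA_real_
  } else {
    windows$zhet <- ifelse(ok, (het - mean(het[ok])) / s, NA_real_)
  }
  windows
}

#' One-sided Z-test significance mask over windows
#'
#' Standardizes the statistic over unmasked windows and flags those whose
#' one-sided normal tail probability is below `alpha` (`upper` for
#' differentiation statistics like Fst/LSBL, `lower` for heterozygosity
#' sweeps).
#'
#' @param values per-window statistic.
#' @param alpha significance level (default 0.05).
#' @param tail `"upper"` or `"lower"`.
#' @param mask optional logical vector; masked or `NA` windows are never
#'   flagged and are excluded from the standardization.
#' @return logical flag vector (FALSE for masked/NA windows).
#' @export
z_significance <- function(values, alpha = 0.05, tail = c("upper", "lower"),
                           mask = NULL) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  if (!is.null(mask)) ok <- ok & !mask
  if (sum(ok) < 2L) stop("need >= 2 unmasked windows")
  s <- stats::sd(values[ok])
  flag <- rep(FALSE, length(values))
  if (is.na(s) || s == 0) {
    warning("constant statistic; no windows flagged")
    return(flag)
  }
  z <- (values - mean(values[ok])) / s
  crit <- stats::qnorm(1 - alpha)
  flag[ok] <- if (tail == "upper") z[ok] > crit else z[ok] < -crit
  flag
}
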