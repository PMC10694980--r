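#' One-way ANOVA of a quantitative value across genotype groups
#'
#' Classical fixed-effects one-way ANOVA, used here to test whether TNB_EBV
#' differs across Q/q haplotype genotype classes. Empty groups are dropped
#' with a warning (e.g. when no qq individuals exist in a population);
#' `NA` values or groups are dropped.
#'
#' @param values numeric vector (e.g. EBVs).
#' @param groups group label per value (e.g. `QQ`/`Qq`/`qq`).
#' @return list of class `anova_oneway`: `groups` (data.frame `group`, `n`,
#'   `mean`), `F`, `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  tab <- table(groups)
  if (any(tab == 0L)) warning("empty groups dropped")
  keep <- names(tab)[tab > 0L]
  if (length(keep) < 2L) stop("need >= 2 non-empty groups")
  if (any(tab[keep] < 2L))
    warning("groups with a single observation contribute no within variance")
  g <- length(keep)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- as.integer(tab[keep])
  grand <- mean(values)
  ssb <- sum(gn * (gm[keep] - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- g - 1L
  dfw <- n - g
  if (dfw <= 0L) stop("no within-group degrees of freedom")
  Fst <- (ssb / dfb) / (ssw / dfw)
  structure(list(
    groups = data.frame(group = keep, n = gn,
                        mean = as.numeric(gm[keep])),
    F = Fst, df_between = dfb, df_within = dfw,
    p_value = stats::pf(Fst, dfb, dfw, lower.tail = FALSE)),
    class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' FPKM transform of a count matrix
#'
#' `FPKM[g, s] = counts[g, s] / (length_kb[g] * library_size_millions[s])`.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths gene lengths in bp (> 0).
#' @param library_sizes total assigned reads per sample (> 0); defaults to
#'   the column sums of `counts`.
#' @return FPKM matrix with the dimensions and dimnames of `counts`.
#' @export
fpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths length must match rows of counts")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  counts / outer(gene_lengths / 1e3, library_sizes / 1e6)
}

#' Per-gene two-sample t-tests between expression groups
#'
#' Student's pooled-variance t-test by default (Welch via
#' `var_equal = FALSE`), two-sided. Genes with zero variance in both groups
#' and equal means get `t = 0`, `p = 1` and are flagged `degenerate`.
#'
#' @param a,b gene x sample matrices for the two groups (same genes;
#'   >= 2 samples each).
#' @param var_equal pooled variance (default TRUE).
#' @return data.frame: `gene`, `t`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
per_gene_ttest <- function(a, b, var_equal = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("gene sets differ")
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(a))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degen <- se == 0 | is.na(se)
  t <- ifelse(degen, ifelse(ma == mb, 0, Inf * sign(ma - mb)), (ma - mb) / se)
  p <- ifelse(degen & ma == mb, 1,
              2 * stats::pt(abs(t), df, lower.tail = FALSE))
  genes <- rownames(a)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(a)))
  data.frame(gene = genes, t = t, p = p, mean_a = ma, mean_b = mb,
             degenerate = degen, row.names = NULL)
}
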