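#' Top-quantile threshold over unmasked windows
#'
#' The threshold is the `k`-th largest value with `k = max(1,
#' ceiling(top_fraction * n_unmasked))` (the empirical top-`top_fraction`
#' cut, genome-wide); all windows with `stat >= threshold` are flagged, so
#' ties at the threshold may push the flagged count slightly above the
#' nominal fraction.
#'
#' @param values per-window statistic (e.g. rIBD).
#' @param top_fraction flagged upper fraction (default 0.005, the top 0.5%).
#' @param mask optional logical; masked or `NA` windows are never flagged.
#' @return list: `threshold`, `flagged` (logical over all windows).
#' @export
quantile_threshold <- function(values, top_fraction = 0.005, mask = NULL) {
  ok <- !is.na(values)
  if (!is.null(mask)) ok <- ok & !mask
  n <- sum(ok)
  if (!n) stop("no unmasked windows")
  if (n < 1 / top_fraction)
    warning("fewer than 1/top_fraction unmasked windows; threshold is coarse")
  k <- max(1L, ceiling(top_fraction * n))
  thr <- sort(values[ok], decreasing = TRUE)[k]
  flagged <- rep(FALSE, length(values))
  flagged[ok] <- values[ok] >= thr
  list(threshold = thr, flagged = flagged)
}

#' Merge flagged windows into regions
#'
#' Consecutive flagged windows on the same chromosome are merged when the gap
#' between them (`next start - previous end`) is strictly less than
#' `merge_gap_bp`. Masked windows inside a gap neither join nor split beyond
#' their genomic distance. Region statistics aggregate over member (flagged)
#' windows only.
#'
#' @param windows window data.frame (`chrom`, `start`, `end`), sorted by
#'   (chrom, start).
#' @param flagged logical vector over windows.
#' @param stat optional per-window statistic for `mean_stat`/`peak_stat`.
#' @param merge_gap_bp merge distance (default 200000, i.e. "< 200 kb").
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_stat`, `peak_stat`.
#' @export
merge_regions <- function(windows, flagged, stat = NULL,
                          merge_gap_bp = 200000) {
  idx <- which(flagged)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_stat = numeric(), peak_stat = numeric())
  if (!length(idx)) return(empty)
  if (is.null(stat)) stat <- rep(NA_real_, nrow(windows))
  ord <- idx[order(windows$chrom[idx], windows$start[idx])]
  regions <- list(); ri <- 0L
  cur <- ord[1L]
  members <- cur
  for (w in ord[-1L]) {
    same <- windows$chrom[w] == windows$chrom[cur]
    gap <- windows$start[w] - windows$end[cur]
    if (same && gap < merge_gap_bp) {
      members <- c(members, w)
    } else {
      ri <- ri + 1L; regions[[ri]] <- members
      members <- w
    }
    cur <- w
  }
  regions[[ri + 1L]] <- members
  out <- do.call(rbind, lapply(regions, function(m) {
    data.frame(chrom = windows$chrom[m[1L]],
               start = windows$start[m[1L]],
               end = windows$end[m[length(m)]],
               n_windows = length(m),
               mean_stat = mean(stat[m]),
               peak_stat = if (all(is.na(stat[m]))) NA_real_
                           else max(stat[m], na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of the genome covered by called regions
#'
#' @param regions region data.frame from [merge_regions()].
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return `sum(region lengths) / sum(chrom_lengths)`.
#' @export
genome_fraction <- function(regions, chrom_lengths) {
  if (!nrow(regions)) return(0)
  if (any(!regions$chrom %in% names(chrom_lengths)))
    stop("region on a chromosome absent from chrom_lengths")
  if (any(regions$end - 1 > chrom_lengths[regions$chrom] + 1))
    stop("region exceeds chromosome length")
  sum(regions$end - regions$start) / sum(chrom_lengths)
}

#' Physical length of called regions
#'
#' Lengths of half-open `[start, end)` regions, in kb.
#'
#' @param regions region data.frame with `start`, `end` columns.
#' @return numeric vector of lengths in kb.
#' @export
region_lengths_kb <- function(regions) (regions$end - regions$start) / 1000

#' Write regions as BED (0-based half-open)
#'
#' @param regions region data.frame.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end - 1L,
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = regions$mean_stat)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
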