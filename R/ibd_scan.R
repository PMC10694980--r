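#' Detect IBD segments between two haplotype sets
#'
#' Deterministic seed-and-extend identity detector on phased haplotypes (the
#' package's stand-in for an LD-model IBD HMM). For each cross-group
#' haplotype pair the informative sites (non-missing in both) are split into
#' maximal exact-identity runs at mismatching sites. Runs at least as long as
#' the seed length `min(min_snps, ceiling((1/max_mismatch_rate - 1)/2))` act
#' as seeds — any segment that can satisfy both the SNP-support and
#' mismatch-rate requirements must contain such a run — and each seed is
#' extended greedily, rightward then leftward, absorbing neighbouring runs
#' while the running mismatch rate (mismatches / informative SNPs in the
#' span) stays at or below `max_mismatch_rate`. Sites missing in either
#' haplotype are ignored (they neither break a run nor count as support). A
#' segment is reported iff its physical span is at least `min_kb` kb and it
#' is supported by at least `min_snps` informative SNPs.
#'
#' @param panel a [haplotype_panel()].
#' @param rows_a,rows_b integer haplotype row indices of the two groups
#'   (e.g. from the recipient and a donor population); only cross pairs
#'   (a in `rows_a`, b in `rows_b`) are compared.
#' @param min_kb minimum segment length in kb (default 150).
#' @param min_snps minimum SNP support (default 100).
#' @param max_mismatch_rate tolerated mismatch fraction within a segment
#'   (default 0.005).
#' @return data.frame of segments: `hap_a`, `hap_b` (row indices), `chrom`,
#'   `start`, `end` (bp, half-open), `n_snps`, `mismatches`.
#' @export
detect_ibd_segments <- function(panel, rows_a, rows_b, min_kb = 150,
                                min_snps = 100L, max_mismatch_rate = 0.005) {
  if (min_kb <= 0) stop("min_kb must be positive")
  if (length(intersect(rows_a, rows_b)))
    stop("rows_a and rows_b must be disjoint (cross-group pairs only)")
  min_bp <- min_kb * 1000
  seed_len <- seed_run_length(min_snps, max_mismatch_rate)
  out <- list(); oi <- 0L
  for (ch in unique(panel$chrom)) {
    cols <- which(panel$chrom == ch)
    pos <- panel$pos[cols]
    A <- panel$alleles[rows_a, cols, drop = FALSE]
    B <- panel$alleles[rows_b, cols, drop = FALSE]
    for (ia in seq_along(rows_a)) {
      a <- A[ia, ]
      a_ok <- !is.na(a)
      for (ib in seq_along(rows_b)) {
        b <- B[ib, ]
        ok <- which(a_ok & !is.na(b))
        if (length(ok) < min_snps) next
        segs <- ibd_pair_segments(a[ok] != b[ok], max_mismatch_rate,
                                  seed_len)
        if (is.null(segs)) next
        # segs columns: first, last (indices into ok), n_snps, mismatches
        st <- pos[ok[segs[, 1L]]]
        en <- pos[ok[segs[, 2L]]] + 1L
        keep <- (en - st) >= min_bp & segs[, 3L] >= min_snps
        if (!any(keep)) next
        oi <- oi + 1L
        out[[oi]] <- data.frame(hap_a = rows_a[ia], hap_b = rows_b[ib],
                                chrom = ch, start = st[keep], end = en[keep],
                                n_snps = segs[keep, 3L],
                                mismatches = segs[keep, 4L])
      }
    }
  }
  if (!oi)
    return(data.frame(hap_a = integer(), hap_b = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), mismatches = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Shortest exact run any reportable segment must contain: with m >= 1
# mismatches a segment needs n >= m/rate SNPs, whose n - m matches split
# into m + 1 runs, so the longest run is >= (1/rate - 1)/2; with m = 0 the
# whole segment is one run of >= min_snps.
seed_run_length <- function(min_snps, max_rate) {
  bound <- if (max_rate > 0) ceiling((1 / max_rate - 1) / 2) else Inf
  max(1L, min(as.integer(min_snps), as.integer(min(bound, .Machine$integer.max))))
}

# Seed-and-extend on a logical mismatch vector over informative sites.
# Returns a matrix (first, last, n_snps, mismatches) in informative-site
# coordinates, or NULL. Deterministic and symmetric in the pair.
ibd_pair_segments <- function(mism, max_rate, seed_len) {
  n <- length(mism)
  mpos <- which(mism)
  if (!length(mpos)) {
    return(matrix(c(1L, n, n, 0L), nrow = 1L))
  }
  run_len <- diff(c(0L, mpos, n + 1L)) - 1L  # exact runs, incl. empty
  if (max(run_len) < seed_len) return(NULL)
  run_start <- c(1L, mpos + 1L)
  run_end <- c(mpos - 1L, n)
  keep <- run_len > 0L
  run_start <- run_start[keep]; run_end <- run_end[keep]
  run_len <- run_len[keep]
  n_runs <- length(run_len)
  seeds <- which(run_len >= seed_len)
  segs <- matrix(0L, nrow = length(seeds), ncol = 4L)
  k <- 0L
  floor_run <- 0L  # last run consumed by a previous segment
  for (s in seeds) {
    if (s <= floor_run) next  # absorbed by the previous extension
    i0 <- i1 <- s
    snps <- run_len[s]; mm <- 0L
    while (i1 < n_runs) {  # rightward
      gap_mm <- run_start[i1 + 1L] - run_end[i1] - 1L
      new_mm <- mm + gap_mm
      new_snps <- snps + gap_mm + run_len[i1 + 1L]
      if (new_mm / new_snps > max_rate) break
      mm <- new_mm; snps <- new_snps; i1 <- i1 + 1L
    }
    while (i0 > floor_run + 1L) {  # leftward, not crossing prior segments
      gap_mm <- run_start[i0] - run_end[i0 - 1L] - 1L
      new_mm <- mm + gap_mm
      new_snps <- snps + gap_mm + run_len[i0 - 1L]
      if (new_mm / new_snps > max_rate) break
      mm <- new_mm; snps <- new_snps; i0 <- i0 - 1L
    }
    k <- k + 1L
    segs[k, ] <- c(run_start[i0], run_end[i1], snps, mm)
    floor_run <- i1
  }
  if (!k) return(NULL)
  segs[seq_len(k), , drop = FALSE]
}

#' Count per-bin IBD sharing (cIBD, tIBD, nIBD)
#'
#' A haplotype pair counts toward a bin's `cIBD` when any of its segments
#' overlaps the bin by at least 1 bp (no proration); a pair never counts twice
#' in one bin. `tIBD` is the constant pair universe
#' `length(rows_a) * length(rows_b)`.
#'
#' @param segments segment data.frame from [detect_ibd_segments()].
#' @param bins window data.frame (`chrom`, `start`, `end`), e.g. from
#'   [make_windows()] with 10 kb bins.
#' @param rows_a,rows_b the haplotype row universes the segments were
#'   computed over.
#' @return `bins` with added columns `cIBD`, `tIBD`, `nIBD`.
#' @export
bin_ibd <- function(segments, bins, rows_a, rows_b) {
  t_ibd <- length(rows_a) * length(rows_b)
  cibd <- integer(nrow(bins))
  if (nrow(segments)) {
    if (!all(segments$hap_a %in% rows_a) || !all(segments$hap_b %in% rows_b))
      stop("segment references a haplotype outside the given universes")
    keys <- character(0)
    bin_idx <- integer(0)
    for (ch in unique(segments$chrom)) {
      bi <- which(bins$chrom == ch)
      si <- which(segments$chrom == ch)
      if (!length(bi)) next
      for (s in si) {
        ov <- bi[bins$start[bi] < segments$end[s] &
                   bins$end[bi] > segments$start[s]]
        if (length(ov)) {
          keys <- c(keys, paste(segments$hap_a[s], segments$hap_b[s], ov))
          bin_idx <- c(bin_idx, ov)
        }
      }
    }
    if (length(keys)) {
      first <- !duplicated(keys)
      cibd <- tabulate(bin_idx[first], nbins = nrow(bins))
    }
  }
  bins$cIBD <- cibd
  bins$tIBD <- t_ibd
  bins$nIBD <- if (t_ibd > 0) cibd / t_ibd else NA_real_
  bins
}

#' Relative IBD: excess sharing with the candidate donor
#'
#' `rIBD = nIBD_source - nIBD_control` per bin; positive values indicate
#' excess haplotype sharing with the candidate donor group (the introgression
#' signal), and values lie in `[-1, 1]` by construction.
#'
#' @param nibd_source,nibd_control numeric per-bin nIBD vectors on identical
#'   bin grids.
#' @return numeric per-bin rIBD.
#' @export
ribd <- function(nibd_source, nibd_control) {
  if (length(nibd_source) != length(nibd_control))
    stop("bin grids differ in length")
  nibd_source - nibd_control
}

#' End-to-end rIBD scan
#'
#' Detects IBD segments between the recipient and each donor group, bins the
#' sharing per `bin_bp` and returns the per-bin sharing table with `rIBD`.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap population map.
#' @param recipient,source,control group labels.
#' @param bin_bp bin size (default 10000 bp).
#' @param chrom_lengths optional chromosome lengths for the bin grid.
#' @inheritParams detect_ibd_segments
#' @return data.frame: `chrom`, `start`, `end`, `cIBD_source`,
#'   `nIBD_source`, `cIBD_control`, `nIBD_control`, `tIBD_source`,
#'   `tIBD_control`, `rIBD`.
#' @export
ribd_scan <- function(panel, popmap, recipient, source, control,
                      bin_bp = 10000L, min_kb = 150, min_snps = 100L,
                      max_mismatch_rate = 0.005, chrom_lengths = NULL) {
  rcp <- hap_rows(panel, popmap, recipient)
  src <- hap_rows(panel, popmap, source)
  ctl <- hap_rows(panel, popmap, control)
  bins <- make_windows(panel, size_bp = bin_bp, min_snps = 1L,
                       chrom_lengths = chrom_lengths)
  seg_s <- detect_ibd_segments(panel, rcp, src, min_kb, min_snps,
                               max_mismatch_rate)
  seg_c <- detect_ibd_segments(panel, rcp, ctl, min_kb, min_snps,
                               max_mismatch_rate)
  bs <- bin_ibd(seg_s, bins, rcp, src)
  bc <- bin_ibd(seg_c, bins, rcp, ctl)
  out <- bins[, c("chrom", "start", "end", "n_snps", "masked")]
  out$cIBD_source <- bs$cIBD
  out$tIBD_source <- bs$tIBD
  out$nIBD_source <- bs$nIBD
  out$cIBD_control <- bc$cIBD
  out$tIBD_control <- bc$tIBD
  out$nIBD_control <- bc$nIBD
  out$rIBD <- ribd(bs$nIBD, bc$nIBD)
  attr(out, "segments") <- list(source = seg_s, control = seg_c)
  out
}
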