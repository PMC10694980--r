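#' Simulation configuration for the three-population panel generator
#'
#' Describes the stated world the simulator emulates: a candidate donor pool
#' ("source", the Asian-lineage stand-in), a background pool ("control", the
#' European-wild stand-in) diverged from it, and a "recipient" population
#' built as recombinant mosaics of control haplotypes into which introgressed
#' tracts copied from source haplotypes are planted.
#'
#' @param n_source,n_control,n_recipient haplotype counts per group (must be
#'   even; two haplotypes per sample).
#' @param chrom_lengths named or unnamed numeric vector of chromosome lengths
#'   in bp.
#' @param snp_density SNPs per kb (default 1).
#' @param divergence drift parameter (Balding-Nichols F) separating the source
#'   and control allele-frequency profiles from their shared ancestral profile;
#'   default 0.2, giving strong but realistic between-lineage differentiation.
#' @param tracts data.frame with columns `chrom`, `start`, `end`,
#'   `carrier_fraction` describing planted introgressed tracts (half-open bp
#'   intervals). `carrier_fraction` is realized exactly:
#'   `round(f * n_recipient)` recipient haplotypes carry each tract.
#' @param n_founders distinct founder haplotypes per pool (default 10):
#'   source and control haplotypes are crossover mosaics of their pool's
#'   founders, so each pool carries realistic within-population IBD sharing
#'   instead of site-wise independent haplotypes.
#' @param recomb_shuffle expected crossovers per Mb per recipient haplotype
#'   when building the control-derived mosaic (default 0.5, i.e. ~2 Mb
#'   ancestry blocks — on the order of 50 generations of backcrossing).
#' @param founder_recomb expected crossovers per Mb when building pool
#'   haplotypes from their founders (default 0.1, i.e. very long within-pool
#'   IBD blocks as in strongly bottlenecked livestock lines; long blocks
#'   also keep the deterministic IBD detector in its high-sensitivity
#'   regime).
#' @param mut_rate per-site flip probability applied to recipient haplotypes
#'   after copying (default 0.001), so IBD detection must tolerate rare
#'   mismatches.
#' @param group_names length-3 character vector naming the source, control
#'   and recipient groups in the emitted population map.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_source = 50L, n_control = 50L, n_recipient = 40L,
                       chrom_lengths = c(chr1 = 10e6),
                       snp_density = 1, divergence = 0.2,
                       tracts = NULL, n_founders = 10L, recomb_shuffle = 0.5,
                       founder_recomb = 0.1, mut_rate = 0.001,
                       group_names = c("source", "control", "recipient"),
                       seed = 1L) {
  stopifnot(n_source %% 2 == 0, n_control %% 2 == 0, n_recipient %% 2 == 0,
            snp_density > 0, divergence >= 0, divergence <= 1,
            n_founders >= 2, recomb_shuffle >= 0, founder_recomb >= 0,
            mut_rate >= 0, mut_rate < 1,
            length(group_names) == 3)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (is.null(tracts)) {
    tracts <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), carrier_fraction = numeric())
  } else {
    stopifnot(all(c("chrom", "start", "end", "carrier_fraction") %in%
                    names(tracts)))
    if (any(!tracts$chrom %in% names(chrom_lengths)))
      stop("tract on unknown chromosome")
    if (any(tracts$start < 1 | tracts$end > chrom_lengths[tracts$chrom] + 1))
      stop("tract outside chromosome bounds")
    if (any(tracts$carrier_fraction < 0 | tracts$carrier_fraction > 1))
      stop("carrier_fraction must be in [0, 1]")
  }
  structure(list(n_source = as.integer(n_source),
                 n_control = as.integer(n_control),
                 n_recipient = as.integer(n_recipient),
                 chrom_lengths = chrom_lengths, snp_density = snp_density,
                 divergence = divergence, tracts = tracts,
                 n_founders = as.integer(n_founders),
                 recomb_shuffle = recomb_shuffle,
                 founder_recomb = founder_recomb, mut_rate = mut_rate,
                 group_names = group_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a three-population phased panel with planted introgressed tracts
#'
#' Each pool has `n_founders` founder haplotypes drawn site-wise from a
#' pool-specific allele-frequency profile (Balding-Nichols drift from a
#' shared ancestral profile); pool haplotypes are crossover mosaics of their
#' pool's founders, so both pools carry genuine within-population IBD
#' sharing. Recipient haplotypes are crossover mosaics of the emitted
#' control haplotypes — sharing long IBD segments with the control pool —
#' except inside planted tracts, where carrier haplotypes are copied from a
#' randomly chosen source haplotype. A small per-site mutation rate is
#' applied to recipient haplotypes afterwards.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `panel` ([haplotype_panel()]), `popmap`
#'   (data.frame `sample_id`, `group`) and `truth` (list: `tracts` with donor
#'   bookkeeping, `carriers` — per tract the carrier haplotype rows and donor
#'   rows, `p_source`, `p_control` per-site reference-allele frequencies used).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  gn <- cfg$group_names
  n_src <- cfg$n_source; n_ctl <- cfg$n_control; n_rcp <- cfg$n_recipient
  chrom_all <- character(0); pos_all <- integer(0)
  mats <- list()
  p_src_all <- numeric(0); p_ctl_all <- numeric(0)
  carriers <- vector("list", nrow(cfg$tracts))
  col_off <- 0L
  for (ch in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[ch]]
    n_snp <- max(2L, round(len / 1000 * cfg$snp_density))
    pos <- sort(sample.int(len, n_snp))
    p_anc <- runif(n_snp, 0.05, 0.95)
    Fdr <- cfg$divergence
    draw_pool <- function(p) {
      if (Fdr == 0) return(p)
      stats::rbeta(length(p), p * (1 - Fdr) / Fdr, (1 - p) * (1 - Fdr) / Fdr)
    }
    p_src <- draw_pool(p_anc)  # reference-allele frequencies
    p_ctl <- draw_pool(p_anc)
    draw_haps <- function(n, p) {
      # allele 1 (ALT) with probability 1 - p
      matrix(stats::rbinom(n * length(p), 1L, rep(1 - p, each = n)),
             nrow = n, byrow = FALSE)
    }
    # pool haplotypes: balanced founder mosaics — founder lineages are held
    # at (near-)equal frequency at every locus by realizing recombination as
    # template swaps between two haplotypes, so within-pool IBD sharing
    # multiplicity is constant along the genome (drift-balanced pool)
    balanced_mosaic <- function(n, templates, rate) {
      K <- nrow(templates)
      cur <- sample(rep_len(seq_len(K), n))
      n_ev <- stats::rpois(1L, rate * len / 1e6 * n / 2)
      events <- sort(sample.int(len, min(n_ev, len)))
      m <- matrix(0L, nrow = n, ncol = n_snp)
      seg_start <- c(1, events)
      seg_end <- c(events, len + 1)
      for (s in seq_along(seg_start)) {
        j <- which(pos >= seg_start[s] & pos < seg_end[s])
        if (length(j)) m[, j] <- templates[cur, j]
        if (s <= length(events)) {
          pair <- sample.int(n, 2L)
          cur[pair] <- cur[rev(pair)]
        }
      }
      m
    }
    # recipients: per-haplotype crossover mosaics of random control
    # haplotypes (recent admixture from sampled individuals)
    mosaic <- function(n, templates, rate) {
      m <- matrix(0L, nrow = n, ncol = n_snp)
      exp_x <- rate * len / 1e6
      for (h in seq_len(n)) {
        brk <- sort(sample.int(len, stats::rpois(1L, exp_x)))
        seg_start <- c(1, brk)
        seg_end <- c(brk, len + 1)
        for (s in seq_along(seg_start)) {
          j <- which(pos >= seg_start[s] & pos < seg_end[s])
          if (length(j))
            m[h, j] <- templates[sample.int(nrow(templates), 1L), j]
        }
      }
      m
    }
    src <- balanced_mosaic(n_src, draw_haps(cfg$n_founders, p_src),
                           cfg$founder_recomb)
    ctl <- balanced_mosaic(n_ctl, draw_haps(cfg$n_founders, p_ctl),
                           cfg$founder_recomb)
    rcp <- mosaic(n_rcp, ctl, cfg$recomb_shuffle)
    # plant tracts on this chromosome
    tr_idx <- which(cfg$tracts$chrom == ch)
    for (ti in tr_idx) {
      tr <- cfg$tracts[ti, ]
      j <- which(pos >= tr$start & pos < tr$end)
      n_car <- round(tr$carrier_fraction * n_rcp)
      car <- if (n_car > 0) sort(sample.int(n_rcp, n_car)) else integer(0)
      don <- if (n_car > 0) sample.int(n_src, n_car, replace = TRUE) else integer(0)
      for (k in seq_along(car)) rcp[car[k], j] <- src[don[k], j]
      carriers[[ti]] <- list(chrom = ch, start = tr$start, end = tr$end,
                             carrier_hap = col_off_free(car), donor_hap = don,
                             snp_cols = j + col_off)
    }
    # recipient mutations
    if (cfg$mut_rate > 0) {
      flip <- matrix(stats::runif(n_rcp * n_snp) < cfg$mut_rate,
                     nrow = n_rcp)
      rcp[flip] <- 1L - rcp[flip]
    }
    mats[[ch]] <- rbind(src, ctl, rcp)
    chrom_all <- c(chrom_all, rep(ch, n_snp))
    pos_all <- c(pos_all, pos)
    p_src_all <- c(p_src_all, p_src)
    p_ctl_all <- c(p_ctl_all, p_ctl)
    col_off <- col_off + n_snp
  }
  alleles <- do.call(cbind, mats)
  sample_ids <- c(sprintf("src_%02d", seq_len(n_src / 2L)),
                  sprintf("ctl_%02d", seq_len(n_ctl / 2L)),
                  sprintf("rcp_%02d", seq_len(n_rcp / 2L)))
  panel <- haplotype_panel(alleles, chrom_all, pos_all, sample_ids)
  popmap <- data.frame(
    sample_id = sample_ids,
    group = rep(gn, c(n_src / 2L, n_ctl / 2L, n_rcp / 2L)))
  # carrier haplotype rows in panel coordinates (recipients come last)
  rcp_row0 <- n_src + n_ctl
  for (ti in seq_along(carriers)) {
    if (!is.null(carriers[[ti]])) {
      carriers[[ti]]$carrier_row <- rcp_row0 + carriers[[ti]]$carrier_hap
      carriers[[ti]]$donor_row <- carriers[[ti]]$donor_hap
    }
  }
  truth <- list(tracts = cfg$tracts, carriers = carriers,
                p_source = p_src_all, p_control = p_ctl_all,
                recipient_rows = rcp_row0 + seq_len(n_rcp),
                source_rows = seq_len(n_src),
                control_rows = n_src + seq_len(n_ctl))
  list(panel = panel, popmap = popmap, truth = truth)
}

# identity helper kept for clarity of carrier bookkeeping
col_off_free <- function(x) x

#' Simulate pedigreed sows with repeated litter-size records
#'
#' Founder sires/dams and mating boars are unrelated non-inbred animals; each
#' sow is an offspring of one founder sire and one founder dam, with breeding
#' value = parent average + Mendelian sampling. Each record is
#' `y = mu + parity + year-season + boar + PE + BV + q_effect * nQ + residual`,
#' with variance fractions of the phenotypic variance `sigma_p2` given by
#' `h2` (additive), `pe_frac` (permanent environment) and `boar_frac`
#' (mating-boar service effect). The Q-allele count `nQ` per sow is drawn
#' `Binomial(2, q_freq)` independently of the pedigree.
#'
#' @param n_sows number of phenotyped sows.
#' @param parities_per_sow records per sow (default 3).
#' @param h2 narrow-sense heritability of a single record (default 0.1,
#'   litter-size-like).
#' @param pe_frac,boar_frac permanent-environment and mating-boar variance
#'   fractions (defaults 0.05 and 0.03). `h2 + pe_frac + boar_frac < 1`.
#' @param q_effect additive phenotype effect per Q allele (litter units).
#' @param q_freq Q allele frequency.
#' @param seed integer seed.
#' @param sigma_p2 total phenotypic variance (default 10, TNB-like).
#' @param mean_tnb trait mean (default 14 piglets).
#' @return list: `pedigree` (`id`, `sire`, `dam`; `NA` = unknown),
#'   `phenotypes` (`sow`, `parity`, `yearseason`, `boar`, `tnb`),
#'   `true_bv` (named, all pedigree animals), `q_genotype` (data.frame
#'   `sow`, `nQ`, `genotype` in QQ/Qq/qq).
#' @export
simulate_pedigree_phenotypes <- function(n_sows, parities_per_sow = 3L,
                                         h2 = 0.1, pe_frac = 0.05,
                                         boar_frac = 0.03, q_effect = 0,
                                         q_freq = 0.3, seed = 1L,
                                         sigma_p2 = 10, mean_tnb = 14) {
  if (h2 < 0 || pe_frac < 0 || boar_frac < 0 || h2 + pe_frac + boar_frac >= 1)
    stop("invalid variance fractions: need h2 + pe_frac + boar_frac < 1")
  set.seed(seed)
  s_u <- h2 * sigma_p2; s_p <- pe_frac * sigma_p2
  s_m <- boar_frac * sigma_p2
  s_e <- (1 - h2 - pe_frac - boar_frac) * sigma_p2
  n_fs <- max(2L, round(n_sows / 10))
  n_fd <- max(2L, round(n_sows / 4))
  n_bo <- max(2L, round(n_sows / 20))
  sires <- sprintf("S%03d", seq_len(n_fs))
  dams <- sprintf("D%03d", seq_len(n_fd))
  boars <- sprintf("B%03d", seq_len(n_bo))
  sows <- sprintf("W%04d", seq_len(n_sows))
  sow_sire <- sample(sires, n_sows, replace = TRUE)
  sow_dam <- sample(dams, n_sows, replace = TRUE)
  ped <- data.frame(
    id = c(sires, dams, boars, sows),
    sire = c(rep(NA, n_fs + n_fd + n_bo), sow_sire),
    dam = c(rep(NA, n_fs + n_fd + n_bo), sow_dam))
  bv <- c(stats::rnorm(n_fs + n_fd + n_bo, 0, sqrt(s_u)))
  names(bv) <- c(sires, dams, boars)
  bv_sow <- 0.5 * (bv[sow_sire] + bv[sow_dam]) +
    stats::rnorm(n_sows, 0, sqrt(0.5 * s_u))
  names(bv_sow) <- sows
  bv <- c(bv, bv_sow)
  boar_eff <- stats::rnorm(n_bo, 0, sqrt(s_m)); names(boar_eff) <- boars
  pe <- stats::rnorm(n_sows, 0, sqrt(s_p)); names(pe) <- sows
  nQ <- stats::rbinom(n_sows, 2L, q_freq)
  parity_eff <- c(0, 0.6, 0.9, 1.0, 0.8, 0.6, 0.4, 0.2, 0, 0)
  ys_eff <- c(0, -0.3, 0.2, 0.4)
  recs <- expand.grid(parity = seq_len(parities_per_sow),
                      sow = seq_len(n_sows))
  n_rec <- nrow(recs)
  ys <- sample.int(4L, n_rec, replace = TRUE)
  bo <- sample.int(n_bo, n_rec, replace = TRUE)
  y <- mean_tnb +
    parity_eff[pmin(recs$parity, length(parity_eff))] +
    ys_eff[ys] + boar_eff[bo] + pe[recs$sow] + bv_sow[recs$sow] +
    q_effect * nQ[recs$sow] + stats::rnorm(n_rec, 0, sqrt(s_e))
  phen <- data.frame(sow = sows[recs$sow], parity = recs$parity,
                     yearseason = paste0("ys", ys), boar = boars[bo],
                     tnb = y)
  qg <- data.frame(sow = sows, nQ = nQ,
                   genotype = c("qq", "Qq", "QQ")[nQ + 1L])
  list(pedigree = ped, phenotypes = phen, true_bv = bv, q_genotype = qg,
       variance_components = variance_components(s_u, s_m, s_p, s_e))
}
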