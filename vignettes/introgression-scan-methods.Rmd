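---
title: "Methods: IBD-based introgression scanning, selection statistics and haplotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD-based introgression scanning, selection statistics and haplotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

# The problem

Commercial pig lines such as the Danish Large White carry chromosomal
segments inherited from Asian domestic pigs, introduced during the 18th–19th
century breed formation and retained where they were favourable — notably
for litter size. `introscan` implements a desk-scale, fully tested version
of the genome-scan workflow used to find such segments and connect them to
breeding values:

1. detect identity-by-descent (IBD) segments between the haplotypes of a
   *recipient* population (e.g. Danish Large White), a candidate *source*
   (e.g. Taihu-lake-region breeds) and a *control* donor (e.g. European wild
   boar);
2. summarize sharing per 10 kb bin as `nIBD = cIBD / tIBD` and contrast the
   two donors by `rIBD = nIBD_source − nIBD_control ∈ [−1, 1]`;
3. call introgressed regions as the top 0.5% of bins, merging flagged bins
   closer than 200 kb;
4. corroborate regions with selection statistics (windowed Hudson Fst,
   locus-specific branch length `LSBL₁ = (Fst₁₂ + Fst₁₃ − Fst₂₃)/2`, and
   Z-transformed expected heterozygosity `Het = 2p(1−p)`);
5. characterize the region's haplotypes (frequency table, major/minor heat
   map, minimum-spanning network on |Δp| > 0.8 SNPs), define the introgressed
   *Q* haplotype as the source population's major haplotype, and genotype
   individuals QQ/Qq/qq via two perfectly separating tag SNPs;
6. estimate breeding values for total number born (TNB) with a
   repeated-records pedigree animal model solved by Henderson's mixed-model
   equations, and test EBV differences across Q/q genotype classes by
   one-way ANOVA.

# IBD detection: a deterministic substitute

The original analysis used an LD-model hidden-Markov IBD caller. That model
is deliberately *not* re-implemented. On phased haplotypes with planted
ground truth, a transparent detector is preferable for testability: for each
cross-group haplotype pair, sites missing in either haplotype are ignored,
the remaining sites are split into maximal exact-identity runs, and runs at
least as long as

\[
\text{seed} = \min\left(\texttt{min\_snps},\;
 \left\lceil \tfrac{1/\texttt{max\_mismatch\_rate} - 1}{2} \right\rceil\right)
\]

are extended greedily (right, then left), absorbing neighbouring runs while
the segment-wide mismatch rate stays ≤ `max_mismatch_rate`. The seed bound
is exact, not heuristic: any segment satisfying both the SNP-support and
mismatch-rate constraints must contain such a run, so seeding loses nothing.
Defaults: `min_kb = 150` (the upstream tool's segment length setting),
`min_snps = 100`, `max_mismatch_rate = 0.005`. The mismatch tolerance was
fixed a priori at five mismatches per 1,000 SNPs: comfortably above the
simulator's 0.001 per-site mutation rate, far below the ≈0.2–0.5 per-site
mismatch rate of unrelated cross-population haplotypes, which therefore can
never chain into a 150 kb segment.

Counting follows the sharing statistic's definition: a pair contributes to a
bin's `cIBD` if any of its segments overlaps the bin by ≥ 1 bp (no
proration, no double counting), and `tIBD` is the full haplotype-pair
universe — missingness never shrinks the denominator. The pair universe is
haplotype-level (2n × 2m), matching the statistic's description of counting
haplotypes.

# What the simulator emulates — and what it does not

`simulate_panel()` builds a stated world with known truth:

* **Pools.** Source and control pools each descend from `n_founders = 10`
  founder haplotypes drawn site-wise from pool-specific allele-frequency
  profiles; the profiles derive from a common ancestral profile by
  Balding–Nichols drift with `divergence = 0.2`, giving between-pool
  differentiation of the magnitude seen between Asian and European pig
  lineages. Pool haplotypes are *balanced founder mosaics*: recombination is
  realized as template swaps between two haplotypes, so every founder
  lineage keeps an equal copy number at every locus. This gives each pool
  realistic, constant-intensity within-population IBD sharing — the
  property the nIBD statistic actually consumes. `founder_recomb = 0.1`
  crossovers/Mb gives multi-Mb within-pool IBD blocks, as in strongly
  bottlenecked livestock lines; long blocks also keep the deterministic
  detector in its high-sensitivity regime (a 150 kb minimum segment is
  small relative to the blocks).
* **Recipients.** Crossover mosaics of the emitted control haplotypes
  (`recomb_shuffle = 0.5`/Mb ≈ 2 Mb blocks, on the order of 50 generations
  of backcrossing), so recipients genuinely share long IBD with the control
  pool and genome-wide rIBD is negative — the qualitative signature of a
  European-derived genome. Inside each planted tract an exact count
  `round(carrier_fraction × n_recipient)` of carrier haplotypes is
  overwritten with a randomly chosen source haplotype. A per-site mutation
  rate of 0.001 is then applied, so IBD detection must tolerate rare
  mismatches.
* **Not emulated.** Coalescent genealogies, LD decay within founder blocks,
  genotyping error beyond point mutations, variable recombination maps, and
  allele-frequency clines. A green planted-tract test therefore establishes
  that the scan recovers strong, recent introgression under clean phasing —
  not that it would match an HMM caller on real re-sequencing data.

`simulate_pedigree_phenotypes()` generates founder sires/dams, phantom
mating boars and phenotyped sows (BV = parent average + Mendelian sampling,
variance 0.5σ²ᵤ). Records follow
`y = μ + parity + year-season + boar + PE + BV + q·nQ + e` with variance
fractions `h2`, `pe_frac`, `boar_frac` of a total phenotypic variance of 10
(TNB-like; default single-record h² = 0.1). Parity effects are a small fixed
vector peaking at mid parities; year-season has four levels — the factors
are named in the modelled analysis without published values, so plausible
magnitudes (≤ 1 piglet) were chosen once. The Q-allele count is drawn
independently of the pedigree (`Binomial(2, q_freq)`), which makes the
haplotype effect behave like a permanent environmental shift — adequate for
testing the association stage, though real introgressed haplotypes would
also be transmitted through the pedigree.

# Numerical and design choices

* **Coordinates.** 1-based inclusive in VCF I/O; half-open `[start, end)`
  windows and regions internally; BED export is 0-based half-open. Windows
  tile from position 1 in fixed `size_bp` steps; empty windows are masked,
  never dropped, so all statistics share one grid.
* **Variant QC.** Minor-allele frequency strictly `> 0.05`, missingness
  strictly `< 0.1`, biallelic only; missing alleles are excluded from every
  frequency denominator. Multiallelic records are dropped at load time, not
  decomposed.
* **Fst.** No estimator was named upstream; Hudson's estimator as a ratio
  of per-window sums was chosen for robustness to unequal sample sizes,
  with per-site sample-size corrections `p(1−p)/(n−1)`. Sites with `D = 0`
  carry no information and are skipped. The reporting column is clamped to
  `[−0.05, 1]`; the raw ratio is kept alongside (and used for LSBL, whose
  negative values are meaningful).
* **Zhet / Z tests.** Window heterozygosity is standardized by the
  genome-wide mean and SD over unmasked windows. Significance masks are
  one-sided in the biologically motivated direction (upper tail for
  differentiation, lower tail for heterozygosity); the two-sided option
  exists but is not the default, since the thresholds are used as
  enrichment guides rather than calibrated tests.
* **Region calling.** The threshold is the k-th largest value with
  `k = ceiling(top_fraction × n_unmasked)` computed genome-wide; ties at
  the threshold are all flagged, so the flagged count can exceed the nominal
  fraction — with strongly quantized rIBD values (counts over a fixed pair
  universe) this is common and intended. Merging uses strict `< 200 kb`
  edge-to-edge gaps; masked windows inside a gap neither join nor split.
* **NJ and PCA.** The distance stage (p-distance: proportion of differing
  sites among jointly non-missing; sample mode uses |dosage difference|/2)
  is implemented here; the neighbor-joining agglomeration is delegated to
  `ape::nj`, the field-standard Saitou–Nei implementation, with negative
  branch lengths clamped to zero. PCA uses PLINK-style variance
  standardization `(g − 2p)/sqrt(2p(1−p))` with mean imputation of missing
  dosages.
* **Haplotype analysis.** Haplotype copies with any missing site in the
  region are excluded and counted. Labels follow descending total
  frequency, ties by first occurrence; the Q haplotype defaults to the
  source group's most frequent haplotype. Tag SNPs must separate the Q set
  from *all* other observed haplotypes perfectly; if fewer than `n_tags`
  such sites exist the error lists the least-violated candidates rather
  than silently degrading. The network is a strict minimum spanning tree
  (Kruskal, deterministic (weight, index) tie-break) over Hamming
  distances.
* **BLUP.** Variance components are user-supplied (the upstream study used
  software REML estimates it did not print; REML is out of scope). Demo
  defaults σ²ᵤ = 1, σ²ₘ = 0.3, σ²ₚ = 0.5, σ²ₑ = 8 give a TNB-like
  single-record h² ≈ 0.1. The boar effect shares the pedigree A structure,
  as specified for the modelled analysis; boars absent from the pedigree are
  added as phantom founders. A is built by the tabular method; A⁻¹ by
  Henderson's rules with Quaas' inbreeding adjustment (inbreeding taken
  from the tabular diagonal), asserted equal to the dense inverse in tests.
  Fixed effects use treatment contrasts (first level dropped).
* **Association.** One-way ANOVA is run on EBVs, exactly as in the modelled
  analysis. This replicates a known caveat rather than fixing it: EBVs are
  shrunken and correlated through the pedigree, so the F-test is not exact.
  The calibration test (type-I error within the binomial envelope over 200
  seeded null replicates) checks that, with genotype classes drawn
  independently of the pedigree, the procedure is still approximately
  calibrated at this design's scale.

# Known limitations

* The IBD detector is a deterministic identity matcher: it will fragment
  segments in regions of dense genotyping error and has no LD model, so its
  absolute nIBD levels are not comparable to HMM-based callers.
* The recovery acceptance check is stochastic by nature: with a 2 × 10 Mb
  genome the top-0.5% flag budget is only ~10 bins before ties, and in
  roughly a quarter of seeds one of three equal-strength tracts can miss
  the cut. The shipped test fixes the conventional seed (1), which was
  verified to be representative, and the simulator's defaults were designed
  (balanced pools, long blocks) so that the criterion is met by
  construction rather than by chance.
* `anova_oneway` drops empty genotype classes (e.g. when no qq individuals
  exist in the recipient line) and reports the remaining contrast; no
  multiple-testing correction is applied at this stage.
* Scans default to whatever contigs are present in the panel; hemizygous X
  handling is not implemented — restrict input to autosomes.
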