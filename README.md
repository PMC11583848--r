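# ptmd

Analysis toolkit for **P-site tRNA-mediated mRNA decay (PTMD)**: linking the
codon in a translating ribosome's P site to co-translational recruitment of
the CCR4-NOT deadenylase (via its CNOT3 subunit) and, downstream, to mRNA
half-life. It is written for people analysing selective ribosome profiling
(IP vs input footprint libraries), metabolic-labeling decay time courses,
and tRNA sequence features, and for anyone who wants a fully synthetic,
ground-truth-known testbed for such pipelines.

## What it computes

* **Footprint processing** — length filtering to the periodic classes
  {29, 30, 32, 35 nt}, triplet-periodicity QC, and P-site offset calling
  (P-site codon starts at the 13th nucleotide, 1-based, for 29–30 nt reads;
  the 14th for 32/35 nt), yielding E/P/A-site codons per footprint.
* **Enrichment** — per footprint species (transcript, 5′ position, length),
  a two-sided Fisher's exact test of IP vs input counts with BH correction
  (enriched: q < 0.01, IP-directed); then the percentage-ratio statistic per
  codon and site,

  `ratio_c = % of enriched footprints with codon c at the site / % of input footprints with codon c at the site`,

  plus amino-acid and tripeptide versions and correlation against external
  per-codon metrics (tAI/CSC-style).
* **Weighted codon score** — per mRNA, `score = Σ w(codon) / n_codons` over
  the ORF, with weights defaulting to the P-site enrichment values of
  CGG/CGA/AGG.
* **Decay kinetics** — log-linear fits of `y(t) = exp(−kt)` to
  labeled-fraction chases (0, 1, 2, 4, 8, 12 h) and reporter time courses
  (0, 2, 4, 6 h), `t½ = ln2/k`, half-life fold-changes between conditions,
  and one-sided Wilcoxon rank-sum comparisons of score-defined strata with
  top-set exclusion.
* **Dwell times** — per-codon A-site occupancy over coverage-matched
  expectation, and Pearson correlation of A-site enrichment with dwell time
  conditioned on the P-site codon class (CGG/CGA/AGG vs complement).
* **tRNA D-arm classifier** — cloverleaf parsing (Sprinzl positions 13/22/46,
  D-loop α-element length), three-outcome PTMD classes
  (α ≥ 2 → blocking; U13:A22:A46 → promoting; else neutral), codon
  inheritance under Crick wobble, and per-transcript class densities.
* **Synthetic data** — transcriptomes, two-library footprint sets with
  injected recruitment weights and dwell times, decay time courses with
  condition-specific stabilisation, and tRNA sets with prescribed features.

## Worked example

```r
library(ptmd)

cfg <- simulation_config(seed = 7,
                         recruitment_weights = c(CGG = 4, CGA = 3, AGG = 2))
tx  <- generate_transcriptome(cfg)
fin <- simulate_footprints(tx, cfg, "input")
fip <- simulate_footprints(tx, cfg, "ip")
ain <- annotate_footprints(fin, tx)
aip <- annotate_footprints(fip, tx)

ft <- test_footprint_enrichment(fip, fin)
ft
#> footprint enrichment test: 9472 species; 256 enriched at FDR < 0.01

site_codon_enrichment(ft, aip, ain, "P", numerator = "ip")
#> codon enrichment at the P-site (numerator: ip); top 6 by ratio:
#>  codon n_enriched n_input pct_enriched pct_input     ratio low_support
#>    CGG      13485    3646       6.7425    1.8230 3.6985738       FALSE
#>    CGA       9749    3636       4.8745    1.8180 2.6812431       FALSE
#>    AGG       5508    3011       2.7540    1.5055 1.8292926       FALSE
#>    CGC       3839    4006       1.9195    2.0030 0.9583125       FALSE
#>    GTA       2529    2644       1.2645    1.3220 0.9565053       FALSE
#>    AAG       3437    3653       1.7185    1.8265 0.9408705       FALSE
```

The three recruitment-weighted arginine codons come back on top, at ratios
equal to the injected multipliers divided by the IP renormalisation
constant (Σw/61 ≈ 1.07 here: 4 → ≈3.7, 3 → ≈2.7, 2 → ≈1.8); all other
codons sit at ≈1. With the default `numerator = "enriched"` the table is
the selective-profiling statistic instead: the same ranking, unweighted
codons at exactly 0, and inflated absolute ratios (see the methods
vignette for why both exist).

Half-life fitting on the chase grid:

```r
t <- c(0, 1, 2, 4, 8, 12)
fit_half_life(t, exp(-(log(2) / 4) * t))
#> half-life fit [ok]: t1/2 = 4 h (k = 0.173 /h, R2 = 1.000, n = 6)
```

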