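---
title: "Haplotype-based selection scans, gene-set enrichment, and branch-site post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based selection scans, gene-set enrichment, and branch-site post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

haploscan detects recent positive selection in phased population panels and
asks whether a focal gene set (for example, a disease-associated gene list
from GWAS) is enriched for the selected genes. A separate, much lighter
layer turns branch-site codon-model log-likelihoods into the
likelihood-ratio statistics used to detect selection over phylogenetic
timescales. This vignette explains the statistical machinery, the choices
behind its defaults, and what the synthetic data generator does and does
not emulate.

```{r setup}
library(haploscan)
```

## The scan model

The population layer combines three classical signals of a recent hard
sweep:

**Extended haplotype homozygosity (EHH).** For a carrier set $C$ of one
core-SNP allele, EHH at distance $d$ is the probability that two
haplotypes drawn from $C$ are identical over the interval from the core
out to $d$:
$$\mathrm{EHH}(d) = \sum_g \binom{k_g}{2} \Big/ \binom{|C|}{2},$$
where $g$ runs over distinct haplotype strings and $k_g$ are their
multiplicities. A sweep drags one haplotype to high frequency faster than
recombination and mutation can break it up, so EHH around the selected
allele decays slowly.

**iHS.** The integrated EHH (iHH) is the trapezoidal area under the decay
curve, accumulated left and right of the core until EHH falls below a
cutoff. The unstandardized score is $\ln(\mathrm{iHH}_A /
\mathrm{iHH}_D)$ for the ancestral/derived carrier classes; long derived
haplotypes therefore give negative raw scores. Because the expectation of
this quantity depends strongly on the derived-allele frequency, scores are
standardized to mean 0, SD 1 within derived-frequency bins, and only the
magnitude |iHS| is interpreted.

**xpEHH.** For two populations A and B, each population's iHH is computed
over *all* of its haplotypes, both integrals stopping at the shared
boundary where the pooled two-population EHH first drops below the cutoff;
the score is $\ln(\mathrm{iHH}_A / \mathrm{iHH}_B)$, standardized
globally. It is sensitive to sweeps at or near fixation in one population,
which iHS (needing both allele classes) misses. The pooled curve starts
from the core-site homozygosity itself, so `xpehh_scan(A, B)` equals
`-xpehh_scan(B, A)` exactly — the pipeline computes each unordered pair
once.

**FST with frequency-binned thresholds.** Per-site differentiation is the
Weir–Cockerham variance-component estimator $\theta = a/(a+b+c)$ computed
from diploid genotype counts. Because FST and allele frequency are
strongly correlated, the top-5% threshold is taken *within*
pooled-frequency bins (width 0.05, undersized bins merged into their
nearest neighbour, nearest-rank upper quantile, ties pass). Negative
estimates are kept unclipped so bin quantiles are not distorted; they
simply never pass.

**The composite call.** Extreme scores cluster around a genuine sweep, so
a site is called a candidate only when all three of these hold:

1. |standardized score| > 2;
2. the 51-SNP window centered on the site is in the genome-wide top 1% by
   its count of |score| > 2 sites (windows truncated at chromosome ends
   are excluded; NA scores count as non-extreme);
3. the site passes the binned FST threshold — for xpEHH the pair's own
   threshold, for the single-population iHS the threshold in at least one
   pair involving the target population.

Candidates are then restricted to exonic positions and classified as CDS,
5' UTR, 3' UTR or non-coding exon, with CDS > 5' UTR > 3' UTR >
non-coding precedence when transcripts disagree; a gene is called
positively selected when it contains at least one retained candidate.
eQTL support can be annotated from an m-value table, with an effect
declared only when m > 0.9 (strict).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.05 | minimum minor-allele frequency (inclusive), required in every population participating in a statistic |
| `cutoff` | 0.05 | EHH value at which integration stops |
| `max_extension_bp` | 1e6 | maximum walk distance from the core; curves still above the cutoff there become NA |
| `max_gap_bp` | 2e5 | maximum tolerated inter-SNP gap during a walk |
| `n_bins`, `min_bin_size` | 100, 20 | iHS standardization bins (equal-width in derived frequency, merged when undersized) |
| `score_cut` | 2 | site-level |score| threshold |
| `window_size` | 51 | SNP window for the clustering rule |
| `top_frac` | 0.01 | fraction of windows allowed to qualify |
| `fst_bin_width`, `fst_quantile` | 0.05, 0.05 | FST frequency bins and upper-tail mass |
| `reps` | 100000 | resampling replicates for enrichment |
| `alpha` | 0.05 | per-tail significance level |

The EHH walk constants are the documented defaults of the standard
scanning tools; all of them are exposed through `scan_params()`.

Distance is physical base pairs. A genetic-map hook is deliberately out of
scope: the pipeline described here uses physical windows, and a constant
recombination map would only rescale iHH without changing standardized
scores.

The MAF filter is read conjunctively — a site must pass in *every*
population participating in the statistic being computed (the target
population for iHS, both for xpEHH and FST). This is the stricter of the
readings of "MAF in test populations" and is recorded in output metadata
through the run manifest.

Sites with missing alleles in a participating population are dropped at
read time; phase-3-style reference panels are essentially complete, and a
determinate rule is more valuable here than an imputation heuristic.

## Enrichment and the lineage layer

Whether the focal gene set is unusually often selected is decided against
an empirical null: draw the same number of genes uniformly without
replacement from the gene universe (all annotated genes eligible for the
scan), count how many are positively selected, repeat (default 100,000
replicates), and report add-one empirical tail probabilities
$$p_{\mathrm{upper}} = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{R + 1}.$$
Both tails are reported at per-tail $\alpha = 0.05$; users wanting one
two-sided decision can Bonferroni to 0.025. Replicates are generated in
seeded chunks of 1000 so a run can be split without changing its stream.
Pairwise lineage comparisons of selected-gene proportions use the exact
conditional (Fisher) test, two-sided by summing hypergeometric
probabilities at or below the observed table's.

The phylogenetic layer consumes per-gene log-likelihood pairs from
branch-site codon-model fits (modified Model A versus the null with
foreground $\omega = 1$). The statistic is $2\Delta\ell$, clamped at zero
with a warning when an optimizer returns a marginally negative difference.
Because the null fixes a parameter at a boundary, the reference
distribution is the mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, i.e.
$p = \tfrac12 \Pr(\chi^2_1 \ge 2\Delta\ell)$. Bonferroni correction uses
an explicit family size (the number of genes successfully tested on the
branch) because that number is an input, not something the table itself
reveals. Fitting codon models, alignments and BEB site posteriors are out
of scope; a convenience parser extracts `lnL` lines from codeml main
output, failing soft to a manual TSV.

The shipped `human_branch_lnl.tsv` carries seven log-likelihood pairs for
the human lineage; two rows are flagged `garbled` because their printed
statistics are internally inconsistent in the source material and are
excluded from numeric checks rather than guessed at.

## What the generator emulates

`simulate_panel()` produces phased, polarized panels whose statistical
structure matches what the scans assume:

- **Allele frequencies.** Ancestral frequencies follow a neutral-like
  $1/x$ spectrum truncated to [0.05, 0.95]; per-population frequencies
  come from the Balding–Nichols model with drift parameter $F$ (default
  0.05, giving realistic continental-scale differentiation). Binomial
  sampling and drift put sites on both sides of the 5% MAF bound, so the
  filter path is always exercised.
- **Linkage.** Haplotypes are recombinant mosaics of per-population
  founder haplotypes (default 100 founders) with Poisson crossovers and
  private mutations, so haplotype identity decays with physical distance.
  With the default rates, neutral EHH falls below the 0.05 cutoff within
  roughly 50–100 kb, comparable to dense human SNP data, and well inside
  the 1 Mb maximum extension.
- **Sweeps.** A planted hard sweep rewrites the derived-allele carriers at
  a core SNP as copies of one donor haplotype over per-carrier exponential
  segment lengths, reproducing the long-shared-haplotype signal;
  `strength = 1` copies whole chromosomes. Auto-placed cores are kept away
  from chromosome ends, separated from each other, and given mid-range
  ancestral frequencies so the planted signal is analyzable (a core that
  fails the MAF filter in the unswept population would be invisible to
  the cross-population statistics by construction, which would measure
  the filter, not the scan).
- **Annotation.** Tiled gene models with 5' UTR/CDS/3' UTR exons and a
  fifth of genes non-coding; a focal gene set; sweeps targeted at focal
  genes with configurable probability (`focal_enrichment = 0` is uniform
  background placement).

The standard test configuration (`sim_config_fixture()`) uses two
populations of 50 diploids and five 1.5-Mb chromosomes of 1500 SNPs with
two sweeps confined to chromosome 1. These sizes were chosen so that a
full scan runs in about two seconds while keeping the genome large
relative to a sweep's footprint: the top-1% window rule and the binned
FST thresholds are *competitive* rules, and on a genome that is mostly
sweep the sweep competes with itself. The fixture's compact footprint
(mean shared segment 2% of the chromosome per side) keeps one sweep's
hitchhikers from saturating the 1% window quota, mirroring the real
situation where sweeps occupy a vanishing fraction of the genome.

What the generator does **not** emulate: demographic history (growth,
bottlenecks, migration), background selection, genotype error, genetic
map heterogeneity, soft sweeps, and gene conversion. Passing tests
therefore show that the statistics and the composite rule behave
correctly on data satisfying their own assumptions — they do not certify
power or false-positive rates on real cohorts, where demography alone can
mimic or mask sweep signals.

## Numerical choices and degenerate inputs

- Trapezoidal iHH integration includes the final trapezoid into the first
  below-cutoff point; raw EHH is integrated (area above zero, not above
  the cutoff).
- Sample SD ($n-1$) in standardization; bins with fewer than 20 non-NA
  scores merge into the nearest bin by centre distance, ties to the lower
  bin.
- Nearest-rank upper quantiles everywhere a "top x%" rule appears, with
  inclusive (`>=`) comparisons so ties pass together.
- The window threshold is the smallest count whose qualifying fraction is
  at most `top_frac`; if every window has the same count, all qualify
  (with a warning) — the determinate reading of a degenerate genome.
- A site's window must be *centered* on it to qualify. The alternative
  contains-rule is available via `call_candidates()` on windows you build
  yourself, but the centered rule gives one window per SNP and a fixed
  denominator.
- Empirical p-values use the add-one rule and can never be zero; with $R$
  replicates the smallest attainable value is $1/(R+1)$.
- Negative LRT statistics clamp to zero with a warning rather than
  erroring: nested optima can cross by optimizer noise.

## Known limitations

- Only biallelic SNPs are supported; multiallelic decomposition,
  imputation and phasing belong upstream.
- Two-population FST only (the pipeline's gates are pairwise); no
  windowed or Hudson estimators.
- The resampling null treats genes as exchangeable units; gene length,
  SNP density and LD clustering of genes are not modelled, which real
  analyses may need to address with matched nulls.
- The branch-site layer post-processes log-likelihoods; it cannot detect
  problems in the upstream model fits it is given.
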