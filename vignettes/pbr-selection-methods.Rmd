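---
title: "Detecting positive selection at MHC peptide-binding codons with pbrselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection at MHC peptide-binding codons with pbrselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrselect)
```

## The scientific problem

Exon 2 of the MHC class II *DRB* gene encodes the β1 domain whose
peptide-binding region (PBR) contacts antigenic peptides. Under balancing
(positive, diversifying) selection, amino-acid-changing substitutions are
favored precisely at the PBR codons, so the per-site nonsynonymous distance
dN exceeds the synonymous distance dS there, while the rest of the exon
evolves near-neutrally. `pbrselect` quantifies that signature for a curated
panel of alleles — one species or breed group, deduplicated to distinct
sequences, aligned to a common coding window (conventionally 234 bp = 78
codons covering mature-protein residues 9–86).

## The estimator

For a panel of $n$ alleles the package computes, within each stratum of a
codon partition (PBR, non-PBR, all codons):

1. **Nei–Gojobori counting.** Each sense codon carries fractional
   synonymous sites $s$ = (number of the 9 single-base changes preserving
   the amino acid)/3 and nonsynonymous sites $3 - s$; changes that create a
   stop codon count as nonsynonymous, so $s + n = 3$ always. Between two
   codons differing at $k$ positions, all $k!$ orderings of single-base
   steps are enumerated, orderings passing through a stop codon are
   discarded (unless every ordering does, in which case all are used), and
   synonymous/nonsynonymous step counts are averaged over the admissible
   orderings. Codon sites containing a gap, an ambiguous base, or an
   observed stop in either sequence are excluded for that pair only
   (pairwise deletion). Site totals $S, N$ are the means of the two
   sequences' per-codon sums; $p_S = S_d / S$, $p_N = N_d / N$.
2. **Jukes–Cantor correction.** $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p)$
   maps each proportion to substitutions per site; it is undefined from
   $p \geq 3/4$ (saturation), and such pairs are excluded with a logged
   count.
3. **Mean pairwise distance.** The panel statistic is the arithmetic mean
   over all $n(n-1)/2$ unordered pairs — an average divergence among
   alleles, not a pooled concatenation.
4. **Codon bootstrap.** Standard errors come from resampling codon columns
   with replacement (nucleotide columns for the K2P distance) and
   recomputing the mean pairwise statistic; the SE is the standard
   deviation across replicates (denominator $R - 1$, default $R = 1000$).
5. **Z-test of positive selection.**
   $Z = (\hat d_N - \hat d_S) / \sqrt{\mathrm{SE}_{d_N}^2 +
   \mathrm{SE}_{d_S}^2}$ with a one-tailed upper-normal $P$ (alternative
   $d_N > d_S$). The two bootstrap variances are treated as independent —
   the convention of the classic MEGA-style test this package reproduces.
6. **K2P nucleotide divergence.** With transition proportion $P$ and
   transversion proportion $Q$ over pairwise-comparable sites,
   $d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)$.

All of this is exposed through one fitting function:

```{r fit}
panel <- make_fixture_panel("paper-like", seed = 101)
fit <- ng_selection(panel$alleles, panel$partition,
                    replicates = 200, seed = 1)
fit
```

The phylogenetic summary applies complete deletion (every alignment column
containing a gap or missing residue in *any* sequence is dropped), Poisson-
corrected amino-acid distances $d = -\ln(1 - p)$, and Neighbor-Joining,
with column-bootstrap supports on internal edges.

## The PBR masks, and why there are two

Interspecies DRB polymorphism tables conventionally star 20 positions of
the 9–86 residue window as peptide contacts after the Brown et al. (1993)
human DR structure, yet selection analyses of the same window conventionally
stratify on a 22-codon PBR. The literature does not pin down the extra two
positions, so the package ships both masks as explicit, named choices
rather than silently preferring one:

* `table2-asterisks` — the 20 conventionally starred residues
  (9, 11, 13, 28, 30, 32, 37, 38, 47, 56, 60, 61, 70, 71, 74, 78, 81, 82,
  85, 86);
* `brown1993-22` (default) — those 20 plus contact residues 26 and 65.
  Residues 57 and 67, peptide contacts in some renderings of the DR
  structure, are conventionally treated as non-PBR in ruminant DRB work
  and stay excluded.

Masks live in **alignment codon coordinates** (1..78); reports add a
residue-number offset (default 8) so position 1 prints as residue 9. A
shorter alignment (e.g. a 75-codon red-deer window) is handled by supplying
a 75-codon mask, never by special-casing.

## The synthetic-data generator

`simulate_alleles()` evolves `n_alleles` sequences independently from one
stop-free random ancestor (a star phylogeny). Mutation events per allele
are Poisson with mean `branch_length * n_codons`; each event proposes a
uniform single-base change at a uniform codon, stop-creating proposals are
rejected, and otherwise acceptance is proportional to 1 for synonymous and
to the stratum's `omega` for nonsynonymous changes (scaled so the largest
relative rate is 1). Defaults define the reference study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_alleles` | 22 | a typical curated single-breed panel |
| `n_codons` | 78 | the 234-bp exon-2 window |
| `omega_pbr` | 3 | diversifying selection of the strength real panels show (PBR dN/dS ≈ 2–9) |
| `omega_nonpbr` | 1 | near-neutral background |
| `branch_length` | 0.4 | proposed events per codon; reproduces the observed overall divergence of curated panels (mean pairwise K2P ≈ 0.12) |

The generator reproduces the **pairwise-distance structure** the estimators
consume: partition-confined elevation of dN, realistic overall divergence,
no stop codons, deterministic per seed. It deliberately does **not**
emulate several features of real MHC data: among-site rate heterogeneity
(simulated variability spreads over many sites, so variable-site fractions
run higher than in real panels of matched divergence), genealogical
correlation between alleles (a coalescent or trans-species genealogy would
correlate pairs; the star phylogeny keeps them independent), recombination
and gene conversion, and codon-usage bias. Passing tests therefore certify
the estimators and their calibration under a clean, known-truth process —
not that real panels satisfy those assumptions.

## Numerical and design choices

* **Pathway fallback.** If every ordering between two codons crosses a
  stop, counts are averaged over all orderings instead — the common
  implementation choice, and testable.
* **Proportions at extreme divergence.** For unrelated random codon pairs
  the pathway-averaged $N_d$ can marginally exceed $N$ (they are counted on
  different scales), so $p_N$ is not clamped to 1; on the method's working
  range — alleles sharing recent ancestry, below Jukes–Cantor saturation —
  both proportions behave as proportions, and the property suite asserts
  this on moderately diverged pairs.
* **NJ determinism.** Q-criterion ties break on the lexicographically
  smallest pair of cluster labels (a cluster is labelled by its smallest
  member), so topology, branch lengths and the total tree length are
  byte-reproducible and invariant under input row order. Negative NJ branch
  lengths are clamped to zero with the deficit recorded in the `"clamped"`
  attribute (display behavior compatible with mainstream phylogenetics
  GUIs).
* **Bootstrap streams.** One master seed yields per-replicate seeds via a
  single `sample.int(2^31 - 1)` draw, so replicates are reproducible and
  independent of evaluation order. Saturated tree-bootstrap replicates
  yield no tree and are excluded from the support denominator (their count
  is retained).
* **Degenerate inputs.** Identical sequences give all-zero estimates with
  zero SE and $Z = 0, P = 0.5$; zero bootstrap variance with *unequal*
  estimates raises a classed error rather than an infinite Z; dS = 0 flags
  the ratio as undefined rather than dividing.
* **Rendering.** Reports print distances to 3 decimals, ratios to 2, and
  one-tailed P to 3 (clamped to [0, 1]), matching the conventions of
  published selection tables; full precision is carried internally.

## Calibration evidence and problem sizes

The acceptance suite checks, at sizes chosen to finish in minutes on one
CPU: exact agreement of site/pathway counting with brute-force enumeration
(all 61 sense codons; 500 random pairs); exact recovery of random additive
4–8-taxon trees by NJ (100 trials); neutral calibration at the reference
conditions (ω = 1, 22 × 78, 200 seeds, 200-replicate bootstraps); selection
recovery (ω_PBR = 5, ω_non-PBR = 0.5, 100 seeds); and byte-identical
reports under a fixed seed. Across-seed means of dN and dS are compared as
a ratio of means — the mean of per-seed ratios would be biased upward by
noise in the denominator (Jensen's inequality).

## Known limitations

* **The neutral point sits slightly below 1.** Because 23 of the 549
  single-base changes among sense codons create stops, a stop-avoiding
  substitution process realizes ~5% fewer nonsynonymous changes than the
  Nei–Gojobori site counts charge for, so at ω = 1 the estimated dN/dS
  centers near 0.91–0.93 (after Jukes–Cantor amplification), not 1.0.
* **The Z-test is conservative.** Its denominator adds the two bootstrap
  variances although dN and dS are positively correlated across codon
  columns, overstating the variance of the difference; combined with the
  neutral deficit above, the one-tailed test rejects far below its nominal
  5% at ω = 1. Both behaviors are documented properties of this classic
  test, not implementation defects; users should read its P-values as
  conservative.
* Mean-of-pairwise distances on a star phylogeny are not independent
  observations; SEs describe codon-resampling uncertainty, not
  allele-sampling uncertainty.
* The package assumes in-frame, pre-aligned input; it performs no
  alignment, no reading-frame search, and no database retrieval.
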