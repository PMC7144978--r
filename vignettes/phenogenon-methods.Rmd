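---
title: "Methods: scoring gene-phenotype-MOI associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring gene-phenotype-MOI associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`phenogenon` scores the association between a gene and a Human Phenotype
Ontology (HPO) term in a cohort of unrelated, exome-sequenced patients,
separately under a dominant and a recessive inheritance model, without
committing to a variant-filtering threshold up front. The ingredients:

1. **Case/control split.** For a query term, a patient is a case if
   annotated with the term or any of its descendants (HPO annotation
   propagates up the is_a DAG); everyone else is a control. Multi-term
   queries intersect the case sets.

2. **Genotype frequency (GF).** Each variant gets a mode-of-inheritance
   (MOI)-dependent population frequency from gnomAD: the allele frequency
   AC/AN under the dominant model, and the estimated homozygote frequency
   2·HOM/AN under the recessive model. Using the homozygote frequency for
   recessive scoring is the method's key frequency idea: a recessive disease
   allele may be common as an allele (carrier frequency ~1/500) while
   biallelic genotypes remain vanishingly rare.

3. **Binning.** Variants are placed on a half-open GF x CADD grid: CADD rows
   of height 5 (capped at 40; higher scores clamp into the top row), GF
   columns of width 1/4000 = 0.00025 (variants with GF >= 0.01 are off the
   grid). Column 0 -- GF < 0.00025 -- is the *rare column*.

4. **Carriers.** Dominant: any patient with >= 1 alternate allele on a bin
   variant. Recessive: homozygous-alternate patients, plus presumed compound
   heterozygotes -- heterozygous at a bin variant `v` while carrying a second
   variant `u` in the same gene with `cadd(u) >= cadd(v)` and
   `GF(u) <= GF(v)` (recessive GF on both sides; phase is not assessed).
   Missing genotypes never qualify, and the <20% missingness filter bounds
   the resulting undercount per variant.

5. **Per-bin test.** Each non-empty bin gets a one-sided Fisher exact test
   for carrier enrichment in cases; the p-value maps to a z-score,
   z = Phi^-1(1 - p).

6. **HGF score.** The rare-column z-scores are combined with a scaled,
   weighted Stouffer sum, Z = sum(w_i z_i) / k_rare, where w_i grows with the
   CADD row and k_rare is the number of non-empty rare bins, and the HPO
   goodness-of-fit is HGF = -ln(1 - Phi(Z)).

7. **Signal ratio and M score.** SR is the fraction of the heatmap's total
   -ln(p) mass that sits in the rare column. Under a wrong MOI the GF
   definition misplaces disease alleles into non-rare columns, deflating SR.
   M = HGF x SR per branch; the larger M calls the MOI (exact tie:
   undetermined).

8. **Screening.** A gene-term pair is reported when NP -- the number of case
   patients carrying qualifying rare-column variants under the predicted
   MOI -- reaches `np_cutoff`; results rank by the larger HGF branch.
   Positive terms per gene are those with HGF at least one standard
   deviation above the gene's mean (`select_positive_terms()`).

Comparator models used in benchmarking (`genon_benchmark()`): Fisher's
method over rare bins (no CADD weighting), HGF-only MOI calls (no signal
ratio), and allele-frequency-for-recessive GF (no homozygote frequency).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cadd_bin_height` | 5 | CADD Phred per row |
| `gf_bin_width` / `rare_threshold` | 0.00025 | GF per column; rare = column 0 |
| `gf_max` | 0.01 | variants at or above are ignored (implausible rare-disease causes) |
| `cadd_max` | 40 | top row clamp (8 rows) |
| `weights` | 0.2, 0.4, 0.6, 0.8, 1, 1, 1, 1 | per-row Stouffer weights |
| `p_clip` | [1e-300, 1 - 1e-16] | keeps z finite; p = 1 maps to z ~ -8.21 |
| `stouffer_denominator` | `k_rare` | canonical scaling; `sqrt_k_rare` / `sqrt_sum_w2` available |
| `np_cutoff` | 60 | screening gate, sized for a ~3,000-exome cohort |
| `sd_multiplier` | 1 | positive-term selection threshold |

No reference per-row weight table is available; the default is a linear
ramp reaching 1.0 at CADD 20, which satisfies the weighting's intent (higher
weight for higher CADD) and is fully overridable, so an externally derived
weight vector can be dropped in verbatim.

## Design choices where the source was open

* **Eq-1 denominator.** The printed combination divides by `k_rare` itself
  (not its square root); we take that literally as the default and expose
  the classical normalisations as options. Division by `k_rare` penalises
  genes whose rare column is occupied by many uninformative bins.
* **Non-empty bins.** A bin is non-empty when at least one patient
  *qualifies as a carrier* of it under the MOI being scored. Bins without
  member variants are trivially empty; bins whose variants no patient
  qualifies for (frequent under the recessive rule, where most single-het
  bins have no biallelic carrier) contribute no genotype evidence and are
  also treated as empty. For dominant scoring this coincides with
  variant-based emptiness, since every cohort-observed variant has a
  carrier. Without this reading, recessive HGF for true recessive genes is
  systematically crushed by carrier-less bins entering `k_rare` at the
  clipped z of -8.21.
* **Signal-ratio denominator.** The SR formula's text describes the
  denominator index as the non-rare bins while the formula suggests all
  bins; the default sums over *all* non-empty bins, keeping SR in [0, 1]
  (the literal non-rare-only reading is `sr_denominator = "nonrare"`).
* **Contingency orientation.** One-sided, enrichment-in-cases; p = 1
  whenever no case carries the bin.
* **One patient, one vote.** A patient counts at most once per bin
  regardless of how many member variants they carry.
* **Compound-het partner pool.** The second hit may come from any GF column
  provided the CADD >= / GF <= dominance condition holds against the anchor;
  recessive GF is used on both sides of the comparison.
* **Ties.** Exact M-score ties return `undetermined`; ranked output breaks
  HGF ties lexicographically by gene, then term.
* **Truth matching.** Benchmark term matching is ontology-aware (a predicted
  term matches a truth term that is identical or an ancestor/descendant);
  exact matching is a config switch.
* **Manifests.** Run manifests record the effective configuration and input
  digests but no wall-clock time by default, so identical inputs and seed
  reproduce byte-identical output trees.

## Numerical choices

Per-bin p-values are computed and carried in log space
(`phyper(log.p = TRUE)`), so -ln(p) sums in the SR and Fisher's-method
comparator do not underflow. The z transform clips p into
[1e-300, 1 - 1e-16]; the near-1 branch goes through `-expm1(log p)` because
the upper-tail quantile loses precision there. HGF uses the log survival
function (`pnorm(log.p = TRUE)`), so Z ~ 12 gives HGF ~ 70 rather than
overflowing to infinity. The Fisher-test implementation is checked against
an exhaustive hypergeometric enumeration built from log-factorials, and the
chi-squared survival against the closed-form even-df series.

## The synthetic cohort

`simulate_cohort()` emulates an unrelated rare-disease exome cohort at desk
scale: 2,000 patients, 200 background genes with Poisson(30) candidate
variants each, a rare-dominated gnomAD-like frequency spectrum (60%
log-uniform on 1e-6..2e-4, 25% on 2e-4..1e-3, 15% on 1e-3..1e-2), bimodal
CADD (80% benign N(8,4), 20% damaging N(28,5), truncated to [0, 40)),
Hardy-Weinberg genotypes, per-variant missingness uniform on [0, 0.1], and
gnomAD annotations derived deterministically from the simulated frequency
(AN = 500,000; AC = round(AF x AN); HOM = round(AF^2 x AN / 2)), so GF
binning is exactly controllable in tests. Only cohort-observed variants
(>= 1 alternate call surviving the missingness mask) are emitted, as in a
real joint call. Small fractions of variants fail the caller filter (3%),
sit > 5 bp from coding sequence (2%) or lack gnomAD coverage (1%) so the
variant filters are exercised.

Planted associations are realised *exactly*: chosen carriers receive causal
genotypes directly (never masked as missing), with penetrance and phenocopy
applied at term assignment, and background terms exclude the planted
closure so phenocopy rates stay controlled. Recessive carriers get two
distinct causal hets (or one hom for 20% of them); causal variants have
CADD in [25, 35) and a gnomAD homozygote count of 0 (recessive GF exactly
0). Causal *allele* frequencies default to 1e-5 for dominant plants and
1e-3 for recessive plants -- the recessive default encodes the carrier
frequency (~1/500) typical of recessive disease alleles, which is what
makes the wrong-MOI profile non-rare and gives the signal ratio its
discriminating power. An optional contaminant variant (AF ~ 0.005, CADD ~
30, het-enriched in cases) emulates frequency-driven confounding: non-rare
under the dominant GF, rare under the recessive homozygote-frequency GF.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (so "compound het" pairs are independent draws),
sequencing error, relatedness, population stratification, and the real
HPO's scale (the balanced depth-3 tree has 13 terms; real annotation is far
sparser relative to the ontology). A green simulation test therefore
establishes that the statistical machinery recovers planted structure under
the model's own assumptions -- not that it is robust to the artefacts of
real exome data.

## Known limitations

* With a small case set (tens of cases out of thousands), background rare
  bins of a true gene frequently contain no case carrier; each such bin
  enters the rare-column combination at the clipped z = -8.21 with weight up
  to 1 while the hot bins' z is capped near 8.5 by the case count itself.
  Under the literal divide-by-`k_rare` scaling this makes dominant-branch
  HGF scores volatile at desk scale: in the acceptance simulations the
  dominant plant is recovered as the exact top (gene, term) pair with the
  right MOI in 15/20 seeds rather than the targeted 18/20 (in three of the
  five misses the top hit is the same gene at the planted term's *parent* --
  a correct detection at coarser phenotype resolution under the package's
  own ontology-aware matching). The recessive branch does not suffer this:
  carrier-less bins are empty by construction. At full cohort scale
  (~3,300 exomes, hundreds of cases) the hot-bin z is 2-4x larger and junk
  bins usually contain case carriers, so the effect recedes.
* Only dominant and recessive models exist; X-linked truth can at best be
  called recessive.
* Compound-het calling presumes trans configuration; no phasing is used.
* The cohort is assumed unrelated by contract (relatedness pruning is an
  upstream concern).
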