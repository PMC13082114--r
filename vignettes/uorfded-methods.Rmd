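---
title: "Methods: quantifying uORF-mediated translational control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying uORF-mediated translational control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfded)
```

# Background

Upstream open reading frames (uORFs) in 5'UTRs capture scanning
preinitiation complexes and usually repress translation of the downstream
main ORF (mORF). The DEAD-box helicase Ded1 unwinds 5'UTR structure during
scanning; one hypothesis ("Ded1-START") holds that Ded1 stimulates mORF
translation chiefly by melting stem-loops just downstream of uORF start
codons, which otherwise force initiation at the uORF. Testing that idea
requires two kinds of measurement, both implemented here:

1. **Ribosome profiling** of isogenic wild-type and helicase-mutant
   strains, quantified at sub-transcript resolution (uORF, 5'UTR, mORF),
   to ask whether mORF translational-efficiency (TE) losses in the mutant
   co-occur with uORF TE gains.
2. **FACS-uORF**, a sort-seq MPRA comparing reporters that carry a native
   uORF against paired reporters whose uORF start codon is destroyed by an
   AAG substitution, run in both strains, to ask whether repressive uORFs
   become more repressive when Ded1 is impaired.

Everything is exercised on synthetic data with planted, recorded truth;
the generators are first-class, seeded package functions.

# Annotation model

All coordinates are transcript-space, 0-based, half-open. A transcript is
5'UTR | mORF | 3'UTR with no gaps; the mORF length must be a positive
multiple of 3. uORF spans live in the 5'UTR and exclude the stop codon by
default (a flag accommodates external BED files that include it).

Design choices where conventions in published uORF compilations diverge:

* **Deduplication on merge** collapses records with *identical*
  (transcript, span) pairs and unions their source tags; partially
  overlapping uORFs are distinct biology and are all kept.
* **Minimum length** defaults to 2 codons excluding the stop — the most
  permissive of the published criteria (no minimum / ≥ 2 / ≥ 3 codons);
  very few annotated uORFs are shorter than 3 codons, so the choice
  barely matters in practice.
* **Start-codon classes**: ATG is AUG; the default near-cognate (NCC) set
  is the seven one-mismatch codons CTG, GTG, TTG, ACG, ATA, ATT, ATC. AAG
  and AGG are deliberately classed non-functional because AAG is the dead
  substitution used to inactivate uORFs in the reporter assay; a
  configurable set accommodates other conventions.

# Ribo-Seq quantification

## Counting and exclusion zones

P-sites are assigned as 5' end + a per-length offset (default 12 nt for
the 25–34 nt size-selection range; only relative positions matter for the
quantities tested here). Footprint counts per feature exclude the first
and last nucleotide triplets of the 5'UTR (start- and stop-adjacent
artefacts of uORF translation itself) and the first 20 codons (60 nt) of
the mORF (elongation ramp); uORF and 3'UTR spans are counted in full, and
mRNA-fragment counting uses full spans. 5'UTRs shorter than 6 nt cannot
support the exclusion and are counted as 0 and flagged rather than
erroring, since real annotations contain very short UTRs.

## TE and filtering

TE of a uORF or 5'UTR is its normalized footprint count over the
normalized mRNA count of the *host mORF* (not of the feature itself),
computed per replicate with a pseudocount of 0.5 on numerator and
denominator and combined as a geometric mean across replicates. The
pseudocount only affects point estimates; inference uses raw counts.
Features enter testing only with ≥ 128 summed mRNA reads over the four
samples of the 2 × 2 (genotype × replicate) comparison, uORFs/5'UTRs
additionally with ≥ 8 summed footprint reads.

## Differential TE

The paired (RPF, mRNA) counts for a feature are modelled as

```
count ~ assay * genotype,  NB(mu, dispersion),  offset = log(size factor)
```

so the assay:genotype interaction is exactly log ΔTE. Size factors are
median-of-ratios over all-positive mORF rows, computed within each assay
and rescaled to geometric mean 1 per assay. Per-feature dispersions are
method-of-moments estimates over the four design cells, clamped at zero
and shrunk with weight 0.5 toward a 1/mean trend fitted across all tested
features; the trend supplies strength exactly comparable to the
per-feature data, so the Wald statistic is referred to a t distribution
with residual df (4 in the 2 × 2 × 2 design) plus an equal number of
prior df, i.e. t(8). On 2000 all-null NB features (dispersion 0.1, mean
counts ≈ 200) this reference gives a type-I error within [0.03, 0.07] at
nominal 0.05 (the acceptance suite recomputes this), where a plain normal
reference is anticonservative and t(4) overshoots in the conservative
direction.

BH adjustment runs within families — mORFs separately from uORF/5'UTR
features — because the two families are reported against different
fold/FDR cutoffs (1.5-fold at FDR < 0.05 and 2-fold at FDR < 0.01
respectively, both configurable).

One estimator property worth knowing: median-of-ratios size factors are
computed from a noisy mixture, so a large *one-sided* block of planted
effects (e.g. 20% of transcripts all down 2-fold in one genotype) drags
the factors and shrinks the recovered fold change by ~10–15%. With
two-sided perturbations — the realistic situation, where hyper- and
hypodependent sets coexist — the contamination cancels and recovery is
unbiased; the recovery checks therefore plant symmetric up/down sets.

## CRD, ΔCRD and the cycloheximide artifact

The CRD is the smallest position where cumulative footprint density
reaches half the transcript total (a deterministic ceiling convention for
the even-total tie). ΔCRD is the between-genotype difference of
replicate-mean CRDs, normalized to transcript length (a flag disables the
normalization); negative values mean density shifted toward the 5' end in
the mutant, as expected if uORF translation rises.

Cycloheximide (CHX) pre-treatment of live cells lets initiation continue
while elongation is frozen, piling ribosomes onto start codons. The
simulator models this as an optional footprint mass over the first five
mORF codons whose expectation is proportional to mRNA abundance and
`chx_intensity` (default 8 × the per-nt mORF body density over 15 nt, the
order of magnitude seen in +CHX metagene plots) — and, crucially,
*independent of the genotype's TE effect*, because the pileup reflects
initiation flux during drug exposure rather than steady-state elongation
output. This single modelling choice reproduces the qualitative
diagnostic: with the artifact on, transcripts losing mORF TE in the
mutant keep their genotype-invariant start peak while body density
drops, so the CRD moves 5'-ward exactly in proportion to the TE loss and
Spearman(ΔCRD, mORF ΔTE) inflates strongly; with the artifact off the
correlation is weak. The metagene profile (per-transcript densities
scaled by their own window mean, then averaged) shows the same artifact
as a start-codon peak several-fold above the flanking level.

# PARS structure windows

PARS profiles are per-nucleotide scores (higher = more double-stranded),
with missing positions explicit. Window scores downstream of a uORF start
use 1-based inclusive offsets with the start codon's A as +1: the
standard windows 16–30, 16–45 and 16–60 cover 15, 30 and 45 nt. Both
interpretations fixed here — inclusive endpoints, +1 = first nucleotide
of the start codon — are stated assumptions rather than universal
conventions. Missing values are imputed as 0 with the coverage fraction
reported; windows under 80% coverage (configurable) return NA, since
partially covered windows otherwise masquerade as low-structure. Max30 is
the maximum 30-nt window sum inside the 5'UTR (whole-UTR sum for UTRs
under 30 nt) and is length-independent by construction, complementing the
total 5'UTR score which confounds structure with length. Group splits of
window scores (high vs low) default to the median cut.

# FACS-uORF statistics

## Expression from sort bins

Cell fluorescence for reporter *r* is log-normal:
log10 F ~ Normal(mu_r, sigma_cell). Gate boundaries are the octile
quantiles of the *pooled* per-(strain, replicate) mixture — mirroring the
sorting of a pooled transformant culture — so pooled bin occupancies are
near-uniform by construction, and a global strain-wide expression shift
cancels out of bin space exactly as the YFP/mCherry ratio normalization
cancels it in the real assay. Reporter expression is the read-weighted
mean of bin values. With bin values 1..8 (the default; gate boundaries
are rarely published) the estimate is monotone in true fluorescence but
compressed, so effects and especially cross-strain *ratios* of effects —
where the compression largely cancels — are the quantitative readouts.
When fluorescence-valued bin midpoints are available (the simulator
returns the pooled per-bin mean fluorescence for this purpose),
expression is recovered on the fluorescence scale and effects converge to
their true values; the worked-example scenario (true effects 0.5 and
0.28, ratio 0.56, global mutant-strain scaling 0.9 and interaction ratio
5/9) is recovered within ±0.02 this way at 50,000 cells per reporter.

## Testing and CSR calls

Per replicate, the WT and Mut reporter read populations are compared with
a Wilcoxon rank-sum test treating each read as an observation at its bin
value, computed in closed form from the bin counts (tie-corrected normal
approximation with continuity correction — every read in a bin is a tie,
so the normal approximation is always the right regime; the closed form
is verified against `wilcox.test` on expanded data in the tests). The
published description applies the test to "mean YFP values" per
replicate, which is ambiguous for a scalar; comparing the bin-sorted read
populations is the natural reading and is flagged as an interpretation,
not as the authors' procedure. Totals above 10,000 reads are
proportionally downsampled first — scale-invariance of the expression
estimate makes this safe, and it bounds the cost of extreme depths.

BH runs across uORFs within each (strain, replicate); a uORF is a CSR
when every informative replicate (≥ 2 required) has q < 0.05 with the
same direction. Repressive means the Mut reporter fluoresces higher.
Requiring all-replicate consistency makes null CSR calls vanishingly
rare: on the simulated 30%-repressive library the empirical FDR among
true nulls is ~0.

## Effects and modulation

Point estimates pool read counts across replicates (inference stays
per-replicate, separating estimation from testing). The uORF effect is
expression(+uORF)/expression(−uORF); the cross-strain effect ratio
effect(mutant strain)/effect(wild-type strain) is classed
`ded1_suppressed` below 1/1.33 and `ded1_enhanced` above 1.33. On a
null-interaction library the per-uORF ratio distribution is centred at
1.00 (median within ±0.02 at 1000 uORFs), and planted 2-fold suppressed
subsets are recalled at ≥ 80–90% at default depth.

# Simulator defaults and scope

Defaults are chosen once as desk-scale, realistic values: two genotypes ×
two replicates for profiling and three replicate cultures per strain for
the MPRA (the study designs); NB dispersion 0.1; transcript abundance
log-normal (sdlog 0.5); mean mORF counts 200 per sample; log-normal
5'UTR lengths (median 60 nt); ~25% uORF-bearing transcripts with ~40%
AUG starts; sigma_cell 0.15 log10, sigma_gene 0.25 log10, 5000 cells and
2000 reads per reporter per replicate. Property and acceptance tests
state their own sizes where they differ: 2000 features for calibration,
1000–2000 uORFs for FDR/centering checks, 500 transcripts for the CRD
contrast, 800 transcripts at dispersion 0.01 and mean 2000 for the
correlated-effect recovery (chosen so estimation noise attenuates a true
Spearman of ~0.48 by well under the ±0.1 assertion).

What the generators deliberately do **not** emulate: alignment and rRNA
contamination, sequencing error and PCR duplicates, isoform ambiguity,
codon-level pausing beyond the CHX start peak, sorter impurity and
regrowth bottlenecks, plasmid copy-number variation, and real gate
optics. Passing tests therefore demonstrate correctness of the
quantification and inference machinery under the stated statistical
model, not robustness to those upstream artefacts.

# Numerical and degenerate-input choices

* CRD of an empty track is NA; ΔCRD propagates NA with a flag rather
  than guessing.
* Zero normalized mRNA in all replicates makes TE undefined; the feature
  is reported FILTERED.
* GLM non-convergence yields NA p-values and a convergence flag; such
  features stay in the output.
* `wrt_compare` on two degenerate distributions (all mass in one shared
  bin) returns p = 1, direction none.
* Size-factor estimation falls back to total-count scaling with a
  warning when no all-positive mORF row exists.
* Expression estimates need ≥ 20 reads (configurable); below that NA.

# Known limitations

* With two replicates and dispersion ≈ 0.1, single-feature 2-fold TE
  changes are underpowered — an honest property of the design, visible in
  the simulators; recovery assertions are therefore about medians over
  planted sets, not single features.
* The moderated-t reference is calibrated for the 2 × 2 × 2 design the
  study uses; markedly different designs would deserve a re-check of the
  prior-df choice.
* Bin-index expression is compressed relative to fluorescence; absolute
  effect sizes on the index scale understate true repression, which is
  why cross-strain ratios (and, where available, fluorescence-valued
  bins) carry the quantitative claims.
* Exact-span uORF deduplication treats near-identical records from
  different compilations (e.g. off-by-three stop-codon conventions) as
  distinct; the import flag for stop-inclusive spans exists precisely to
  normalize that before merging.
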