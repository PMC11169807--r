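---
title: "Models and methods behind mabctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mabctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabctools)
```

# The problem

Marker-assisted backcrossing (MABC) transfers a single target allele from a
donor line into an elite recurrent parent while recovering as much of the
recurrent genome as possible.  The motivating application is *Brassica
rapa*: the reference Chinese cabbage line Chiifu is strongly
self-incompatible, and the recessive *mm* allele of the M-locus protein
kinase (*MLPK*) — a G-to-C substitution at coding position 1277 causing the
G194R exchange — abolishes the stigmatic self-incompatibility response when
homozygous.  `mabctools` implements the computational layer of such a
programme: coordinate arithmetic on a physical/genetic map, a meiosis
simulator that stands in for real plants and resequencing data,
melt-temperature-based background marker design, recurrent-genome recovery
scoring and selection, introgression-segment analysis, and
compatibility-index phenotyping.

# Genome map and recombination model

A `genome_map` stores, per chromosome, a physical length (bp), a genetic
length (cM), and a monotone set of (bp, cM) anchor points.  `bp_to_cM()`
and `cM_to_bp()` interpolate linearly between anchors.  The default
*B. rapa* map ships the ten chromosome lengths used throughout
(`brapa_genome_map()`; 945.32 cM total).  By default only the two terminal
anchors (1 bp ↔ 0 cM; end ↔ full length) are present, i.e. a
telomere-to-telomere linear map; interior anchors from a real linkage map
can be loaded with `read_genome_map()`.  Because marker cM positions in the
motivating study came from an external linkage map, per-marker genetic
positions (and quantities derived from them, such as maximum marker gaps)
are reproducible here only up to this linear approximation.

Crossovers are modelled as a Poisson process on the genetic map: per
chromosome the crossover count is Poisson with mean `gen_len/100`
(one expected crossover per Morgan), breakpoints are uniform in cM, and no
interference or obligate chiasma is imposed.  This is the simplest model
consistent with map distances; `recombination_fraction()` accordingly uses
Haldane's map function $r = (1 - e^{-2d/100})/2$, with Kosambi available as
an option for users who prefer positive interference in distance
conversions.  Real meiosis shows interference and at least one obligate
chiasma per bivalent; the practical consequence (see *Limitations*) is that
whole-chromosome non-recombinant transmissions are somewhat more frequent
here than in real data, which accelerates background recovery under
selection.

# The synthetic-data generator

`make_parents()` emulates the discovery of parental differences by
whole-genome resequencing of two fully homozygous inbreds.  Variants are
placed uniformly per chromosome at 20 SNPs/Mb and 10 INDELs/Mb.  These
densities are a deliberately scaled-down emulation — the real comparison
yielded roughly 100× more variants — chosen once so that (i) dense
genotype matrices remain small enough to simulate thousands of plants, and
(ii) after the marker-design filters (below), every chromosome retains a
candidate pool comfortably above the number of background markers requested
from it.  INDEL lengths follow `1 + Geometric(p = 0.25)` capped at 30 bp,
a long-tailed shape typical of short-read INDEL calls; 5% of donor calls
are flagged heterozygous to exercise the homozygosity filter, mimicking
residual heterozygosity and calling artefacts.  The target locus is carried
only by the donor.

Phase is represented exactly: each haplotype is a sorted list of
donor-derived intervals in cM space, so genotype queries are interval
lookups and no per-base arrays are ever built.  `simulate_gamete()` clips
alternating parental strands at the crossover breakpoints;
`backcross()` and `self_pollinate()` combine gametes into seeded,
reproducible populations.  `call_genotypes()` reads truth from the
diplotype at each locus and then applies genotyping error (a flip to a
uniformly chosen wrong state) and missingness independently per call.

The compatibility-index (CI) phenotype uses an additive modifier model,
`modifier_model()`: latent CI = baseline for the target genotype
(`MM`/`Mm` 0.1, `mm` 1.0) + Σ effect × donor dosage/2 over modifier loci +
Gaussian noise, clipped at zero; seeds set = round(CI × flowers).  The four
default modifier positions are the midpoints of the candidate donor
segments on A03, A06, A07 and A09 that the motivating study associated with
residual self-compatibility segregation; each contributes +3 CI per
homozygous donor dose, so an *mm* plant carrying two donor modifiers
reaches CI ≈ 7, while *mm* alone (CI ≈ 1) remains self-incompatible —
matching the qualitative observation that the recessive target genotype by
itself is insufficient.  The noise standard deviation is 0.5 CI units: the
model should classify a wild-type `MM` plant (baseline 0.1) as
self-incompatible (CI < 1) in well over 95% of assays, which requires
σ ≤ 0.9/1.645 ≈ 0.55; 0.5 satisfies this with margin while still producing
visible spread.  The true genetic architecture of the residual segregation
is unknown; this model is explicitly a stand-in, with every parameter
exposed.

# Background marker design

HRM (high-resolution melting) genotyping distinguishes the two parental
alleles of a small amplicon by the melt-curve shift its length/composition
difference causes.  The designer follows the published filter chain:

1. `filter_variants()` keeps INDELs called homozygous in the donor with
   length ≥ 3 bp.
2. `build_amplicon_pair()` searches amplicon extents around the INDEL so
   that both allele products lie in 130–260 bp and primers (18–23 bp) lie
   outside the INDEL interval, using the 150 bp flanking context.  The
   grid is deterministic first-fit over product lengths in *ascending*
   order with arms balanced around the variant: the shortest feasible
   product is chosen because a fixed-length difference shifts the melting
   temperature of a short amplicon the most.  This is constraint checking,
   not thermodynamic primer optimisation (no hairpin/dimer screening).
3. `predict_tm()` computes each product's melting temperature with the
   nearest-neighbor model: enthalpy and entropy are summed over
   dinucleotide stacks from the unified duplex parameter table (shipped as
   an editable TSV, `nn_params()`), plus terminal initiation terms and a
   symmetry correction, and
   $T_m = \Delta H / (\Delta S + R \ln(C_T/x)) - 273.15$.
   Sodium concentration enters through the entropic salt term
   $0.368\,(N{-}1)\ln[\mathrm{Na^+}]$, an identity at the 1 M default.
   The total strand concentration defaults to 0.25 µM with $x = 4$ for
   non-self-complementary duplexes (typical PCR conditions; the original
   protocol does not state them).  A stated reaction temperature of 37 °C
   parameterises free-energy reporting in such protocols, not $T_m$, which
   is defined by the ΔH/ΔS ratio; it therefore does not enter the
   calculation.
4. `score_delta_tm()` retains pairs whose predicted ΔTm strictly exceeds
   0.5 °C.  On the default synthetic genome roughly a quarter of eligible
   INDELs pass, with retained ΔTm spanning ≈ 0.5–1.9 °C.

`select_even_panel()` then picks the configured number of markers per
chromosome (totalling 131 by default) by splitting each chromosome's
genetic length into equal-width cM bins and taking, per bin, the candidate
nearest the bin midpoint (ties: larger ΔTm, then smaller bp; an empty bin
falls back to the nearest unused candidate with a warning).  The published
goal was even spacing over both maps; the bin-midpoint rule is this
package's concrete algorithm for it.  `density_report()` reports, per
chromosome, length/count densities in Mb and cM and the maximum adjacent
marker gap in cM — measured between adjacent markers only, not to
chromosome ends, since the original definition is unstated — plus
genome-wide means of the ten per-chromosome values.

`design_target_marker()` builds the KASP-style allele-specific assay for
the target SNP: two 3′-anchored forward primers ending on the G and C
allele respectively plus a common reverse primer, with
`kasp_genotype()` decoding signal pairs (both → `Mm`, G-only → `MM`,
C-only → `mm`, neither → no call).

# Selection

`compute_pr()` scores the proportion of recurrent-parent genome,
$PR = \frac{2\,n_{rec} + n_{het}}{2\,(n_{rec}+n_{het}+n_{don})} \times 100,$
and `compute_hgb()` the background homozygosity
$HGB = \frac{n_{rec}+n_{don}}{n_{rec}+n_{het}+n_{don}} \times 100.$
Missing calls are excluded from numerator and denominator alike (the
original workflow filtered missing loci before scoring; marker-level
treatment was unstated, and exclusion is the unbiased choice).  Scores from
marker panels and from dense resequencing-like calls are tagged
`marker` (PRm/HGBm) and `dense` (PRs/HGBs).

`two_step_mas()` mirrors the two-round strategy used in the large BC2:
rank all carriers by PR over three anchor markers (defaults: the first
panel marker on A01, A02 and A09 — the chromosomes named for the first
round; no finer criterion was published), keep the best 96, then re-rank
the survivors by PR over the full panel.  All rankings break ties on
lexicographic individual id for determinism.  `segregation_test()` is the
1-df chi-square goodness-of-fit without Yates correction (counts are large
in every intended use).

# Segment analysis

`delineate_segments()` turns a chromosome's dense calls into a tiling of
homozygous-recurrent / heterozygous / homozygous-donor segments: maximal
runs of identical state (missing skipped) become segments; runs supported
by fewer than `min_support = 3` informative loci are absorbed into the
flanking run with more support (ties to the left), which absorbs isolated
miscalls at the ~1–2% error rates the generator produces; boundaries
between runs are placed at the midpoint between the last locus of one run
and the first of the next — unbiased under locally uniform recombination —
and the outer segments extend to 1 and the chromosome end.  Segment
lengths are inclusive, `(end − start + 1)/10^6` Mb, matching printed
coordinate conventions; BED export converts to 0-based half-open.

`drag_report()` returns the segment containing the target locus — the
linkage-drag block — and flags the inconsistency of a homozygous-recurrent
segment in a plant genotyped `mm`.  `shared_segments()` intersects the
non-recurrent regions of a set of carrier individuals and subtracts the
union of non-carriers' non-recurrent regions (interval arithmetic via
IRanges), the operation used to nominate candidate modifier segments
private to self-compatible plants.

# Phenotype classification

`compute_ci()` is seeds per pollinated flower; classes are boundary
inclusive: SI (CI < 1), MSC (1 ≤ CI ≤ 4), SC (CI > 4).  Pollen-tube counts
classify as SI (< 10), MSC (10–25), SC (> 25).  Full precision is kept
internally; printed outputs round to the conventional 1–2 decimals.

# The pipeline

`run_pipeline()` chains the stages at the study's population sizes:
parents → F1 → BC1 (12) → BC2 (1120, two-step MAS keeping 96) → BC3 (768)
with `Mm` selection and top-PR mothers at each step; the top three BC3
plants found families of 60 selfed progeny from which ten `mm` plants each
are retained; the best plant per family is genotyped densely, segments are
delineated, the drag block reported, CI phenotypes simulated, and donor
segments shared by self-compatible but absent from self-incompatible
selections intersected.  All randomness derives from one master seed
(stage seeds are drawn once from it), making every artifact — VCF, panel
and density TSVs, per-generation genotype matrices and background reports,
graphical-genotype matrix, BED/TSV segments, drag and shared-segment
reports, CI table, JSON summary — byte-reproducible.  If a generation
yields no carrier (possible only at tiny sizes), the cross is re-simulated
with a derived seed, as a breeder would repeat a failed cross.  A full run
at the default sizes takes a few seconds on one core.

# Limitations

* **No interference / obligate chiasma.**  Background recovery under
  intense selection is slightly faster than in real programmes; with top-1
  selection the best BC3 PRm approaches ~99.6%, above the ~97% reported in
  comparable real material.  A consequence is that donor modifier segments
  (and hence self-compatible selections and non-empty shared-segment
  reports) are rarer in late generations than the motivating study
  observed; the modifier machinery is exercised directly by the phenotype
  model's own tests instead.  Because the `mm` selection step fixes the
  drag segment, the best BC3S1 PRm can sit marginally below the best BC3
  PRm at some seeds.
* **Uniform variant placement, independent errors.**  Real variant density
  clusters (pericentromeric deserts, structural hotspots) and genotyping
  errors correlate with sequence context; passing tests here say nothing
  about those failure modes.
* **Linear two-anchor maps.**  Real recombination is strongly non-uniform
  along chromosomes; supply interior anchors for realistic cM placement.
* **Marker design is constraint checking.**  No primer thermodynamic
  penalties, hairpins, dimers, or off-target checks; the published ΔTm
  range of retained markers (0.8–2 °C) cannot be matched exactly without
  the original marker list and parameter set (two nearest-neighbor sources
  are cited there without a choice; the unified table is this package's
  documented default).

# A compact example

```{r example, eval = FALSE}
map <- brapa_genome_map()
parents <- make_parents(map, seed = 1)
cand <- design_hrm_candidates(parents$variants, map)
panel <- select_even_panel(cand, map)
density_report(panel, map)

summary <- run_pipeline(pipeline_config(seed = 1), "mabc_run")
unlist(summary$max_prm)
```
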