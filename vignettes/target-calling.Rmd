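---
title: "Calling piRNA cleavage targets from degradome and small-RNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling piRNA cleavage targets from degradome and small-RNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisliceR)
```

## The problem

Pachytene piRNAs are an extraordinarily abundant class of small RNAs in
male meiotic cells (~10^7^ molecules per primary spermatocyte). They guide
PIWI proteins to cleave complementary transcripts, but most piRNA species
have no obvious target: the question this package addresses is *which*
transcripts a given piRNA population actually cleaves, and what that
cleavage does to target abundance, translation, and how it relates to
transcription rate.

The evidence for a cleavage event is a 5′-monophosphorylated 3′ fragment
of the target (a "cleavage product"), captured by sequencing RNAs that
carry a 5′ monophosphate. A cleavage product alone does not identify the
guide; the analytical core of this package decides, for every
(piRNA, cleavage product) pair, whether the piRNA had both the
complementarity and the intracellular abundance to have directed cleavage
at that exact site, and then applies two further filters that make a call
high-confidence:

1. **Exclusivity** — no piRNA from outside the focal loci could explain
   the same site; and
2. **Genotype dependence** — the cleavage product is present in control
   cells but lost (or reduced ≥8-fold) when the focal piRNA loci are
   knocked out.

## Coordinates and the slicing register

All positions are 0-based. Guide positions are counted g1–g30 from the
piRNA 5′ end. The register follows standard Argonaute geometry: slicing
occurs between the target nucleotides paired to g10 and g11, so the 5′
nucleotide of the 3′ cleavage product (coordinate *p*) pairs g10, and
guide position *k* pairs transcript coordinate *p* + 10 − *k*. Windows
hanging off a transcript end are evaluated with the out-of-range
positions unpaired rather than rejected, so sites near transcript ends
are still scored on their overlapping part.

Pairing is Watson–Crick (A·U, G·C, with T read as U). G·U wobbles count
as mismatches by default; `align_guide_at_site(..., wobble = TRUE)`
switches them on, since the choice of pairing chemistry is a modelling
decision rather than something the data dictate.

## The abundance-tiered pairing rules

Cleavage competence depends jointly on pairing extent and piRNA
concentration: a highly abundant piRNA can cleave through a shorter
contiguous match, while a scarce piRNA needs extensive pairing. Four
parallel rules (combined by OR) encode this:

| rule | abundance precondition | geometry |
|------|------------------------|----------|
| R1 | ≥ 1 ppm (10 molecules/cell) | ≥ 20 nt paired anywhere in g2–g25 |
| R2 | ≥ 5 ppm (50 molecules/cell) | contiguous pairing g3–g15 |
| R3 | ≥ 10 ppm (100 molecules/cell) | contiguous pairing g3–g16 |
| R4 | ≥ 50 ppm (500 molecules/cell) | contiguous pairing g4–g17 |

Two conventions worth making explicit: all threshold comparisons are
inclusive (≥ and ≤ exactly as written), and the R2 window is a subset of
the R3 window, so any pair satisfying R3's geometry also satisfies R2's —
the rules are evaluated independently and reported separately, but
callability is their union either way. "Sufficient abundance" for the
exclusivity filter uses the same four tiers.

The guide sequence used for pairing is the representative full-length
member of a prefix group (ties broken lexicographically); positions
beyond the guide's length are unpaired, so a 26-nt guide can never pair
g27–g30.

## Absolute quantification

piRNA 3′ ends are heterogeneous (3′ trimming), so reads are collapsed
into **prefix groups** keyed by their 5′ 25-nt sequence; a group is the
unit of quantification and target calling. Reads carry 9-nt UMIs at both
ends; PCR duplicates are identical (insert, UMI-pair) combinations. Nine
equimolar synthetic spike-in oligonucleotides per library convert read
counts to molecules (molecules per read = total spike molecules / total
spike reads, exact-match assignment with no mismatches).

The detection filter requires a group to reach ≥ 1 ppm in *every*
control replicate. 1 ppm of 10^7^ piRNAs per cell is 10 molecules per
cell; under a Poisson model across cells, a mean of 10 molecules means
≥ 99.99% of cells contain at least one (`detectability_probability(10)` =
0.99995). One molecule in an 1,800 µm³ cell is ~0.92 pM, which is why
concentrations are quoted interchangeably in ppm, molecules/cell, and pM.
A group is *undetectable* in a mutant when its mean abundance there is
≤ 0.1 ppm.

## The synthetic world

Every stage is testable without sequencing data through
`generate_world()`, which plants ground truth and simulates all assay
tables. The model:

* **Kinetics.** Each transcript has a transcription rate k~tx~ (uniform
  1–100 units/h), a decay rate k~dec~ (uniform 0.1–1 /h), and, for
  planted targets, a slicing rate k~slice~ (uniform 0.05–0.6 /h). The
  first-order steady state is k~tx~/(k~dec~ + k~slice~) in the control
  and k~tx~/k~dec~ once the guide is lost, so the expected derepression
  is 1 + k~slice~/k~dec~ — spanning ~1.05–7-fold with a median near
  1.5-fold. The range was chosen to reproduce the regime where most
  cleavage has only a modest effect on target levels; a generator whose
  planted targets all double or more would be testing a different
  biology.
* **piRNA population.** 10 loci × 30 guides of 26–30 nt; the first two
  loci are the focal (knocked-out) loci and the last locus is flagged as
  biogenesis-dependent on them (its guides also disappear in the mutant,
  and it is excluded from the control-target universe). Relative
  abundances are log-normal (sdlog 2.5) rescaled to 10^6^ ppm, spanning
  roughly 1–2×10^4^ ppm — i.e. ~0.01–10 nM, the concentration range
  observed for this piRNA class. 17% of guides are flagged
  repeat-derived.
* **Planted sites.** 30% of transcripts receive one site; tiers are drawn
  from an equal mix, the guide is drawn among those passing the tier's
  abundance precondition, and `plant_target_site()` writes exactly the
  requested geometry (window positions complementary, flanking rule
  positions forced to mismatch by setting the target base equal to the
  guide base, which cannot pair even as a wobble). R1 sites are planted
  as the minimal example: exactly 20 paired in g2–g25 as two blocks, so
  no contiguous-core rule fires.
* **Counts.** All count tables draw negative-binomial noise (dispersion
  0.05) around expected library proportions at depth 10^6^, with four
  replicates per genotype. Degradome abundance of a planted product is
  proportional to the slicing flux k~slice~ × steady-state abundance;
  5% of degradome reads are background 5′-end species at random
  positions (with a few flagged as multi-mapping), so the 0.1-ppm
  threshold and the unambiguous-only rule are exercised. GRO-seq signal
  is Poisson around k~tx~ per kb of gene body beyond the first 500 bp.
  RNA-seq includes nine spike rows in a 2-fold dilution series (3% of
  the library) for molecule calibration; ribosome-footprint occupancy is
  proportional to mRNA abundance (TE = 1 — the generator plants *no*
  translational regulation, matching the conclusion the TE contrast is
  designed to support).

What the generator does **not** emulate: sequencing error, adapter
chemistry beyond UMI placement, PCR duplication in emitted FASTQ,
multi-site targets, transcription-rate differences between targets and
non-targets, bursting, or isoform structure. Passing tests therefore
demonstrate the correctness of the analytical machinery on data matching
the stated noise model, not robustness to artifacts real libraries can
contain.

## Differential abundance

The two-genotype contrast is a deliberately simple negative-binomial
Wald test, fully specified so results are reproducible from this package
alone: median-of-ratios size factors (geometric-mean reference, the
DESeq convention), per-gene method-of-moments dispersion averaged across
groups and floored at 0.01, log2 fold change of normalized group means
with pseudocount 0.5, a delta-method Wald z on the log ratio, and
Benjamini–Hochberg adjustment. It is not a reimplementation of a
shrinkage-based DE package, and for small replicate numbers its
dispersion estimate is noisier; the null simulations in the test suite
show the realized fraction of q < 0.01 calls on null data stays below
0.01.

Two numerical facts about recovery at the default study conditions
(depth 10^6^, 4 replicates, dispersion φ = 0.05) are worth stating
because they bound what any estimator can do here. The standard error of
a log2 ratio of two 4-replicate means is
√(2(φ + 1/µ)/n)/ln 2 ≈ 0.23 log2 units, so individual planted fold
changes scatter with that spread around the truth — the tests assert
calibration (≥ 90% of targets within 2 SE) and small aggregate bias
(|bias| < 0.1 log2 units over ~100 targets), not per-target accuracy
beyond the noise floor. Second, one-sided derepression shifts the
median-of-ratios reference slightly toward the mutant, a composition
effect shared by all global-scaling normalizations; at the default
planted fraction and effect sizes it contributes about −0.04 log2 units
of the residual bias.

## Other design choices

* Degradome presence is any-replicate detection at ≥ 0.1 ppm; the
  8-fold-reduction criterion compares replicate means, with the mutant
  mean floored at a 0.01-ppm pseudocount ("detected but not in the
  mutant" is implemented as < 0.1 ppm, with a strict-zero option).
* Multiple guides explaining one site are all reported; exclusivity is
  evaluated across locus classes, not within.
* Seed-site scanning (g2–g8·t1A, seed + ≥7 nt in g9–g30, seed + ≥12 nt
  with an ELAVL1 motif) counts the additional g9–g30 pairing
  non-contiguously, and the ELAVL1 motif defaults to a configurable
  U-rich pentamer scoped to the same 3′UTR — the motif definition is a
  parameter, not a claim.
* The 1.25-fold polymerase-density boundary belongs to both classes, as
  the class definitions overlap at the boundary.
* Duplex ΔG° annotation is a Watson–Crick nearest-neighbor stack sum
  (Xia/Turner parameters) over runs of consecutively paired positions,
  with no initiation or terminal terms; it annotates calls and is never
  used to decide them.
* Non-targets for the transcription-rate comparison are transcripts (at
  > 5 copies/cell) for which no guide is callable at any detected
  cleavage site, i.e. transcripts failing all tier geometries at any
  abundance.

## Problem sizes

The default world uses 200 transcripts (0.9–3 kb), 300 piRNAs, 60
planted targets, four replicates per genotype at depth 10^6^, and the
16 = 4 × 4 replicate-pairing permutation summary; the whole pipeline runs
in under a second and the full test suite, including the brute-force
pairing oracle over every window of multi-hundred-nt transcripts, in well
under a minute. These sizes were chosen so that every property of
interest (tier mix, recall/precision, permutation stability, KS
contrasts) is measurable with stable statistics while the worked example
stays instant.

## Limitations

Cleavage products are short-lived in cells, so on real data the caller
inherits the degradome's sensitivity: absence of a product is weak
evidence of absence of cleavage, which is why the genotype-dependence
filter conditions on products that *are* detected in the control. The
extrapolation from focal-locus targets to the transcriptome-wide count
assumes target yield scales with the piRNA species fraction. And the NB
contrast, by design, trades the refinements of modern DE packages for
full specification — with few replicates its tail behavior is
approximate, which is why class thresholds (FDR < 0.01, ≥ 1.5-fold) are
applied to it rather than any claim of exact error control.
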