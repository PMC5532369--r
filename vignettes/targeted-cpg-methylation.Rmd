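---
title: "Designing and quantifying RNA-programmed CpG methylation"
author: "methylaid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying RNA-programmed CpG methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaid)
```

## The system being modelled

A split CpG methyltransferase (M.SssI divided into an N-terminal MN and a
C-terminal MC fragment) can be directed to a single CpG site by fusing MC
to catalytically dead Cas9 (dCas9). The fusion only assembles an active
enzyme where dCas9 is parked by its sgRNA, so methylation is confined to
CpG sites a short distance from the protospacer-adjacent motif (PAM). Two
strand roles matter throughout: the **cis** strand carries the PAM and
protospacer; the **trans** strand is the sgRNA-complementary one. The key
design variable is the **gap**: the number of base pairs between the PAM
and the target CpG.

`methylaid` packages the quantitative design rules of this system — a
helical-geometry model, a gap-to-efficiency profile, and multiplexing
interference rules — together with a seeded bisulfite-sequencing
simulator and a per-cytosine methylation quantifier, so that the whole
design-simulate-measure loop runs on synthetic data.

## Helical geometry

Because B-DNA twists ~34.3° per base pair, each added base pair of gap
rotates the MTase docking site around the helix axis relative to the
dCas9 C-terminus. The model is anchored at a gap of 8 bp, where
structural superposition places the fusion point at 20° for trans-strand
methylation and 290° for cis-strand methylation:

```{r}
m <- helical_model()
angle_at_gap(m, c(8, 9, 12), "trans")
helical_period(m)   # bp per full turn; the efficiency oscillates with ~this period
```

The anchors do not determine the *sense* of rotation with increasing
gap, so `rotation_sign` is exposed as a parameter (default `+1`). The
choice only affects polar-plot presentation: efficiency prediction is
deliberately empirical (below) and never consumes the sign, because the
anchor angles and the observed optimum gap cannot be reconciled under a
single rotation sense with a naive "near 0° is efficient" rule. The
geometry module is therefore descriptive; `angular_separation()` gives
the distance of any angle from the 0° reference ("same side of the
helix") for visualisation.

Gaps are base-pair counts, so fractional gaps are rejected rather than
interpolated.

## The gap-to-efficiency profile

Methylation efficiency as a function of gap has a characteristic,
experimentally established shape: zero below 8 bp and above 25 bp,
oscillation with roughly one helical turn of period, a first-turn
optimum at a gap of 12, a second-turn optimum at 22–23, and trans-strand
efficiency at least as high as cis everywhere. The packaged default
profile encodes that shape as a raised cosine with period 10.5 bp
(matching 360/34.3), trans amplitude 0.30 and cis fixed at 0.55 × trans,
rounded to 4 decimals (which makes the symmetric 22/23 crest an exact
tie, reported as a two-gap peak):

```{r}
p <- default_gap_profile()
targetable_window(p)
peak_gaps(p, 8:15)
peak_gaps(p, 16:25)
```

The numeric values are a configuration artifact, not measured data: the
published gap scan is graphical, so the package constrains the *shape*
and ships one smooth parameterisation satisfying it. Users with
calibration data can drop in a replacement via `read_gap_profile()`
(tab-delimited `gap`, `p_cis`, `p_trans`), and every downstream
function accepts it.

Per-site predictions combine the two strands assuming independent
strand-specific events, `p_any = 1 - (1 - p_cis)(1 - p_trans)`, and are
classified with the transfer classes used to port the bacterial rules to
human cells: low (< 5%), medium (5–20%), high (> 20%). We read the
published "5–20%" literally, so the medium class is closed on both
boundaries.

## Scanning and coordinates

`find_pams()` enumerates strict NGG PAMs (no NAG; input `N` never
matches) with a full 20-nt protospacer, on both strands, honouring
circular topology; `find_cpgs()` enumerates CpG dinucleotides including
an origin-spanning one on plasmids. `enumerate_target_sites()` pairs
them using the package's gap convention: **the number of bases strictly
between the PAM's 3'-terminal base and the cis-strand C of the CpG**.
The published material never states an inclusive/exclusive convention,
so this one is fixed and used consistently everywhere; all headline
quantities are convention-independent.

Coordinates are 1-based inclusive (the R/Bioconductor convention)
in-memory and in reports; BED exports convert to 0-based half-open.

## Multiplexing rules

Bound dCas9 covers ~23 bp (protospacer + PAM, the modelled footprint).
The demonstrated interference rules are:

* a target CpG within 4 nt of another guide's footprint is obstructed
  (demonstrated at 1 nt and 4 nt distances) — status `blocked`;
* guides whose footprints overlap but whose target CpGs are clear merely
  compete for the site and work near full efficiency via complex
  exchange — status `competing`;
* guides 33 bp apart on the same strand function independently —
  status `compatible`.

`block_margin` defaults to 4 bp, the strongest demonstrated blocking
distance. No threshold between 4 and 33 bp was measured, so the default
is an engineering extrapolation and is configurable (and flagged in the
pair reason text). Competing guides are modelled as fully exchangeable:
`effective_prediction()` takes the maximum single-guide prediction per
cytosine rather than splitting occupancy, and zeroes obstructed CpGs.
Chromatin accessibility and sgRNA expression differences are out of
scope (anomalously inaccessible sites exist and are not predicted).

## The synthetic-data generator

`build_reference()` emulates the structure of the reporter plasmid used
to characterise the system: a circular (by default) sequence carrying
one planted PAM + protospacer cassette per requested target gap, the
target CpG embedded in an FspI site (TGCGCA, CpG at internal positions
3–4) so the restriction-protection assay applies, at least two FspI
sites overall, and ~240 background CpG sites (matching the reporter's
241 off-target CpG census). The background sequence is CpG-free outside
planted sites, so the generator knows exactly where every CpG is.

Ground-truth per-cytosine, per-strand probabilities default to
independent draws from Beta(0.5, 99.5) — mean 0.5% — chosen once so the
simulated plasmid sits in the observed sub-1% median off-target regime.
An optional proximity mode inflates the background within a window of
the target PAM to mimic topology-driven off-target methylation, which
concentrates within a few hundred bp of the bound site.

Downstream: `sample_molecules()` draws Bernoulli states per molecule;
`bisulfite_convert()` converts unmethylated cytosines to T on both
strands (conversion efficiency defaults to 1.0 — no failed-conversion
rate is published — and non-CpG cytosines always convert, since the
MTase is CpG-specific); `sample_reads()` draws uniform-start single-end
reads (wrapping on plasmids) whose names encode molecule, strand and
start for oracle testing; `digest_fspi()` cuts each unprotected TGCGCA
bluntly between positions 3 and 4.

What the generator deliberately does **not** model: PCR amplification
bias, quality scores and adapter content, paired-end inserts,
library-size selection, and failed conversion at non-CpG cytosines.
Passing tests on this generator therefore demonstrate correctness of the
pipeline's arithmetic and bookkeeping under an idealised error model,
not robustness to real library artefacts.

## Quantification

`align_bisulfite()` is a native toy-scale three-letter aligner: reads
and both reference strands are C→T collapsed, and every offset on both
strands is scanned exhaustively; the unique best placement within
`max_mismatches` (default 2) wins, ambiguous bests are discarded, and
unaligned reads are counted, not fatal. This is exact and
dependency-free but quadratic — intended for references up to a few tens
of kb, not genomes. `call_methylation()` then reads C (methylated) / T
(unmethylated) at reference cytosines on the assigned strand,
aggregating per position, strand and CpG/non-CpG context. Zero-coverage
cytosines report `NA`, never 0.

Summary statistics mirror the published analysis: `fold_preference()`
divides the (maximum) target fraction by the median off-target fraction,
floored at `1/(2 × total off-target calls)` to avoid division by zero on
finite samples; `compare_profiles()` is squared Pearson correlation on
raw fractions (no transform); `comethylation_matrix()` reconstructs
same-molecule co-methylation from the simulator's molecule labels,
mirroring what clonal bisulfite sequencing adds over population-level
pyrosequencing. Sites under 10 calls (configurable) are excluded from
medians and correlations as unstable; no multiple-testing machinery is
applied because the pipeline reports descriptive estimates only.

## Worked pipeline

```{r, eval = FALSE}
ref <- build_reference(n_offtarget_cpgs = 240, target_gaps = 12,
                       topology = "circular", seed = 1)
tpos <- ref$targets$c_forward_pos + 1L          # trans cytosine
spec <- set_site_probability(ref$spec, tpos, "-", 0.344)
states <- sample_molecules(spec, 2000, seed = 2)
conv <- bisulfite_convert(states, ref$record, spec)
reads <- sample_reads(conv, ref$record, read_length = 75,
                      depth = 1000, error_rate = 0, seed = 3)
tab <- call_methylation(align_bisulfite(reads, ref$record))
tab[tab$pos == tpos & tab$strand == "-", ]
fold_preference(tab, data.frame(pos = tpos, strand = "-"))
```

With 2000 molecules at depth 1000 the recovered target fraction carries
a standard error of about 2.4 percentage points (molecule sampling plus
per-strand read sampling), so estimates typically land within a few
points of the specified 34.4%. These problem sizes (a ~2.6 kb reference,
~35k reads) were chosen as the package's standard demonstration scale;
the test suite uses smaller versions of the same constructions.

## Numerical and degenerate-input choices

* Angles are normalised to `[0, 360)`; separations to `[0, 180]`.
* `peak_gaps()` compares profile values within 1e-12 of the maximum, so
  the rounded default profile reports exact ties; ties return all tied
  gaps ascending.
* An all-zero profile has no targetable window and errors rather than
  returning an empty range.
* Reads longer than the reference, mismatched record pairs, and
  probabilities outside `[0, 1]` error early with explicit messages.
* Every stochastic step takes an explicit seed; identical seeds give
  byte-identical FASTQ output.

## Known limitations

The aligner and simulator are plasmid-scale by design. The efficiency
profile is a shape-constrained stand-in until calibrated with user data.
The interference margin between 4 and 33 bp is an extrapolation.
Human-cell quantities (promoter methylation percentages, off-target
correlation values measured on real sequencing data) require the
original deposited reads and cell experiments; the package covers the
corresponding machinery with property tests on synthetic data instead of
claiming to reproduce those numbers.
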