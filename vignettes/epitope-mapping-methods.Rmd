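---
title: "Methods: peptide-scan epitope mapping, plate workup and inhibitor titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-scan epitope mapping, plate workup and inhibitor titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscanr)
```

pepscanr implements the laboratory workup used to characterise
anti-ADAMTS13 autoantibodies in immune-mediated thrombotic
thrombocytopenic purpura (TTP), as an end-to-end, testable pipeline:
overlapping-peptide library design, peptide-ELISA positivity calling,
epitope-region deconvolution across a patient cohort, Bethesda inhibitor
titration, and total-immunoglobulin quantification. This vignette explains
the model behind each stage, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-cohort tests do and do not
demonstrate about real data.

## Peptide-scan design

Linear B-cell epitopes are localised by tiling a protein region with
fixed-length peptides at a constant offset: 20-mers advanced 5 residues at
a time, so consecutive peptides share 15 residues. An antibody binding a
linear epitope of at least the overlap length must light up a *run* of
consecutive peptides, and the geometry of that run localises the epitope
more finely than any single peptide.

`tile_peptides()` starts a window every `offset` residues from the region
start and always emits a final full-length window ending exactly at the
region end. When the region span minus the window length is not a multiple
of the offset, that last window is off the offset grid; it is emitted
anyway, with a warning, because truncating the scan would leave the region
C-terminus uncovered. Coordinates are 1-based and inclusive throughout, the
convention of the serology literature.

The packaged fixtures describe the ADAMTS13 proximal domains. Two points
deserve note:

* **Region bounds.** The domain grouping table of the source assay lists
  the metalloprotease–disintegrin block as 75–383 and the
  cysteine-rich–spacer block as 440–680, but the published peptide
  coordinates (a final 20-mer at 365–384, and a final spacer peptide
  ending at 684) are only consistent with tiled ranges 75–384 and
  440–684, which also reproduce the published library size of
  59 + 46 = 105 peptides. The fixtures use 75–384 and 440–684.
* **Synthetic scaffold sequence.** No sequence accession ships with the
  assay description, so the packaged FASTA
  (`adamts13_proximal_synthetic.fasta`) is a synthetic stand-in assembled
  from published peptide fragments whose printed coordinates and lengths
  agree; the ~28% of positions not covered by a consistent fragment carry
  deterministic placeholder residues (seed 13, recorded in
  `data-raw/synthetic_protein.R`). Every computation in the package
  depends only on the geometry, which is exact; the placeholder residues
  affect only cosmetic sequence display for unanchored spans.

Peptide names follow the field convention of deriving names from domain
names (`MP1`, `Cys/Spa20`, `Dis/TSP1 59`): a peptide overlapping two
annotated domains gets a compound label, N-terminal domain first — also
when the straddle is an exact half/half split. Domain boundaries in the
fixture (MP to 285, Dis 286–383, Cys to 549, Spa 550–680, with short
thrombospondin stubs closing each region) were inferred from which
published peptides carry simple versus compound names; the
cysteine-rich/spacer boundary is the midpoint of the feasible window
(545–554) left by those constraints.

## Plate workup and positivity calling

The plate model follows standard ELISA practice:

1. **Blank subtraction** (`subtract_blanks()`): the mean OD of each
   plate's blank wells is subtracted from every other well on that plate.
   Corrected values below zero are floored at 0 with a warning; blanks
   become 0, which makes the operation idempotent.
2. **Duplicate averaging** (`average_duplicates()`): each patient ×
   analyte is assayed in duplicate; the pair is collapsed to its mean, and
   pairs whose absolute spread exceeds 20% of the mean (configurable) are
   flagged discordant but kept — dropping them silently would bias a
   positivity screen.
3. **Cut-off** (`compute_cutoff()`): `mean + k·SD` of the plate's
   negative-control wells, with `k = 3` by default — the standard
   serology convention, chosen here because the source assay states that a
   cut-off exists without giving its form. At `k = 3` the nominal
   false-call rate per well is the one-sided normal tail, about 0.13%,
   *provided the control SD is well estimated* (see the simulator notes
   below).
4. **Call** (`call_binding()`): positive means *strictly greater* than
   the cut-off; a well exactly at the cut-off is negative.

Total IgM/IgA quantification fits the conventional four-parameter
logistic to the standard series by Levenberg–Marquardt least squares and
inverts it analytically; ODs at or beyond the asymptotes are flagged
rather than quantified, and quantifiable values outside the standard range
are flagged as extrapolated. Standards whose mean ODs dip by more than 5%
of the dynamic range between consecutive concentrations are rejected as
non-monotone; smaller dips are treated as plate noise (the 4PL fit is
unaffected by them, and the log-linear fallback interpolates isotonised
means). Reference ranges are IgA 1.1–2.6 and IgM 0.23–1.4 mg/mL in
citrate plasma.

## Epitope deconvolution

Per patient, maximal runs of positive peptides whose intervals share at
least one residue are merged into epitope regions
(`merge_positive_peptides()`). Two positives that merely touch (zero
shared residues) are *not* merged: with a 5-residue offset, a skipped
intervening peptide is evidence of two distinct reactivities.

Within a region, the **core** is the span of residues covered by the
maximal number of supporting peptides (`core_epitope()`). The strict
all-peptide intersection is offered as an alternative
(`mode = "intersection"`) but is empty whenever a run is longer than
`length/offset` = 4 peptides, so maximal coverage is the default; when
intersection mode encounters an empty intersection it falls back to the
maximal-coverage core with a warning. For a clean run of consecutive
positives the maximal-coverage core reproduces the kind of ~20-residue
"epitope area" reported for the C-terminal spacer region (a run of
peptides 645–684 yields core 650–669).

Cohort pooling (`epitope_map()`) groups regions with identical
supporting-peptide sets across patients; a region's frequency is the
fraction of the cohort positive for *all* of its supporting peptides, and
regions at or above the `shared_threshold` (default 0.5, configurable —
the source assay does not state its shared/non-shared criterion) are
reported as shared. Domain reactivity is called per patient: a domain is
reactive if any positive peptide overlaps it, straddling peptides counting
for both neighbours. The per-patient summary category runs over the
metalloprotease/disintegrin pair and the cysteine-rich/spacer pair
(`MP_only`, …, `Cys_and_Spa`, `all_four`, `none`); when both pairs are
reactive but not all four domains, the pair with more reactive domains
names the category, ties resolving to the cysteine-rich/spacer pair (the
immunodominant axis in this assay). The seven-row reporting table produced
by `report_tables()` instead counts each pair-axis predicate
independently, which is how such cohorts are conventionally tabulated
(its rows are not mutually exclusive); percentages are printed as whole
numbers (53 of 59 prints as 90%).

## Mixing study and Bethesda titration

Heat-inactivated patient plasma (56 °C, 1 h — modelled in the simulator
as zero endogenous activity) is mixed 1:1 with pooled normal plasma
(PNP). Residual activity is `RA = 100 · mix / PNP` percent. RA of 25–75%
(inclusive) is the quantifiable inhibitor band; above 75% there is no
clinically significant inhibitor.

One Bethesda unit is the inhibitor amount halving activity, giving the
classical relation `RA = 100 · 2^(−BU)`; the package adopts it because
the source assay defines 1 BU as a 50% reduction without printing a
formula. Over a saline dilution ladder, `bethesda_titre()` picks the
in-band dilution with RA closest to 50% (ties to the lower dilution) and
reports `log2(100/RA) · dilution` BU/mL. If every dilution reads above
75% the titre is 0; if every dilution reads below 25% the sample needs
further dilution and the function says so as an error. The `dilution`
column is the pre-mix saline fold-dilution; the fixed 1:1 mix with PNP is
part of the assay definition, not folded into it. Classification is
non-inhibitory < 0.5, low 0.5–5, strong > 5 BU/mL; the published bands
leave exactly 5 BU unassigned ("<5" and ">5"), and the package assigns it
to *low* so the classes partition the axis.

## The synthetic cohort generator

`generate_cohort()` emulates the data shapes above so that every stage is
testable without patient material. Its defaults are the package's fixed
study conditions:

* **Cohort**: 53 patients, matching the size of the published
  epitope-mapped cohort.
* **Planted epitopes**: each patient draws intervals independently from a
  catalog (`default_epitope_catalog()`) of eight immunodominant areas
  with population frequencies taken from published cohort reactivity
  rates (two universal areas — the first metalloprotease peptide and the
  C-terminal spacer region — and six intermediate ones). Catalog entries
  are spaced so different epitopes never produce overlapping positive
  runs, keeping planted and recovered epitopes in one-to-one
  correspondence for scoring.
* **OD model**: a peptide's expected corrected OD is
  `baseline + amplitude · 1[overlap ≥ 10 residues]` with per-well
  Gaussian noise (baseline 0.10, amplitude 0.80, noise SD 0.05, all in OD
  units). The step-at-half-peptide-overlap model is the simplest that
  reproduces the runs-of-consecutive-positives structure of real
  peptide-scan data; a graded linear-overlap mode is available
  (`graded_signal = TRUE`).
* **Plate layout**: duplicate wells on 96-well plates, each plate
  carrying two blanks and **twelve** sero-negative control wells. The
  control replication is deliberate assay design, not an arbitrary
  layout: with `mean + 3·SD` cut-offs the false-call rate only approaches
  its nominal ~0.1–0.2% per well when the SD is estimated from enough
  replicates (with duplicate controls the estimate is so unstable that
  false calls run near 6% per peptide, visibly corrupting downstream
  region cores).
* **Inhibitor titres**: a three-component log-normal mixture in
  proportions 17:17:19 with medians 0.10, 1.85 and 9.74 BU/mL
  (log-scale SDs 0.40, 0.49, 0.31 back-computed from the published group
  ranges), sampled per patient; the mixing series follows
  `RA = 100 · 2^(−BU/dilution)` over a 1–64-fold ladder with 2% activity
  noise.
* **Immunoglobulins**: IgM ~ N(1.59, 0.27²), IgA ~ N(2.10, 0.60²) mg/mL
  (published cohort means), read through a fixed 4PL with the same plate
  noise.

All randomness flows from the single `seed` through `withr::with_seed()`,
so generation is byte-reproducible and leaves the caller's RNG state
untouched.

`score_recovery()` compares pipeline output with the planted truth: a
planted epitope is *recovered* when some inferred core midpoint in the
same patient lies within 5 residues (the tiling offset) of the epitope
midpoint; region sensitivity/precision, Bethesda relative error and class
agreement, and immunoglobulin relative error are reported alongside. At
the default conditions the 53-patient cohort recovers ≥ 90% of planted
epitopes and ≥ 95% of inhibitor classes (the packaged tests assert
exactly this, and a noiseless run is exact: interior epitope cores land
within half an offset of the planted midpoint, and titres are recovered to
machine precision).

**What the simulator does not model**: graded antibody affinity and
avidity effects, polyclonal mixtures binding overlapping but distinct
epitopes within one area, plate-position (edge) effects, inter-plate
drift, cross-reactive or conformational binding, and prozone effects.
Passing recovery tests therefore demonstrates that the *pipeline
arithmetic* is correct under the stated noise model — not that the assay
itself has these operating characteristics on patient material. Epitopes
planted at the extreme ends of a tiled region are intrinsically harder:
the positive run is truncated by the region boundary, biasing the core
midpoint by up to one offset (the packaged universal areas at 75–94 and
645–684 sit exactly at this 5-residue limit, which is why the recovery
tolerance equals the offset).

## Numerical choices and degenerate inputs

* Ties at the positivity cut-off are negative; band edges at 25% and 75%
  RA are in-band; exactly 5 BU/mL is *low*.
* A single negative control yields SD = 0, so the cut-off equals that
  control's OD.
* Corrected ODs below zero are floored at 0 (warned), keeping blank
  subtraction idempotent.
* Region merging is order-independent; calls are sorted internally.
* Off-grid final tiling windows are emitted with a warning rather than
  silently dropped or silently shifted.
* Problem sizes in the packaged tests — 53-patient cohorts, 1,000-case
  merge/core oracle sweeps, hundred-plate false-call simulations — were
  chosen as the smallest sizes at which the Monte-Carlo properties are
  stable.

## Known limitations

* The epitope model is strictly linear; discontinuous (conformational)
  epitopes are out of scope by construction of the assay.
* The published "epitope area" sequence for the C-terminal spacer region
  is printed as 30 residues against a 20-position coordinate span; the
  package reports both the maximal-coverage core and the intersection
  candidate rather than guessing intent.
* The shared/non-shared threshold and the cut-off multiplier are
  conventions (0.5 and 3), configurable because the source assay states
  neither.
* The fixture's placeholder residues mean peptide *sequences* outside the
  published fragments are not biologically meaningful; coordinates and
  names are.
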