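---
title: "Annotating cyclic surfactin homologs from LC-ESI-MS/MS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cyclic surfactin homologs from LC-ESI-MS/MS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfannot)
```

## The problem

Surfactins are cyclic lipopeptides produced by *Bacillus* species: a
seven-residue peptide closed into a lactone with a β-hydroxy fatty acid of
variable chain length. A producing strain secretes a *family* of homologs
that differ only in the acyl chain, so their protonated molecular ions form
a ladder of peaks spaced by one CH₂ (14.0157 Da) in the MS1 survey — for
the C12–C15 homologs, \[M+H\]⁺ near m/z 994, 1008, 1022 and 1036 — usually
accompanied by sodiated partners 21.982 Da higher and dehydration
satellites 18.011 Da lower. Collision-induced dissociation (CID) of one
precursor produces prefix (b-type) and suffix (y-type) fragment ladders
whose consecutive mass gaps are amino-acid residue masses; reading those
gaps, plus the mass left over at the head of the b ladder, identifies the
peptide sequence and the acyl chain length.

`surfannot` mechanises this desk arithmetic as a reproducible pipeline:
homolog-series detection and adduct/neutral-loss pairing on MS1 peak lists,
spectrum-graph ladder reconstruction and family classification on MS2 peak
lists, the companion plate-assay statistics (residual activity rate, MIC
calling, inhibition-zone grading), and a synthetic-data generator that
makes every stage testable without instrument files.

## The mass model

All arithmetic is monoisotopic. Residue masses (the amino acid as
incorporated in a chain, i.e. minus water) ship as a plain-text table that
users can override (`residue_mass_table()`). Two ambiguity groups are
handled explicitly:

* **Leu/Ile** are exactly isobaric and are merged into one reporting
  symbol, `"Leu/Ile"`.
* **Gln/Lys** differ by 0.036 Da — far below the working accuracy — so
  whenever one matches, the other is co-reported.

The acyl moiety follows the linear homolog law
\(L(n) = 14.01565\,n + 29.97418\) Da, i.e. the composition CₙH₍₂ₙ₋₂₎O₂ of
the β-hydroxy acyl unit as it exists inside the closed lactone. This
calibration is a reconstruction — unit-resolution spectra cannot fix the
elemental composition — but it is the one under which
\(\mathrm{proton} + L(n) + \sum \mathrm{residues}\) reproduces all four
published precursors within 0.7 Da, and it is exposed as a configurable
`lipid_series()` (default domain C8–C20; the surfactin template accepts
C10–C17).

## Tolerances

Unit-resolution CID peak lists are sloppy: the published fragment
arithmetic this package mirrors deviates from monoisotopic theory by up to
~1.5 Da in single gaps. Three tolerance classes are used, all configurable
through `annotation_config()`:

| tolerance | default | governs |
|---|---|---|
| `step_tol` | 0.8 Da | residue matching of single mass gaps (graph edges, candidate sets) |
| `anchor_tol` | 1.2 Da | lipid-anchor residual, b/y complement sums, template re-checks |
| `loss_tol` | 0.75 Da | water-loss (neutral-loss) searches |
| `ms1_tol` | 0.1 Da (0.6 in nominal mode) | homolog spacing in MS1 |

The step tolerance is deliberately tighter than the anchor tolerance: a
single gap involves two peaks, while the anchor residual accumulates the
error of a peak plus several summed reference masses. `nominal = TRUE`
widens the MS1 tolerance for peak lists printed as unit-mass integers.

Fixed template positions are re-checked against the *raw* mass gap at
`template_tol` (1.2 Da) rather than only against the 0.8 Da candidate set.
This matters in real data: in the published C13 spectrum the gap assigned
to Asp is 1.08 Da off, so its best 0.8 Da candidate is Asn; the wider
re-check, applied only where the family template pins a residue, accepts
the assignment without loosening the candidate sets everywhere else.

## Ladder reconstruction

`build_spectrum_graph()` formalises manual differencing: peaks are nodes
and a directed edge u→v exists when v−u matches a residue within
`step_tol`. Molecular-ion satellites (peaks above the precursor minus the
smallest residue mass) are excluded — they are not backbone fragments.
Ladders are paths in this DAG.

`extract_ladder()` offers two strategies. `"longest"` returns the single
longest path, ties broken by total intensity, then lower starting m/z,
then lexicographic order — fully deterministic, and property-tested against
exhaustive enumeration. `"maximal"` returns every maximal path.

`annotate_spectrum()` does **not** simply take the longest path, because
suffix-ion peaks can chain into prefix-ion peaks by coincidence: in the
C12 worked example the y-rung at 440.16 sits 113.91 Da (an Asn match)
below the b-rung at 554.07, so the single longest path is a chimeric
six-rung mix of both ladders. Instead, every contiguous window of every
maximal path is interpreted against each complete family template:

1. With \(r\) rungs, the first \(p = L_{\mathrm{template}} - r\) positions
   are folded into the lipid anchor. Template-consistent prefix residue
   combinations are enumerated (fixed positions contribute their residue,
   variable positions the template's variable domain), and the anchor
   residual `first rung − proton − Σ prefix` is matched against the lipid
   law at `anchor_tol`.
2. The remaining positions come from the ladder's residue steps and from
   the terminal gap `precursor − top rung`.
3. Fixed template positions are checked as described above; the chain
   length must lie in the template's lipid range.

Each surviving interpretation is scored as

> **score = assigned positions − total absolute mass discrepancy (Da)**,

where the discrepancy sums the anchor error, every step's best-candidate
error and the terminal error. The highest score wins; ties (compared at
1e-6) go to the ladder with more rungs, then the lower starting m/z. The
total-error form (rather than a mean) is what lets the pipeline prefer a
shorter self-consistent ladder over a longer chimera: the chimeric
interpretation drags in a ~1 Da anchor misfit that a mean would dilute.

Two deliberate tie-breaking rules deserve note:

* **Isobaric prefixes.** Because Leu = Val + CH₂ exactly, the prefix
  (Glu, Leu/Ile) with a C12 chain and (Glu, Val) with a C13 chain give
  numerically identical anchor errors. Ties (compared at 1e-4 Da, which
  also absorbs rounding of the mass constants) resolve toward the smaller
  chain length — mass is assigned to the peptide before the lipid. These
  alternatives are genuinely indistinguishable at this accuracy; the
  reported sequence records the ambiguity sets.
* **b/y identity.** A candidate ladder is accepted as b-type only if it
  admits a valid lipid anchor under some template; the y-type suffix
  ladder is then extracted from the peaks the b ladder did not consume.
  Complement pairs (b + y ≈ precursor, within `anchor_tol`) are reported
  as a confidence feature and never veto an annotation.

A spectrum matching no template returns a valid annotation with family
`"unassigned"` built from the plain longest path.

### Position numbering

Following the convention for this compound class, the acyl chain counts as
position 1 of the molecule and the peptide residues are numbered 1–7; the
terminal residue read from the precursor gap is therefore the "b8"
assignment in the source nomenclature. The mapping to conventional
proteomics indices is: molecule position *k* (peptide residue *k*) ↔
b\(_{k+1}\) prefix ions; the reported b-rung at prefix length *k* covers
the acyl chain plus residues 1..*k*.

## The synthetic generator

`generate_theoretical_spectrum()` produces the noiseless fragment pattern:
precursor \(= \mathrm{proton} + L(n) + \sum\mathrm{residues}\); b rungs at
prefix lengths 2–6; y rungs as plain suffix residue sums of lengths 3–5
(the suffix-sum model, without proton or water terms, is the absolute-mass
convention consistent with the published y values); optional water-loss
and molecular-ion peaks. `add_noise()` adds Gaussian m/z jitter (default
0.2 Da for MS2 fragments — under which the worst published deviations are
~3.75 sd — and 0.02 Da for the MS1 survey, whose centroids are far more
accurate than CID arithmetic), decoy peaks, and log-normal intensities.

Decoys are drawn uniformly (default m/z 200–1000) subject to an exclusion
rule: at least `decoy_exclusion` (2 Da) from every existing peak **and**
from every residue relation with every existing peak, so default-mode
decoys cannot take part in any ladder and recovery tests are well-posed.
An adversarial mode instead places decoys exactly at residue offsets to
stress tie-breaking; it is exercised in the test-suite but makes no
recovery guarantee. All generators are deterministic given their seed.

What the simulator does *not* emulate: chromatographic peak shapes,
isotope envelopes, multiple charge states, intensity physics, and
correlated mass-calibration drift (jitter is independent per peak).
Passing round-trip tests therefore show the reconstruction logic is
correct under the stated noise model, not that the pipeline is robust to
every artefact of real instrument data.

The bioassay generator draws zone diameters
\(\mathrm{DAC} = \mathrm{DAC}_{\mathrm{control}} \times \mathrm{rate}/100
+ \mathcal{N}(0, \sigma)\), truncated at zero, around a configurable true
residual-rate curve. The default curve emulates a thermal-stability
design: 40–80 °C held over 10 days with retention declining linearly to
96–85 % graded by temperature, a control at 100 %, 3 replicates,
σ = 0.5 mm, control diameter 32 mm.

## Bioassay statistics

* `residual_rate()` is the plain ratio 100 × DAC(treated)/DAC(control);
  it is scale-invariant and may exceed 100 %.
* `mic_from_dilution()` first checks controls (the positive control must
  grow, the negative must not), then calls the MIC as the lowest
  concentration showing no growth. Growth reappearing *above* the MIC is
  biologically anomalous; the call is returned with a non-monotonicity
  flag rather than suppressed. This definition is stated explicitly
  because dilution-series practice varies on how skipped wells are read.
* `grade_dac()` maps diameters to the −/+/++/+++ scale with left-closed
  bins. The cut-offs (10/20/30 mm) are a documented reconstruction — the
  scale itself is conventional and source material rarely defines the bin
  edges — anchored so that a zone over 3 cm scores "+++"; they are
  configurable.
* `summarize_stability()` applies the rate row-wise against the
  time-matched control mean and aggregates replicates to mean ± sd; a
  missing time-matched control is an alignment error, not a silent drop.

## Numerical choices and degenerate inputs

* Duplicate m/z within a spectrum are merged by intensity sum at
  construction (graph code assumes strictly ascending peaks); the merge is
  logged.
* Empty spectra, empty graphs, header-only tables, and all-growth
  dilution series all return well-defined empty/no-match results rather
  than errors; a negative anchor residual and a missing control are hard
  errors because they indicate an inconsistent interpretation or design.
* Maximal-path enumeration is capped (default 10 000 paths) with a
  warning; the cap is unreachable for exclusion-respecting inputs.
* Scores are compared after rounding to 1e-6 and anchor errors to 1e-4 so
  that floating-point noise and mass-constant rounding cannot flip
  deterministic tie-breaks.

## Test problem sizes

The shipped suite validates series detection against exhaustive chain
enumeration on 100 random spectra of up to 50 peaks, ladder extraction
against exhaustive longest-path search on 100 random graphs of up to 12
peaks, noiseless annotation round-trips for every chain length C10–C17,
and noisy recovery (0.2 Da jitter, 20 decoys per spectrum) over 100
simulated homolog spectra, requiring at least 95 % family-and-chain
recovery. Monte-Carlo recovery of the stability curve uses 6 replicates
per condition-time cell and a 3-propagated-sd band. These sizes were
chosen as the smallest that exercise the combinatorics convincingly.

## Known limitations

* Only singly protonated species are modelled: no charge states above 1,
  no deisotoping, no average-mass mode.
* Iturin and fengycin templates ship as incomplete stubs; only the
  surfactin template is complete, so spectra of other families return
  `"unassigned"` rather than a competing label.
* The y-ion absolute-mass convention (plain suffix sums) was chosen for
  consistency with the published ladder arithmetic; data calibrated to
  the standard proton+water y convention will still sequence correctly
  through consecutive differences but may lose complement pairs.
* MGF and delimited peak tables are the only input formats; profile data
  and vendor formats must be converted upstream.
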