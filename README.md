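# surfannot

Annotation of cyclic surfactin-family lipopeptides from LC-ESI-MS/MS peak
lists, plus the companion antimicrobial-assay statistics.

Surfactins are cyclic lipopeptides from *Bacillus*: a seven-residue peptide
(Glu¹–X²–Leu³–X⁴–Asp⁵–Leu⁶–X⁷, with X generally Val/Leu/Ile) closed into a
lactone with a β-hydroxy fatty acid of variable chain length. Homologs
differ by CH₂ units in the acyl chain, so their protonated precursors form
a 14.0157 Da-spaced series in MS1 (e.g. m/z 994, 1008, 1022, 1036 for
C12–C15), with [M+Na]⁺ partners +21.982 Da and [M−H₂O]⁺ satellites
−18.011 Da. CID fragmentation yields b-type prefix and y-type suffix ion
ladders whose consecutive gaps are residue masses; the mass left at the
head of the b ladder, `first rung − proton − Σ leading residues`, inverts
the acyl mass law `L(n) = 14.01565·n + 29.97418` Da to give the chain
length n.

`surfannot` implements this end to end, for people who have centroided
peak lists (MGF or delimited tables) and want reproducible, tolerance-
controlled homolog annotation instead of manual differencing:

- **masses** — monoisotopic residue/lipid/adduct mass tables and matching
  (`residue_mass_table()`, `match_residue()`, `lipid_series()`,
  `chain_length_from_mass()`), with Leu/Ile merged and Gln/Lys co-reported.
- **MS1** — homolog-series detection, sodium-adduct pairing, neutral-loss
  search (`detect_homolog_series()`, `pair_sodium_adducts()`,
  `find_neutral_loss()`).
- **MS2** — spectrum-graph construction, deterministic ladder extraction,
  lipid-anchor chain-length inference, b/y complement reconciliation,
  template-based family classification, and the orchestrating
  `annotate_spectrum()`.
- **bioassay** — residual activity rate (100 × DAC ratio), MIC calling
  from broth-dilution series with control quality gates, inhibition-zone
  grading, stability summaries.
- **simulation** — a seeded generator of surfactin-like MS1/MS2 spectra
  (jitter, exclusion-constrained decoys, adducts, water loss) and bioassay
  tables, used throughout the test suite.
- **pipeline / CLI** — `pipeline_annotate()`, `pipeline_simulate()`,
  `pipeline_bioassay()` write TSV/JSON reports plus a reproducibility
  manifest; `exec/surfannot` is a thin command-line wrapper
  (`surfannot annotate --input run.mgf --out results`).

## Worked example

Annotate the C12 homolog from its printed fragment peak list:

```r
library(surfannot)

sp <- ms_spectrum(c(341.13, 440.16, 553.99,                  # y ladder
                    441.05, 554.07, 653.36, 768.42, 881.66,  # b ladder
                    976.53),                                 # [M-H2O]+
                  ms_level = 2, precursor_mz = 994, rt = 6.53)
annotate_spectrum(sp)
#> Lipopeptide annotation (precursor m/z 994.0000, Rt 6.53 min)
#>   family: Surfactin, acyl chain C12 (anchor error -0.246 Da)
#>   sequence: Glu-Leu/Ile-Leu/Ile-Val-Asp-Leu/Ile-Leu/Ile
#>   b ladder: 5 rungs; y ladder: 3 rungs; 3 complement pair(s)
#>   water loss [M-H2O]+ at 976.53 (error +0.541 Da)
#>   score: 5.535
```

Reading the output: the winning b-type ladder is
441.05 → 554.07 → 653.36 → 768.42 → 881.66 (residue gaps Leu/Ile, Val,
Asp, Leu/Ile); the terminal gap 994 − 881.66 = 112.34 Da matches Leu/Ile;
the anchor residual 441.05 − 1.007 − (Glu + Leu/Ile) sits 0.246 Da below
the C12 acyl mass, giving the chain length; the y ladder
341.13 → 440.16 → 553.99 supplies three b/y complement pairs (e.g.
994 − 553.99 = 440.01 against the b rung 441.05). The score is the number
of assigned positions (7) minus the summed absolute mass discrepancies in
Da. The same call on the m/z 1008 peak list yields Surfactin C13.

MS1 series detection on the four precursors:

```r
detect_homolog_series(c(994, 1008, 1022, 1036), tol = 0.6)[[1]]
#> Homolog series: 4 members, fitted spacing 14.0000 Da (target 14.0157)
#>   m/z: 994.0000 -> 1008.0000 -> 1022.0000 -> 1036.0000
```

And the bioassay side:

```r
tab <- generate_bioassay_table(sim_bioassay_config(seed = 1))
head(summarize_stability(tab, "control"), 4)
#>   condition time mean_rate   sd_rate n
#> 1       40C    0  98.39846 0.8332490 3
#> 2       40C    2  98.31805 1.8604538 3
#> 3       40C    4 100.95488 0.2020843 3
#> 4       40C    6  98.97349 1.4405414 3
grade_dac(c(31, 22, 15, 8))
#> [1] +++ ++  +   -
#> Levels: - < + < ++ < +++
```

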