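# mcpminer

Mining multicopy neuropeptide precursors from translated transcriptomes.

## The problem

Neuropeptide precursors (preproneuropeptides) are hard to find by homology
alone: the active peptides are short, fast-evolving, and often specific to
a clade. What *is* conserved is their architecture — an N-terminal signal
peptide, then multiple near-identical peptide paracopies excised at
dibasic `[KR]-[KR]` convertase sites, each often followed by a glycine
that becomes a C-terminal amide. `mcpminer` operationalizes that
architecture as a tested, reusable pipeline for anyone surveying
peptidergic signaling in non-model transcriptomes:

- **Motif scanning** with PROSITE-style variable-gap patterns such as
  `x(5, 200)-G-[KR]-[KR]-x(2, 35)-G-[KR]-[KR]-x(2, 35)-G-[KR](0, 1)`
  (amidated multicopy precursors), plus non-amidated and RFamide/monobasic
  variants (`builtin_patterns()`), with a parser and scanner for custom
  patterns.
- **Prohormone processing model**: signal-peptide gate (external predictor
  scores at a 0.34 cutoff, or a built-in heuristic for testing), dibasic
  and monobasic cleavage prediction, peptide excision, amidation via the
  Gly donor (`annotate_precursor()`).
- **Multicopy-peptide (MCP) family calling**: single-linkage grouping of
  paracopies under a normalized BLOSUM62 alignment similarity,
  position-frequency matrices, consensus motifs like `SFxNa` with `x` for
  variable positions, cross-dataset family merging with per-dataset
  presence (`group_paracopies()`, `merge_families()`).
- **Reciprocal search** for hidden orthologs: exact Smith–Waterman with
  BLOSUM62/BLOSUM45 and Karlin–Altschul e-values
  (`E = K·m·n·e^(−λS)`), reciprocal-best-hit annotation, and a 12-column
  tabular adapter for external engines (`reciprocal_search()`).
- **Mass confirmation**: theoretical monoisotopic masses under fixed
  carbamidomethyl-C and variable oxidation/acetylation/sulfation, with
  amidation forced by the precursor model, matched to observed neutral
  masses within 4.5 ppm (`enumerate_modified_forms()`, `match_masses()`).
- **A ground-truthed synthetic benchmark** — decoy proteomes with planted
  precursors and matching mass lists — so every stage is testable without
  downloads (`generate_proteome()`).

See the methods vignette (`vignettes/mcp-discovery.Rmd`) for the model,
parameter rationale, and limitations.

## Worked example

Run the pipeline on a simulated benchmark with known truth:

```r
library(mcpminer)

gen <- generate_proteome(plant_spec(n_decoys = 150, n_planted = 12,
                                    seed = 17))
report <- run_pipeline(list(synth = gen$proteins),
                       pipeline_config(seed = 17))
report
#> MCP discovery report
#>   input            synth=162
#>   motif_prefilter  synth=12
#>   signal_gate      synth=12
#>   mcp_call         precursors=12 groups=12
#>   families         families=3
#>   reciprocal       pairs=12
#>   3 MCP families: PxFVa, LxFa, SFxNa
```

The log is the candidate funnel: 162 input proteins, 12 survive the motif
prefilter, all 12 pass the signal-peptide gate, all 12 are called MCP
precursors (≥ 2 similar paracopies), and their paracopy groups merge into
the three planted families — named by consensus, `x` marking variable
positions, trailing `a` marking uniform amidation. Scoring against the
ground truth:

```r
evaluate_recovery(report, gen$truth, n_decoys = 150)
#> $recall           [1] 1
#> $family_accuracy  [1] 1
#> $decoy_fpr        [1] 0
#> $n_planted        [1] 12
#> $n_recovered      [1] 12
```

Individual precursors print as processed products, e.g. a `PxFVa`
precursor's peptides include `PEFV-NH2`, `PNFV-NH2`, `PTFV-NH2` —
amidated paracopies interleaved with spacer segments. `write_report()`
emits the full TSV/FASTA report (calls, peptides, families, presence
matrix, PFMs, reciprocal pairs, mass matches, run log).

Real data enters the same way: `translate_fasta()` for six-frame
translation of transcripts, `read_fasta(..., "protein")` for proteins,
`read_signal_table()` for external signal-peptide predictions, and
`read_observed_masses()` for peptidomics mass lists. A thin CLI over
these functions is included at `inst/scripts/mcpminer.R`.

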