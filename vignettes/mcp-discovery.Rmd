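---
title: "Discovering multicopy neuropeptide precursors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering multicopy neuropeptide precursors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpminer)
```

## The biological model

Neuropeptides are short secreted signaling peptides. They are not encoded
directly: a precursor protein (preproneuropeptide) carries an N-terminal
signal peptide followed by a propeptide region in which one or more active
peptides are embedded between cleavage sites recognized by prohormone
convertases. Three features of this architecture are exploitable for
sequence-level discovery, and together they define everything this package
computes:

1. **Secretion.** A genuine precursor must begin with a signal peptide.
   Sequences whose 5' end is missing cannot be tested for one and are
   tracked as *untestable* rather than negative.
2. **Processing.** Convertase cleavage occurs predominantly at dibasic
   sites (KK, KR, RK, RR) and occasionally at single basic residues in
   specific contexts. A glycine immediately preceding a site is not part
   of the mature peptide: it is consumed as the amide donor, leaving the
   preceding residue C-terminally amidated.
3. **Recurrence.** Many invertebrate neuropeptide precursors are
   *multicopy* (MCP): they carry several near-identical paracopies of the
   active peptide. Recurrent `G-[KR]-[KR]` (amide donor + dibasic) blocks
   at bounded spacings are a strong precursor signature even when the
   peptide itself has no detectable homolog.

The screening motifs are expressed in PROSITE-style syntax with
variable-length gaps. The three built-ins cover amidated multicopy
precursors, non-amidated multicopy precursors, and RFamide-type precursors
processed at monobasic `R-F-G-[KR]` sites:

```{r}
vapply(builtin_patterns(), function(p) p$source_text, "")
```

## Pipeline stages and their parameters

The pipeline composes seven stages; each is exposed as an ordinary
function and orchestrated by `run_pipeline()`.

| Stage | Function | Key parameters (default) |
|---|---|---|
| translation | `six_frame_translate` | min segment 20 aa, standard code |
| motif scan | `scan_pattern` | built-in patterns, lazy per-start policy |
| signal gate | `call_signal_peptide` | score cutoff 0.34 |
| cleavage + peptides | `find_cleavage_sites`, `extract_peptides` | dibasic rule, `fgr` monobasic rule |
| paracopy grouping | `group_paracopies` | linkage 0.5, min 2 copies |
| family merge | `merge_families` | consensus similarity 0.5, conservation 0.5 |
| reciprocal search | `reciprocal_search` | BLOSUM62, e-value cutoff 1 |
| mass confirmation | `match_masses` | 4.5 ppm, min peptide length 4 |

The 0.34 signal-peptide cutoff, the e-value presets (1 for precursor
searches, 1e-30 for the stringent receptor-style preset), the 4.5 ppm
precursor tolerance, the 20 ppm fragment tolerance (carried only as
metadata in the peptide-database export) and the 4-residue minimum peptide
length are the screening parameters of the survey the pipeline
operationalizes; the linkage/conservation thresholds formalize grouping
steps that were originally manual, and are therefore exposed as tunables.

### Translation and 5'-completeness

How transcriptomes are translated is a design choice of this package: all
six frames, split at stop codons, segments shorter than 20 aa dropped. A
segment preceded by an in-frame stop codon has a known 5' boundary; it is
trimmed to its first Met (the ORF start) and flagged
`five_prime_complete`. A segment abutting the transcript edge may be
missing its true start: it is kept untrimmed and flagged incomplete, which
downstream exempts it from the signal-peptide gate (`untestable_partial`)
instead of rejecting it. Codons containing `N` translate to `X`; `X`
satisfies pattern wildcards but never a residue class, so ambiguity can
widen a gap but never fake a cleavage site.

### Motif scanning policy

The match policy for variable-gap patterns is underdetermined: with
`x(5,200)` gaps, the number of distinct expansions is combinatorial. The
scanner therefore reports, by default, one match per distinct start
position using the shortest total extension (lazy repeats), which is
sufficient to locate candidate regions — candidates are re-analyzed by the
downstream processing model, not by the match geometry. The exhaustive
policy (`policy = "all"`) is retained for users who need every expansion.
Equality of both policies with a brute-force enumeration oracle is part of
the test suite. Patterns are compiled to anchored lazy regular
expressions; per-element spans are recovered from capture groups and
re-validated to tile the match interval.

### The signal-peptide stand-in

Production use should import an external predictor's scores
(`external` table, gated at 0.34). The built-in heuristic exists so that
the pipeline is testable without that dependency, and is deliberately
simple and documented: Met at position 0, a run of ≥ 6 consecutive
hydrophobic residues (A,I,L,M,F,V,W,C) within positions 1–30, cleavage
after the first small residue (A,G,S,C,T) following the run, score =
run length / 10 capped at 1. It is a contract, not a model of signal
peptidase; its false-negative behavior on real proteomes is unknown and
users are expected to supply predictor output there.

### Cleavage conventions

Dibasic sites are resolved left-to-right and non-overlapping, so `KRR`
yields one site at the first pair — alternative pairings change only site
bookkeeping, not peptide content, except at run boundaries where a
deterministic rule is required. The monobasic rule is pluggable; the
default implements only the `...F-G-R` context implied by the RFamide
pattern, a reproducible subset of what dedicated monobasic predictors
model. Site residues are excluded from peptides uniformly. A segment that
is a lone donor G is degenerate (its amidated peptide would be empty) and
is skipped with a warning; the tiling check accounts for such gaps.
N-terminal Gln is annotated as a pyroglutamation candidate but never
alters mass by default.

### Grouping and family calling

Paracopy grouping needs a quantitative stand-in for "recurrent peptide
sequences": pairwise global alignment (BLOSUM62, gap open 10 / extend 1)
normalized by the self-score of the shorter peptide, single-linkage at
0.5. Uniformly amidated groups are aligned right-anchored, because amide
motifs are C-terminal; otherwise the anchor that maximizes mean column
conservation is chosen. Consensus motifs take the modal residue where its
frequency reaches 0.5 and `x` elsewhere, and a trailing `a` names
uniformly amidated families ("SFxNa"). Mixed amidation within a family is
reported, not rejected. Families merge by single linkage over consensus
similarity (with `x` aligned as the BLOSUM62 ambiguity residue X).
Canonical sorting before linkage makes both steps order-independent.

### Reciprocal search

The search stage is exact Smith–Waterman (via the Biostrings aligner)
rather than a seeded heuristic: candidate sets at this scale are small
enough that exactness is affordable, and tests hold the implementation to
a quadratic DP oracle. E-values follow the Karlin–Altschul form
`E = K m n exp(-λS)` with the standard gapped parameters for BLOSUM62
(gap 11/1: λ = 0.267, K = 0.041) and BLOSUM45 (gap 14/2: λ = 0.224,
K = 0.0744). These reproduce the *shape* of familiar search statistics,
not any specific engine's numbers, so raw-score cutoffs are also
accepted, and a 12-column tabular adapter allows an external engine to be
swapped in for large runs.

### Mass confirmation

Validation is at the precursor-mass level only: theoretical neutral
monoisotopic masses (residue masses + water 18.0105646863 Da) under fixed
carbamidomethyl-C (+57.02146) and variable oxidation-M (+15.99491),
acetyl-N-terminus (+42.01057, restricted to the mature protein's
N-terminal peptide, per the usual database-search convention), sulfation-Y
(+79.95682), with amidation (−0.98402) forced on — never enumerated — when
the precursor model flags a Gly donor. Up to 3 variable modifications are
combined per peptide. Matching is boundary-inclusive (|ppm| ≤ 4.5), with a
1e-9 ppm guard for floating-point representation of masses sitting
exactly on the tolerance. Fragment-level scoring, target-decoy FDR and
spectral validation require raw spectra and a search engine and are out of
scope; `write_peptide_db()` exports the predicted forms as a database for
such engines.

## The synthetic benchmark

`generate_proteome()` builds datasets with known truth. Planted precursors
follow the grammar the patterns assume: a heuristic-compatible signal
peptide (Met + 7–10 hydrophobic residues + Ser), then per paracopy a
spacer (2–10 aa, non-basic, G-free), a dibasic site, the paracopy, an
optional Gly donor and a closing dibasic site. Paracopies realize a family
motif ("SFxN", "LxF", "PxFV" by default, all amidated) with `x` positions
drawn uniformly and a 0.05 per-position mutation rate; 6–12 copies per
precursor, which is typical of real multicopy precursors and guarantees at
least two non-overlapping matches of the three-unit amidated pattern.
Decoys are uniform-composition proteins of 80–400 aa (an empirical
frequency option exists); dibasic pairs arise in them by chance, which is
intended — the MCP call must rest on paracopy recurrence, not on the mere
presence of cleavage sites. Observed-mass lists apply Gaussian ppm noise,
dropout, and uniform contaminant masses to the planted peptides' modified
masses.

What the benchmark does *not* emulate: real spacer/propeptide composition
biases, homopolymeric and low-complexity tracts, assembly artifacts,
sequencing error, incomplete 5' ends, and realistic signal-peptide
diversity. Passing the benchmark therefore demonstrates the pipeline's
internal consistency and its behavior under the stated noise model, not
recall on real transcriptomes — there, signal-peptide calls should come
from a dedicated predictor and recovered candidates still warrant manual
review.

Benchmark scales used by the package's own checks: the recovery benchmark
runs 5,000 decoys with 50 planted precursors (mutation rate 0.05) and
expects ≥ 95% precursor recall, ≥ 90% family-assignment accuracy and
≤ 1% decoy false positives; scanner/oracle equivalence uses 500 random
pattern–sequence pairs; alignment/oracle equivalence uses 200 random
pairs up to 80 aa; determinism is checked by writing two reports from
identical inputs and comparing bytes.

## Worked example

```{r}
gen <- generate_proteome(plant_spec(n_decoys = 150, n_planted = 12,
                                    seed = 17))
report <- run_pipeline(list(synth = gen$proteins),
                       pipeline_config(seed = 17))
report
evaluate_recovery(report, gen$truth, n_decoys = 150)
```

## Known limitations

- The built-in signal heuristic is a testing stand-in, not a predictor.
- The default monobasic rule covers only the RFamide `F-G-R` context.
- E-values are model-based, not calibrated to any external engine.
- Exact Smith–Waterman is quadratic per pair; beyond a few thousand
  sequences per side, use the tabular adapter with an external engine.
- Family naming is consensus-based; deciding whether a family is an
  ancient MCP type or a species-specific expansion is left to the user,
  who gets per-dataset presence counts for exactly that purpose.
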