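---
title: "Condition-resolved phospho-site analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-resolved phospho-site analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphostate)
```

This vignette documents the statistical procedure the package implements,
the semantics of every tunable that matters, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the underlying conventions are genuinely ambiguous.

## The setting

The input is a PSM-level table from a database search of an
affinity-purification LC-MS/MS experiment targeting one protein, across a
condition × replicate design. The canonical design (`knl1_design()`) is a
DMSO vehicle control plus three microtubule-disrupting treatments
(nocodazole, paclitaxel, STLC) × 3 replicates, where the three treatments
form the *mitotically arrested* set. Each PSM row carries its peptide
sequence, the target accession, and a modification string with per-residue
phospho localization confidences (percent). The package never runs or wraps
a search engine; rows are expected pre-filtered to peptide FDR < 1% (a
`peptide_fdr` column, when present, is re-filtered at the configurable
threshold, default 0.01).

## Digestion and mapping

`digest_protein()` cleaves C-terminally to K/R except before proline (the
Keil rule — the stated enzyme constraint in typical searches is just
"tryptic", but every mainstream engine defaults to the proline exception,
so we adopt it), with up to `max_missed` retained internal sites (default
2) and a 6–50 aa length filter for digest listings. Observed peptides are
*not* digest-constrained: `map_psms()` places them by exact substring search
(I/L distinct), so semi-tryptic evidence still maps. The theoretical digest
is used for coverage expectations and simulation only — observed evidence is
never discarded because theory says it should not exist.

Peptides occurring more than once in the target are resolved by
`ambiguity_policy`: `"first"` (default — deterministic and auditable, with
the ambiguity counted in the run log), `"all"` (one mapped span per match,
flagged), or `"drop"`. Phospho positions become absolute coordinates as
`span start + peptide position − 1`, and every mapped phospho letter is
checked against the protein sequence.

## Coverage and depth

Depth at residue *i* is the number of mapped spans containing *i*. Percent
coverage is the share of residues with depth ≥ 1. **Mean depth is averaged
over covered residues only**, not the whole chain: reported
coverage/depth pairs like "72%, 20.2" read naturally as "72% of the protein
seen, ~20 PSMs where seen", and dividing by the full length would shrink
depth by roughly the coverage fraction. This is the one place where a
different convention changes values materially, so it is called out here.

Statistics are computed per replicate and then averaged arithmetically per
condition (replicate-then-average, matching how averaged coverage maps are
reported), never by pooling PSMs first. Report tables print at 2 decimal
places; everything in memory is full precision.

## Site filtering and classification

Per (residue, condition, replicate) the evidence is the phospho-PSM count
and the **maximum** localization confidence across those PSMs — a single
well-localized PSM establishes the site; requiring every PSM to pass would
conflate localization with abundance. An observation *qualifies* when

- best confidence **strictly** exceeds `min_confidence` (default 75%), and
- the phospho-PSM count is ≥ `min_phospho_psms` (default 2).

A condition's site set is the union of its qualifying replicates
(`set_mode = "per_replicate"`). The alternative reading — pool counts across
replicates before filtering — is available as `set_mode = "pooled"` because
the underlying convention ("the sum of sites that met these criteria across
replicates") is ambiguous; per-replicate-then-union is the default because
it treats replicates as independent pieces of evidence and is the stricter
interpretation.

Site averages are the zero-inclusive arithmetic mean of raw replicate
counts over **all** declared replicates, independent of qualification:
counts (2, 0, 0) under 3 replicates average to 0.67. This is deliberate —
report-style averages such as 0.67 are only reachable with zero-inclusive
raw averaging, and making averages depend on the filter would double-count
it.

Classification over the union of all sets:

| label | rule |
|---|---|
| `shared_all` | in every condition's set |
| `arrested_shared` | in every arrested condition's set, absent from the reference set |
| `condition_unique` | in exactly one condition's set |
| `other` | everything else |

A `condition_unique` site is **starred** when detected in ≥ 2 replicates of
its condition. "Detected" defaults to a per-replicate count reaching the
count threshold regardless of confidence (`star_mode = "any_evidence"`),
which matches the reading that a site with 2 phospho-PSMs in 2 of 3
replicates earns its star; `star_mode = "qualifying"` additionally demands
the confidence bound per replicate.

## Motifs

The default MELT-class scan uses the degenerate pattern
`[MILV][ED][MILV]T` with the threonine as acceptor, taking non-overlapping
matches left to right. Because the literature's established motif
coordinates for a given target are curated rather than derivable from a
regex, a user-supplied coordinate file is authoritative when present and
the scan is a convenience fallback. A motif counts as phosphorylated in a
condition when its acceptor position is in that condition's site set
(`motif_mode = "acceptor_only"`; signaling runs through the acceptor
threonine) — `"any_in_window"` is available for sensitivity checks. SHT-class
motifs go through the same engine with a second `motif_pattern()`.

## Interactor fold changes

Per protein and condition, raw PSM counts are averaged over the declared
replicates (zeros filled for missing cells) and compared against the
reference condition with one pseudocount:

$$\mathrm{FC} = \frac{\overline{\mathrm{PSM}} + 1}{\overline{\mathrm{PSM}}_{\mathrm{ref}} + 1}$$

so the reference column is exactly 1 and a protein absent from the
reference gets FC = mean + 1 rather than a division by zero. Note that
"add 1 to every replicate count, then average, then take the ratio" is
arithmetically identical to the formula above; the only genuinely distinct
alternative — average of per-replicate ratios — is provided as
`pseudocount_stage = "per_replicate"` for sensitivity analysis, and the
averaged-then-pseudocounted form is the default. No control subtraction or
enrichment scoring is performed; the matrix is a semi-quantitative summary.

## The synthetic-data generator

`simulate_psm_dataset()` emulates the structure the analysis assumes:

- a 2342 aa target with ~10% K/R (so fully cleaved tryptic peptides have
  realistic lengths; the 6–50 aa detectability filter then lands percent
  coverage in the 70–90% range without any tuning);
- per-peptide abundance `mean_depth × LogNormal(−σ²/2, σ)` (default mean
  depth 20, σ = 0.5), with per-cell spectral counts Poisson around it —
  standard over-dispersed spectral-count behaviour;
- 40 planted sites, 30% shared-all (occupancy 0.7 everywhere), 30%
  arrest-shared (0 in the reference, 0.7 under arrest) and 40%
  condition-unique (0.8 in one condition), planted at least 3 residues
  apart inside detectable peptides without touching K/R/P, so planting
  never alters the digest; planted threonines get MELT sequence context so
  the motif module is exercised end to end;
- localization confidences from Beta(9,1)×100 for true placements and
  Beta(2,4)×100 for decoys (decoy rate 1% of PSMs), so the 75% filter
  separates them imperfectly and the filter is actually exercised;
- inert methionine oxidations (5% of PSMs with an M) to exercise the
  modification grammar.

The generator computes its own expected classification analytically
(`expected_truth()`): per condition, the probability that at least one of
the replicates qualifies, with the phospho-PSM count approximated as
Poisson(mean depth × occupancy) and the best-confidence bound from the Beta
model; a condition is expected-active when that probability is ≥ 0.5, and
the membership pattern is classified with the same semantics as the
pipeline. Recovery tests are therefore a round trip of the set semantics,
not an independent re-derivation — which is exactly what they are meant to
check.

What the generator does **not** emulate: missed-cleavage and semi-tryptic
products (they change local depth, not set semantics), peptide-specific
ionization efficiency, co-eluting isobaric localization swaps, FDR
structure (all simulated rows are "true"), retention time, and mass error.
Passing recovery tests therefore demonstrates the correctness of the
aggregation/filter/classification logic under a realistic count model — not
robustness to search-engine pathologies.

## Numerical and degenerate-input choices

- Confidence bound is strict (`> 75`), count bound inclusive (`≥ 2`);
  a missing confidence with a nonzero count never qualifies and is treated
  as unlocalized.
- Schematic bins: `< 5` low, `[5, 10]` mid, `> 10` high — the middle bin is
  closed on both ends because the conventional "<5 / 5–10 / >10" labels
  leave the boundaries ambiguous.
- A fully uncovered profile reports mean depth 0 with a `covered = FALSE`
  flag rather than NaN.
- Empty site lists, empty motif files and empty condition sets all
  propagate to header-only report tables.
- Report TSVs print doubles at fixed precision (2 d.p.; fold changes
  4 d.p.) with stable row sorts, so identical inputs give byte-identical
  files.

## Problem sizes

The test suite validates digestion against a brute-force substring oracle
on 500 random sequences (length ≤ 60) at 0–2 missed cleavages, depth
against naive counting on 200 random placements, set construction against a
per-triple oracle on 1000 randomized tables, and end-to-end recovery on 20
simulated datasets at the full default scale (2342 aa, 4 × 3 design, mean
depth 20, 40 planted sites — roughly 30,000 PSM rows per dataset). These
sizes give stable rates while keeping a full run around a minute.

## Known limitations

- Protein inference is out of scope: PSMs are taken at their declared
  accession, and shared peptides across proteins are not resolved.
- The classifier is set-based and semi-quantitative; it does not test
  differential phosphorylation statistically, and occupancy/stoichiometry
  estimation is explicitly not attempted.
- Localization confidence is consumed as an opaque percent; the package
  does not re-score localization.
- Reproducing published counts for a specific deposited dataset requires
  the user to export that deposition into the `psm.tsv` dialect
  (`reproduce_published_counts()`); no downloading is performed.
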