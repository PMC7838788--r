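---
title: "Methods: comparing probing data to a reference RNA structure model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing probing data to a reference RNA structure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsparis)
```

## Scope and assumptions

`dmsparis` compares in-cell probing data (DMS-Seq counts, PARIS duplex
reads) against a *fixed* reference secondary-structure model of one
transcript. The model — sequence, symmetric pairing table, and a named
hairpin/pseudoknot catalog — is an input artifact; the catalog's numbering
is authoritative and is never recomputed from the pairing. The package
deliberately performs no folding, no refolding from probing data, and no
reactivity normalization: the classification operates on raw read counts
against an explicit threshold, which is how the comparative analyses it
supports were designed. Coordinates are 1-based and inclusive everywhere;
any 0-based interchange format (BEDPE-style input) is converted at the
reader boundary only.

Two assumptions matter for interpretation:

1. DMS methylates accessible A and C only, so G/U positions never carry a
   call (`not_AC`) and base pairs are probed through whichever partner is
   an A or C.
2. Per-nucleotide counts are treated as independent observations by the
   rank test, which is known to be only approximately true (neighbouring
   stem positions are correlated); the `UTestResult` carries this caveat in
   its `note` field.

## The classification rule and its boundary

An A/C position with count `c` is **structured** iff `c <= dms_threshold`.
The boundary is inclusive by construction ("no more than" the threshold),
and we state it prominently because an off-by-one here shifts every
downstream count: a count exactly at the threshold is structured.
`calibrate_threshold()` returns the full admissible interval
`[max(structured anchors), min(unstructured anchors) - 1]` rather than a
single number, because any threshold inside the interval classifies every
anchor correctly; the suggested value is the floor of the interval
midpoint. The interval is reported alongside whatever threshold the user
configures — a configured value need not equal the midpoint, and the
package takes no position on which interior value is best. Overlapping
anchor sets are reported as infeasible rather than resolved silently.

Thresholds are *per dataset* and live in `analysis_config()`
(`dms_threshold`, default 250 reads — appropriate for a high-expression
context; 20 for the low-expression reference data). No threshold is ever
inferred from the data being classified.

## Hairpin disruption

A pair `(i, j)` is **lost** iff at least one partner is called
unstructured (the either-partner rule; with Watson–Crick stems each pair
typically exposes exactly one informative A or C). Three deliberate
choices:

- The denominator of `fraction_lost` is the hairpin's *total* pair count,
  not only the evaluable pairs. Worked arithmetic on full stem sizes
  (13/25, 5/8, 8/12, 4/6) requires this, and it is conservative: unprobed
  pairs can only dilute the fraction.
- Pairs with no A/C datapoint can never be counted lost.
- A hairpin is disrupted iff `fraction_lost >= disruption_cutoff`
  (default 0.5, "at least half").

Hairpins whose pairing was itself derived from PARIS data (tagged
`paris_derived` in the catalog) carry no independent DMS support and are
excluded from hairpin-level disruption tallies. Whether *per-datapoint*
tallies also exclude positions inside such hairpins is genuinely ambiguous
in the source analyses; `exclude_paris_positions` (default `FALSE`) exposes
both modes. Similarly, published hairpin denominators vary between subsets
of the full catalog (194 vs 161 vs 101 analyzable hairpins, depending on
coverage and derivation); the loader therefore accepts arbitrary catalog
subsets and hard-codes no count — the denominator is always whatever the
supplied catalog and coverage make evaluable.

## PARIS read compression

The constants are verbatim rule constants: quality floor Q30 (inclusive —
"lower than Q30" is removed), per-arm offset ≤ 20 nt, region length
≥ 10 nt, support ≥ 3 reads. The merging sentence behind them is ambiguous
about what "overlapped by 20 or fewer nts" measures, so the package
implements two readings behind `compress_rule`:

- `"offset"` (default): two reads link when corresponding arms overlap by
  ≥ 1 nt *and* all four start/end offsets are ≤ `compress_max_offset`.
- `"symdiff"`: two reads link when corresponding arms overlap and each
  arm pair's symmetric-difference length is ≤ `compress_max_offset`.

Grouping is single-linkage (transitive closure), computed after
sort-normalizing the reads so the result is independent of input order.
A group's arm is the *intersection* of its members' arms — the region every
supporting read covers — expanded symmetrically to `min_region_len` when
shorter. Degenerate case: a linkage chain can leave an empty intersection;
the arm then collapses to the chain's midpoint before expansion. Reads are
swap-normalized on ingest so arm1 always precedes arm2.

The long-range cutoff (inner gap ≥ 80 nt between arms) is a declared
convention, not a measured fact; it is configurable
(`long_range_min_gap`).

## Matching duplex groups to the model

A group is consistent with a catalog element when each arm covers the
corresponding strand by at least `min(ceiling(0.5 * arm_length), 5)`
nucleotides — and never more than the strand itself has: the requirement
is additionally capped at the strand length, so a short helix strand fully
contained in an arm is a complete match. Without the cap, stems shorter
than 5 bp could never be matched once arms are expanded to the 10-nt
minimum region, which would contradict the by-construction case of a group
whose arms coincide exactly with a model helix. Both arm-to-strand
assignments are tried. When several elements match, the tie breaks toward
the larger total overlap, then the smaller element id.

Pseudoknot status is rule-ordered: **maintained** if any consistent group
matched the pseudoknot; otherwise **rearranged** if any divergent group
overlaps either arm; otherwise **lost** (no duplex evidence at all).

## Annotation overlay

In DMS mode, an annotation overlapping a disrupted hairpin by ≥ 1 nt gains
accessibility; one overlapping only structure-gain positions loses it;
covered-but-unchanged is `unchanged`; no covered positions is `no_data`.
Conflicting evidence resolves to the verdict with the larger overlapped
length, ties toward increased accessibility (loss dominates). In PARIS
mode, overlap with any divergent group arm yields decreased accessibility.
For miRNA sites the region tested is the whole site in DMS mode and the
seed sub-interval in PARIS mode by default (`mirna_dms_region`,
`mirna_paris_region`), reflecting that the loss analyses count sites *in*
hairpins while the rearrangement analyses reason about seed regions; the
minimum-overlap question (1 nt vs full seed) is left to these toggles
because the published tallies do not state it, and full-data reproductions
should report both. Point features (modifications, SNPs, mutations) use
single-position overlap with no flanking window.

`seed_pairing()` pairs miRNA nucleotides 2–8 antiparallel against the 3′
portion of the site. G:U wobbles count as pairing but not as Watson–Crick;
disruption is defined on the WC count only, a conservative reading of
canonical/noncanonical pair notation. A mutation must match its stated
reference allele or the function errors — a guard against coordinate
drift between annotation tables and the model sequence.

## Rank test

`mann_whitney_u()` uses midranks, `U1 = R1 - n1(n1+1)/2`, tie-corrected
variance `n1 n2 / 12 * ((N+1) - sum(t^3 - t) / (N (N-1)))`, a z from
`min(U1, U2)`, and a two-sided normal p with **no continuity correction**
(none is part of the procedure being reproduced). Consequences we verify
in tests: U agrees exactly with a pair-count enumeration; for
`n1, n2 <= 8` the two-sided p agrees with the exact permutation
distribution to within 0.15, the empirical error bound of the uncorrected
approximation at these sizes (exact-p granularity is ~0.03 at n = 4). When
every pooled value is identical the variance is zero and the result is
reported as `z = 0, p = 1`.

## What the simulator emulates — and what it does not

`gen_model()` packs non-overlapping Watson–Crick stems of 4–25 bp with
loops of 12–20 nt plus pseudoknots pairing two distant unpaired intervals;
WC-only stems guarantee every pair exposes exactly one informative A/C.
`simulate_dms()` draws counts from two negative-binomial regimes
(`mu_structured = 50`, `mu_unstructured = 600`, variance
`mu + dispersion * mu^2` with `dispersion = 0.1` by default) at covered
A/C positions; the default missing blocks (the leading ~15% of the
transcript and a central ~19% block) mimic an expressed shorter isoform
and an unprobed central region. `dispersion = 0` is defined as the exact
noise-free limit (every count equals its regime mean) so that threshold
behavior can be tested without sampling error; small positive values
approach Poisson. `simulate_paris()` emits `reads_per_helix = 5` reads per
surviving helix with per-endpoint jitter ≤ 5 nt, replaces rearranged
helices' reads with decoy duplexes placed to *fail* the arm-to-strand
match criterion against every true strand (so truth labels are
unambiguous), and adds PCR duplicates, sub-Q30 reads and off-transcript
reads at 10%/10%/5%.

The simulator does **not** model sequence-context DMS reactivity,
read-level sequencing errors, partial duplex melting, or coverage that
varies smoothly along the transcript. Passing recovery tests therefore
demonstrates that the *rules* are implemented correctly and are separable
under the stated count regimes — not that the thresholds are optimal for
any particular real dataset.

`score_recovery()` tallies disrupted-hairpin detection over DMS-derived
hairpins whose every pair is evaluable. Hairpins partially inside coverage
gaps cannot reach the 50% disruption cutoff no matter the data — scoring
them would measure coverage, not detection — and restricting to supported
hairpins is exactly what the real analyses do when they evaluate only the
hairpins their data cover.

## Problem sizes and numerical conventions

Tests and the acceptance script use transcripts of 200 nt (oracle
equivalence, ≥ 200 random cases against brute-force recomputation) and
2,000 nt with 20 hairpins (recovery, 50 seeded replicates); these sizes
give stable statistics while keeping the whole suite fast. Reported
percentages use half-up rounding to one decimal (`round_half_up()`), not
banker's rounding. All generators are deterministic per seed, with
distinct derived seeds per stage so that regenerating one stage does not
perturb another.

## Known limitations

- Accessibility verdicts are structural predictions, not binding
  measurements; they say a site's occlusion changed, not that binding
  follows.
- The compression rule's two readings can split or merge borderline read
  clusters differently; full-data analyses should be run under both
  (`inst/scripts/full_data_workflow.R` does).
- The rank test's independence assumption is violated by design of the
  data; its p values support a direction-of-effect statement, not a
  calibrated error rate.
- With `"symdiff"` compression, very long reads can chain more aggressively
  than under `"offset"`; both remain single-linkage and order-invariant.
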