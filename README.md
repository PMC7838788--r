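# dmsparis

Comparative RNA secondary-structure analysis from in-cell probing data.

## The problem

Long noncoding RNAs such as MALAT1 act largely through their secondary
structure: hairpins and pseudoknots occlude miRNA-binding sites,
protein-binding sites and modification sites, and opening or rearranging
those structures changes what the transcript can bind. Given a reference
secondary-structure model of a transcript — a sequence, a base-pairing
table, and a named catalog of hairpins (H1…Hn) and pseudoknots (PK1…PKm) —
this package asks how two kinds of in-cell probing data depart from that
model in a different cellular context:

- **DMS-Seq** reports per-nucleotide read counts at adenosines and
  cytidines; accessible (unpaired) A/C positions accumulate many reads.
- **PARIS** reports chimeric reads whose two arms mark the two strands of a
  psoralen-crosslinked duplex.

It is an *analysis* package for comparing probing data against a fixed
model; it never refolds or predicts structure.

## The method

**Per-nucleotide calls.** An A or C position with count *c* is called
*structured* when *c* ≤ *t* and *unstructured* when *c* > *t*, where the
threshold *t* is per-dataset configuration (20 for a low-expression
fibroblast dataset, 250 for a high-expression K562-type dataset).
`calibrate_threshold()` reports the admissible interval
[max(structured anchors), min(unstructured anchors) − 1] from counts at
nucleotides of known status. Comparing calls to the model partitions
positions into *agree*, *loss* (paired but unstructured) and *gain*
(unpaired but structured).

**Hairpin disruption.** A base pair (i, j) is *lost* when either partner is
called unstructured; a hairpin with ≥ 50% of its pairs lost is *disrupted*.
The denominator is the full stem size, so unprobed pairs dilute, never
inflate, the fraction. `novel_changes()` counts pairs lost in one condition
but not in a reference condition.

**Duplex groups.** PARIS reads are quality-filtered (Phred ≥ 30, arms
inside the transcript), PCR-deduplicated by (barcode, arms), and compressed
by single-linkage clustering (arms overlapping, per-arm start/end offsets
≤ 20 nt) into groups with arms ≥ 10 nt and support ≥ 3 reads. Each group is
*short-range* or *long-range* (inner gap ≥ 80 nt) and *consistent* with a
catalog element or *divergent* from the model; pseudoknots are then
*maintained*, *rearranged* or *lost*.

**Annotation overlay.** miRNA sites (with seed sub-intervals), U1/rRNA/
protein sites, modifications, SNPs and mutations are intersected with the
structural changes: loss of structure ⇒ increased accessibility,
gain/rearrangement ⇒ decreased. `seed_pairing()` scores Watson–Crick vs
wobble pairing of miRNA nucleotides 2–8 against a site, before and after a
point mutation.

**Statistics.** `mann_whitney_u()` is a from-scratch rank-sum test with
midranks, tie-corrected variance and a two-sided normal-approximation p,
used to confirm that unstructured positions carry higher counts.

**Simulation.** `gen_model()` / `simulate_dms()` / `simulate_paris()`
generate models and datasets with known perturbations (unfolded hairpins,
decoy duplexes, PCR duplicates, low-quality and off-transcript reads) so
recovery of the truth is testable end to end without downloads.

## Worked example

The built-in fixture encodes four disrupted hairpins of the MALAT1
reference model with the informative A of each pair on the 5′ strand:

```r
library(dmsparis)
ex <- worked_example_hairpins()
calls <- classify_positions(ex$profile_condition, ex$model, ex$config_condition)
disruption_table(ex$model, calls, ex$config_condition)
#>   hairpin_id n_pairs_total n_pairs_lost fraction_lost disrupted
#> 1        H44            25           13     0.5200000      TRUE
#> 2        H45             8            5     0.6250000      TRUE
#> 3        H98            12            8     0.6666667      TRUE
#> 4       H155             6            4     0.6666667      TRUE
```

H44 loses 13 of its 25 pairs (52.0%), crossing the ≥ 50% disruption cutoff;
relative to the reference condition, 8 of those losses are novel:

```r
ref <- classify_positions(ex$profile_reference, ex$model, ex$config_reference)
novel_changes(calls, ref, ex$model$hairpins[[1]])
#> [1] 8
```

Threshold calibration from the anchor counts (217 structured; 314 and 322
unstructured) admits any threshold in [217, 313] and suggests the midpoint:

```r
calibrate_threshold(c(217), c(314, 322))
#> $feasible  TRUE
#> $interval  lo 217, hi 313
#> $suggested 265
```

A seed-disruption check for miR-92a-3p against its binding site, with an
A→U substitution inside the seed-complementary window:

```r
wx <- worked_example_seed()
seed_pairing(wx$site_seq, wx$mirna_seq, wx$site_start, wx$mutation, wx$mirna_name)
#> Seed pairing for miR-92a-3p
#>   WC pairs in seed: 7 -> 6 after mutation
#>   disrupted: TRUE
```

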