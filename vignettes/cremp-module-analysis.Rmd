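---
title: "Detecting and analysing cysteine-spacing repeat modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing cysteine-spacing repeat modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crempr)
library(ggplot2)
```

## The biological problem

Cysteine-rich eggshell membrane proteins (CREMPs) of birds and oviparous
reptiles are structural proteins built almost entirely from short tandem
modules delimited by cysteines. Each module holds four cysteines with fixed
spacing, `C-X4-C-X5-C-X8-C`, followed by a cysteine-free tail; `X` is any
residue except cysteine. Two module types occur: type **a** with a
6-residue tail (27 residues in total) and type **b** with an 11-residue
tail (32 residues). One a followed by one b gives the 59-residue repeat
unit in which the pattern was first recognised; a two-repeat a-b-a-b
fragment is 118 residues and, fully oxidised, pairs its 16 cysteines into
8 disulfide bonds. Observed architectures include strict (a-b)~n~
alternation, (a-b-b)~n~, and long (a)~n~ runs.

Because such runs of nearly identical repeats defeat genome assembly,
full-length CREMP sequences are unknown and analyses operate on fragments:
detecting modules, classifying their type, summarising repeat
architecture, profiling conservation, and asking whether the two module
types segregate evolutionarily. `crempr` implements that pipeline over
plain data frames, with a synthetic generator supplying ground-truth data
for validation.

## The module grammar

A `module_spec` is a spacing template: ordered inter-cysteine gaps, a tail
length, a per-gap tolerance (default ±1 residue, covering the documented
single-residue deviations in the lizard protein), and a maximum tail
insertion (default 64, accommodating the longest observed insert of 59
residues). `cremp_grammar()` bundles the canonical a and b templates with
the conserved-residue catalogue:

* shared, absolutely conserved: D3, K8, G9, G17, P19;
* diagnostic for a: P7 and P26 (never seen in b);
* diagnostic for b: K25 (only in b).

Positions are numbered 1-based from the module's first cysteine. The
source descriptions of these conserved positions do not state the
numbering origin explicitly; position 1 = first cysteine is the only
origin that places all eight catalogued residues between the correct
cysteine anchors (C1, C6, C12, C21), so the package adopts it throughout.

```{r grammar}
g <- cremp_grammar()
g
build_canonical_sequence(g$specs$a)
build_canonical_sequence(g$specs$b)
```

Grammars are serialisable to YAML (`read_grammar()`/`write_grammar()`), so
related four-cysteine grammars — for instance the looser slime-mold
`C-X4-C-X5-C-X6-10-C` spacing, via a tolerant third gap — can be scanned
with the same machinery.

## Scanning: candidate generation and chaining

No detection algorithm accompanies the published pattern, only the pattern
itself, so the scanner design is the package's own. Modules are
cysteine-delimited and the documented deviations are local, which makes a
cysteine-anchored scan natural:

1. **Candidates** (`find_candidate_modules()`). Every cysteine starts a
   potential module. Since spacer regions may not contain cysteine, the
   remaining anchors must be the next three cysteines; the candidate is
   kept when every observed gap is within tolerance of a template's gaps.
   The tail is the canonical tail; when the next module's anchoring
   cysteine sits farther away, the tail extends to meet it, up to
   `max_tail_insert` extra residues (a *tail insert*). A terminal module
   (no following cysteine) keeps its canonical tail, and yields no
   candidate if the sequence ends before a full canonical tail — inserts
   are only observable when bounded by the next module.
2. **Chaining** (`chain_modules()`). Weighted-interval-scheduling dynamic
   programming selects a non-overlapping candidate subset maximising, in
   order: residues covered, module count, fewer spacing deviations, and
   higher agreement with the conserved-residue catalogue. The last
   criterion resolves a real ambiguity: an a-module followed by a tail
   insert covers the same residues as a b-module with a 5-residue-shorter
   insert, and only the diagnostic residues distinguish the readings (the
   published lizard alignment treats inserted modules as a-type, which
   diagnostic agreement recovers). All tie-breaks are deterministic.
   Runs of contiguous selected modules (configurable slack
   `max_gap_between_modules`, default 0) become repeat regions.

Architecture strings render one letter per module (`architecture_string()`)
and compress to their smallest dividing period (`compress_pattern()`), e.g.
`abababab` → `(ab)4`.

```{r scan}
seqs <- protein_sequences("toy", strrep(paste0(
  build_canonical_sequence(g$specs$a),
  build_canonical_sequence(g$specs$b)), 3))
scan <- scan_proteins(seqs, g)
glance(scan)
scan$regions[, c("start", "end", "n_modules", "architecture", "pattern")]
```

## Classification

`classify_module()` applies an explicit rule cascade: (1) an exact
canonical template match (gaps and tail), unopposed by the other type's
diagnostics, gives a plain `a`/`b`; (2) otherwise the diagnostic residues
vote (P7/P26 for a, K25 for b) and a strict majority gives
`a_variant`/`b_variant`; (3) with no or tied votes, the tail — after
removing any insert — is compared with the canonical tails and the nearer
type wins. Diagnostic positions are anchored to the cysteine that precedes
them, so a shrunk or grown gap shifts downstream positions by the
cumulative offset rather than invalidating them. The cascade is the
package's design: the source material defines the two types and their
diagnostics but gives no decision procedure for deviant modules.

A consequence worth noting: a module with a one-residue gap deletion is
reported `a_variant` even where the original description calls the run
"basically of the a type"; architecture strings therefore render variants
by their base letter, reserving `v` for modules that cannot be classified
at all.

## Conservation profiles

`stack_modules()` collects same-type modules at full canonical length,
excluding gap-deviant modules (realigning them is out of scope) and
truncating tail-inserted modules to their canonical prefix (inserts are
C-terminal extensions). Cross-type stacks use the published equal-length
device: exactly 5 residues are trimmed from every b module's C-terminus so
all rows are 27 long. `position_profile()` reports per-position residue
fractions and sequence-logo information content, `log2(20) − H` bits with
`H` the column's Shannon entropy. `X` counts as its own symbol in both
frequencies and entropy but can never be "informative"; because a 21st
symbol could push `H` past the 20-letter maximum, information is clamped
to `[0, log2 20]`. No small-sample correction is applied — stacks are
small and the original logos visibly used none. Consensus and
conserved-position calls break ties toward the lexicographically smaller
residue: arbitrary, but deterministic.

```{r profile, fig.width = 7, fig.height = 3}
prof <- position_profile(stack_modules(scan, "cross"))
glance(prof)
autoplot(prof)
```

## Composition vectors

`composition_vector()` pools residue counts into 17 components: the 20
standard residues minus tryptophan, with D+N and E+Q merged. This is the
convention required to compare gene-derived compositions with
acid-hydrolysis data (Asp/Asn and Glu/Gln are indistinguishable after
hydrolysis, and Trp is destroyed); hydroxylysine and hydroxyproline in
literature reference tables are folded into Lys and Pro at config load.
Distances between vectors are plain Euclidean distances on the percentage
scale, and `rank_references()` orders a reference panel by distance. The
shipped reference config pins only the two eggshell-membrane components
reported in the primary literature (Gly 9.5%, Cys 10.1%) and is explicitly
partial: the ranking procedure is reproducible in form, but reference
panels are user-supplied data, not hidden constants. For orientation, the
canonical a-b repeat is 8/59 ≈ 13.6% cysteine before substitution noise.

## Module segregation

The published claim that a and b modules "rigorously segregate" rests on a
ClustalW guide tree. Re-running ClustalW would be pure glue, so the claim
is recast in fully specified, testable form: p-distances (mismatch
fraction; `X` mismatches everything including `X`) over the cross-type
stack, a hand-rolled UPGMA with size-weighted average linkage and a
lexicographic tie rule (`upgma_tree()`, returning an `ape::phylo`), and a
two-cluster purity statistic (`segregation_purity()`): cut the tree at its
final merge and count majority-type leaves in the two clusters. Purity 1.0
reproduces perfect segregation. `nw_identity()` provides the companion
global-alignment percent identity (Needleman–Wunsch, match 1 / mismatch 0 /
gap −1, deterministic diagonal-first traceback) for untrimmed repeat
comparisons; published identity figures (86% between repeats, 56% between
species) depended on ClustalW's unstated scoring and are not reproduced
here.

```{r segregation}
seg <- segregate_modules(scan)
glance(seg)
```

## The synthetic generator

`simulate_protein()` builds proteins from the grammar with known ground
truth: each planned module starts canonical, then applies scheduled
single-residue gap edits and tail inserts, then point substitutions.
Choices made where the source material is silent:

* **Background/flank residues**: uniform over the 19 non-cysteine
  residues. A cysteine-free background keeps anchor statistics clean and
  mirrors the cysteine-defined module grammar; real inter-module context
  in contigs is unknown.
* **Insert alphabet**: 45% A, 45% P, 10% spread over the other 17
  non-cysteine residues — a stylised encoding of the "strikingly proline-
  and alanine-rich" inserts.
* **Protection**: by default substitutions never touch cysteine anchors or
  catalogued residues and never introduce cysteine, matching the observed
  absolute conservation; both protections can be switched off.
* **Seeding**: one seeded stream per simulation; a run is reproducible
  from (parameters, seed) and restores the caller's RNG state.

`recovery_report()` scores predictions against the planted truth
(precision, recall, exact-boundary rate, type accuracy, with optional
boundary slack).

```{r simulate}
sim <- simulate_protein(strrep("ab", 4), g, substitution_rate = 0.05,
                        seed = 42)
recovery_report(sim$truth, scan_proteins(sim$seq, g)$hits)
```

What the generator does *not* emulate: duplication histories, realistic
indel processes beyond the schedule, compositional bias of real spacer
residues, and sequencing-gap artefacts in contigs. Passing tests on
synthetic data therefore demonstrate correctness of the pipeline's logic
under the module grammar, not performance on raw genomic translations.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED output; TSV
  annotations additionally carry 1-based inclusive columns to match
  residue numbering in the literature.
* `X` is accepted on input, never matches a diagnostic, mismatches
  everything in p-distances, and is excluded (like W) from compositions.
* Empty candidate sets, empty regions and empty architecture strings are
  valid results; empty module stacks and sub-2-leaf trees are errors.
* UPGMA merge ties: lexicographically smallest pair of cluster
  representative labels. Chain ties: deviations, then diagnostic
  agreement, then candidate order. All paths are deterministic.

## Known limitations

* **Terminal-module ambiguity.** Next to a long cysteine-free flank, a
  trailing a-module cannot be distinguished from a b-module by spacing
  alone: the b reading covers five more residues and coverage-maximal
  chaining prefers it, so the final module of a run may be reported with
  the longer tail. Between modules the next anchor disambiguates; at the
  C-terminus nothing does.
* **Segregation purity at high noise.** The root-split purity statistic is
  sensitive to outliers. In seeded experiments (100 replicates per
  condition, (a-b)×4 stacks), purity was 1.0 in every replicate at 2%
  per-position substitution and in 93/100 at 5%, but only ~81/100 at 10%:
  an occasional extra-noisy module merges last, so the root split isolates
  that outlier rather than the a/b division, even though the two types
  still form clean subtrees. At 10% per-row substitution two same-type
  rows already differ at ~19% of their substitutable positions, which is
  well beyond the conservation level the real repeats display. The
  all-conditions form of the segregation claim therefore holds only up to
  roughly 5% substitution; the boundary condition is kept in the test
  suite as a strict, and honestly failing, check.
* **No gapped realignment** of gap-deviant modules in stacks, no
  six-frame translation of nucleotide contigs, and no joining of module
  runs across sequencing gaps — regions are reported per contiguous
  translated sequence.

## Problem sizes

The shipped tests and checks run on desk-scale data chosen to exercise
every code path: random sequences up to 200 residues against a brute-force
scanning oracle (200 instances), exhaustive chain enumeration on instances
with ≤ 10 candidates, plans up to 100 modules for exact-recovery checks,
50-replicate recovery and 100-replicate segregation experiments, and a
38-module synthetic encoding of the published lizard module schedule.
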