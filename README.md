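# crempr

Detection and analysis of the modular repeat architecture of
cysteine-rich eggshell membrane proteins (CREMPs).

## The problem

Under the calcified shell of bird and reptile eggs lies a fibrous,
disulfide-crosslinked membrane whose major structural protein is built
from short tandem modules delimited by cysteines. Each module follows the
spacing grammar

```
C-X4-C-X5-C-X8-C-<tail>
```

where `X` is any residue except cysteine. Type **a** modules carry a
6-residue tail (27 residues total), type **b** an 11-residue tail (32
residues); one a followed by one b forms the canonical 59-residue repeat,
and an a-b-a-b fragment is 118 residues with 16 cysteines (8 disulfide
bonds when fully oxidised). Besides the cysteine anchors (positions 1, 6,
12, 21 from the first cysteine), D3, K8, G9, G17 and P19 are absolutely
conserved in both types, while P7/P26 are diagnostic of a and K25 of b.
Because long runs of near-identical repeats break genome assembly,
analyses must work on sequence fragments.

`crempr` is for sequence analysts working with such proteins (or any
four-cysteine spacing grammar): it detects modules under configurable
templates with tolerances, chains them into repeat regions, classifies
module types by a diagnostic-residue rule cascade, profiles per-position
conservation (WebLogo-style information content, `log2 20 − H` bits),
compares amino-acid compositions by Euclidean distance, quantifies a/b
segregation via p-distance + UPGMA + a two-cluster purity statistic, and
ships a seeded synthetic-protein generator with ground truth so the whole
pipeline is testable without external data. Functions take data frames
first and return tibbles; result objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Simulate a four-repeat (a-b)×4 protein with 5% substitution noise between
cysteine-free flanks, scan it, and quantify recovery and module
segregation:

```r
library(crempr)

g <- cremp_grammar()
sim <- simulate_protein(strrep("ab", 4), g, substitution_rate = 0.05,
                        flank_lengths = c(12, 12), seed = 2024)
scan <- scan_proteins(sim$seq, g)

glance(scan)
#> # A tibble: 1 × 5
#>   n_sequences n_modules n_regions residues_covered total_residues
#>         <int>     <int>     <int>            <int>          <int>
#> 1           1         8         1              236            260

scan$regions[, c("start", "end", "n_modules", "architecture", "pattern")]
#> # A tibble: 1 × 5
#>   start   end n_modules architecture pattern
#>   <int> <int>     <int> <chr>        <chr>
#> 1    12   248         8 abababab     (ab)4

recovery_report(sim$truth, scan$hits)
#> # A tibble: 1 × 6
#>   n_truth n_predicted precision recall exact_boundary_rate type_accuracy
#>     <int>       <int>     <dbl>  <dbl>               <dbl>         <dbl>
#> 1       8           8         1      1                   1             1

glance(segregate_modules(scan))
#> # A tibble: 1 × 5
#>   n_modules n_types purity mean_within mean_between
#>       <int>   <int>  <dbl>       <dbl>        <dbl>
#> 1         8       2      1       0.127        0.190
```

Reading the output: all 8 planted modules are recovered with exact
boundaries and types inside one contiguous region of 236 residues
(positions 12–248, 0-based half-open), whose architecture `abababab`
compresses to `(ab)4`. In the segregation summary, same-type modules
differ at ~13% of positions while a-vs-b rows (b trimmed by 5 residues to
equal length) differ at ~19%, and the UPGMA root split separates the two
types perfectly (purity 1). `write_annotations()` exports hits as TSV,
BED or JSON; `ape::write.tree(segregate_modules(scan)$tree)` gives the
Newick tree; `autoplot()` on scans, profiles and segregation objects
draws the standard figures.

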