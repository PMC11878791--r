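# psiflow

Splice-graph quantification of Percent Spliced In (PSI) for Smart-seq
single-cell RNA-seq, with discovery of unannotated junctions and exons and
a permutation-based differential-splicing caller.

## The problem and the model

Full-length single-cell protocols make per-cell splicing analysis possible,
but coverage is low and uneven, so the naive estimate
`PSI = observed coverage / expected coverage` is unstable in exactly the
cells one cares about. psiflow estimates, for every exon and junction *i*
of a gene's splice graph and every cell *c*, the inclusion fraction
Ψᵢᶜ ∈ [0, 1], by solving one weighted least-squares system per cell that
stacks three kinds of equations:

* **coverage** (weight 1): Ψᵢᶜ = aᵢᶜ / αᶜ, where aᵢᶜ is the observed mean
  per-base exon depth or junction read count and αᶜ the cell's
  gene-coverage scalar (estimated separately for exons, α_E, and
  junctions, α_J);
* **conservation of flow** (weight 6): at every node of the splice-graph
  DAG, Ψ of the exon equals the sum of Ψ over incoming junctions, and over
  outgoing junctions; the artificial source and sink are pinned to
  Ψ = 100% (weight 1);
* **intra-cell-type similarity** (weight 4): Ψᵢᶜ equals the α-weighted
  mean of Ψ values from the cell's expression-nearest neighbors
  (previous iteration), which lets well-covered cells stabilize
  poorly covered ones.

Ψ and α are estimated alternately (expectation / maximization), with an
intermediate step that rescales each cell's Ψ vector so the average
*cross-section* sum of the graph equals 1 — a global flow constraint that
prevents slow drift between Ψ and α. Splice graphs are built from a GTF,
extended with unannotated junctions/exons supported by ≥ 5 reads in
≥ 10 cells, and simplified by dropping unobserved elements that are not
needed for connectivity. Differential splicing between two cell groups is
called on Δ = difference of group-mean Ψ, against a normal null fitted to
Δ values from 10 random group reassignments, with Benjamini–Hochberg
correction (significant at adjusted p < 0.01).

## A worked example

Simulate a 20-gene study (two cell types × 40 cells, each gene carrying
one unannotated junction), quantify it, and call differential splicing:

```r
library(psiflow)
sim   <- simulate_dataset("novelJ", n_genes = 20, n_cells_per_type = 40,
                          seed = 7)
res   <- quantify_dataset(sim)
head(res$psi, 4)
#> # A tibble: 4 × 6
#>   gene_id element_id  type  is_novel cell_id   psi
#>   <chr>   <chr>       <chr> <lgl>    <chr>   <dbl>
#> 1 G001    E:1001-1133 exon  FALSE    C001    1
#> 2 G001    E:2268-2344 exon  FALSE    C001    0.999
#> 3 G001    E:4140-4355 exon  FALSE    C001    0.869
#> 4 G001    E:4823-5177 exon  FALSE    C001    0.397
```

Each row is one element in one cell: G001's exon at 4823–5177 is included
in ~40% of that cell's transcripts, while the first exon is constitutive.
Calling differential splicing between the two simulated types and scoring
against the simulator's ground truth:

```r
calls <- diff_splicing(res$psi, sim$cells[, c("cell_id", "group")])
glance(calls)
#> # A tibble: 1 × 6
#>   n_elements n_tested n_significant    null_mu null_sigma alpha
#> 1        325      325            91 -0.0000356     0.0219  0.01

evaluate_detection(calls, sim$truth$delta)
#> # A tibble: 1 × 6
#>      tp    fp    fn    tn precision recall
#> 1    29     0    11    83         1  0.725
```

91 of 325 elements are significant at adjusted p < 0.01; at the exon
level every call is correct (precision 1) and 72% of truly differential
exons are found. The median per-gene base-pair-weighted absolute Ψ error
is 0.0043 (0.43 percentage points), and 19 of the 20 withheld novel
junctions were rediscovered and added to the graphs.

A command-line wrapper for counts-mode directories is installed at
`inst/scripts/psiflow.R` (`simulate` and `run` subcommands).

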