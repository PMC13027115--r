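# TCRforge

Reconstruction of T-cell receptor (TCR) repertoires from barcoded
single-cell RNA-seq reads, and the downstream clonal-dynamics analytics
used to compare patient groups, tissues and treatment timepoints.

Single-cell RNA-seq libraries contain TCR transcripts even when no
dedicated scTCR-seq assay was run. TCRforge screens reads against a
germline V(D)J segment reference, embeds cell barcodes into read
identifiers (`barcode:umi:id`) for per-cell demultiplexing, assembles
each cell's reads into contigs by greedy overlap consensus, annotates V/J
segments by local alignment, and extracts the CDR3 junction between the
conserved V-segment cysteine codon and the J-segment F/W codon. Chains
are kept when their CDR3 passes the locus-specific validity filter
(TRA/TRG: starts with C, ends with F or W; TRB/TRD: starts with `CASS`,
ends with F).

On top of the reconstructed chains it provides:

* **Clonotype calling** — one clonotype per (locus, allele-stripped V
  gene, CDR3 amino-acid sequence), counted in cells per sample, in a
  `RepertoireTable` (a `SummarizedExperiment`).
* **Sharing architecture** — private / intra-group / inter-group
  classification across patients, top-shared clonotype selection,
  CDR3 length distributions, positional conservation (sequence-logo
  matrices with information content in bits), V–J pairing tables, and
  tissue-flow (Sankey) edge exports.
* **Repertoire statistics** — clonality (cumulative frequency of the top
  10% of clones, k = max(1, ⌊0.1 n⌋)), diversity (unique clonotypes over
  total cells), clonal expansion index (1/N)ΣRᵢ, expansion proportions
  across timepoints, tissue enrichment E = log2(Tpre/Npre), tumor
  response Δ = log2(Tpost/Tpre), and two-group tests (t / exact
  Mann–Whitney) with FDR correction.
* **Benchmarking** — matching reconstructed chains to a ground-truth set
  per cell and locus under three nested modes (CDR3 nucleotide, CDR3
  amino acid, gene level), with overlap, read recall and per-component
  (V/D/J/CDR3) precision.
* **A seeded simulator** — multi-patient (MSI/MSS), multi-tissue
  (blood/normal/tumor), pre/post-treatment single-cell V(D)J read sets
  with skewed clone sizes, biased gene usage, junctional diversity,
  public (shared) clonotype pools, sequencing error, and full ground
  truth, so the whole pipeline is testable offline.

## A worked example

```r
library(TCRforge)

ref <- syntheticGermlineReference()          # built-in synthetic germline
cfg <- simConfig(seed = 1,
                 patients = c("P01", "P04"),
                 groups   = c(P01 = "MSS", P04 = "MSI"),
                 n_clonotypes_per_sample = 20,
                 clone_size_param = 1, error_rate = 0,
                 shared_clone_fraction = 0.1)
run <- runEndToEnd(ref, cfg, tempdir())

run$benchmark[, c("match_mode", "n_reference", "n_query", "n_matched",
                  "overlap_vs_reference_pct")]
#>    match_mode n_reference n_query n_matched overlap_vs_reference_pct
#> 1 junction_nt         240     240       240                      100
#> 2 junction_aa         240     240       240                      100
#> 3  gene_level         240     240       240                      100

head(run$metrics[, c("sample_id", "n_unique", "total_clones",
                     "clonality", "diversity")], 3)
#>        sample_id n_unique total_clones clonality diversity
#> 1  P01_blood_Pre       20           20       0.1         1
#> 2 P01_blood_Post       20           20       0.1         1
#> 3 P01_normal_Pre       20           20       0.1         1

table(SummarizedExperiment::rowData(run$repertoire)$sharing_class)
#> inter_group     private
#>           2         214
```

All 240 simulated chains are recovered with their exact junction
(error-free tiling reads), every sample has 20 singleton clonotypes
(clonality 0.1 = 2/20 with k = 2, diversity 1), and the 10% public-pool
draw yields a small inter-group shared fraction against a private
majority (with one patient per group, intra-group sharing cannot occur).
The printed-count overlap arithmetic is available directly:

```r
overlapRates(6962, 1026, 765)
#> vs_reference_pct     vs_query_pct
#>            10.99            74.56
```

A thin CLI over the same functions is installed at
`system.file("cli", "tcrforge", package = "TCRforge")` with subcommands
`simulate`, `run`, `metrics`, `share` and `benchmark`.

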