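# pollsort

Automatic cell type annotation for single-cell RNA-seq by marker-gene
approval voting.

## The problem

Clustering a scRNA-seq expression matrix is routine; deciding *what* each
cluster is remains a manual, subjective step in most workflows. `pollsort`
automates it. Cells are clustered, and each cluster is labeled by letting
marker genes vote: every marker approves all cell types it is listed for in
a user-replaceable marker database, and the winning type is the one whose
approval score is most significant against a null model of random clusters.
The package is aimed at anyone annotating immune-type-rich tissues (bone
marrow, PBMC) or any dataset for which a marker/cell-type table exists.

## The method

For an expression matrix `X[i, j]` (genes × cells):

1. **Preprocess** — keep genes expressed somewhere; divide each cell by its
   total (`Σ_i X[i,j] = 1`); `log2`-transform with zeros replaced by the
   global smallest nonzero value `m`; keep high-variation genes
   (`σ_i / ⟨σ⟩ ≥ θ`, default `θ = 0.3`) for clustering.
2. **Cluster** — project cells on the top 100 principal components; pick the
   number of clusters `n` at the first peak (from the large-`n` side) of the
   mean adjusted-Rand-index curve over repeated mini-batch K-means
   partitions (12 partitions, 66 pairs per run); cut a Ward agglomerative
   tree at `n`; lay out cells in 2-D with t-SNE for figures.
3. **Vote** — build the binary marker/type matrix `M[k, m]` over expressed
   markers and normalize it twice (`M̃`): by each type's marker count, then
   by each marker's type count, so private markers weigh most. Call marker
   support per cluster from centroid z-scores (`Z̃[m,c] = 1` iff
   `Z[m,c] ≥ ζ`, default `ζ = 0.3`) and score
   `V[k,c] = Σ_m M̃[k,m] Z̃[m,c] / Σ_{k',m} M̃[k',m] Z̃[m,c]`.
4. **Test** — recompute `V` on 10⁴ size-preserving random reassignments of
   cells to clusters, standardize the observed score into `Λ[k,c]`, and
   label each cluster `T_c = argmax_k Λ[k,c]`. Clusters with ≤ 3 supporting
   markers are flagged `*`; clusters with no positive `Λ` or no supporting
   marker are labeled `Unknown`.
5. **Recurse** — re-run the whole pipeline on the cells of one major type
   with a sub-type marker table (`run_subtype()`).

See `vignettes/pollsort-methods.Rmd` for assumptions, parameter meanings and
design choices.

## Worked example

```r
library(pollsort)

# synthetic dataset with planted ground truth: 3 types x 100 cells,
# 5 private markers per type, fold change 10, no dropout
d <- generate_dataset(n_types = 3, cells_per_type = 100,
                      n_background_genes = 200, fold_change = 10,
                      dropout_rate = 0, seed = 11)

fit <- run_pipeline(d$expr, d$db, n_grid = 2:6, ari_reps = 6, ari_runs = 4,
                    n_random = 500, seed = 11, tsne = FALSE)
fit
#> pollsort_fit: 300 cells, 4 clusters
#>  cluster cell_type max_lambda support_count low_support
#>        1     TYPE1   2.093884             5       FALSE
#>        2     TYPE2   2.149989             5       FALSE
#>        3     TYPE3   2.197379             5       FALSE
#>        4     TYPE3   2.350379             4       FALSE

adjusted_rand_index(fit$assignment$labels, d$truth$true_type)
#> [1] 0.9624827
```

The stability curve resolved reproducible substructure inside one planted
type (`n = 4`: clusters 3 and 4 are both TYPE3); every cluster is labeled
with its planted type with 4-5 supporting markers (no `*` flag), and the
clustering agrees with the planted partition up to that pure split
(ARI = 0.96). `Lambda of 2.1-2.4` means each winning score sits about two
null standard deviations above the random-cluster expectation. Figures:
`plot_ari_curve(fit$ari)`, `plot_voting_matrix(fit$vote, fit$assignment)`,
`plot_marker_centroid_heatmap(fit$vote)`, `plot_embedding(...)`.

Results are written as delimited text with
`write_results(fit$vote, fit$assignment, "out/")`.

## Command line

```sh
Rscript inst/cli/pollsort.R simulate --types 4 --cells-per-type 200 --out sim/
Rscript inst/cli/pollsort.R run --expr sim/expression.tsv \
    --markers sim/markers.tsv --out res/ --n-clusters AUTO --seed 0
Rscript inst/cli/pollsort.R subtype --expr sim/expression.tsv \
    --labels res/cells.tsv --type TYPE1 --markers sub_markers.tsv --out sub/
```

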