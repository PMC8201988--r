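# epirank

Rank genes by the magnitude of their epigenetic alteration between two
biological conditions — tumor vs. normal, two developmental stages, two
treatment arms — integrating the differential signal of multiple epigenetic
marks over **both** gene promoters and their distal enhancers.

## Who this is for

Epigenomics groups with ChIP-seq-style signal tracks for several histone
marks (e.g., H3K27ac, H3K4me1/3, H3K36me3, H3K27me3, H3K9me3) in two groups
of samples, plus chromatin-interaction evidence (promoter-capture Hi-C,
ChIA-PET, or any BEDPE-like anchor table) linking distal
promoter-interacting regions (PIRs) to their target genes. Much of the
regulatory alteration in disease happens at enhancers, so a promoter-only
view of "most epigenetically altered genes" misses it; this package folds
enhancer alterations back onto their target genes.

## The method

1. **Element scoring by differential PCA.** Signals are summarized per
   regulatory element at a 1-kb scale, square-root transformed, and
   quantile-normalized within each mark. The matrix of between-condition
   mean differences, `D` (G elements × M marks), is decomposed as

   ```
   D = B V + E
   ```

   (SVD: `B = U S` holds element coordinates, `V` the mark loadings, `E`
   the residual). Each element's score is `|dPC1| + |dPC2|` — the first two
   components capture the coordinated changes of activating and repressive
   marks.

2. **Propagation over the enhancer→promoter graph.** Elements become
   vertices of a directed graph (edges PIR → target promoter), weighted by
   their scores. Personalized PageRank with restart probabilities
   proportional to the weights drains all enhancer mass into the promoters
   it targets, yielding one **meta-gene score** per gene and a ranked gene
   list. A promoter-only baseline ranking (scores without propagation) is
   produced alongside.

3. **Benchmarking by ECDF/AUC.** For any gene set `G`, the running count of
   set members among the top-k ranked genes, `eCDF_G(k) = Σ_{i≤k} δ_i`,
   normalized by `|G|`, gives an enrichment curve; its area under the curve
   (AUC) is 1.0 when the set occupies the top ranks and ≈ 0.5 for a random
   scatter. A degree-preserving rewiring null (double-edge swaps keeping
   every in/out-degree) tests whether high ranks are explained by
   connectivity alone.

A self-contained synthetic-epigenome generator (`simulate_epigenome()`)
plants multiplicative differential signal at the promoters and/or enhancers
of a known marker-gene subset so the whole pipeline can be validated
end-to-end without external data.

## Worked example

```r
library(epirank)

# two conditions x 3 samples x 6 marks; differential signal planted at the
# enhancers (only) of 10 of 100 genes
sim <- simulate_epigenome(sim_config(n_genes = 100, marker_mode = "enhancer",
                                     seed = 42))
res <- epirank_run(sim)
res
#> epirank_result: 100 genes ranked, 100 promoters, 427 PIRs, 427 edges
#> top genes: GENE0001, GENE0052, GENE0061, GENE0007, GENE0034

head(res$ranked, 3)
#>   rank     gene      score
#> 1    1 GENE0001 0.03317111
#> 2    2 GENE0052 0.02573717
#> 3    3 GENE0061 0.02486067

truth_eval(res$ranked, sim$truth)            # network ranking
#> enrichment_result 'planted_markers': 10/100 genes, AUC = 0.9300
truth_eval(res$promoter_ranked, sim$truth)   # promoter-only baseline
#> enrichment_result 'planted_markers': 10/100 genes, AUC = 0.6440

rewiring_null(res$graph, sim$truth$markers, n_perm = 100, seed = 1)
#> rewiring_null_result 'gene_set': observed AUC 0.9300, null mean 0.4952 (n=100), p = 0.009901
```

With the signal planted at enhancers, the promoter-only ranking barely sees
the markers (AUC 0.64) while the propagated ranking recovers them
(AUC 0.93); randomizing the wiring destroys the enrichment (null mean
≈ 0.50), showing the recovery rides on the true enhancer→promoter links,
not on connectivity.

A thin command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/epirank.R", package = "epirank"))')
Rscript $CLI simulate --out simdir --n-genes 200 --seed 1
Rscript $CLI rank --in simdir --out rankdir
Rscript $CLI benchmark --ranks rankdir/ranked_genes.tsv \
    --sets simdir/markers.txt --out benchdir --null 200 --in simdir
```

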