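# mirXtalk

miRNA-mediated pathway crosstalk analysis for tumor progression studies.

`mirXtalk` is an R package for dissecting how microRNAs co-regulate
biological pathways as a tumor progresses through malignancy grades. It is
aimed at computational biologists with matched miRNA and mRNA expression
profiles across graded tumor samples (e.g. glioma grades II, III, IV), a
predicted miRNA-target list, a protein-protein interaction (PPI) network
and pathway gene sets, who want to move from per-feature differential
calls to a network-level picture: which pathways do dysregulated miRNAs
act on, which pathway pairs talk to each other, and do the resulting
modules stratify patient survival?

## The method

The chain has six statistical stages:

1. **Differential calling.** Each miRNA and gene is tested for grade III
   vs II and grade IV vs II (grade II as control) with the unpaired
   pooled-variance t test; Benjamini-Hochberg FDR is controlled at 5%
   within each (feature kind, contrast) family.
2. **Signature pairs.** A predicted pair (miRNA, target gene) is kept
   when both features are differential with *opposite* directions and
   their expression is inversely correlated: Pearson r ≤ −0.4 with
   asymptotic-test P < 0.05.
3. **miRNA-pathway network.** For each miRNA, its inversely correlated
   target set is tested against every pathway with the cumulative
   hypergeometric tail

   P = P(X ≥ m), X ~ Hypergeometric(N, M, n),

   where N is the gene universe, M the pathway size, n the target-set
   size and m their overlap; edges with P < 0.05 form a bipartite
   network. Hub miRNAs are the inclusive top 15% by degree.
4. **Pathway crosstalk.** For pathways i and j, every PPI edge e(a, b)
   joining differential genes a ∈ i, b ∈ j contributes the
   Fisher's-method interaction strength

   W(e(a,b)) = −2 (ln P(a) + ln P(b) + ln P(a,b)),

   with P(a), P(b) the genes' differential p-values and P(a,b) their
   expression-correlation p-value; the pair's crosstalk weight is the sum
   of W over qualifying edges. Significance comes from a permutation null
   that redraws both pathways' differential-gene sets (same sizes) from
   the pooled differential genes and recomputes the weight; the p-value
   is (r + 1)/(B + 1).
5. **Modules.** Maximal bicliques of the miRNA-pathway network (miRNA
   sets jointly regulating pathway sets) and k-clique-percolation
   communities of the crosstalk network (k = 3 by default), plus a
   "core module" extractor around an anchor pathway.
6. **Survival.** Samples are split in two by K-means (k = 2) on the
   standardized expression of the core-module signature genes and
   miRNAs; Kaplan-Meier curves are compared by the log-rank test, in
   gene-only, miRNA-only and combined modes.

A synthetic-data generator (`simulateCrosstalkData()`) emulates all five
inputs with planted differential signal, negative miRNA-target coupling,
pathway-concentrated target sets, densely wired crosstalk pathway pairs
and a planted two-group hazard difference, so the whole chain can be
validated against ground truth.

## Worked example

```r
library(mirXtalk)

d <- simulateCrosstalkData(syntheticConfig(seed = 1))
d$mirnaExpr
#> ExpressionMatrix (miRNA): 150 features x 160 samples

diffM <- rbind(callDifferential(d$mirnaExpr, d$annotation, "III_vs_II"),
               callDifferential(d$mirnaExpr, d$annotation, "IV_vs_II"))
diffG <- rbind(callDifferential(d$geneExpr, d$annotation, "III_vs_II"),
               callDifferential(d$geneExpr, d$annotation, "IV_vs_II"))

sig <- selectSignaturePairs(diffM, diffG, d$targetPairs,
                            d$mirnaExpr, d$geneExpr, d$annotation)
nrow(sig)                       # 320 signature pairs over 40 miRNAs
head(sig, 1)
#>   mirna_id gene_id  contrast direction_pattern          r          r_p
#> 1  miR-068   G0526 III_vs_II  miR_up_gene_down -0.9581078 7.744178e-53

uni <- intersect(featureIds(d$geneExpr),
                 unique(unlist(geneSets(d$geneSets))))
net <- buildMirnaPathwayNetwork(sig, d$geneSets, uni)
net
#> MirnaPathwayNetwork: 40 miRNAs, 25 pathways, 80 edge records

ct <- buildCrosstalkNetwork(d$geneSets, d$ppi, d$geneExpr, diffG,
                            B = 500, seed = 2)
ct
#> CrosstalkNetwork: 25 pathways, 14 significant / 300 scored pairs (B = 500)

e <- networkEdges(ct)
deg <- sort(table(c(e$pathway_i, e$pathway_j)), decreasing = TRUE)
core <- extractCoreModule(ct, names(deg)[1])
core$core
#> "PW006" "PW012" "PW015" "PW022"   # the planted core crosstalk module

coreGenes <- unique(unlist(geneSets(d$geneSets)[core$nodes]))
st <- stratifyAndTest(
  d$mirnaExpr, d$geneExpr, d$annotation,
  signatureGenes = intersect(unique(sig$gene_id), coreGenes),
  signatureMirnas = unique(networkEdges(net)$mirna_id[
    networkEdges(net)$pathway_id %in% core$nodes]),
  seed = 5)
st$chisq; st$p
#> log-rank chi-square = 19.51, p = 1e-05
st$curves$short$median; st$curves$long$median
#> median survival: short 11.2 months (n = 84), long 25.2 months (n = 76)
```

The significant crosstalk pairs concentrate on the planted core module,
and clustering patients on the core-module signature separates the
planted risk groups by more than a factor of two in median survival.

`runPipeline("all", pipelineConfig(outDir = "out", seed = 1))` runs the
same chain as a staged pipeline, writing one tab-separated table per
stage plus GraphML network exports and YAML manifests;
`inst/scripts/run-pipeline.R` is an equivalent command-line wrapper.

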