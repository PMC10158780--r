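# cfChIPquant

Tumors shed nucleosome-bound DNA into blood plasma, and the histone mark
H3K36me3 is deposited co-transcriptionally over the bodies of actively
transcribed genes. Chromatin immunoprecipitation performed directly on plasma
(cfChIP-seq) against H3K36me3, followed by targeted capture sequencing of a
lung-cancer gene panel, therefore reads out tumor gene expression from a
blood draw. `cfChIPquant` implements the quantification and concordance
analysis for this assay: from per-gene deduplicated read counts and TPM
expression matrices to enrichment profiles, active/inactive gene
classification, differential-enrichment versus differential-expression
agreement statistics, and paired mutational-allele-fraction comparisons. A
seedable synthetic-data generator emulates the study design (a 197-gene
panel, cell-line triplicates, 8 + 4 patients, 4 healthy donors) so every
stage is testable without sequencing data.

The package is aimed at computational biologists working on liquid-biopsy
epigenomics who need a tested, reusable reference implementation of this
quantification scheme.

## The model

For a (cf)ChIP sample with deduplicated read counts `N_i` over panel genes,
per-gene enrichment is the library-size- and footprint-normalized rate

    E_i = N_i * 1e9 / (T * k_i),        T = Σ_i N_i  (included genes)

where the coverage factor `k_i` is the number of bases of gene *i* captured
above depth 100 in a reference capture experiment. Genes captured solely
within the first 25% of the gene body from the TSS are excluded (H3K36me3 is
depleted there). For patient plasma, the hematopoietic background is removed
by subtracting the average healthy-donor counts `H̄_i` gene-wise:

    E_i = (N_i − H̄_i) * 1e9 / ((Σ N − Σ H̄) * k_i)

Both forms conserve `Σ E_i k_i = 1e9`. Group differences use
`log2FC_i = log2(Ē_i^a + ε) − log2(Ē_i^b + ε)` on group-mean enrichment.

On the expression side, genes with mean `log2(TPM+1) > 0.2` in a group are
*active*; differential expression between groups uses the mean-of-logs fold
change, a two-sided Welch t-test per gene on `log2(TPM+1)` and
Benjamini–Hochberg FDR, with `|log2FC| > 1` and `q < 0.05` calling a gene
differentially expressed. Concordance is quantified by Spearman rank
correlation, ROC analysis of active-gene discrimination (Mann–Whitney AUC,
Hanley–McNeil SE, z-ratio `(AUC − 0.5)/SE`), per-direction agreement
sensitivities with Fisher's exact test, and a paired t-test on
input-vs-cfChIP mutational allele fractions (allele-specific transcription).

## Worked example

```r
library(cfChIPquant)

cfg <- simulationConfig(seed = 1)
ds  <- simulateDataset(cfg)
ds@panel
#> GenePanel "synthetic-panel": 197 genes, 161 included
#>   (36 TSS-window excluded, 0 with k = 0)

## can enrichment tell active from inactive genes?
chip <- chipEnrichment(ds@counts, ds@panel, samples = paste0("NSCLC_rep", 1:3))
inc  <- includedGenes(ds@panel)
roc  <- rocActiveGenes(groupMeanEnrichment(chip), ds@truth$activity[inc])
roc
#> RocResult: AUC = 0.9655 (SE 0.0129), z = 36.158, p = 2.75e-286
#>   [122 active vs 39 inactive]
sensitivityAtSpecificity(roc, 0.75)
#> [1] 0.9508197

## differential expression vs background-subtracted plasma enrichment
de  <- differentialExpression(ds@tpm, "NSCLC", "SCLC")
table(de$status)
#> filtered_inactive  not_de  up_in_a  up_in_b
#>                33     135       14       15

bg  <- makeBackground(ds@counts, ds@panel)
cd  <- SummarizedExperiment::colData(ds@counts)
pat <- rownames(cd)[cd$assay_type == "cfchip" & cd$condition != "healthy"]
rel <- cfchipRelativeEnrichment(ds@counts, bg, ds@panel, samples = pat)
fc  <- relativeLog2FC(
  groupMeanEnrichment(rel, grep("P0[1-8]", pat, value = TRUE)),   # NSCLC
  groupMeanEnrichment(rel, grep("P09|P1[0-2]", pat, value = TRUE))) # SCLC
agreementAnalysis(de[de$gene_id %in% names(fc), ], fc)
#> AgreementResult
#>   sensitivity up_in_a: 1  up_in_b: 1
#>   Fisher's exact p = 2.243e-07

## allele-specific transcription: paired MAF shift, cfChIP vs input
pairedMafTest(pairVariants(ds@variants), gene = "TP53")
#> PairedMafResult: n = 9, mean difference = 2.96% (95% CI 0.26-5.67%), p = 0.0356
#>   direction: 7 up, 2 down, 0 unchanged
```

The ROC says mean ChIP enrichment separates the generator's truly active from
inactive genes almost perfectly at this depth; the agreement table says every
differentially expressed gene covered by the panel shifted its plasma
enrichment in the expected direction; and the paired MAF test detects the
simulated preferential pulldown of transcribed mutant alleles (7 of 9
variants up in the immunoprecipitated compartment).

A full staged run (enrichment → DE → concordance → MAF, with TSV outputs and
a plain-text report) is available through `writeDataset()`, `pipelineConfig()`
and `runPipeline()`; `validateInputs()` checks inputs first.

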