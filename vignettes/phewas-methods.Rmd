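---
title: "Cross-survey PheWAS: models, filters and design choices"
author: "phewasKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-survey PheWAS: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phewasKit)
```

## The problem

A phenome-wide association study (PheWAS) inverts the usual GWAS design:
instead of testing many variants against one phenotype, a modest panel of
SNPs is tested against hundreds of phenotypes drawn from an epidemiologic
collection. With thousands of unadjusted tests, the central methodological
question is how to separate signal from noise without a multiple-testing
correction that assumes independent tests (phenotypes are strongly
correlated, and per-test power varies with each phenotype's sample size).
The answer implemented here is *cross-survey replication*: a result counts
only if it appears independently in two surveys of the same population
frame, in the same stratum, for the same phenotype class, with the same
direction of effect.

`phewasKit` implements that workflow end to end for a two-survey
collection stratified by self-reported race-ethnicity, and pairs it with a
synthetic data generator so that every stage can be exercised and
calibrated without access to restricted individual-level survey data.

## The association model

Every test is an unadjusted single-SNP regression under an additive
genetic model. For a continuous measurement $y$ and genotype $g \in
\{0,1,2\}$ (copies of the coded allele),

$$y_i = \alpha + \beta g_i + \varepsilon_i,$$

fitted by ordinary least squares on complete cases; the reported p-value
is the two-sided t test of $\beta$ on $n-2$ degrees of freedom
(`fitLinear()`, closed form). For a binary measurement the same linear
predictor enters a logistic link, fitted by maximum likelihood
(`fitLogistic()`, IRLS with relative deviance tolerance $10^{-8}$, at
most 50 iterations), with a two-sided Wald test of $\beta/\mathrm{se}$
against the standard normal. The test family is a design choice — the
output of an unadjusted scan is conventionally Wald-based, and nothing
downstream depends on the distinction between Wald and likelihood-ratio
p-values at these sample sizes.

Degenerate inputs are flagged rather than thrown: a constant genotype or
phenotype, fewer than three complete cases, a single outcome level, IRLS
non-convergence, or a standard error above 100 on the coded scale (the
signature of separation) all mark the result unavailable, and flagged
results can never qualify for replication.

No covariates, no survey design weights, no genomic control: the scan is
deliberately unadjusted, and replication across surveys carries the
burden of error control.

## Harmonization and measurements

Phenotypes are harmonized at two levels.

* **Phenotype classes** (`assignClasses()`): a curated class map bins
  survey-specific raw names ("Vitamin A", "Serum Vitamin A") into one
  class per phenotype. The map is data, not code — the original binning
  of this kind of collection is manual curation, so the package consumes
  a TSV and reports unmapped names instead of guessing.
* **Exact harmonization** (`harmonizeCombined()`): only when the
  identical phenotype was measured in both surveys can the samples be
  pooled into a combined-survey variable for a re-test. Classes that are
  binned but not exactly harmonized simply have no combined result.

Each raw phenotype expands into one or more analyzable *measurements*
(`buildMeasurements()`): continuous phenotypes are carried both
untransformed and as $\ln(y+1)$ (the +1 keeps zero-valued observations in
the analysis; the transformed copy is a distinct measurement of the same
class and is skipped when negative values make it undefined), and
categorical phenotypes become one A-versus-not-A binary indicator per
observed category, inheriting the parent's class.

## The replication filter

A (SNP, class, stratum) group is retained iff some measurement in each
survey satisfies, with strict inequalities, $p < 0.01$, coded-allele
frequency $> 0.01$ and $n > 200$, and the two surveys' qualifying
measurements agree in the sign of $\beta$. Two decisions here were
genuinely open:

* A qualifying cross-survey pair must match on transform status. Betas on
  the raw and $\ln(y+1)$ scales are not comparable, so sign agreement is
  only evaluated within a scale. A transformed hit in one survey cannot
  pair with an untransformed hit in the other.
* $\beta = 0$ exactly has no direction and cannot qualify.

Within each survey the *best* qualifying measurement is the one with the
smallest p-value (ties: larger $n$, then lexicographic name), mirroring
lowest-p reporting per class. Under the null, two independent surveys at
$p<0.01$ with a coin-flip sign agreement give an expected pass rate of
$0.01^2 \times 0.5 = 5\times10^{-5}$ per group; the test suite verifies
this calibration on $2\times10^5$ simulated null groups.

## Classification, pleiotropy, generalization

Retained groups are labelled against a catalog of previously reported
SNP-phenotype associations: an exact class match for the SNP is
**replicated**; otherwise a shared *related-group* tag (e.g. one lipid
group covering HDL-C, LDL-C, total cholesterol and triglycerides) makes
it **related**; otherwise it is **novel**. The related calls in the
original analyses of this kind were expert judgement; encoding them as
explicit tags in a data file makes the category reproducible and
auditable, which is why the package ships a clearly-curated
`related_groups.tsv` rather than a similarity heuristic. Direction
agreement with the catalog is reported but never changes the category.

A SNP is **pleiotropic** when its retained results span two or more
distinct classes, counted across strata jointly. A (SNP, class) group is
**generalized** when retained in two or more strata with one direction,
and **discordant** when the directions differ.

## Correlations

Pairwise Pearson correlations among significant phenotypes are computed
on pairwise-complete observations (maximizing usable n in survey data
with scattered missingness), per survey and stratum. The partner report
lists phenotypes with signed $r > 0.6$, strict; the screen uses signed
correlations, with absolute values taken only for the heatmap. Heatmap
ordering is fixed to complete-linkage clustering on the Euclidean
distance between $|r|$ rows (unavailable cells treated as 0 for ordering
only), so orderings are reproducible across runs and machines.

## Networks

Significant SNPs are annotated with their nearest gene: 1-based
coordinates, closed gene spans, strand ignored, distance measured to the
nearer span boundary (0 inside the span, negative upstream, positive
downstream), ties broken by gene symbol. Context strings (intron,
UTR-3, ...) are consumed from the annotation input, never recomputed.
Gene groupings — pathways from KEGG-style resources, GO terms, curated
pathway databases — are all consumed through one GMT parser.

The association graph has typed nodes (SNP, gene, grouping,
phenotype-class) and is built per stratum. A grouping node is added only
when at least two of the graph's genes are members: a single-member
grouping can never create the gene–gene link that matters and would only
add orphan clutter. Pruning keeps components with at least two PheWAS
SNPs whose genes are linked through at least one shared grouping; chains
through intermediate genes and groupings are allowed, so two genes joined
only via a third gene's groupings still survive. Everything else —
single-SNP stars, SNP pairs whose genes share nothing — is dropped.

## The synthetic generator

`simulateStudy()` emulates the structure of a two-survey epidemiologic
collection:

* **Genotypes**: per survey and stratum, $g \sim \mathrm{Binomial}(2,
  p_\text{stratum})$ — Hardy-Weinberg proportions at stratum-specific
  coded-allele frequencies.
* **Phenotypes**: continuous $y = \text{baseline} + \sum_k \beta_k g_k +
  \lambda F + \varepsilon$; binary through a logistic link with intercept
  set from the configured prevalence; categorical drawn from a category
  set. Correlation blocks share a standard-normal latent factor $F$, so
  two members correlate at $\lambda_1\lambda_2 / \sqrt{(\lambda_1^2 +
  \sigma_1^2)(\lambda_2^2 + \sigma_2^2)}$ — a closed form the tests check
  against.
* **Naming**: harmonized classes keep one raw name in both surveys;
  non-harmonized classes get deterministic survey suffixes, so the class
  map is generated alongside the data and harmonization is exercised
  without manual curation.
* **Missingness**: MCAR, independent across genotype and phenotype
  cells — the simplest mechanism consistent with the complete-case
  analysis downstream. Phenotypes are generated from the *complete*
  genotypes before masking, so missingness is observational, not causal.
* **Seeding**: one master seed expands into deterministic per-stream
  seeds (genotypes, phenotypes, sex, missingness), so each component is
  reproducible on its own.

`defaultSimulationConfig()` fixes the study-like conditions: three strata
(NHW/NHB/MA) at per-survey sizes 3300/1730/1975, per-survey female
proportions 0.5667/0.5179, ten SNPs with stratum-specific frequencies
0.05–0.5, a lipid-style three-class block (loading 0.45, member noise SD
0.25, implied pair correlation 0.76), one pleiotropic SNP planted on
three classes with mixed directions plus two single-class effects of
0.3–0.6 SD per allele, and 5% missingness. Phenotype distributions are
stated defaults, not estimates — the source analyses do not describe
their phenotype distributions, so baselines and noise SDs were chosen
once as values a survey scientist would call unremarkable (total
cholesterol 5.2 mmol/L, diastolic BP 72 mmHg, ...), with block members
kept several noise SDs above zero so the $\ln(y+1)$ transform stays
defined.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs, population admixture, age structure,
oversampling weights, informative missingness, and measurement-unit
duplication within a survey. Passing tests therefore demonstrate the
pipeline's statistical behaviour (calibration, recovery, bookkeeping) on
clean additive data, not robustness to the full messiness of real survey
phenotypes.

## Numerical choices and problem sizes

* OLS is the exact closed form on centered sums; the suite requires
  agreement with `stats::lm` to $10^{-10}$ relative error on 1,000
  random instances.
* Logistic fits are checked against a brute-force likelihood-grid
  maximizer to $10^{-4}$ on small instances.
* Null p-value uniformity is checked by Kolmogorov-Smirnov at $10^4$
  tests; the replication filter's null pass rate on $2\times10^5$ groups
  (100 SNPs × 1,000 single-measurement classes × 2 strata, n = 300 per
  stratum per survey) must stay below $3\times10^{-4}$ against the
  $5\times10^{-5}$ theory value.
* Planted-effect recovery uses the default configuration at scale 0.4
  (per-survey stratum sizes 1320/692/790), where every planted effect has
  per-survey power well above 0.99, across ten seeds.

These sizes were chosen so the whole suite runs in well under a minute of
compute while leaving each check ample resolution.

## Known limitations

* The "related" category is only as good as the curated group tags;
  SNP-proxy (LD-based) matching against the catalog is out of scope.
* Combined-survey re-tests exist only for exactly harmonized phenotypes;
  no attempt is made to convert units across surveys.
* The scan is unadjusted by design; confounding (including medication
  effects on biomarkers) is not modelled, so retained results are
  hypothesis-generating, not causal claims.
* Correlation matrices use pairwise-complete cells, which need not be
  positive semi-definite; they are reported, not inverted.

## A short tour

```{r tour, eval = FALSE}
expt <- simulateStudy(defaultSimulationConfig(seed = 1, scale = 0.4))
scan <- runScan(expt)
ret  <- combinedRetest(applyReplicationCriteria(scan), scan)
cl   <- classifyAssociations(
    ret,
    readCatalog(system.file("extdata", "prior_associations.tsv",
                            package = "phewasKit")),
    readRelatedGroups(system.file("extdata", "related_groups.tsv",
                                  package = "phewasKit")))
detectPleiotropy(cl)
assessGeneralization(cl)
summarizeCategories(cl)
```
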