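---
title: "Models and methods for quantifying A-to-I editing in blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying A-to-I editing in blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodedit)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so an edited position shows a mix of
A and G reads on the gene strand. In bulk blood RNA-seq, the overwhelming
majority of the ~2M catalogued editing positions are edited rarely and at
trace levels. `bloodedit` implements the full analysis chain for
characterising the *consistently* edited fraction of the blood editome and
for asking what drives inter-individual variability in global editing:
gene expression (chiefly *ADAR* itself), blood cell composition,
biological and pharmacological covariates, and common genetic variation.

Because the cohort that motivates this design is access-restricted, the
package ships a synthetic cohort generator with recorded ground truth;
every claim the test suite makes is a claim about recovering known planted
structure, not about real blood.

## Editing quantification and CES selection

The editing level of site $i$ in sample $j$ is $G_{ij}/(A_{ij}+G_{ij})$,
the fraction of edited reads among gene-strand A/G reads. Sites covered by
fewer than 10 reads (inclusive threshold, configurable) in a sample are
treated as missing there — low-coverage ratios are dominated by sampling
noise. Minus-strand sites are resolved by complementing (T plays A, C
plays G) in `strand_resolve()`.

Candidate sites pass three exclusion filters before quantitative analysis
(`apply_site_filters()`): membership in an editing-site catalogue,
absence from a known-SNV list (a "perfectly edited" site that is really a
G allele is a genotype, not editing), and location outside alignment
trouble spots — pseudogenes, segmental duplications of high identity, and
single-exon (often retrotransposed) genes. Mask channels are BED intervals
(0-based, half-open); site positions are 1-based, and the conversion is
centralised in one helper so there is a single place for off-by-one
errors.

A site is a **consistently edited site (CES)** if its level reaches at
least 5% in at least 20% of subjects, both thresholds inclusive; the
sample count is `ceiling(min_fraction * n)`. Per-sample levels below 5%
are *not* zeroed beforehand — the consistency rule itself enforces the
detection threshold, and double-thresholding would silently change the
rule's meaning.

## The CES total editing rate

The per-subject global statistic is

$$\mathrm{rate}_j=\frac{\sum_{i=1}^m G_{ij}}{\sum_{i=1}^m C_{ij}},$$

edited reads over total reads pooled across the $m$ CES covered by at
least 10 reads in that subject — a coverage-weighted mean of per-site
levels, computed identically for the ALU-only and non-ALU subsets.
Pooling by reads rather than averaging ratios keeps noisy low-coverage
sites from dominating.

## Co-editing structure

`pairwise_site_correlation()` computes Spearman's rho (average-rank ties,
pairwise-complete samples, two-sided t-approximation p) for all unordered
site pairs. Pairs with fewer than 3 complete observations or a constant
vector are skipped and reported. Because the tests share samples and sites
co-vary, the default FDR adjustment is Benjamini–Yekutieli, which is valid
under arbitrary dependence; Benjamini–Hochberg is selectable. Reporting
follows two conventions deliberately: computation runs over the
$m(m-1)/2$ unique pairs, while the report also prints the all-against-all
count $m^2$ used by the convention in which each site is analysed against
every other ($2079^2 = 4{,}322{,}241$ at the reference CES count).
Distance stratification classes are literal: below 50 bp (strict), up to
1 kb, same-chromosome beyond, inter-chromosomal.

Agreement of mean editing levels with an external reference is summarised
by Lin's concordance correlation coefficient,
$\mathrm{CCC} = 2\,\mathrm{cov}(x,y)\,/\,(\sigma_x^2+\sigma_y^2+(\bar x-\bar y)^2)$
with population moments, which penalises location and scale shift as well
as decorrelation.

## Expression association

`robust_association()` regresses the total editing rate on a predictor
plus covariates by Huber M-estimation (tuning constant 1.345, the
conventional 95%-efficiency choice) and compares full and null models.
The p-value is a robust F-type test (squared Wald t on the predictor
term); the partial $R^2$ is $(\mathrm{RSS}_0-\mathrm{RSS}_1)/\mathrm{RSS}_0$
with both models' residuals weighted by the *full* fit's robustness
weights — using each fit's own weights lets differential downweighting
leak into the ratio and biases it low on clean data, which the shared
weighting avoids. An OLS flavour exists for oracle cross-checks, and both
are computed in practice; the robust one is primary. Degenerate
predictors (constant, or collinear with the covariates — e.g. the ADAR
gene scanned while ADAR expression is a covariate) return p = 1 and
partial $R^2$ 0 rather than an error, which is what a genome-wide loop
needs.

`genomewide_expression_scan()` runs one such test per gene with a shared
null fit, BH adjustment, and tiers at FDR < 0.05 / 0.01. The covariate
set is a configuration list (the package does not re-derive a stepwise
selection whose inputs are unavailable); a log2 summed-CES-coverage
covariate is included by callers because per-site variance depends on
depth below roughly 40x. With `remove_adar`, ADAR expression joins the
covariates, isolating effects beyond the dominant editor.

Covariate screening (`variable_association()`) dispatches on variable
kind — Pearson for continuous, Mann–Whitney–Wilcoxon for binary,
Kruskal–Wallis for categorical — and additionally reports `p_cell`, a
likelihood-ratio comparison of linear models with and without the
variable on top of the four rate-associated cell fractions, so
cell-mediated effects (e.g. age acting through cell composition) can be
told apart from direct ones. Variables informative in fewer than 30
subjects are rejected. Gene-set over-representation uses the one-sided
upper-tail hypergeometric test against the expressed-gene background,
with set membership intersected with the background first.

## PPI network analysis

`build_ppi()` merges three edge-list dialects with the source-specific
filters applied first: STRING-like edges need a combined score strictly
above 400 (literal "above") and at least one allowed evidence channel;
BioGRID-like edges must be physical; BioPlex-like edges pass as-is.
Parallel edges collapse with their sources recorded; self-loops and
blacklisted nodes (ubiquitin-family proteins, which interact with nearly
everything and would swamp any neighbourhood) are dropped.

The ADAR neighbourhood is seeded by all three family members when
present; `direct` is the 1-hop set and `connected` the hop-distance-2
set, excluding the seeds. Enrichment of a significant gene set among the
connected nodes is tested by resampling: `n_draws` uniform groups of the
same size are drawn from the background without replacement, and the
empirical p is $(b+1)/(B+1)$ where $b$ counts draws with at least the
observed connected count — the +1 correction keeps the p-value valid
(never zero) where the raw fraction could be. The reference condition is
$10^6$ draws; tests and the acceptance script use $10^3$–$10^5$ so the
whole suite stays within routine run times, which only coarsens the
smallest resolvable p. Node importance is reported as degree and
betweenness centrality normalised by $2/((n-1)(n-2))$, with components
handled independently and betweenness defined as 0 below 3 nodes.

## PCA of the editing matrix

Missing levels are imputed before PCA. The default imputer is
missForest-style: iterate over sites in decreasing observation order,
regress each site on all others with a random forest, replace its missing
entries, and stop when the relative change drops below $10^{-4}$ or after
10 iterations; imputed values are clipped to [0, 1] and observed entries
are never touched. A k-nearest-site average (Euclidean profile distance)
and a per-site mean are provided as fast options, and the fast option is
what large-matrix runs and most tests use — the forest's advantage is
accuracy on structured missingness, not speed. Components come from the
SVD of the centred, unscaled samples-by-sites matrix (the `prcomp`
default), with each component's sign fixed so its largest-magnitude
loading is positive.

The retained dimension uses a plateau rule that had to be formalised from
a visual criterion: over the top 30 variance fractions, keep the
components strictly above `baseline + 0.2 * (first - baseline)`, where
`baseline` is the window mean. This keeps exactly the components that
stand out above the spectrum's plateau, returns 1 on a flat spectrum, and
recovers the planted dimension on synthetic 5-factor data; the 0.2 ratio
and the window are configuration, not claims of equivalence to any visual
judgement. Site–PC correlation classes are literal bands: moderate
($0.3\le|r|\le0.5$), weak ($|r|<0.3$), both Bonferroni-gated at
$\alpha/(\text{sites}\times k)$; $|r|>0.5$ falls outside both literal
bands and is reported separately as "strong" so the information is not
lost while the band counts stay comparable.

## Genetics

Genotype QC runs samples first, then SNPs, thresholds strict as stated:
sample missingness > 1%; heterozygosity-rate z beyond ±3 SD (the cutoff
for "excessive" is not standardised, so ±3 SD is the default and
configurable); PI_HAT > 0.18 by PLINK-style method-of-moments IBD from
IBS sharing, removing the higher-missingness member of each flagged pair;
SNP missingness > 5%; Hardy–Weinberg exact p < 1e-6; MAF < 0.01. The HWE
test is the exact conditional test: given allele counts, sum the
probabilities of heterozygote counts no more probable than the observed
one. PI_HAT is estimated on complete-dosage SNPs; with only a few hundred
SNPs the estimator is noisy and will flag some unrelated pairs, which is
a property of the estimator at small marker counts, not a bug — the
synthetic panel uses thousands of SNPs.

Association is the additive model: OLS of the rate on A1 dosage plus
covariates (biological covariates and the first five genotype PCs),
casewise-complete per SNP, monomorphic SNPs skipped. Clumping is greedy:
the unassigned SNP with the smallest p (ties broken by genomic order)
indexes a clump absorbing unassigned SNPs within ±500 kb and $r^2\ge0.5$;
membership partitions the tested SNPs. SNP-set variance explained is a
joint fixed-effect model — $(\mathrm{RSS}_{cov}-\mathrm{RSS}_{full})/\mathrm{RSS}_{cov}$
with an F test, collinear SNPs pruned via QR — a deliberate substitute
for REML on a genetic relatedness matrix, which is out of proportion for
a set of a few dozen SNPs at a few hundred samples and is documented as a
substitute, not an equivalent. No genome-wide significance threshold is
asserted; clumps are reported ranked by p.

## The synthetic cohort

`generate_cohort()` emulates the study conditions: 450 subjects, 2000
strong sites (plus 15% weak decoys below the consistency rule and 25%
excluded decoys split over the five exclusion reasons), 3000 genes, 5000
SNPs. Editing probabilities live on the logit scale:

$$\mathrm{logit}\,p_{ij} = \mathrm{logit}\,p^0_i + t_j
  + 0.4\,\ell_{c(i),j} + \lambda_i f_j + \varepsilon_{ij},$$

with baseline spectrum $p^0$ mostly between 0.06 and 0.36 plus a ~1.6%
highly edited tail (≥ 0.92), clustered sites sharing a local co-editing
factor $\ell$ (this is what makes sub-50-bp pairs correlate strongly),
two latent factors with zero-mean loadings (shape variation that cancels
in the total rate), and site-sample noise with sd 0.3. The sample signal
is

$$t_j = c_j + a\,z_j + b\,(d_j-\bar d) + u_j,$$

where $c_j$ is a cell-composition combination scaled to sd 0.12, $z_j$
the ADAR-expression driver, $d_j$ the causal-SNP dosage and $u_j$
unexplained noise. The components are orthogonalised and rescaled in
sample so the planted fractions are exact: $a^2 = 0.13\,\sigma_g^2$
(ADAR explains 13% of the covariate-adjusted signal variance, mirroring
the reported magnitude), $b = 0.032$ per allele on the logit scale —
chosen so the rate-scale per-allele effect is ≈ 0.004, the magnitude the
reference analysis reports — which at $\sigma_g = 0.10$ leaves the
causal locus about 5% of the signal variance. Coverage is negative
binomial (mean 40, size 5), edited reads binomial, so missingness and
coverage-dependent noise arise mechanically. Cell fractions are Dirichlet
over 7 blood cell types with neutrophil dominance; the planted age
variable acts on editing *only* through the cell combination, giving the
mediation analysis a known positive and a known null. Genotypes copy one
of four founder haplotypes per 500-kb block with 2% per-SNP copy error —
enough LD for clumping to be meaningful — and the causal block's founders
are split so the clump has high-$r^2$ members. Expression is standard
normal residual-style, with the ADAR gene tracking $z$ (noise sd 0.15),
50 direct genes loading 0.35 on the non-ADAR signal and 30 mediated genes
loading 0.6 on $z$ alone. The PPI generator wires truth genes into the
ADAR 2-hop neighbourhood at a configurable odds ratio over a base
connection probability of 0.25, on top of uniform background edges and
deliberately filterable decoys (sub-400 scores, genetic-evidence edges,
promiscuous ubiquitin nodes).

Every output stream derives its own RNG seed from the master seed by a
named-hash scheme, so regenerating one file reproduces it exactly.

What the generator does **not** emulate: per-site variance components of
real blood (no public estimates exist — noise magnitudes are calibration
choices), linkage to a real genetic map, realistic pathway structure in
expression, batch artefacts, or any case/control contrast (controls only).
Passing tests therefore demonstrate that the pipeline recovers known
structure at realistic scales and noise levels, not that any biological
conclusion transfers to real cohorts.

## Problem sizes used in tests and the acceptance script

Unit tests run miniature cohorts (tens of samples, one–two hundred
sites). Parameter-recovery checks run the full emulated conditions —
450 subjects, 2000 sites, 5000 SNPs, 20 seeds — once per session and
share the results between assertions. The permutation-enrichment
calibration uses 400 replicate graphs of 1200 nodes, groups of 150 and
999 draws each — group size matters here because the count statistic is
discrete, and small groups leave probability atoms large enough that a
uniformity test flags the (correct, conservative) discreteness itself.
The null calibration of the SNP scan uses an independent-SNP panel,
since p-values of SNPs inside one LD block are dependent and a KS test
assumes independence. The acceptance script uses $10^5$ draws for its
single enrichment test and a 600-site subset with the kNN imputer for
the PCA stage. These sizes are the package's own choices balancing
resolution against routine run times.

## Known limitations

* The robust nested comparison is a Wald-type F on one added degree of
  freedom; it does not generalise to multi-column predictors (none occur
  in this pipeline).
* The plateau rule is a formalisation of a visual criterion; different
  ratio choices give different k on shallow spectra.
* PI_HAT is unreliable below a few hundred complete SNPs.
* The dependence-robust FDR (BY) is conservative; the choice between BY
  and BH materially changes the significant-pair count at weak signal.
* CCC against an external reference is only meaningful on the
  intersection of sites, and the package leaves assembling that
  intersection to the caller.
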