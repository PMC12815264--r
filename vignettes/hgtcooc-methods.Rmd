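---
title: "Methods: linking horizontal gene transfer to co-occurrence and environment"
author: "hgtcooc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking horizontal gene transfer to co-occurrence and environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtcooc)
```

# The analysis

`hgtcooc` implements an end-to-end analysis of horizontal gene transfer
(HGT) among prokaryotic genomes distributed across metagenomic samples. The
chain is: call putative HGT events from gene sequences; call genome presence
per sample from breadth of coverage; test pairwise co-occurrence; model the
binary pair-level HGT state on co-occurrence, phylogenetic distance and
ecology; test functional enrichment of transferred genes; and model
per-sample HGT prevalence on environmental covariates with a random forest.
Because the corresponding real datasets are externally hosted genome and
metagenome collections, the package ships a synthetic-data generator with
planted ground truth, and every statistical component is validated by
parameter recovery against that truth.

# HGT detection

**Rationale.** A region of high nucleotide identity shared by two distantly
related genomes is unlikely to be inherited from their common ancestor; above
a length and identity threshold it is evidence of transfer. Detection is
restricted to genome pairs that differ at the genus rank or above: within a
genus, high identity is the expected vertical signal.

**Cluster / reciprocal-best-hit path (focal).** All genes are clustered
greedily at >= 95% identity with a 0.95 length-difference cut-off: genes are
processed in descending length (ties by lexicographic id) and join the first
cluster whose representative qualifies. Identity is 1 - Hamming/length for
equal lengths and 1 - editDistance/max(length) otherwise; with the 0.95
length cut-off the two definitions differ by a bounded amount and the
ungapped model keeps the partition reproducible against an all-pairs oracle
with the same tie rules. Within each multi-genome cluster, a cross-genus
gene pair is called an event when each gene is the other's highest-identity
match in the partner genome (reciprocity; ties by lexicographic id), with at
most one event per cluster and genome pair. Events on contigs shorter than
5000 bp are removed *after* calling, mirroring the order used with
assembled-genome data where short contigs carry unreliable context.

**Region path (sensitive).** Exact shared 31-mers seed ungapped extensions
in both directions, trimmed back to the maximum-scoring endpoints under an
X-drop of 20. Segments >= 500 bp at >= 95% identity are retained; per genome
pair, overlapping segments are resolved to the highest scorer (reported
score = matches - mismatches; ties broken by length, then coordinates) and
genes overlapping a retained segment by >= 1 bp become region events. Two
numerical choices matter here. First, extension uses an internal mismatch
penalty of 3: a +1/-1 walk ascends through *any* background above 50%
identity, so it would never terminate against the ~74% identity orthologous
background and would swallow true regions into rejected low-identity
extensions. With penalty 3 the walk descends below ~75% identity and the
X-drop fires; the reported score is still matches - mismatches. Second,
seeds landing inside an already-extended interval on the same diagonal are
skipped, which merges the hundreds of seeds a single match would otherwise
re-extend.

**Binning.** Events are binned by identity (>= 99% as recent transfer,
95-99% as older) and by divergence level -- the highest rank at which the
two taxonomies differ. Per-level event counts are normalized by the number
of genome pairs at that level, making rates comparable across levels.

# Co-occurrence

Presence is breadth of coverage >= 30% (inclusive); RPKM of absent genomes
is zeroed. Genomes present in fewer than 10 samples are excluded, as are
samples with no present genomes. For a genome pair with margins $k_a, k_b$
in $N$ samples and joint count $o$, the test is the upper tail
$P[X \ge o]$, $X \sim \mathrm{Hypergeometric}(N, k_a, k_b)$ (the observed
table included -- the standard exact convention; the spec-level choice is
recorded because the method name alone does not fix the tail). The effect
size is the ratio $o N / (k_a k_b)$; significance is Benjamini-Hochberg
q < 0.05 *and* ratio > 1, with one BH family per run. Two supporting
measures are provided: the simple overlap
$|S_a \cap S_b| / \min(|S_a|, |S_b|)$ (inflated for ubiquitous genomes,
which is why it is not the focal statistic) and the compositional
proportionality $\rho$ on centered-log-ratio profiles with a pseudocount of
1 RPKM unit. Which proportionality variant to use was an open choice; the
clr-based $\rho$ is the package default and the pseudocount is a parameter.

Size-fraction classification requires strictly more than 75% of a genome's
occupied samples in one fraction group *and* the highest median RPKM there;
unlabeled samples count in the denominator (conservative). Per-sample
feature prevalence is the fraction of present genomes carrying a feature;
matched small/large fraction samples are compared with two-sided paired
Wilcoxon signed-rank tests and a mean-ratio fold change.

# Pair-level association model

One row per cross-genus pair of prevalence-surviving genomes: response
`hgt` (>= 1 event), predictors `cooccur` (significance flag), patristic
distance, per-variable |difference of environmental medians| (medians over
each genome's occupied samples), and a size-fraction category with
"mixed or unclassified" as the reference level so the two remaining
coefficients are directly interpretable. Continuous predictors are
orderNorm-transformed: value of rank $r$ among $n$ maps to
$\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties, so one unit equals
one standard deviation. Note that a heavily tied column (patristic distance
under an ultrametric simulation takes one value per divergence level) has
compressed spread after the transform; this is a property of rank
transforms, not an error. The logit model is fitted by IRLS (deviance
tolerance 1e-8) with Wald standard errors, 95% CIs as estimate ± 1.96 SE,
AIC for model comparison, and generalized VIFs for collinearity.
Quasi-complete separation is detected from fitted probabilities within
1e-8 of 0/1 and flagged rather than hidden. Wald z p-values are used; the
source analysis did not state a test type, so the most common glm
convention was chosen.

`colliderSimulation()` demonstrates the interpretation hazard: with
distance and co-occurrence generated independently and HGT depending
positively on co-occurrence and negatively on distance, conditioning on HGT
makes the non-co-occurring stratum show markedly lower distances. The same
qualitative contrast in real data therefore does not imply a mechanistic
link between the two predictors.

# Functional enrichment

Clusters receive COG categories by majority rule over annotated members;
ties and annotation-free clusters stay unassigned, and the
eukaryote-specific categories A, B, Y, Z are excluded. Enrichment of HGT
involvement is tested per category with two-sided Fisher's exact tests over
the universe of COG-assigned clusters (cluster level, so multi-gene
clusters are not counted repeatedly), BH-corrected within each stratum
(overall, and per identity-bin x divergence-level). Mobile-genetic-element
flags are tested at the gene level (the flags derive from contig-level
annotation); folds are cross-product odds ratios ad/bc, with the
Haldane-Anscombe 0.5 correction applied and flagged when a margin is zero.

# Environmental random forest

Redundant covariates (|Spearman rho| >= 0.95 to a retained variable, greedy
in listed order) are dropped; variables are clustered by average linkage on
|1 - rho| -- kept exactly as written even though it maps anticorrelated
pairs to distance ~2, because that is the documented procedure. The
regression forest uses permutation importance and out-of-bag R^2; mtry
defaults to floor(sqrt(p)) (3 for 12 predictors). Importance significance
comes from refitting with the response shuffled and computing the
proportion of null importances at or above the observed one. The
function's default p-value adds one to numerator and denominator to avoid
zero p; the plain proportion is available via `plusOne = FALSE` and is what
the recovery analyses use, because with 12 variables and a few hundred
replicates the add-one floor times the BH factor can never clear q < 0.05
-- a resolution artifact, not evidence. Null forests may use fewer trees
than the observed fit; when *calibration* is being measured the two tree
counts are kept equal, since unequal counts change the null importance
variance and make the test conservative. Interpretation uses ICE curves
(per-sample prediction along a grid in one variable; their mean is the
partial dependence) and the Friedman-Popescu
$H^2 = \sum_i [PD_{jk}(x_i) - PD_j(x_i) - PD_k(x_i)]^2 / \sum_i PD_{jk}(x_i)^2$
with mean-centered partial dependence functions evaluated at the sample
points.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is validated.

**Taxonomy and tree.** A seven-rank taxonomy with fixed per-rank branching
produces an ultrametric species tree; the patristic distance between two
genomes is a constant per divergence level, strictly increasing from
species (0.12 substitutions/site) to domain (1.30). The species-level value
is chosen so that even congeneric orthologs fall below the 95% identity
threshold, giving the detector a calibrated vertical background: every
>= 95% cross-genus match on the fixture is a planted event.

**Genes.** Each of the (default) 100 single-copy families evolves down the
tree under per-branch substitution with probability 1 - exp(-rate b),
uniform over the three alternative bases, no indels, so identity is
1 - Hamming/length. The exact expected ortholog identity at path length d
follows from composing the per-branch transition matrices:
$1 - \tfrac{3}{4}(1 - e^{-4 r d/3})$ (the Jukes-Cantor form); at the
cross-genus minimum d = 0.30 this is ~0.75. Genes are laid head-to-tail on
1-5 contigs per genome; a contig's sequence is the concatenation of its
genes. Gene order is shuffled independently per genome -- gene order is not
conserved between distant prokaryotes, and a collinear layout would create
long ortholog-ortholog diagonals that no ungapped extension heuristic
should be expected to segment.

**Planted transfers.** Each event copies a donor family over the
recipient's own ortholog of that family (one >= 95% cross-genus pair per
event, nothing left behind). Recent events draw target identity from
U(0.995, 1) -- away from the 0.99 bin edge so binomial mutation noise does
not demote them -- and older events from U(0.955, 0.985); realized identity
(exact, since mutated sites always change base) is recorded. The default
28 recent / 12 older events put ~70% of events in the recent bin, the
regime reported for ocean genomes. Pair choice is biased toward
niche-sharing pairs (weight 8) and exponentially toward close pairs (decay
1.5/unit distance), planting the positive co-occurrence and negative
distance effects the regression should recover. Two negative controls are
planted: a perfect-copy event rehoused on a carved-out 4000 bp contig
(removable only by the contig filter) and a 400 bp perfect sub-gene region
(below the 500 bp segment minimum).

**Samples and environment.** 200 samples carry 12 oceanographic covariates
on plausible scales (depth, temperature, salinity, nitrate, oxygen,
chlorophyll-a, PAR, fCDOM, bbp470, latitude, longitude, potential density),
with moderate planted correlation structure (depth vs PAR strongly
negative) but nothing redundant at |rho| >= 0.95. Occupancy is logistic per
genome: niche groups share driver variables and slopes (planting
co-occurrence), genomes involved in planted HGT additionally respond to
chlorophyll-a (slope 2 on the standardized scale -- planting the
environment-to-prevalence link), and fraction specialists are penalized 4
logits outside their fraction (so they satisfy the >75% support rule).
Present genomes get breadth 0.3 + 0.7 Beta(2,2) and log-normal RPKM;
absent genomes get sub-threshold breadth.

**What the generator does not emulate.** Read-level noise, assembly
chimerism, indels, contamination between genomes, uneven genome sizes and
real taxonomic structure are all absent. Passing recovery tests on these
fixtures demonstrates that the statistical machinery is correct and
calibrated under its own assumptions -- not that the thresholds are optimal
for any particular real dataset.

# Problem sizes and seeds

The shipped study fixture uses 50 genomes x 100 genes x 1 kb, 40 planted
events and 200 samples, chosen so the whole validation chain (including an
all-pairs clustering of 5000 genes and per-pair segment scans) runs
comfortably on a laptop-class single core. Random-forest validation uses
n = 150 samples with 12 variables (one driver, R^2 ~ 0.5), 200 null
replicates at 100 trees for recovery and equal tree counts for
calibration; forest sizes are parameters, and the 10000-tree default of
`fitRf()` matches common practice for final analyses. Every stochastic
function takes an explicit seed; the fixture seeds are pinned, so all
shipped analyses are bit-reproducible.

# Known limitations

* The cluster path reproduces the *contract* of CD-HIT-style clustering
  (greedy, length-sorted, representative-based), not its exact heuristics;
  acceptance is defined against the all-pairs oracle with the same rules.
* The region path is an ungapped re-implementation of a BLASTn-style scan;
  gapped alignment is deliberately omitted because qualifying hits are
  >= 95% identical and indel-free in the generator's model.
* The paired-genome GLMM with a genome-ID random effect (duplicated-table
  design) is out of scope; only the fixed-effects logit is fitted.
* |1 - rho| distance and the strict ">75%" support rule are kept exactly as
  documented even where smoother alternatives exist.
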