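---
title: "Models and methods in pollenDrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pollenDrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenDrive)
```

pollenDrive implements the computational methods used to dissect a
toxin–antidote pollen gene drive: a multi-locus gamete simulator, a
single-pollen introgression mapper, ΔSNP-index bulked segregant analysis,
small-RNA hairpin locus classification, siRNA target scoring with degradome
support, and haplotype-based selection scans. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generators do and do not emulate. The package
is an interactive analysis library: the exported functions, this vignette
and `scripts/acceptance.R` are its interface.

## The genetic model

The system is a sporophytic-toxin / gametophytic-antidote drive. A diploid
plant carrying the toxin haplotype (a hairpin locus producing 22-nt
siRNAs, which requires a Dicer-competent genotype to be processed) poisons
all four products of meiosis before they separate. A haploid gamete then
survives with probability

$$s \;=\; \bigl(1 - T\,(1 - A)\bigr)\,(1 - b)$$

* `T ∈ {0, 1}` — sporophytic toxin exposure. `T = 1` iff the parent plant
  carries the toxin allele **and** at least one Dicer-competent allele
  (`Dcl2` or `dcl2T`). A `dcl2_mu1/dcl2_mu1` sporophyte makes no toxin.
* `A ∈ [0, 1]` — the gamete's own combined antidote efficacy: the maximum
  over *antidote groups* of the product of per-locus efficacies. The
  default (crisp) table has one group requiring the reduced-secondary-siRNA
  Dicer allele (`dcl2T` or `dcl2_mu1`, efficacy 1) together with the
  unlinked antidote `Tpd2` (efficacy 1), and a second group in which the
  amplifier-null `rgd1` rescues alone. An immune responder allele
  (target-site deletion) also counts as a full antidote, whereas a
  frameshift-null responder kills the gamete outright — the responder
  product itself is required for pollen function. All efficacies accept
  continuous overrides; a gamete allele missing from the table is an error,
  never a silent default.
* `b` — background abortion, applied independently to every class. Default
  0.0602, the wild-type baseline abortion rate; analytic checks use 0.

Crisp rules reproduce the system's headline numbers exactly: the
heterozygote's surviving fraction is $\tfrac14 (1-b)$ (only
`dcl2T ∧ Tpd2` gametes survive), the homozygote aborts only $b$, and an
`rgd1/+` heterozygote under toxin rescues exactly half its gametes.

**Recombination.** Loci live on a marker map of inter-locus recombination
fractions `r ∈ [0, 0.5]`; distances in cM convert via the Haldane function
`haldane_r()`. Analytic mode enumerates all classes over heterozygous loci
(≤ 12; the switch probability between consecutive heterozygous loci is the
probability of an odd number of crossovers across the intervening
intervals); simulation mode draws gametes by a Markov walk along the map.
Paracentric inversions are declared as intervals tagged by a haplotype
allele; when exactly one parental haplotype carries the tag, `r` is set to
0 between loci inside the interval (heterokaryotypic suppression), while
homokaryotypes recombine at map values.

**Transmission.** Female transmission passes the meiotic distribution
unchanged — the toxin does not act through the female germ line. Male
transmission keeps survivors, removes pollination-competition-excluded
classes and renormalizes. The default exclusion removes gametes whose
allele pair at the (`dcl2`, `Tpd1`) interval is non-parental; this models
the observed failure of surviving toxin-interval recombinants to appear in
progeny, for which two mechanisms (pollination competition, elevated
secondary siRNAs) are plausible but unquantified. The rule can be disabled
(`competition$enabled = FALSE`) or replaced by a continuous per-class
competition coefficient.

**Phenotype classes.** `simulate_cross()` classifies each progeny by the
viability rules applied to its own future pollen (with `b = 0`): *fertile*
when no toxin is produced or pollen viability is ≥ 0.9, *sterile* at
≤ 0.05, *semi-sterile* (the drive class) between. Under this classifier a
maternal recombinant that carries the toxin without the linked Dicer
antidote is sterile even when `Tpd2` is present, so the fertile :
semi-sterile ratio in maternal progeny slightly exceeds 2 : 1 at
`r = 0.187`; tabulating the four genotypic classes at the two unlinked
loci (as in the acceptance script) gives the exact 2 : 1 : 1 phenotypic
and 1 : 1 : 1 : 1 genotypic expectations.

**Default layout.** `tpd_model()` abstracts the mapped system: responder,
Dicer locus, toxin hairpin and the endosperm marker `Bt1` on chromosome 5
(with the 13-Mb inversion spanning the toxin and `Bt1`), `y1` and `Tpd2`
on chromosome 6 (r = 0.215 between them), the amplifier on chromosome 1.
The female-side `dcl2`–`Tpd1` recombination fraction defaults to 0.187;
the literature also quotes ~12% for the same interval, and the model
deliberately takes `r` as an input rather than resolving the discrepancy.

## Single-pollen introgression mapping

Haploid genotype calls at donor-diagnostic markers are encoded 1 (alt =
donor), −1 (ref), 0 (missing). Whole-genome-amplified single-cell data are
sparse, so missing entries are filled by **windowed consensus imputation**:
the `window_markers` (default 5) nearest non-missing calls of the same
grain on the same chromosome vote, and the entry becomes the sign of their
mean when `|mean| ≥ min_confidence` (default 0.6). Ties in neighbour
selection break toward smaller genomic distance, then lower position.
Observed calls are never altered; the imputer only fills zeros. This
replaces reference-panel imputation: no panel exists for synthetic data,
and the drive signal is megabase-scale, far coarser than imputation
resolution.

Mean marker signal is binned (100-kb default) and smoothed with a sliding
window (1 Mb window, 200-kb step). Aggregate donor-allele frequency per
marker is `n(+1)/(n(+1)+n(−1))` across grains, by default over observed
calls only (imputed entries are excluded to avoid circular smoothing).
Drive intervals are maximal runs of smoothed windows with frequency ≥ 0.95
spanning ≥ 1 Mb; the threshold is this package's operationalization of
"consistently observed in all surviving pollen" — no published threshold
exists — and both knobs are arguments.

## ΔSNP-index bulked segregant analysis

Pooled reads from phenotype-contrasted bulks give per-marker alternate
allele frequencies (`min_depth` filter, default 1). The per-bin
ΔSNP index is the mean frequency of the first (affected/sterile) pool
minus the second, so the toxin locus is positive; bins are 100 kb and the
sliding window mirrors the pollen pipeline (1 Mb / 200 kb — the window
geometry is not published for the BSA, only the bin size). Significance
uses a two-proportion z-test on summed per-bin read counts with a
pool-size-aware overdispersion inflation `1 + depth_bin / pool_size`:
reads within a bin resequence the same few pooled individuals, whose
genotypes are shared across linked markers, so binomial variance alone is
too small; the inflation is deliberately conservative. Benjamini–Hochberg
control across bins flags bins at `q ≤ 0.01`.

## Small-RNA clusters and hairpin loci

Alignments (interval tables with length, strand and collapsed count — not
raw BAM, which decouples the analysis from alignment tooling) merge into
clusters at `merge_gap` ≤ 75 bp. Clusters need CPM ≥ 5 in at least one
library and a *clear size bias*: the dominant 21/22/24-nt class must hold
≥ 50% of reads and ≥ 2× the runner-up (the published criterion is
qualitative; these two constants are this package's operationalization and
are arguments).

A hairpin locus is a cluster that is single-strand biased
(`strand_fraction ≥ 0.8`, computed per locus) **and** whose 5′ half
locally aligns to the reverse complement of its 3′ half with arm length
≥ `min_arm` and **pairing fraction** ≥ 0.6. The pairing fraction is a
dependency-free proxy for thermodynamic folding: aligned matches pair
fully and apparent G↔A / T↔C pairs (G:U wobbles in the folded RNA) count
half. For the long, near-perfect inverted repeats this classifier targets,
the proxy is monotone with folding stability; it is *not* a general RNA
structure predictor and will miss short, bulged, or multi-branch hairpins.

Differential accumulation uses an implemented replicate-aware count test:
log2 fold change on group-mean CPM with pseudocount 0.5; a two-sided exact
binomial test of the first group's summed counts against the library-size
expectation, with effective counts deflated by a moment-based dispersion
factor (replicate variance / Poisson expectation, floored at 1) when
replicates are over-dispersed. Calls require `|log2FC| ≥ 2` and BH
`q ≤ 0.01`. A group with a single library is allowed with a warning —
dispersion then cannot be estimated and the test is anti-conservative.

## siRNA target scoring and degradome support

Every ungapped window of the transcript is scored with the classic
expectation scheme: mismatch 1.0, G:U wobble 0.5, both doubled within the
seed (guide positions 2–13); sites with `E ≤ 5.0` are reported. All
constants are arguments because the upstream tool's exact parameter set is
not published. The guide pairs the site antiparallel — guide position *p*
pairs transcript coordinate `site_start + L − p` — and the cleavage
position is the base paired to guide position 10 (the 5′-monophosphate of
the 3′ cleavage fragment), reported 0-based. Cleavage mode requires
perfect pairing at guide positions 10 and 11; any mismatch, wobble or
bulge there predicts translational repression. Degradome (PARE) support
sums CPM-normalized 5′-end counts at the cleavage position ± 1 nt;
support is any signal > 0 by default. 5′-nucleotide AGO sorting follows
the plant rule set: 5′C → Ago5, 5′A → Ago2, 5′U → Ago1, 5′G unassigned.

## Selection scans

EHH around a core allele is the fraction of carrier pairs identical at
every site out to a distance, truncated below 0.05 (a flag). iHH
integrates EHH by trapezoid over positions (bp, or genetic positions via
linear map interpolation) in both directions; sites with < 2 carriers of
either allele, failing the MAF ≥ 0.05 filter, or whose EHH never decays
below the cutoff before the chromosome end are dropped — the standard
behaviour of haplotype-scan tools, whose default cut-offs these are.
`ln(iHH_A/iHH_D)` is standardized to mean 0, sd 1 within derived-allele
frequency bins (default 50 quantile bins, halved until every bin holds
≥ 2 sites), genome-wide across chromosomes. The EHH kernel and the
forward simulator are implemented in C++ (Rcpp), as is usual for this
class of tool; all randomness flows through R's RNG so `set.seed()`
governs everything.

The windowed statistic counts top-5% |iHS| sites per 10-kb window.
Windows are binned into 10 quantiles by SNP count and each window's
one-sided empirical p is `(r + 0.5)/(m + 1)` with `r` the number of
same-bin windows with a strictly greater count plus half the ties
(midrank). Because the statistic is an integer count, midrank p values
are heavily tied and *cannot* be uniform in the Kolmogorov–Smirnov sense;
`ties = "random"` breaks ties by randomized ranks (the standard
probability-integral-transform device), which is exactly rank-uniform
under the null and is what the calibration test uses. Bonferroni
adjustment across populations multiplies p by the number of populations,
capped at 1. Windowed F~ST~ uses the haploid-sample Weir–Cockerham ANOVA
estimator (phased data carry no heterozygosity term): per-site components
`a = (MSP − MSG)/n_c` and `b = MSG` summed within windows,
`θ = Σa / Σ(a+b)`; monomorphic windows are `NA`.

## Synthetic data: what it emulates, and what it does not

Each generator emits inputs *plus truth annotations*; recovery tests never
read the truth except in the harness. All generators are bitwise
reproducible under a fixed seed.

* **Marker panel / pollen genomes** — two 60-Mb chromosomes, marker
  density 10⁻⁴/bp, four introgression blocks (toxin and unlinked antidote
  blocks of 8 Mb, transmitted to all surviving pollen; two neutral donor
  blocks at 50% transmission). Pollen haplotypes come from the male
  gamete pipeline of a compact drive model; whole-genome-amplification
  noise is independent per-marker dropout (default 0.3) plus symmetric
  allele flips (default 0.01) — the simplest falsifiable noise model; real
  WGA artefacts are locally correlated and coverage-biased, which this
  does not emulate. Default 178 grains.
* **Bulk pools** — 400 maternal progeny, pools of 50 by phenotype, read
  depth 50 per marker, binomial reads around each pool's true allele
  frequency. Note the distinction between carrier fraction (1.0 for the
  toxin block in the sterile pool: every sterile plant is a heterozygous
  carrier) and allele frequency (0.5), which drives the read counts.
  A `null = TRUE` mode draws phenotype-blind pools for calibration.
* **Small RNA** — 25 hairpins (200-bp arms, 50-bp loops, 2% arm
  mutations, ≥ 90% 22-nt reads, 95% strand purity), 200 double-stranded
  siRNA loci without strand bias, 50 background loci below the CPM
  cut-off by construction; negative-binomial replicate counts (size 20 —
  moderate biological dispersion), 3 + 3 libraries, 16-fold induction of
  planted "up" loci.
* **Target system** — 20 random 500-nt transcripts, 22-nt guides with one
  planted perfectly complementary site each; translational-mode sites get
  a central mismatch opposite guide position 10; cleavage-mode sites get a
  degradome peak at the base paired to guide position 10; one transcript
  carries an immune allele with a 27-bp in-frame deletion removing a
  site's seed pairing.
* **Population genetics** — a haploid forward Wright–Fisher population
  (120 haplotypes) over 10 scaled chromosomes of 4 Mb (the maize
  karyotype at desk scale), mutation 3 and recombination 0.2 per
  chromosome per haplotype per generation, 700 generations from a
  monomorphic start (past 4–6 N, near mutation–drift equilibrium at
  scaled θ). This is deliberately a forward model, not a coalescent:
  desk-scale, dependency-free, and adequate for scan recovery tests,
  though its diversity and LD scales are compressed relative to real
  maize data. The optional sweep plants a selected allele on one founder
  haplotype on chromosome 5, raises it to frequency 0.7, and runs a
  drift-free selective phase (default 10 generations, mutation 0.4): each
  haplotype slot persists and recombines with a random partner, accepted
  only if it keeps its sweep-site allele. Selection thereby pins the
  frequency while recombination moves random backgrounds on and off the
  swept haplotype (hitchhiking with escape), and the absence of lineage
  copying avoids spurious clonal EHH structure that a drifting
  generation-by-generation phase would create in a 120-haplotype
  population. The phase is run at a reduced mutation rate because a rapid
  sweep is brief on the mutational timescale.

## Problem sizes

The test suite and acceptance script use the sizes above: 10,000 gametes
for viability fractions, 4,000 progeny for segregation ratios, 178 pollen
grains for interval recovery, 50 phenotype-blind BSA replicates for
calibration, 1,000 random guide/transcript pairs for the scorer oracle,
and ~3,200 10-kb windows (≈ 36,000 segregating sites) per selection-scan
genome. These are the package's chosen desk-scale study conditions.

## Known limitations

* The drive model treats antidote efficacy as a per-allele constant; it
  does not model siRNA dose–response, partial rescue kinetics, or
  multi-generation population trajectories of drive spread.
* The sterile class is modelled as shedding no viable toxin-exposed,
  antidote-less pollen; a residual-viability override exists on the
  efficacy table but defaults to zero.
* The hairpin classifier's pairing proxy does not fold RNA; bulged or
  branched hairpins below ~60% pairing are missed by design.
* The windowed empirical-p construction is rank-based within SNP-count
  bins; with integer counts, tied windows share p values, and calling a
  specific window "the" top hit is granular at low SNP counts.
* The forward simulator's scaled parameters compress time; estimates of
  absolute sweep age or strength are not meaningful, only the relative
  window ranking is.
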