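# pollenDrive

Tools for studying **gametophytic gene drive by toxin–antidote systems in
plant pollen**, modelled on the maize × teosinte *mexicana* hybrid system in
which a hairpin-derived 22-nt siRNA toxin, produced sporophytically from the
*Tpd1* haplotype, silences an essential pollen lipase (*Tdr1*) and aborts
every pollen grain that does not itself carry antidote alleles (the linked
hypomorphic Dicer allele *dcl2^T* together with the unlinked *Tpd2*, or an
amplifier-null such as *rgd1*, or an immune responder allele).

The package covers the full computational arc of such a study:

| stage | functions |
|---|---|
| genetic model & simulation | `tpd_model()`, `make_gametes()`, `apply_viability()`, `transmit()`, `simulate_cross()`, `marker_transmission()` |
| single-pollen introgression mapping | `read_vcf_calls()`, `encode_matrix()`, `impute_matrix()`, `bin_signal()`, `smooth_track()`, `aggregate_frequency()`, `call_drive_intervals()` |
| ΔSNP-index bulked segregant analysis | `pool_frequencies()`, `delta_snp_index()`, `bsa_significance()`, `bsa_intervals()` |
| small-RNA loci & hairpins | `call_clusters()`, `classify_hairpins()`, `differential_clusters()`, `annotate_cluster_targets()` |
| siRNA target scoring & degradome | `score_sites()`, `ago_sort()`, `call_mode()`, `ipare_support()`, `evaluate_allele()` |
| selection scans | `compute_ehh()`, `compute_ihs()`, `window_ihs_stat()`, `weighted_fst()`, `adjust_populations()` |
| synthetic data | `synth_config()`, `gen_pollen_vcf()`, `gen_bulk_pools()`, `gen_srna_readset()`, `gen_target_system()`, `gen_popgen_haplotypes()` |

Every analysis stage has a matching synthetic-data generator that emits the
inputs *plus ground-truth annotations*, so the whole pipeline is testable
offline with no external data.

## The model

A gamete class with meiotic frequency *p* survives with probability

```
s = (1 − T · (1 − A)) · (1 − b)
```

where `T ∈ {0,1}` is the **sporophytic** toxin exposure (the diploid parent
carries the toxin haplotype and a Dicer-competent allele, so all four
meiotic products are exposed), `A ∈ [0,1]` is the **gametophytic** combined
antidote efficacy of the gamete's own alleles (maximum over antidote groups;
within a group per-locus efficacies multiply), and `b` is a background
abortion rate. Male transmission additionally removes
pollination-competition-excluded classes (by default, toxin-interval
recombinants among survivors) and renormalizes; female transmission passes
all meiotic products. Recombination follows a marker map of recombination
fractions (or cM via `haldane_r()`), with suppression inside paracentric
inversions when the sporophyte is heterokaryotypic.

## Worked example

```r
library(pollenDrive)

model <- tpd_model()              # b = 0.0602, r(dcl2–Tpd1) = 0.187
het   <- tpd_heterozygote(model)  # Tpd1–dcl2T/tpd1; Tpd2/tpd2

# pollen abortion of the drive heterozygote
v <- apply_viability(make_gametes(het, model, n = 10000, seed = 1), het, model)
100 * (1 - attr(v, "viable_fraction"))
#> [1] 76.01

# everything that transmits through pollen carries the full drive haplotype
transmit(apply_viability(make_gametes(het, model), het, model),
         het, model, "male")[, c("dcl2", "Tpd1", "Tpd2", "prob")]
#>    dcl2 Tpd1 Tpd2 prob
#> 1 dcl2T Tpd1 Tpd2    1

# recover the drive intervals from 178 noisy single-pollen genomes
cfg <- synth_config(n_pollen = 178, dropout = 0.3, error = 0.01)
set.seed(11)
pv  <- gen_pollen_vcf(cfg)
mm  <- impute_matrix(as_marker_matrix(pv$calls, pv$markers))
trk <- frequency_track(aggregate_frequency(mm), chrom_lengths = cfg$chrom_lengths)
call_drive_intervals(trk)
#>   chrom   start      end mean_freq
#> 1  chr5 1.6e+07 24000000 0.9903324
#> 2  chr6 1.6e+07 24000000 0.9898439
```

The 76% aborted pollen, the all-or-nothing male transmission of the
`dcl2T–Tpd1 + Tpd2` haplotype, and the two recovered intervals (the planted
toxin and antidote introgression blocks) are the genetic signature of the
drive.

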