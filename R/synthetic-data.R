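## Synthetic data generators: every input the pipeline consumes, with the
## statistical structure the analyses assume, so all stages are testable
## offline. Truth annotations are emitted alongside every dataset.

#' Configuration for the synthetic data generators
#'
#' Defaults mirror the study conditions where printed (178 pollen grains,
#' 100-kb bins); the compact two-chromosome genome keeps desk-scale runs
#' fast.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param marker_density markers per bp of the donor-diagnostic panel.
#' @param blocks data.frame of truth introgression blocks: `chrom`, `start`,
#'   `end`, `tag_locus` (model locus whose gamete allele determines donor
#'   status of the whole block), `donor_allele`, `driven` (logical).
#' @param dropout whole-genome-amplification dropout rate `d` (call set to
#'   missing).
#' @param error genotyping error rate `e` (call sign flipped).
#' @param n_pollen number of surviving pollen grains to genotype.
#' @param n_progeny maternal progeny population size behind the bulk pools.
#' @param pool_size individuals per phenotype pool.
#' @param pool_depth sequencing depth per marker per pool.
#' @param srna small-RNA plan; see [gen_srna_readset()].
#' @param targets target-system plan; see [gen_target_system()].
#' @param popgen population-genetics plan; see [gen_popgen_haplotypes()].
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(chrom_lengths = c(chr5 = 60e6, chr6 = 60e6),
                         marker_density = 1e-4,
                         blocks = default_truth_blocks(),
                         dropout = 0.3, error = 0.01,
                         n_pollen = 178,
                         n_progeny = 400, pool_size = 50, pool_depth = 50,
                         srna = list(n_hairpin = 25, n_sirna = 200,
                                     n_background = 50, n_up_sirna = 0,
                                     arm_len = 200, loop_len = 50,
                                     locus_len = 300, n_rep = 3,
                                     lib_size = 1e6, hairpin_cpm = 200,
                                     sirna_cpm = 50, background_cpm = 2,
                                     up_fold = 16, strand_purity = 0.95,
                                     size_purity = 0.9, nb_size = 20,
                                     arm_mut = 0.02),
                         targets = list(n_tx = 20, tx_len = 500,
                                        n_guide = 12, guide_len = 22,
                                        peak_cpm = 100),
                         popgen = list(n_hap = 120, n_chrom = 10,
                                       chrom_len = 4e6, mu = 3,
                                       recomb = 0.2, generations = 700,
                                       sweep = FALSE, sweep_chrom = 5,
                                       sweep_pos = 2.005e6,
                                       sweep_freq = 0.7,
                                       sweep_founders = 1,
                                       post_sweep_gens = 10,
                                       sweep_mu = 0.4)) {
  stopifnot(dropout >= 0, dropout <= 1, error >= 0, error <= 1,
            n_pollen > 0, marker_density > 0)
  structure(list(chrom_lengths = chrom_lengths,
                 marker_density = marker_density, blocks = blocks,
                 dropout = dropout, error = error, n_pollen = n_pollen,
                 n_progeny = n_progeny, pool_size = pool_size,
                 pool_depth = pool_depth, srna = srna, targets = targets,
                 popgen = popgen),
            class = "synth_config")
}

#' Default truth introgression blocks for the compact synthetic genome
#' @return data.frame of blocks (see [synth_config()]).
#' @export
default_truth_blocks <- function() {
  data.frame(
    chrom = c("chr5", "chr6", "chr5", "chr6"),
    start = c(16e6, 16e6, 40e6, 40e6),
    end = c(24e6, 24e6, 48e6, 48e6),
    tag_locus = c("Tpd1", "Tpd2", "nb1", "nb2"),
    donor_allele = c("Tpd1", "Tpd2", "mex", "mex"),
    driven = c(TRUE, TRUE, FALSE, FALSE))
}

#' Compact drive model matching the synthetic genome
#'
#' Same rules as [tpd_model()] but laid out on the two synthetic
#' chromosomes, with two neutral introgression tag loci (`nb1`, `nb2`)
#' unlinked to the drive loci.
#'
#' @param b background abortion rate.
#' @return a `"drive_model"`.
#' @export
tpd_synth_model <- function(b = 0.0602) {
  loci <- rbind(
    locus_def("dcl2", "chr5", 6e6, "antidote_primary",
              c("Dcl2", "dcl2T", "dcl2_mu1")),
    locus_def("Tpd1", "chr5", 20e6, "toxin", c("tpd1", "Tpd1")),
    locus_def("nb1", "chr5", 44e6, "marker", c("w22", "mex")),
    locus_def("Tpd2", "chr6", 20e6, "antidote_unlinked", c("tpd2", "Tpd2")),
    locus_def("nb2", "chr6", 44e6, "marker", c("w22", "mex")))
  r <- c("dcl2:Tpd1" = 0.187, "Tpd1:nb1" = 0.5, "Tpd2:nb2" = 0.5)
  rules <- viability_rules(b = b, responder = NULL)
  drive_model(loci, r, rules = rules)
}

#' The drive parent used by the synthetic generators
#'
#' Heterozygous for the donor haplotype: `Tpd1-dcl2T` linked, `Tpd2`
#' unlinked, plus donor alleles at the neutral blocks.
#'
#' @param model a `"drive_model"` from [tpd_synth_model()].
#' @return a `"diploid"`.
#' @export
tpd_synth_parent <- function(model = tpd_synth_model()) {
  diploid(haplotype(model, Tpd1 = "Tpd1", dcl2 = "dcl2T", Tpd2 = "Tpd2",
                    nb1 = "mex", nb2 = "mex"),
          haplotype(model))
}

#' Generate a donor-diagnostic marker panel with truth blocks
#'
#' Markers are placed uniformly; only markers inside declared donor blocks
#' carry the alternate allele on the donor haplotype (the panel is
#' donor-diagnostic, so outside-block markers are reference on both
#' haplotypes).
#'
#' @param config a `"synth_config"`.
#' @param seed optional RNG seed.
#' @return list with `markers` ([marker_panel()] table, plus `block` index
#'   column: NA outside blocks) and `blocks` (the truth table).
#' @export
gen_marker_panel <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bl <- config$blocks
  for (ch in unique(bl$chrom)) {
    b <- bl[bl$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping truth blocks on ", ch)
    }
  }
  if (sum(config$chrom_lengths) * config$marker_density < 10) {
    stop("marker density too low for genome size")
  }
  pieces <- lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    n <- round(L * config$marker_density)
    pos <- sort(unique(ceiling(stats::runif(n) * (L - 1))))
    data.frame(chrom = ch, pos = pos)
  })
  mk <- do.call(rbind, pieces)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(mk), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  markers <- marker_panel(mk$chrom, mk$pos, ref, alt)
  markers$block <- NA_integer_
  for (k in seq_len(nrow(bl))) {
    hit <- markers$chrom == bl$chrom[k] & markers$pos > bl$start[k] &
      markers$pos <= bl$end[k]
    markers$block[hit] <- k
  }
  list(markers = markers, blocks = bl)
}

#' Generate single-pollen genotype calls shaped by the drive
#'
#' Pollen haplotypes are drawn from the male-transmitted gamete
#' distribution of the drive model (survivors only); each marker call is
#' then masked to missing at the dropout rate and sign-flipped at the error
#' rate, emulating whole-genome-amplification artefacts.
#'
#' @param config a `"synth_config"`.
#' @param model a `"drive_model"` (default [tpd_synth_model()]).
#' @param parent the pollen parent (default [tpd_synth_parent()]).
#' @param vcf_path optional path; when given, observed calls are written as
#'   a haploid VCF.
#' @param seed optional RNG seed.
#' @return list with `markers`, `blocks`, `truth` (markers x pollen matrix
#'   of 1/-1), `calls` (observed matrix with 0 = missing), `gametes`
#'   (per-pollen allele table at the model loci) and `vcf_path`.
#' @export
gen_pollen_vcf <- function(config, model = tpd_synth_model(),
                           parent = tpd_synth_parent(model),
                           vcf_path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- gen_marker_panel(config)
  markers <- panel$markers
  bl <- panel$blocks
  n <- config$n_pollen
  tg <- transmit(apply_viability(make_gametes(parent, model), parent, model),
                 parent, model, "male")
  cls <- sample.int(nrow(tg), n, replace = TRUE, prob = tg$prob)
  gametes <- tg[cls, model$loci$name, drop = FALSE]
  rownames(gametes) <- NULL
  truth <- matrix(-1L, nrow(markers), n)
  for (k in seq_len(nrow(bl))) {
    rows <- which(!is.na(markers$block) & markers$block == k)
    if (!length(rows)) next
    donor <- gametes[[bl$tag_locus[k]]] == bl$donor_allele[k]
    truth[rows, donor] <- 1L
  }
  calls <- truth
  flip <- matrix(stats::runif(length(calls)) < config$error, nrow(calls))
  calls[flip] <- -calls[flip]
  drop <- matrix(stats::runif(length(calls)) < config$dropout, nrow(calls))
  calls[drop] <- 0L
  colnames(truth) <- colnames(calls) <- sprintf("pollen_%03d", seq_len(n))
  if (!is.null(vcf_path)) write_vcf_haploid(calls, markers, vcf_path)
  list(markers = markers, blocks = bl, truth = truth, calls = calls,
       gametes = gametes, vcf_path = vcf_path)
}

#' Generate fertile/sterile bulk pool read counts
#'
#' Maternal progeny are simulated from the drive cross and pooled by
#' phenotype (sterile pool: toxin without the unlinked antidote; fertile
#' pool: no toxin). Read counts at every panel marker are binomial at the
#' configured depth around each pool's true alternate-allele frequency.
#' With `null = TRUE` both pools are random draws from the same progeny
#' population (no linked sterility), for calibration.
#'
#' @param config a `"synth_config"`.
#' @param model a `"drive_model"`.
#' @param parent the drive mother (default [tpd_synth_parent()]).
#' @param null generate phenotype-blind pools (default FALSE).
#' @param seed optional RNG seed.
#' @return list with `counts` (long PoolCounts table: `marker`, `chrom`,
#'   `pos`, `pool`, `ref`, `alt`), `truth` (per-marker true allele and
#'   carrier frequencies per pool), `markers`, `blocks`.
#' @export
gen_bulk_pools <- function(config, model = tpd_synth_model(),
                           parent = tpd_synth_parent(model),
                           null = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- gen_marker_panel(config)
  markers <- panel$markers
  bl <- panel$blocks
  if (config$pool_size < 10) stop("pool sizes must be >= 10")
  cross <- simulate_cross(parent, wild_type(model), model,
                          n_progeny = config$n_progeny)
  if (null) {
    idx <- sample.int(nrow(cross), 2 * config$pool_size)
    pools <- list(sterile = cross[idx[seq_len(config$pool_size)], ],
                  fertile = cross[idx[-seq_len(config$pool_size)], ])
  } else {
    st <- cross[cross$phenotype == "sterile", ]
    fe <- cross[cross$phenotype == "fertile", ]
    if (nrow(st) < config$pool_size || nrow(fe) < config$pool_size) {
      stop("n_progeny too small for requested pool_size")
    }
    pools <- list(sterile = st[seq_len(config$pool_size), ],
                  fertile = fe[seq_len(config$pool_size), ])
  }
  freq_at <- function(pool, k) {
    tl <- bl$tag_locus[k]; da <- bl$donor_allele[k]
    dose <- (pool[[paste0(tl, "_mat")]] == da) +
      (pool[[paste0(tl, "_pat")]] == da)
    c(allele = mean(dose) / 2, carrier = mean(dose > 0))
  }
  out <- list(); truth <- list()
  for (pn in names(pools)) {
    p_alt <- rep(0, nrow(markers))
    carrier <- rep(0, nrow(markers))
    for (k in seq_len(nrow(bl))) {
      rows <- which(!is.na(markers$block) & markers$block == k)
      if (!length(rows)) next
      f <- freq_at(pools[[pn]], k)
      p_alt[rows] <- f[["allele"]]
      carrier[rows] <- f[["carrier"]]
    }
    alt <- stats::rbinom(nrow(markers), config$pool_depth, p_alt)
    out[[pn]] <- data.frame(marker = markers$id, chrom = markers$chrom,
                            pos = markers$pos, pool = pn,
                            ref = config$pool_depth - alt, alt = alt)
    truth[[pn]] <- data.frame(marker = markers$id, pool = pn,
                              allele_freq = p_alt, carrier_freq = carrier)
  }
  list(counts = do.call(rbind, c(out, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       markers = markers, blocks = bl)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x) {
    paste(rev(strsplit(x, "")[[1]]), collapse = "")
  }, character(1)))
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                        b), 1), character(1))
  paste(ch, collapse = "")
}

#' Generate a synthetic small-RNA read set with planted hairpin loci
#'
#' Builds a genome in which hairpin loci are true inverted repeats
#' (arm + loop + reverse-complemented arm, with a small arm mutation rate),
#' plus double-stranded siRNA loci without strand bias and weakly expressed
#' background loci that fail the CPM cut-off by construction. Per-library
#' read counts are negative-binomial; hairpin reads are mostly 22 nt and
#' strand-pure, and hairpin loci (plus any extra "up" siRNA loci) are
#' up-regulated in the `TPD` group.
#'
#' @param config a `"synth_config"` (see the `srna` element).
#' @param seed optional RNG seed.
#' @return list with `alignments` (interval table: `chrom`, `start`, `end`,
#'   `strand`, `length`, `count`, `sample`), `lib_sizes` (named vector),
#'   `groups` (sample -> group), `genome` (named sequence vector),
#'   `truth` (locus table with `type`, `up`, arm coordinates for hairpins).
#' @export
gen_srna_readset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- config$srna
  if (sc$arm_len * 2 + sc$loop_len > sc$locus_len + 2 * sc$arm_len) {
    # loci are sized from their parts; guard nonsensical plans
  }
  if (sc$arm_len <= 0 || sc$loop_len < 0) stop("invalid hairpin plan")
  n_loci <- sc$n_hairpin + sc$n_sirna + sc$n_up_sirna + sc$n_background
  gap <- 500
  seqs <- character(n_loci)
  type <- character(n_loci)
  up <- logical(n_loci)
  arm5 <- arm3 <- rep(NA_real_, n_loci)
  lens <- numeric(n_loci)
  i <- 0
  for (k in seq_len(sc$n_hairpin)) {
    i <- i + 1
    arm <- .random_dna(sc$arm_len)
    loop <- .random_dna(sc$loop_len)
    arm2 <- .mutate_seq(.revcomp(arm), sc$arm_mut)
    seqs[i] <- paste0(arm, loop, arm2)
    type[i] <- "hairpin"; up[i] <- TRUE
    lens[i] <- nchar(seqs[i])
    arm5[i] <- sc$arm_len; arm3[i] <- sc$arm_len
  }
  for (k in seq_len(sc$n_sirna + sc$n_up_sirna)) {
    i <- i + 1
    seqs[i] <- .random_dna(sc$locus_len)
    type[i] <- "sirna"; up[i] <- k > sc$n_sirna
    lens[i] <- sc$locus_len
  }
  for (k in seq_len(sc$n_background)) {
    i <- i + 1
    seqs[i] <- .random_dna(sc$locus_len)
    type[i] <- "background"
    lens[i] <- sc$locus_len
  }
  starts <- cumsum(c(gap, head(lens + gap, -1)))
  genome <- paste0(
    paste(vapply(seq_len(n_loci), function(j) {
      paste0(seqs[j], .random_dna(gap))
    }, character(1)), collapse = ""))
  genome <- paste0(.random_dna(gap), genome)
  genome <- c(srna1 = genome)
  truth <- data.frame(chrom = "srna1", start = starts,
                      end = starts + lens, type = type, up = up)
  truth$arm5_start <- ifelse(type == "hairpin", starts, NA)
  truth$arm5_end <- ifelse(type == "hairpin", starts + arm5, NA)
  truth$arm3_start <- ifelse(type == "hairpin", starts + lens - arm3, NA)
  truth$arm3_end <- ifelse(type == "hairpin", starts + lens, NA)

  samples <- c(paste0("TPD_", seq_len(sc$n_rep)),
               paste0("WT_", seq_len(sc$n_rep)))
  groups <- stats::setNames(rep(c("TPD", "WT"), each = sc$n_rep), samples)
  base_cpm <- ifelse(type == "hairpin", sc$hairpin_cpm / sc$up_fold,
                     ifelse(type == "sirna", sc$sirna_cpm, sc$background_cpm))
  aligns <- list()
  for (s in samples) {
    mult <- ifelse(up & groups[[s]] == "TPD", sc$up_fold, 1)
    mu <- base_cpm * mult * sc$lib_size / 1e6
    tot <- stats::rnbinom(n_loci, mu = mu, size = sc$nb_size)
    ## background loci fail the CPM cut-off by construction
    cap <- ceiling(5 * sc$lib_size / 1e6) - 1
    tot[type == "background"] <- pmin(tot[type == "background"], cap)
    for (j in which(tot > 0)) {
      n_frag <- min(tot[j], 8L)   # collapse reads into a few weighted rows
      cnt <- stats::rmultinom(1, tot[j], rep(1, n_frag))[, 1]
      cnt <- cnt[cnt > 0]
      size_cl <- if (type[j] == "hairpin") {
        ifelse(stats::runif(length(cnt)) < sc$size_purity, 22,
               sample(c(21, 24), length(cnt), replace = TRUE))
      } else if (type[j] == "sirna") {
        ifelse(stats::runif(length(cnt)) < sc$size_purity, 24,
               sample(c(21, 22), length(cnt), replace = TRUE))
      } else {
        sample(c(21, 22, 24), length(cnt), replace = TRUE)
      }
      strand <- if (type[j] == "hairpin") {
        ifelse(stats::runif(length(cnt)) < sc$strand_purity, "+", "-")
      } else {
        sample(c("+", "-"), length(cnt), replace = TRUE)
      }
      st <- truth$start[j] +
        floor(stats::runif(length(cnt)) * (lens[j] - size_cl))
      aligns[[length(aligns) + 1]] <-
        data.frame(chrom = "srna1", start = st, end = st + size_cl,
                   strand = strand, length = size_cl, count = cnt,
                   sample = s)
    }
  }
  alignments <- do.call(rbind, c(aligns, make.row.names = FALSE))
  list(alignments = alignments,
       lib_sizes = stats::setNames(rep(sc$lib_size, length(samples)),
                                   samples),
       groups = groups, genome = genome, truth = truth)
}

#' Generate a transcript/guide/degradome target system
#'
#' Plants one perfectly (cleavage mode) or centrally mismatched
#' (translational mode) complementary site per guide in a random transcript.
#' Cleavage-mode sites receive a degradome 5'-end peak at the position
#' paired to guide nucleotide 10 (the 5' end of the 3' cleavage fragment);
#' translational-mode sites receive none. One transcript additionally gets
#' an "immune" allele carrying a 27-bp in-frame deletion that removes a
#' planted site's seed-pairing region.
#'
#' @param config a `"synth_config"` (see the `targets` element).
#' @param seed optional RNG seed.
#' @return list with `transcripts` (named sequences), `guides` (table with
#'   `id`, `seq`), `degradome` (per-position 5'-end counts: `transcript`,
#'   `pos`, `count`), `immune` (list with `transcript`, `ref_seq`,
#'   `alt_seq`, `deleted`), `truth` (guide -> transcript/site/mode).
#' @export
gen_target_system <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tc <- config$targets
  if (tc$n_guide < 1) stop("need at least one siRNA guide")
  if (tc$guide_len < 19) stop("siRNA guides must be >= 19 nt")
  tx <- stats::setNames(vapply(seq_len(tc$n_tx), function(i) {
    .random_dna(tc$tx_len)
  }, character(1)), sprintf("tx%02d", seq_len(tc$n_tx)))
  L <- tc$guide_len
  truth <- data.frame(guide = sprintf("sir%02d", seq_len(tc$n_guide)),
                      transcript = sample(names(tx), tc$n_guide,
                                          replace = TRUE),
                      site_start = NA_real_,
                      mode = rep_len(c("cleavage", "translational"),
                                     tc$n_guide))
  guides <- character(tc$n_guide)
  deg <- list()
  for (i in seq_len(tc$n_guide)) {
    t_id <- truth$transcript[i]
    s <- 30 + (i - 1) * 35   # staggered, non-overlapping even on shared tx
    site <- substr(tx[[t_id]], s + 1, s + L)
    guide <- .revcomp(site)  # perfect complement of the site
    if (truth$mode[i] == "translational") {
      ## mismatch opposite guide position 10: target index s + L - 10 (0-based)
      p <- s + L - 10 + 1
      old <- substr(tx[[t_id]], p, p)
      comp <- chartr("ACGT", "TGCA", substr(guide, 10, 10))
      repl <- setdiff(c("A", "C", "G", "T"), c(old, comp,
                                               chartr("ACGT", "GTAC", comp)))
      substr(tx[[t_id]], p, p) <- repl[1]
    } else {
      deg[[length(deg) + 1]] <- data.frame(transcript = t_id,
                                           pos = s + L - 10,
                                           count = tc$peak_cpm)
    }
    guides[i] <- guide
    truth$site_start[i] <- s
  }
  ## zero-count anchors make the track cover every transcript
  deg[[length(deg) + 1]] <- data.frame(transcript = names(tx), pos = 0,
                                       count = 0)
  degradome <- do.call(rbind, c(deg, make.row.names = FALSE))
  ## immune allele: delete 27 bp spanning the seed pairing of the first
  ## cleavage-mode site (seed = guide positions 2-13, i.e. the 3' part of
  ## the target site)
  ci <- which(truth$mode == "cleavage")[1]
  t_id <- truth$transcript[ci]
  s <- truth$site_start[ci]
  del_start <- s + L - 13   # covers targets paired to guide pos 2..13 + spill
  ref_seq <- tx[[t_id]]
  alt_seq <- paste0(substr(ref_seq, 1, del_start),
                    substr(ref_seq, del_start + 28, nchar(ref_seq)))
  list(transcripts = tx,
       guides = data.frame(id = truth$guide, seq = guides),
       degradome = degradome,
       immune = list(transcript = t_id, ref_seq = ref_seq, alt_seq = alt_seq,
                     deleted = c(del_start, del_start + 27)),
       truth = truth)
}

#' Generate phased genome-wide haplotypes by forward Wright-Fisher
#' simulation
#'
#' A minimal haploid Wright-Fisher population simulated independently per
#' chromosome (chromosomes assort freely), with uniform mutation placement
#' and Poisson crossovers, run for a fixed number of generations.
#' Optionally a recent partial sweep is superimposed on one chromosome:
#' the selected allele is planted on a founder haplotype and raised to the
#' configured frequency, then a drift-free selective phase recombines
#' random backgrounds on and off the swept haplotype while selection pins
#' the allele frequency (hitchhiking with escape by recombination). The
#' derived allele (1) is the mutant state; ancestral is 0.
#'
#' @param config a `"synth_config"` (see the `popgen` element: `n_chrom`
#'   chromosomes of `chrom_len` bp; `mu` and `recomb` are per chromosome
#'   per haplotype per generation).
#' @param seed optional RNG seed.
#' @return list with `haplotypes` (haplotype x site 0/1 matrix over all
#'   chromosomes), `chrom` (chromosome name per site), `positions` (bp
#'   within chromosome), `sweep` (`NULL`, or list with `chrom`, `pos` and
#'   the truth 10-kb window).
#' @export
gen_popgen_haplotypes <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pg <- config$popgen
  if (pg$n_hap %% 2 != 0) stop("haplotype count must be even")
  if (isTRUE(pg$sweep) && (pg$sweep_freq <= 0 || pg$sweep_freq >= 1)) {
    stop("sweep frequency must lie in (0, 1)")
  }
  chroms <- sprintf("chr%02d", seq_len(pg$n_chrom))
  Hs <- vector("list", pg$n_chrom)
  poss <- vector("list", pg$n_chrom)
  sweep <- NULL
  for (k in seq_len(pg$n_chrom)) {
    res <- wf_sim_cpp(pg$n_hap, pg$chrom_len, pg$mu, pg$recomb,
                      pg$generations)
    H <- res$haplotypes
    pos <- res$positions
    if (isTRUE(pg$sweep) && k == pg$sweep_chrom) {
      n_car <- round(pg$sweep_freq * pg$n_hap)
      founders <- sample.int(pg$n_hap, pg$sweep_founders)
      carriers <- c(founders,
                    sample(setdiff(seq_len(pg$n_hap), founders),
                           n_car - length(founders)))
      src <- rep_len(founders, n_car)
      H[carriers, ] <- H[src, , drop = FALSE]
      ins <- findInterval(pg$sweep_pos, pos)
      newcol <- integer(pg$n_hap); newcol[carriers] <- 1L
      H <- cbind(H[, seq_len(ins), drop = FALSE], newcol,
                 H[, setdiff(seq_len(ncol(H)), seq_len(ins)),
                   drop = FALSE])
      pos <- append(pos, pg$sweep_pos, after = ins)
      if (pg$post_sweep_gens > 0) {
        ## the selective phase runs at a reduced mutation rate: a rapid
        ## sweep is brief on the mutational timescale
        res2 <- wf_sweep_cpp(H, pos, pg$chrom_len, pg$sweep_mu, pg$recomb,
                             pg$post_sweep_gens, pg$sweep_pos)
        H <- res2$haplotypes; pos <- res2$positions
      }
      w0 <- floor(pg$sweep_pos / 1e4) * 1e4
      sweep <- list(chrom = chroms[k], pos = pg$sweep_pos,
                    window = c(w0, w0 + 1e4))
    }
    Hs[[k]] <- H
    poss[[k]] <- pos
  }
  H <- do.call(cbind, Hs)
  dimnames(H) <- list(sprintf("hap%03d", seq_len(nrow(H))), NULL)
  list(haplotypes = H,
       chrom = rep(chroms, vapply(poss, length, integer(1))),
       positions = unlist(poss), sweep = sweep)
}
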