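## Small-RNA locus analysis: de novo cluster calling with CPM and size-bias
## filters, strand-bias and inverted-repeat (hairpin) classification,
## replicate-aware differential accumulation, and feature annotation.

#' Call small-RNA clusters from alignment intervals
#'
#' Alignments closer than `merge_gap` are merged into clusters (across all
#' samples). Clusters must reach `min_cpm` in at least one sample, and must
#' show a clear size bias: the dominant read length class (21/22/24 nt)
#' must hold at least half the reads and at least twice the runner-up;
#' otherwise the cluster is discarded.
#'
#' @param alignments interval table: `chrom`, `start`, `end`, `strand`,
#'   `length`, `count`, `sample`.
#' @param lib_sizes named vector of total mapped reads per sample (for
#'   CPM).
#' @param merge_gap maximum gap to merge alignments (default 75 bp).
#' @param min_cpm minimum CPM in any sample (default 5).
#' @param min_frac,min_ratio dominant size-class rules (defaults 0.5, 2).
#' @return data.frame of clusters: interval, per-size-class counts
#'   (`n21`, `n22`, `n24`, `n_other`), `plus`, `minus`, `strand_fraction`,
#'   `dominant_size`, per-sample CPM columns (`cpm_<sample>`), `max_cpm`,
#'   `type` (`"siRNA"` here; see [classify_hairpins()]), and `status`
#'   (`retained`/`discarded_cpm`/`discarded_size`); plus attribute
#'   `unclustered_count` (always 0: clustering partitions the input).
#' @export
call_clusters <- function(alignments, lib_sizes, merge_gap = 75,
                          min_cpm = 5, min_frac = 0.5, min_ratio = 2) {
  if (any(lib_sizes <= 0)) stop("zero-depth library")
  missing_ls <- setdiff(unique(alignments$sample), names(lib_sizes))
  if (length(missing_ls)) stop("no library size for sample(s): ",
                               paste(missing_ls, collapse = ", "))
  gr <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(alignments$start + 1,
                                                alignments$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1,
                               ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  cl <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  n_cl <- length(red)
  cnt <- alignments$count
  sizec <- ifelse(alignments$length %in% c(21, 22, 24),
                  as.character(alignments$length), "other")
  agg <- function(sel) {
    out <- rep(0, n_cl)
    if (any(sel)) {
      a <- rowsum(cnt[sel], cl[sel])
      out[as.integer(rownames(a))] <- a[, 1]
    }
    out
  }
  res <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red))
  res$n21 <- agg(sizec == "21")
  res$n22 <- agg(sizec == "22")
  res$n24 <- agg(sizec == "24")
  res$n_other <- agg(sizec == "other")
  res$plus <- agg(alignments$strand == "+")
  res$minus <- agg(alignments$strand == "-")
  total <- res$plus + res$minus
  res$strand_fraction <- pmax(res$plus, res$minus) / total
  samples <- names(lib_sizes)
  percell <- matrix(0, n_cl, length(samples),
                    dimnames = list(NULL, samples))
  for (s in samples) {
    a <- agg(alignments$sample == s)
    percell[, s] <- a / lib_sizes[[s]] * 1e6
    res[[paste0("count_", s)]] <- a
  }
  for (s in samples) res[[paste0("cpm_", s)]] <- percell[, s]
  res$max_cpm <- apply(percell, 1, max)
  sz <- as.matrix(res[, c("n21", "n22", "n24")])
  top <- apply(sz, 1, max)
  second <- apply(sz, 1, function(x) sort(x, decreasing = TRUE)[2])
  dom <- c(21, 22, 24)[apply(sz, 1, which.max)]
  clear <- top >= min_frac * total & top >= min_ratio * pmax(second, 1e-9) &
    total > 0
  res$dominant_size <- ifelse(clear, dom, NA)
  res$status <- ifelse(res$max_cpm < min_cpm, "discarded_cpm",
                       ifelse(!clear, "discarded_size", "retained"))
  res$type <- ifelse(res$status == "retained", "siRNA", "discarded")
  attr(res, "unclustered_count") <- 0
  attr(res, "lib_sizes") <- lib_sizes
  res
}

## pairing fraction between a 5' arm and the reverse complement of a 3'
## arm from a local alignment: matches pair fully; G:T apparent mismatches
## correspond to G:U wobbles in the folded RNA and count half
.pair_fraction <- function(al) {
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  match <- p == s & p != "-"
  wobble <- (p == "G" & s == "A") | (p == "T" & s == "C")
  (sum(match) + 0.5 * sum(wobble)) / length(p)
}

#' Identify hairpin (inverted-repeat) loci among clusters
#'
#' A retained cluster is called a hairpin when (1) its reads are
#' single-strand biased (`strand_fraction >= min_strand_fraction`) and (2)
#' a local alignment of the locus 5' half against the reverse complement
#' of its 3' half yields an arm of at least `min_arm` bp whose implied
#' base-pairing fraction (G:U wobble counting half) reaches `min_pairing`.
#'
#' @param clusters table from [call_clusters()].
#' @param genome named character vector of chromosome sequences.
#' @param min_strand_fraction default 0.8.
#' @param min_pairing default 0.6.
#' @param min_arm minimum aligned arm length in bp (default 50).
#' @param min_cpm minimum expression for hairpin reporting (default 5).
#' @param flank bp of sequence context added on each side (default 0).
#' @return data.frame of hairpin loci: cluster interval, `arm5_start`,
#'   `arm5_end`, `arm3_start`, `arm3_end`, `loop_start`, `loop_end`,
#'   `arm_len`, `identity`, `pairing_fraction`, `strand_fraction`.
#' @export
classify_hairpins <- function(clusters, genome, min_strand_fraction = 0.8,
                              min_pairing = 0.6, min_arm = 50, min_cpm = 5,
                              flank = 0) {
  cand <- which(clusters$status == "retained" &
                  !is.na(clusters$strand_fraction) &
                  clusters$strand_fraction >= min_strand_fraction &
                  clusters$max_cpm >= min_cpm)
  out <- list()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1.5)
  for (i in cand) {
    ch <- clusters$chrom[i]
    if (!ch %in% names(genome)) {
      warning("no sequence for ", ch, "; cluster skipped")
      next
    }
    s0 <- max(clusters$start[i] - flank, 0)
    e0 <- min(clusters$end[i] + flank, nchar(genome[[ch]]))
    seq <- substr(genome[[ch]], s0 + 1, e0)
    L <- nchar(seq)
    if (L < 2 * min_arm) next
    half <- floor(L / 2)
    s5 <- substr(seq, 1, half)
    s3rc <- .revcomp(substr(seq, L - half + 1, L))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s5), Biostrings::DNAString(s3rc),
      type = "local", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1)
    arm_len <- Biostrings::nchar(Biostrings::alignedPattern(al))
    if (arm_len < min_arm) next
    pf <- .pair_fraction(al)
    if (pf < min_pairing) next
    ## arm coordinates on the genome (0-based half-open)
    p_rng <- al@pattern@range
    s_rng <- al@subject@range
    arm5 <- c(s0 + BiocGenerics::start(p_rng) - 1,
              s0 + BiocGenerics::end(p_rng))
    ## subject was reverse-complemented: flip back onto the 3' half
    arm3 <- c(e0 - BiocGenerics::end(s_rng), e0 - BiocGenerics::start(s_rng) + 1)
    ident <- Biostrings::pid(al) / 100
    out[[length(out) + 1]] <- data.frame(
      cluster = i, chrom = ch,
      start = clusters$start[i], end = clusters$end[i],
      arm5_start = arm5[1], arm5_end = arm5[2],
      arm3_start = arm3[1], arm3_end = arm3[2],
      loop_start = arm5[2], loop_end = arm3[1],
      arm_len = arm_len, identity = ident, pairing_fraction = pf,
      strand_fraction = clusters$strand_fraction[i])
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      arm5_start = numeric(), arm5_end = numeric(),
                      arm3_start = numeric(), arm3_end = numeric(),
                      loop_start = numeric(), loop_end = numeric(),
                      arm_len = numeric(), identity = numeric(),
                      pairing_fraction = numeric(),
                      strand_fraction = numeric()))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Differential small-RNA accumulation between two groups
#'
#' log2 fold change is computed on group-mean CPM with a pseudocount; the
#' p value comes from a two-sided exact binomial test of the group-1 total
#' against the expectation from summed library sizes, with a moment-based
#' overdispersion correction: when the replicate variance of per-sample
#' counts exceeds the multinomial expectation, effective counts are
#' deflated by the estimated dispersion factor before testing. Calls
#' require both `|log2FC| >= min_lfc` and BH `q <= max_q`.
#'
#' @param clusters table from [call_clusters()] (uses the
#'   `count_<sample>` columns of retained clusters).
#' @param groups named character vector sample -> group (two groups).
#' @param lib_sizes named library sizes (defaults to the attribute stored
#'   by [call_clusters()]).
#' @param min_lfc minimum |log2FC| (default 2).
#' @param max_q FDR threshold (default 0.01).
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data.frame: cluster interval, `cpm_<group>` means, `log2fc`,
#'   `p`, `q`, `call` (`up`/`down`/`ns`; up = higher in the first group).
#' @export
differential_clusters <- function(clusters, groups,
                                  lib_sizes = attr(clusters, "lib_sizes"),
                                  min_lfc = 2, max_q = 0.01,
                                  pseudocount = 0.5) {
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups are required")
  for (g in gl) {
    if (!any(groups == g)) stop("group with zero libraries: ", g)
    if (sum(groups == g) < 2) {
      warning("group ", g, " has a single library; ",
              "dispersion cannot be estimated from replicates")
    }
  }
  keep <- clusters$status == "retained"
  idx <- which(keep)
  s1 <- names(groups)[groups == gl[1]]
  s2 <- names(groups)[groups == gl[2]]
  C1 <- as.matrix(clusters[idx, paste0("count_", s1), drop = FALSE])
  C2 <- as.matrix(clusters[idx, paste0("count_", s2), drop = FALSE])
  L1 <- sum(lib_sizes[s1]); L2 <- sum(lib_sizes[s2])
  cpm1 <- rowMeans(t(t(C1) / lib_sizes[s1]) * 1e6)
  cpm2 <- rowMeans(t(t(C2) / lib_sizes[s2]) * 1e6)
  log2fc <- log2((cpm1 + pseudocount) / (cpm2 + pseudocount))
  x1 <- rowSums(C1); x2 <- rowSums(C2)
  ## moment-based overdispersion: ratio of replicate variance of counts to
  ## the Poisson expectation, pooled across both groups (>= 1)
  phi <- vapply(seq_along(idx), function(i) {
    v <- c(if (ncol(C1) > 1) stats::var(C1[i, ]) / max(mean(C1[i, ]), 1),
           if (ncol(C2) > 1) stats::var(C2[i, ]) / max(mean(C2[i, ]), 1))
    if (!length(v)) 1 else max(1, mean(v, na.rm = TRUE))
  }, numeric(1))
  p <- vapply(seq_along(idx), function(i) {
    n_eff <- round((x1[i] + x2[i]) / phi[i])
    if (n_eff == 0) return(1)
    k_eff <- round(x1[i] / phi[i])
    stats::binom.test(min(k_eff, n_eff), n_eff,
                      p = L1 / (L1 + L2))$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  call <- ifelse(q <= max_q & log2fc >= min_lfc, "up",
                 ifelse(q <= max_q & log2fc <= -min_lfc, "down", "ns"))
  data.frame(cluster = idx, chrom = clusters$chrom[idx],
             start = clusters$start[idx], end = clusters$end[idx],
             cpm_1 = cpm1, cpm_2 = cpm2, log2fc = log2fc, p = p, q = q,
             call = call)
}

#' Annotate clusters with overlapping genomic features
#'
#' Each cluster gets the class of the feature with maximal overlap (ties
#' break toward the longer feature, then the first by coordinate);
#' clusters overlapping nothing are `intergenic`. The summary reports both
#' cluster-count and read-weighted fractions per class, and the
#' read-weighted fraction falling in hairpin loci when given.
#'
#' @param clusters table from [call_clusters()] (retained rows are
#'   annotated).
#' @param features interval table from [read_gff3_features()] (needs
#'   `classification`).
#' @param hairpins optional hairpin table from [classify_hairpins()].
#' @return list with `clusters` (annotated with `feature_class`) and
#'   `summary` (per class: `n`, `frac`, `read_frac`; plus a
#'   `hairpin` row when `hairpins` is given).
#' @export
annotate_cluster_targets <- function(clusters, features, hairpins = NULL) {
  idx <- which(clusters$status == "retained")
  cl <- clusters[idx, , drop = FALSE]
  cl_gr <- GenomicRanges::GRanges(cl$chrom,
                                  IRanges::IRanges(cl$start + 1, cl$end))
  cls <- rep("intergenic", nrow(cl))
  if (nrow(features)) {
    ft_gr <- GenomicRanges::GRanges(features$chrom,
                                    IRanges::IRanges(features$start + 1,
                                                     features$end))
    ov <- GenomicRanges::findOverlaps(cl_gr, ft_gr)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(cl_gr[qh], ft_gr[sh]))
      flen <- features$end[sh] - features$start[sh]
      ord <- order(qh, -w, -flen, features$start[sh], features$chrom[sh])
      first <- !duplicated(qh[ord])
      cls[qh[ord][first]] <- features$classification[sh[ord][first]]
    }
  }
  cl$feature_class <- cls
  reads <- cl$plus + cl$minus
  summary <- do.call(rbind, lapply(split(seq_len(nrow(cl)), cls),
                                   function(ii) {
    data.frame(class = cls[ii[1]], n = length(ii),
               frac = length(ii) / nrow(cl),
               read_frac = sum(reads[ii]) / sum(reads))
  }))
  rownames(summary) <- NULL
  if (!is.null(hairpins) && nrow(hairpins)) {
    hp_gr <- GenomicRanges::GRanges(hairpins$chrom,
                                    IRanges::IRanges(hairpins$start + 1,
                                                     hairpins$end))
    in_hp <- IRanges::overlapsAny(cl_gr, hp_gr)
    summary <- rbind(summary,
                     data.frame(class = "hairpin", n = sum(in_hp),
                                frac = mean(in_hp),
                                read_frac = sum(reads[in_hp]) / sum(reads)))
  }
  list(clusters = cl, summary = summary)
}
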