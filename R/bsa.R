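## Delta-SNP-index bulked segregant analysis: contrast pooled allele
## frequencies between two phenotype bulks in 100-kb bins with
## sliding-window smoothing, then flag bins by a two-proportion test with
## Benjamini-Hochberg control.

#' Per-marker alternate-allele frequencies for two pools
#'
#' @param counts long PoolCounts table: `marker`, `chrom`, `pos`, `pool`,
#'   `ref`, `alt` (exactly two pool names).
#' @param min_depth markers below this total depth in either pool are
#'   excluded (default 1).
#' @return wide data.frame: `marker`, `chrom`, `pos`, then per pool
#'   `<pool>_ref`, `<pool>_alt`, `<pool>_freq`.
#' @export
pool_frequencies <- function(counts, min_depth = 1) {
  pools <- unique(counts$pool)
  if (length(pools) != 2) stop("exactly two pools are required")
  sp <- split(counts, counts$pool)
  common <- Reduce(intersect, lapply(sp, function(x) x$marker))
  if (length(common) == 0) stop("no markers shared between pools")
  out <- NULL
  for (pn in pools) {
    x <- sp[[pn]]
    x <- x[match(common, x$marker), , drop = FALSE]
    depth <- x$ref + x$alt
    freq <- ifelse(depth > 0, x$alt / depth, NA_real_)
    cols <- stats::setNames(data.frame(x$ref, x$alt, freq),
                            paste0(pn, c("_ref", "_alt", "_freq")))
    if (is.null(out)) {
      out <- cbind(data.frame(marker = x$marker, chrom = x$chrom,
                              pos = x$pos), cols)
    } else out <- cbind(out, cols)
  }
  depth_ok <- (out[[paste0(pools[1], "_ref")]] +
                 out[[paste0(pools[1], "_alt")]] >= min_depth) &
    (out[[paste0(pools[2], "_ref")]] + out[[paste0(pools[2], "_alt")]] >=
       min_depth)
  out <- out[depth_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  out
}

#' Delta SNP index in bins with sliding-window smoothing
#'
#' Per-bin delta = mean alt-allele frequency of the first pool minus the
#' second (sign convention: pass the sterile/affected pool first so the
#' toxin locus is positive). Bin counts are also summed for the
#' significance test.
#'
#' @param freqs table from [pool_frequencies()].
#' @param pools character vector of length 2: (positive pool, negative
#'   pool); defaults to the order seen in `freqs`.
#' @param bin_width bin size in bp (default 100 kb).
#' @param window,step sliding-window smoothing of delta (defaults 1 Mb /
#'   200 kb); `NULL` window skips smoothing.
#' @param chrom_lengths optional named chromosome lengths.
#' @return list with `bins` (per-bin delta, per-pool mean frequencies and
#'   summed ref/alt counts, `n_markers`) and `windows` (smoothed delta
#'   track, `NULL` when smoothing is skipped).
#' @export
delta_snp_index <- function(freqs, pools = attr(freqs, "pools"),
                            bin_width = 1e5, window = 1e6, step = 2e5,
                            chrom_lengths = NULL) {
  stopifnot(length(pools) == 2)
  f1 <- freqs[[paste0(pools[1], "_freq")]]
  f2 <- freqs[[paste0(pools[2], "_freq")]]
  b1 <- .bin_values(freqs$chrom, freqs$pos, f1, bin_width, chrom_lengths)
  b2 <- .bin_values(freqs$chrom, freqs$pos, f2, bin_width, chrom_lengths)
  bins <- data.frame(chrom = b1$chrom, start = b1$start, end = b1$end,
                     n_markers = b1$n_markers)
  bins[[paste0(pools[1], "_freq")]] <- b1$value
  bins[[paste0(pools[2], "_freq")]] <- b2$value
  bins$delta <- b1$value - b2$value
  for (pn in pools) {
    for (al in c("ref", "alt")) {
      cnt <- .bin_values(freqs$chrom, freqs$pos,
                         freqs[[paste0(pn, "_", al)]], bin_width,
                         chrom_lengths)
      bins[[paste0(pn, "_", al)]] <-
        ifelse(is.na(cnt$value), 0, cnt$value * cnt$n_markers)
    }
  }
  windows <- if (!is.null(window)) {
    tr <- bins[, c("chrom", "start", "end")]
    tr$value <- bins$delta
    smooth_track(tr, window, step)
  }
  list(bins = bins, windows = windows, pools = pools)
}

#' Significance of per-bin delta SNP index
#'
#' Two-proportion z-test on the summed per-bin read counts of the two
#' pools, with a pool-size-aware overdispersion inflation of the variance
#' (factor `1 + depth_bin / pool_size`, where `depth_bin` is the summed bin
#' depth): reads within a bin resequence the same few pooled individuals,
#' so the binomial variance alone is too small. P values are two-sided;
#' q values are Benjamini-Hochberg over all testable bins and bins with
#' `q <= max_q` are flagged.
#'
#' @param delta result of [delta_snp_index()].
#' @param pool_size individuals per pool (sets the overdispersion
#'   inflation).
#' @param max_q FDR threshold for flagging (default 0.01).
#' @return the `bins` table with `p`, `q` and `flagged` columns.
#' @export
bsa_significance <- function(delta, pool_size, max_q = 0.01) {
  bins <- delta$bins
  pools <- delta$pools
  a1 <- bins[[paste0(pools[1], "_alt")]]
  n1 <- a1 + bins[[paste0(pools[1], "_ref")]]
  a2 <- bins[[paste0(pools[2], "_alt")]]
  n2 <- a2 + bins[[paste0(pools[2], "_ref")]]
  p <- rep(NA_real_, nrow(bins))
  testable <- n1 > 0 & n2 > 0
  pbar <- (a1 + a2) / (n1 + n2)
  infl <- 1 + (n1 + n2) / (2 * pool_size)
  se2 <- pbar * (1 - pbar) * (1 / n1 + 1 / n2) * infl
  z <- (a1 / n1 - a2 / n2) / sqrt(se2)
  ok <- testable & se2 > 0
  p[ok] <- 2 * stats::pnorm(-abs(z[ok]))
  p[testable & se2 == 0] <- 1   # monomorphic in both pools
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  bins$p <- p
  bins$q <- q
  bins$flagged <- !is.na(q) & q <= max_q
  bins
}

#' Flagged BSA intervals as BED
#'
#' Merges adjacent flagged bins of consistent delta sign.
#'
#' @param bins table from [bsa_significance()].
#' @return data.frame `chrom`, `start`, `end`, `sign`, `mean_delta`.
#' @export
bsa_intervals <- function(bins) {
  hit <- bins[bins$flagged, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sign = numeric(),
                      mean_delta = numeric()))
  }
  sgn <- sign(hit$delta)
  gr <- GenomicRanges::GRanges(paste0(hit$chrom, ":", sgn),
                               IRanges::IRanges(hit$start + 1, hit$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  md <- tapply(hit$delta[S4Vectors::queryHits(ov)],
               S4Vectors::subjectHits(ov), mean)
  nm <- strsplit(as.character(GenomicRanges::seqnames(red)), ":")
  data.frame(chrom = vapply(nm, `[`, "", 1),
             start = GenomicRanges::start(red) - 1,
             end = GenomicRanges::end(red),
             sign = as.numeric(vapply(nm, `[`, "", 2)),
             mean_delta = as.numeric(md))
}
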