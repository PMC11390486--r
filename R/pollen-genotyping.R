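## Single-pollen genotyping: sparse marker matrix encoding, windowed
## consensus imputation, binned/smoothed introgression tracks, aggregate
## allele frequency and drive-interval calling.

#' Encode genotype calls as a sparse marker matrix
#'
#' Entries are 1 (alt allele), -1 (ref allele), 0 (missing). Rows are
#' markers sorted by (chrom, pos), columns are samples. Heterozygous calls
#' are not meaningful for haploid pollen and are rejected.
#'
#' @param calls table from [read_vcf_calls()] (columns `sample`, `marker`,
#'   `chrom`, `pos`, `call`).
#' @return object of class `"marker_matrix"`: list with `calls` (integer
#'   matrix), `markers` (chrom/pos table).
#' @export
encode_matrix <- function(calls) {
  key <- paste(calls$sample, calls$marker)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (sample, marker) call(s): ",
         paste(utils::head(dup, 5), collapse = "; "))
  }
  if (any(calls$call == "het")) {
    stop("heterozygous calls cannot be encoded for haploid pollen")
  }
  mk <- unique(calls[, c("marker", "chrom", "pos")])
  mk <- mk[order(mk$chrom, mk$pos), , drop = FALSE]
  rownames(mk) <- NULL
  samples <- sort(unique(calls$sample))
  M <- matrix(0L, nrow(mk), length(samples),
              dimnames = list(mk$marker, samples))
  code <- c(ref = -1L, alt = 1L, missing = 0L)
  M[cbind(match(calls$marker, mk$marker), match(calls$sample, samples))] <-
    code[calls$call]
  structure(list(calls = M, markers = mk), class = "marker_matrix")
}

#' Build a marker matrix directly from a call matrix
#'
#' @param M integer matrix coded 1/-1/0, rows in (chrom, pos) order.
#' @param markers marker table with `chrom`, `pos` (and optionally `id`).
#' @return a `"marker_matrix"`.
#' @export
as_marker_matrix <- function(M, markers) {
  stopifnot(nrow(M) == nrow(markers), all(M %in% c(-1L, 0L, 1L)))
  if (is.null(colnames(M))) colnames(M) <- paste0("S", seq_len(ncol(M)))
  ord <- order(markers$chrom, markers$pos)
  mk <- markers[ord, , drop = FALSE]
  rownames(mk) <- NULL
  structure(list(calls = M[ord, , drop = FALSE],
                 markers = data.frame(marker = mk$id %||% rownames(mk),
                                      chrom = mk$chrom, pos = mk$pos)),
            class = "marker_matrix")
}

#' Decode a marker matrix back to a call table
#'
#' Inverse of [encode_matrix()].
#'
#' @param mm a `"marker_matrix"`.
#' @return data.frame with `sample`, `marker`, `chrom`, `pos`, `call`.
#' @export
decode_matrix <- function(mm) {
  M <- mm$calls
  idx <- expand.grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
  lab <- c(`-1` = "ref", `0` = "missing", `1` = "alt")
  data.frame(sample = colnames(M)[idx$col],
             marker = mm$markers$marker[idx$row],
             chrom = mm$markers$chrom[idx$row],
             pos = mm$markers$pos[idx$row],
             call = unname(lab[as.character(M[as.matrix(idx)])]))
}

#' Windowed-consensus imputation of missing calls
#'
#' Each missing entry is replaced by the sign of the mean of the
#' `window_markers` nearest non-missing entries of the same sample on the
#' same chromosome, provided the absolute mean reaches `min_confidence`;
#' otherwise it stays missing. Observed calls are never altered. Ties in
#' nearest-neighbour selection break toward the smaller genomic distance,
#' then the lower position.
#'
#' @param mm a `"marker_matrix"`.
#' @param window_markers odd neighbour count >= 3 (default 5).
#' @param min_confidence minimum |mean| of the neighbourhood (default 0.6).
#' @return a `"marker_matrix"` with extra elements `confidence` (per-entry
#'   |mean| for entries that were missing) and `was_imputed` (logical
#'   matrix).
#' @export
impute_matrix <- function(mm, window_markers = 5, min_confidence = 0.6) {
  if (window_markers < 3 || window_markers %% 2 == 0) {
    stop("window_markers must be odd and >= 3")
  }
  chrom_id <- as.integer(factor(mm$markers$chrom,
                                levels = unique(mm$markers$chrom)))
  res <- impute_consensus_cpp(mm$calls, chrom_id, mm$markers$pos,
                              as.integer(window_markers), min_confidence)
  out <- mm
  dimnames(res$imputed) <- dimnames(mm$calls)
  out$calls <- res$imputed
  out$confidence <- res$confidence
  out$was_imputed <- mm$calls == 0L & res$imputed != 0L
  out
}

## mean of non-missing values per (chrom) bin; generic helper shared by the
## pollen and BSA tracks
.bin_values <- function(chrom, pos, value, bin_width, chrom_lengths = NULL) {
  chroms <- if (is.null(chrom_lengths)) unique(chrom) else names(chrom_lengths)
  pieces <- lapply(chroms, function(ch) {
    sel <- chrom == ch & !is.na(value)
    L <- if (is.null(chrom_lengths)) max(pos[chrom == ch], 0) else
      chrom_lengths[[ch]]
    n_bin <- max(ceiling(L / bin_width), 1)
    starts <- (seq_len(n_bin) - 1) * bin_width
    b <- pmin(floor((pos[sel] - 1) / bin_width) + 1, n_bin)
    v <- rep(NA_real_, n_bin)
    n <- integer(n_bin)
    if (any(sel)) {
      agg <- rowsum(value[sel], b)
      cnt <- rowsum(rep(1, sum(sel)), b)
      i <- as.integer(rownames(agg))
      v[i] <- agg[, 1] / cnt[, 1]
      n[i] <- cnt[, 1]
    }
    data.frame(chrom = ch, start = starts, end = starts + bin_width,
               value = v, n_markers = n)
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Mean marker signal in genomic bins
#'
#' Bin value is the mean of the non-missing (non-zero) matrix entries in
#' the bin: per sample when `sample` is given, across all samples
#' otherwise. Bins with no informative markers are `NA`.
#'
#' @param mm a `"marker_matrix"`.
#' @param bin_width bin size in bp (default 100 kb).
#' @param sample optional sample name (default: aggregate over all).
#' @param chrom_lengths optional named lengths to fix the bin grid.
#' @return bin track data.frame: `chrom`, `start`, `end`, `value`,
#'   `n_markers`.
#' @export
bin_signal <- function(mm, bin_width = 1e5, sample = NULL,
                       chrom_lengths = NULL) {
  stopifnot(bin_width > 0)
  M <- mm$calls
  if (!is.null(sample)) M <- M[, sample, drop = FALSE]
  s <- rowSums(M)               # zeros contribute nothing to the sum
  n_obs <- rowSums(M != 0L)
  chrom <- mm$markers$chrom; pos <- mm$markers$pos
  chroms <- if (is.null(chrom_lengths)) unique(chrom) else
    names(chrom_lengths)
  pieces <- lapply(chroms, function(ch) {
    sel <- chrom == ch
    L <- if (is.null(chrom_lengths)) max(pos[sel], 0) else
      chrom_lengths[[ch]]
    n_bin <- max(ceiling(L / bin_width), 1)
    starts <- (seq_len(n_bin) - 1) * bin_width
    b <- pmin(floor((pos[sel] - 1) / bin_width) + 1, n_bin)
    sums <- cnts <- rep(0, n_bin)
    if (any(sel)) {
      agg <- rowsum(cbind(s[sel], n_obs[sel]), b)
      i <- as.integer(rownames(agg))
      sums[i] <- agg[, 1]; cnts[i] <- agg[, 2]
    }
    data.frame(chrom = ch, start = starts, end = starts + bin_width,
               value = ifelse(cnts > 0, sums / cnts, NA_real_),
               n_markers = cnts)
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Sliding-window smoothing of a bin track
#'
#' Window value is the unweighted mean of the non-missing bin values whose
#' bins overlap the window; windows with no data are `NA`.
#'
#' @param track bin track from [bin_signal()] (or any data.frame with
#'   `chrom`, `start`, `end`, `value`).
#' @param window window width in bp (default 1 Mb; must be >= bin width).
#' @param step step in bp (default 200 kb; must be <= window).
#' @return window track data.frame: `chrom`, `start`, `end`, `value`,
#'   `n_bins`.
#' @export
smooth_track <- function(track, window = 1e6, step = 2e5) {
  bw <- track$end[1] - track$start[1]
  if (window < bw) stop("window must be at least the bin width")
  if (step > window) stop("step must not exceed window")
  pieces <- lapply(unique(track$chrom), function(ch) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    L <- max(tr$end)
    starts <- seq(0, max(L - window, 0), by = step)
    mid <- (tr$start + tr$end) / 2
    val <- vapply(starts, function(s) {
      sel <- tr$end > s & tr$start < s + window & !is.na(tr$value)
      if (!any(sel)) NA_real_ else mean(tr$value[sel])
    }, numeric(1))
    nb <- vapply(starts, function(s) {
      sum(tr$end > s & tr$start < s + window & !is.na(tr$value))
    }, numeric(1))
    data.frame(chrom = ch, start = starts, end = starts + window,
               value = val, n_bins = nb)
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Aggregate donor-allele frequency across pollen grains
#'
#' Per-marker frequency of the alternate (donor) allele over all samples:
#' `n(+1) / (n(+1) + n(-1))`. By default imputed entries are ignored so
#' smoothing is not circular.
#'
#' @param mm a `"marker_matrix"` (possibly imputed).
#' @param use_imputed include imputed entries (default FALSE).
#' @return data.frame `marker`, `chrom`, `pos`, `n_alt`, `n_ref`, `freq`
#'   (NA for markers with no calls).
#' @export
aggregate_frequency <- function(mm, use_imputed = FALSE) {
  if (ncol(mm$calls) < 1) stop("need at least one sample")
  M <- mm$calls
  if (!use_imputed && !is.null(mm$was_imputed)) M[mm$was_imputed] <- 0L
  n_alt <- rowSums(M == 1L)
  n_ref <- rowSums(M == -1L)
  freq <- ifelse(n_alt + n_ref > 0, n_alt / (n_alt + n_ref), NA_real_)
  data.frame(marker = mm$markers$marker, chrom = mm$markers$chrom,
             pos = mm$markers$pos, n_alt = n_alt, n_ref = n_ref,
             freq = freq)
}

#' Bin and smooth an aggregate frequency table
#'
#' Convenience wrapper: per-marker frequencies -> 100-kb bins -> sliding
#' window.
#'
#' @param freqs table from [aggregate_frequency()].
#' @param bin_width,window,step track geometry (defaults 100 kb / 1 Mb /
#'   200 kb).
#' @param chrom_lengths optional named chromosome lengths.
#' @return smoothed window track.
#' @export
frequency_track <- function(freqs, bin_width = 1e5, window = 1e6,
                            step = 2e5, chrom_lengths = NULL) {
  bins <- .bin_values(freqs$chrom, freqs$pos, freqs$freq, bin_width,
                      chrom_lengths)
  smooth_track(bins, window, step)
}

#' Call drive intervals from a smoothed frequency track
#'
#' Maximal runs of overlapping windows whose value reaches `threshold`,
#' reported when the merged span reaches `min_span`.
#'
#' @param track window track of donor-allele frequency.
#' @param threshold minimum window frequency (default 0.95).
#' @param min_span minimum interval span in bp (default 1 Mb).
#' @return BED-like data.frame `chrom`, `start`, `end`, `mean_freq`.
#' @export
call_drive_intervals <- function(track, threshold = 0.95, min_span = 1e6) {
  hit <- track[!is.na(track$value) & track$value >= threshold, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_freq = numeric()))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    hit$chrom, IRanges::IRanges(hit$start + 1, hit$end)))
  ov <- GenomicRanges::findOverlaps(GenomicRanges::GRanges(
    hit$chrom, IRanges::IRanges(hit$start + 1, hit$end)), gr)
  mean_freq <- tapply(hit$value[S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov), mean)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    mean_freq = as.numeric(mean_freq))
  out <- out[out$end - out$start >= min_span, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard overlap between two interval sets
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return intersection length / union length.
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(a$start + 1, a$end)))
  gb <- GenomicRanges::reduce(GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start + 1, b$end)))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}
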