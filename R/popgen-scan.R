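## Haplotype-based selection scan: EHH decay, integrated haplotype scores
## standardized within derived-allele-frequency bins, a windowed
## extreme-|iHS| statistic with SNP-count quantile binning and empirical
## p values, Bonferroni adjustment across populations, and Weir-Cockerham
## FST in windows (haploid-sample formulation for phased data).

#' Extended haplotype homozygosity around a core allele
#'
#' `EHH(x)` is the fraction of carrier pairs that are identical at every
#' site between the core and `x`. The curve starts at 1 at the core, is
#' non-increasing outward, and is truncated once it falls below `cutoff`
#' (or at the chromosome end).
#'
#' @param haps haplotype x site 0/1 matrix.
#' @param positions site positions in bp (or genetic-map units).
#' @param core core site index (1-based column).
#' @param allele core allele (0 or 1).
#' @param cutoff truncation threshold (default 0.05).
#' @return data.frame `site`, `pos`, `direction` (-1/0/+1), `ehh`; `NULL`
#'   when the allele has fewer than 2 carriers.
#' @export
compute_ehh <- function(haps, positions, core, allele, cutoff = 0.05) {
  car <- which(haps[, core] == allele)
  if (length(car) < 2) return(NULL)
  n_pair <- choose(length(car), 2)
  run <- function(dir) {
    grp <- rep(1L, length(car))
    out <- list()
    j <- core + dir
    while (j >= 1 && j <= ncol(haps)) {
      grp <- as.integer(factor(paste(grp, haps[car, j])))
      ehh <- sum(choose(tabulate(grp), 2)) / n_pair
      out[[length(out) + 1]] <- data.frame(site = j, pos = positions[j],
                                           direction = dir, ehh = ehh)
      if (ehh < cutoff) break
      j <- j + dir
    }
    do.call(rbind, out)
  }
  rbind(run(-1),
        data.frame(site = core, pos = positions[core], direction = 0,
                   ehh = 1),
        run(1))
}

#' Integrated haplotype scores (iHS) for all sites
#'
#' For each site passing the MAF filter, EHH curves for the ancestral (0)
#' and derived (1) alleles are integrated over position by the trapezoid
#' rule, outward until EHH < `cutoff` (sites whose curves never decay
#' before the chromosome end are dropped, as are sites with < 2 carriers
#' of either allele). The unstandardized score `ln(iHH_A / iHH_D)` is then
#' standardized to mean 0, sd 1 within derived-allele-frequency bins.
#'
#' @param haps haplotype x site 0/1 matrix (0 = ancestral).
#' @param positions site positions (bp, or interpolated genetic positions
#'   from [interpolate_genetic_map()]).
#' @param chrom optional chromosome name per site; EHH integration never
#'   crosses a chromosome boundary, and standardization is genome-wide.
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param n_bins derived-frequency standardization bins (default 50;
#'   reduced automatically so every non-empty bin has >= 2 sites).
#' @return data.frame `site`, `chrom`, `pos`, `freq_derived`, `ihh_anc`,
#'   `ihh_der`, `uihs` (unstandardized), `ihs` (standardized), `bin`.
#' @export
compute_ihs <- function(haps, positions, chrom = NULL, maf_min = 0.05,
                        cutoff = 0.05, n_bins = 50) {
  if (is.null(chrom)) chrom <- rep("chr0", length(positions))
  pieces <- lapply(unique(chrom), function(ch) {
    ii <- which(chrom == ch)
    sc <- ehh_scan_cpp(haps[, ii, drop = FALSE],
                       as.numeric(positions[ii]), maf_min, cutoff)
    ok <- sc$ok & sc$ihh_anc > 0 & sc$ihh_der > 0
    data.frame(site = ii[ok], chrom = ch, pos = positions[ii][ok],
               freq_derived = sc$freq_derived[ok],
               ihh_anc = sc$ihh_anc[ok], ihh_der = sc$ihh_der[ok])
  })
  out <- do.call(rbind, c(pieces, make.row.names = FALSE))
  if (nrow(out) == 0) stop("no sites pass the MAF and truncation filters")
  out$uihs <- log(out$ihh_anc / out$ihh_der)
  repeat {
    br <- unique(stats::quantile(out$freq_derived,
                                 probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(out$freq_derived, br, include.lowest = TRUE, labels = FALSE)
    if (min(table(bin)) >= 2 || n_bins == 1) break
    n_bins <- max(1, floor(n_bins / 2))
  }
  out$bin <- bin
  mu <- tapply(out$uihs, bin, mean)
  sdv <- tapply(out$uihs, bin, stats::sd)
  out$ihs <- (out$uihs - mu[as.character(bin)]) / sdv[as.character(bin)]
  out <- out[is.finite(out$ihs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpolate physical positions onto a genetic map
#'
#' Linear interpolation of a two-column position/cM table; positions
#' outside the table extrapolate from the nearest segment.
#'
#' @param pos physical positions (bp).
#' @param map data.frame with columns `pos` (bp) and `cm`.
#' @return genetic positions (cM).
#' @export
interpolate_genetic_map <- function(pos, map) {
  stats::approx(map$pos, map$cm, xout = pos, rule = 2)$y
}

#' Windowed extreme-|iHS| statistic with empirical p values
#'
#' Windows of `window` bp are scored by the number of |iHS| values in the
#' genome-wide top `top_frac`; windows are binned into `n_quantiles`
#' quantiles by their SNP count, and each window's one-sided empirical p
#' is computed from its rank within its quantile bin as
#' `(r + 0.5) / (m + 1)` where `r` counts bin windows with a strictly
#' greater statistic (`ties = "midrank"` adds half the tied windows;
#' `ties = "random"` breaks ties uniformly at random, giving exactly
#' rank-uniform p under the null).
#'
#' @param scores table from [compute_ihs()].
#' @param window window size in bp (default 10 kb).
#' @param top_frac fraction defining "extreme" |iHS| (default 0.05).
#' @param n_quantiles SNP-count quantile bins (default 10).
#' @param ties `"midrank"` (default) or `"random"`.
#' @return data.frame per non-empty window: `chrom`, `start`, `end`,
#'   `n_snps`, `extreme_count`, `quantile_bin`, `p_emp`.
#' @export
window_ihs_stat <- function(scores, window = 1e4, top_frac = 0.05,
                            n_quantiles = 10, ties = c("midrank", "random")) {
  ties <- match.arg(ties)
  if (nrow(scores) == 0) stop("no iHS scores supplied")
  if (is.null(scores$chrom)) scores$chrom <- "chr0"
  thr <- stats::quantile(abs(scores$ihs), 1 - top_frac)
  win <- paste0(scores$chrom, ":", floor(scores$pos / window))
  n_snps <- as.integer(table(win))
  extreme <- tapply(abs(scores$ihs) >= thr, win, sum)
  key <- strsplit(names(extreme), ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(key, `[`, "", 1),
                    start = as.numeric(vapply(key, `[`, "", 2)) * window,
                    n_snps = n_snps,
                    extreme_count = as.integer(extreme))
  out$end <- out$start + window
  br <- unique(stats::quantile(out$n_snps,
                               probs = seq(0, 1,
                                           length.out = n_quantiles + 1)))
  out$quantile_bin <- cut(out$n_snps, br, include.lowest = TRUE,
                          labels = FALSE)
  out$p_emp <- NA_real_
  for (b in unique(out$quantile_bin)) {
    ii <- which(out$quantile_bin == b)
    s <- out$extreme_count[ii]
    m <- length(ii)
    if (ties == "random") {
      s <- s + stats::runif(m) * 0.5   # jitter < resolution breaks ties
      r <- m - rank(s, ties.method = "first")
    } else {
      r <- vapply(s, function(x) sum(s > x) + (sum(s == x) - 1) / 2,
                  numeric(1))
    }
    out$p_emp[ii] <- (r + 0.5) / (m + 1)
  }
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "n_snps", "extreme_count",
               "quantile_bin", "p_emp")]
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment of window p values across populations
#'
#' @param p_list list (length k) of per-window empirical p vectors, one per
#'   population, aligned on the same windows.
#' @return list of adjusted vectors: `min(1, p * k)`.
#' @export
adjust_populations <- function(p_list) {
  k <- length(p_list)
  m <- unique(lengths(p_list))
  if (length(m) != 1) stop("window sets differ between populations")
  lapply(p_list, function(p) pmin(1, p * k))
}

#' Assign regions the best p value of intersecting windows
#'
#' @param regions interval data.frame (`chrom` optional, `start`, `end`).
#' @param windows window table from [window_ihs_stat()] with a p column.
#' @param p_col name of the p column (default `"p_emp"`).
#' @return `regions` with a `min_p` column (NA when nothing intersects).
#' @export
annotate_regions <- function(regions, windows, p_col = "p_emp") {
  regions$min_p <- vapply(seq_len(nrow(regions)), function(i) {
    sel <- windows$end > regions$start[i] & windows$start < regions$end[i]
    if (!any(sel)) NA_real_ else min(windows[[p_col]][sel], na.rm = TRUE)
  }, numeric(1))
  regions
}

## Weir-Cockerham variance components for haploid samples at one site:
## MSP/MSG ANOVA formulation (no heterozygosity term for phased data).
.wc_components <- function(n, p) {
  r <- length(n)
  N <- sum(n)
  pbar <- sum(n * p) / N
  msp <- sum(n * (p - pbar)^2) / (r - 1)
  msg <- sum(n * p * (1 - p)) / sum(n - 1)
  nc <- (N - sum(n^2) / N) / (r - 1)
  c(a = (msp - msg) / nc, bc = msg)
}

#' Weir-Cockerham FST in genomic windows (haploid samples)
#'
#' Per-site variance components are computed with the haploid-sample
#' (phased-data) Weir-Cockerham ANOVA estimator and summed within windows:
#' the weighted window estimate is `sum(a) / sum(a + b + c)`. Monomorphic
#' windows are `NA`.
#'
#' @param haps haplotype x site 0/1 matrix.
#' @param positions site positions in bp.
#' @param pop factor/vector assigning each haplotype to a population
#'   (at least 2 haplotypes per population, 2+ populations).
#' @param window window size in bp (default 10 kb); `NULL` returns the
#'   single genome-wide estimate.
#' @param chrom optional chromosome name per site.
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `fst` (or one
#'   row with `window = NULL`).
#' @export
weighted_fst <- function(haps, positions, pop, window = 1e4, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("chr0", length(positions))
  pop <- as.factor(pop)
  n <- as.numeric(table(pop))
  if (any(n < 2)) stop("every population needs at least 2 haplotypes")
  sp <- split(seq_len(nrow(haps)), pop)
  freqs <- vapply(sp, function(ii) colMeans(haps[ii, , drop = FALSE]),
                  numeric(ncol(haps)))
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1,
                                           dimnames = list(NULL, names(sp)))
  comp <- t(vapply(seq_len(ncol(haps)), function(j) {
    .wc_components(n, freqs[j, ])
  }, numeric(2)))
  win <- if (is.null(window)) rep("all:0", length(positions)) else
    paste0(chrom, ":", floor(positions / window))
  a_sum <- tapply(comp[, 1], win, sum)
  t_sum <- tapply(comp[, 1] + comp[, 2], win, sum)
  key <- strsplit(names(a_sum), ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(key, `[`, "", 1),
                    start = as.numeric(vapply(key, `[`, "", 2)) *
                      (if (is.null(window)) 0 else window),
                    n_snps = as.integer(table(win)),
                    fst = ifelse(t_sum > 0, a_sum / t_sum, NA_real_))
  out$end <- out$start + (if (is.null(window)) max(positions) else window)
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "n_snps", "fst")]
  rownames(out) <- NULL
  out
}

#' Read a phased VCF into a haplotype matrix
#'
#' @param path VCF with phased GT fields (`0|1`).
#' @return list with `haplotypes` (2N x S 0/1 matrix) and `positions`.
#' @export
read_phased_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.numeric(vcfR::getFIX(v)[, "POS"])
  sp <- strsplit(gt, "|", fixed = TRUE)
  h1 <- matrix(as.integer(vapply(sp, `[`, "", 1)), nrow(gt), ncol(gt))
  h2 <- matrix(as.integer(vapply(sp, `[`, "", 2)), nrow(gt), ncol(gt))
  H <- t(cbind(h1, h2))
  rownames(H) <- c(paste0(colnames(gt), "_1"), paste0(colnames(gt), "_2"))
  list(haplotypes = H, positions = pos)
}
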