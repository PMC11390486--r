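# Marker matrix encoding, consensus imputation, binning/smoothing and
# drive-interval calling.

make_calls <- function() {
  data.frame(sample = rep(c("p1", "p2"), each = 3),
             marker = rep(c("m1", "m2", "m3"), 2),
             chrom = "chr1", pos = rep(c(100, 200, 300), 2),
             call = c("alt", "ref", "missing", "missing", "missing",
                      "missing"))
}

test_that("encoding is exact and round-trips", {
  mm <- encode_matrix(make_calls())
  expect_equal(unname(mm$calls[, "p1"]), c(1L, -1L, 0L))
  expect_equal(unname(mm$calls[, "p2"]), c(0L, 0L, 0L))  # all-missing column
  back <- decode_matrix(mm)
  key <- function(d) d[order(d$sample, d$marker),
                       c("sample", "marker", "call")]
  expect_equal(key(back), key(make_calls()), ignore_attr = TRUE)

  dup <- rbind(make_calls(), make_calls()[1, ])
  expect_error(encode_matrix(dup), "duplicate")

  het <- make_calls(); het$call[1] <- "het"
  expect_error(encode_matrix(het), "haploid")
})

test_that("random call tables survive encode/decode", {
  set.seed(8)
  calls <- expand.grid(sample = paste0("s", 1:5),
                       marker = paste0("m", 1:40),
                       stringsAsFactors = FALSE)
  calls$chrom <- "chr2"
  calls$pos <- as.numeric(sub("m", "", calls$marker)) * 1000
  calls$call <- sample(c("ref", "alt", "missing"), nrow(calls), TRUE)
  back <- decode_matrix(encode_matrix(calls))
  ord <- function(d) d[order(d$sample, d$pos), c("sample", "marker", "call")]
  expect_equal(ord(back), ord(calls), ignore_attr = TRUE)
})

test_that("imputation fills confident neighbourhoods and nothing else", {
  mk <- data.frame(id = paste0("m", 1:5), chrom = "chr1",
                   pos = c(10, 20, 30, 40, 50) * 1000)
  # missing entry flanked by (1, 1, 1, 1) -> 1
  M <- matrix(c(1L, 1L, 0L, 1L, 1L), ncol = 1)
  mm <- as_marker_matrix(M, mk)
  imp <- impute_matrix(mm, window_markers = 5, min_confidence = 0.6)
  expect_equal(unname(imp$calls[3, 1]), 1L)
  expect_true(imp$was_imputed[3, 1])

  # alternating neighbourhood: |mean| = 0 stays missing
  M2 <- matrix(c(1L, -1L, 0L, 1L, -1L), ncol = 1)
  imp2 <- impute_matrix(as_marker_matrix(M2, mk), 5, 0.6)
  expect_equal(unname(imp2$calls[3, 1]), 0L)

  # observed calls are never altered
  set.seed(9)
  M3 <- matrix(sample(c(-1L, 0L, 1L), 200, TRUE, prob = c(.4, .2, .4)),
               ncol = 4)
  mk3 <- data.frame(id = paste0("m", 1:50), chrom = rep(c("c1", "c2"), 25)[
    order(rep(c("c1", "c2"), 25))], pos = rep(seq(1e4, 25e4, 1e4), 2))
  mm3 <- as_marker_matrix(M3, mk3)
  imp3 <- impute_matrix(mm3)
  obs <- mm3$calls != 0L
  expect_identical(imp3$calls[obs], mm3$calls[obs])
  expect_true(all(imp3$calls[mm3$calls == 0L & !imp3$was_imputed] == 0L))

  expect_error(impute_matrix(mm, window_markers = 4), "odd")
})

test_that("imputation recovers truth on noisy synthetic pollen", {
  cfg <- synth_config(n_pollen = 60, dropout = 0.3, error = 0.01)
  set.seed(10)
  pv <- gen_pollen_vcf(cfg)
  mm <- as_marker_matrix(pv$calls, pv$markers)
  imp <- impute_matrix(mm)
  acc <- mean(imp$calls[imp$was_imputed] == pv$truth[imp$was_imputed])
  expect_gte(acc, 0.98)
})

test_that("binning averages informative entries and conserves counts", {
  mk <- data.frame(id = paste0("m", 1:4), chrom = "chr1",
                   pos = c(10e3, 40e3, 90e3, 250e3))
  M <- matrix(c(1L, 1L, -1L, 0L,
                1L, 0L, 0L, -1L), ncol = 2)
  mm <- as_marker_matrix(M, mk)
  tr <- bin_signal(mm, bin_width = 1e5, chrom_lengths = c(chr1 = 4e5))
  # first bin holds entries (1, 1, -1) across samples plus (1) = mean 1/2
  expect_equal(tr$value[1], mean(c(1, 1, -1, 1)))
  expect_equal(tr$value[3], -1)     # single informative entry
  expect_true(is.na(tr$value[2]))   # empty bin
  expect_equal(sum(tr$n_markers), sum(M != 0))

  # per-sample mode
  tr1 <- bin_signal(mm, bin_width = 1e5, sample = "S1",
                    chrom_lengths = c(chr1 = 4e5))
  expect_equal(tr1$value[1], mean(c(1, 1, -1)))
})

test_that("sliding windows mean the contributing bins", {
  bins <- data.frame(chrom = "chr1", start = seq(0, 9e5, 1e5),
                     end = seq(1e5, 1e6, 1e5), value = 0.5)
  w <- smooth_track(bins, window = 1e6, step = 2e5)
  expect_true(all(w$value == 0.5))   # constant track stays constant

  bins$value <- c(rep(NA, 4), 1, rep(NA, 5))  # interior bin [4e5, 5e5)
  w2 <- smooth_track(bins, window = 2e5, step = 1e5)
  # the single informative bin feeds exactly window/step overlapping windows
  expect_equal(sum(!is.na(w2$value)), 2)
  expect_true(all(w2$value[!is.na(w2$value)] == 1))

  bins$value <- rep(c(0.2, 0.8), 5)
  w3 <- smooth_track(bins, window = 2e5, step = 2e5)
  expect_equal(w3$value, rep(0.5, 5))  # step = window: block means
  # smoothing is bounded by contributing bins
  w4 <- smooth_track(bins, window = 4e5, step = 2e5)
  expect_true(all(w4$value >= 0.2 & w4$value <= 0.8))
})

test_that("aggregate frequency is the donor fraction of observed calls", {
  mk <- data.frame(id = c("a", "b"), chrom = "chr1", pos = c(1e4, 2e4))
  M <- matrix(c(1L, 1L,
                1L, 1L,
                -1L, 0L), nrow = 2)
  mm <- as_marker_matrix(M, mk)
  fr <- aggregate_frequency(mm)
  expect_equal(fr$freq[fr$marker == "a"], 2 / 3)
  expect_equal(fr$freq[fr$marker == "b"], 1)
  # no-call marker is missing
  M0 <- matrix(c(0L, 0L), nrow = 2)
  fr0 <- aggregate_frequency(as_marker_matrix(M0, mk[1:2, ]))
  expect_true(all(is.na(fr0$freq)))
  # imputed entries are excluded by default
  mm2 <- as_marker_matrix(matrix(c(1L, 1L, 1L, 1L), nrow = 2), mk)
  mm2$was_imputed <- matrix(c(FALSE, TRUE, FALSE, FALSE), nrow = 2)
  fr2 <- aggregate_frequency(mm2)
  expect_equal(fr2$n_alt[2], 1)
  expect_equal(aggregate_frequency(mm2, use_imputed = TRUE)$n_alt[2], 2)
})

test_that("drive intervals are called only where frequency saturates", {
  tr <- data.frame(chrom = "chr1", start = seq(0, 48e5, 2e5),
                   end = seq(0, 48e5, 2e5) + 1e6,
                   value = c(rep(0.5, 10), rep(0.99, 8), rep(0.5, 7)))
  iv <- call_drive_intervals(tr, threshold = 0.95, min_span = 1e6)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 20e5)
  expect_equal(iv$end, 34e5 + 1e6)

  expect_equal(nrow(call_drive_intervals(tr, threshold = 1.01)), 0)
  tr$value <- 0.5
  expect_equal(nrow(call_drive_intervals(tr)), 0)
})

test_that("null pollen data yields no drive intervals; drive data two", {
  cfg <- synth_config(n_pollen = 60)
  set.seed(12)
  # null: no drive, male transmission without toxin
  model <- tpd_synth_model()
  wt <- diploid(haplotype(model, nb1 = "mex", nb2 = "mex"), haplotype(model))
  pv0 <- gen_pollen_vcf(cfg, model = model, parent = wt)
  mm0 <- impute_matrix(as_marker_matrix(pv0$calls, pv0$markers))
  tr0 <- frequency_track(aggregate_frequency(mm0),
                         chrom_lengths = cfg$chrom_lengths)
  expect_equal(nrow(call_drive_intervals(tr0)), 0)

  set.seed(13)
  pv <- gen_pollen_vcf(cfg)
  mm <- impute_matrix(as_marker_matrix(pv$calls, pv$markers))
  tr <- frequency_track(aggregate_frequency(mm),
                        chrom_lengths = cfg$chrom_lengths)
  iv <- call_drive_intervals(tr)
  expect_equal(nrow(iv), 2)
  truth <- pv$blocks[pv$blocks$driven, ]
  expect_gte(interval_jaccard(iv, truth), 0.8)
})
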