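# Small-RNA cluster calling, size/strand classification, hairpin
# identification and differential accumulation.

align_row <- function(start, len, strand, count, sample = "s1",
                      chrom = "c1") {
  data.frame(chrom = chrom, start = start, end = start + len,
             strand = strand, length = len, count = count, sample = sample)
}

test_that("clusters respect the CPM cut-off and size-bias rules", {
  lib <- c(s1 = 1e6)
  # CPM 4.9 -> dropped; CPM 5.1 -> kept
  al <- rbind(align_row(100, 22, "+", 4.9), align_row(5000, 22, "+", 5.1))
  cl <- call_clusters(al, lib)
  expect_equal(cl$status[order(cl$start)], c("discarded_cpm", "retained"))

  # (21: 10, 22: 80, 24: 10) -> dominant size 22
  al2 <- rbind(align_row(100, 21, "+", 10), align_row(120, 22, "+", 80),
               align_row(140, 24, "+", 10))
  cl2 <- call_clusters(al2, lib)
  expect_equal(cl2$dominant_size, 22)
  expect_equal(cl2$status, "retained")

  # (21: 40, 22: 45, 24: 15) -> no clear bias, discarded
  al3 <- rbind(align_row(100, 21, "+", 40), align_row(120, 22, "+", 45),
               align_row(140, 24, "+", 15))
  cl3 <- call_clusters(al3, lib)
  expect_equal(cl3$status, "discarded_size")
  expect_true(is.na(cl3$dominant_size))

  expect_error(call_clusters(al, c(s1 = 0)), "zero-depth")
})

test_that("cluster counts partition the input reads", {
  set.seed(17)
  start <- sample.int(5e4, 60)
  al <- do.call(rbind, lapply(start, function(s) {
    align_row(s, sample(c(21, 22, 24, 26), 1), sample(c("+", "-"), 1),
              sample(10:200, 1))
  }))
  cl <- call_clusters(al, c(s1 = 1e6))
  expect_equal(sum(cl$plus + cl$minus), sum(al$count))
  expect_equal(sum(cl$n21 + cl$n22 + cl$n24 + cl$n_other), sum(al$count))
})

test_that("strand relabelling flips strand counts symmetrically", {
  set.seed(18)
  al <- do.call(rbind, lapply(sample.int(2e4, 20), function(s) {
    align_row(s, 22, sample(c("+", "-"), 1), sample(5:50, 1))
  }))
  cl <- call_clusters(al, c(s1 = 1e6))
  al_flip <- al
  al_flip$strand <- ifelse(al$strand == "+", "-", "+")
  cl_flip <- call_clusters(al_flip, c(s1 = 1e6))
  expect_equal(cl$plus, cl_flip$minus)
  expect_equal(cl$strand_fraction, cl_flip$strand_fraction)
})

test_that("hairpin classification needs both strand bias and structure", {
  set.seed(19)
  arm <- random_dna(200)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(arm, "")[[1]]),
                                     collapse = ""))
  hp_seq <- paste0(arm, random_dna(50), rc)
  genome <- c(c1 = paste0(random_dna(300), hp_seq, random_dna(300),
                          random_dna(450), random_dna(300)))
  hp_start <- 300
  sh_start <- 300 + nchar(hp_seq) + 300   # random locus, same length
  # reads tile both arms of the hairpin (the siRNA duplex maps to the same
  # genomic strand across the whole locus)
  offs <- seq(10, 410, by = 50)
  al <- rbind(
    do.call(rbind, lapply(offs,
                          function(o) align_row(hp_start + o, 22, "+", 110))),
    do.call(rbind, lapply(offs,
                          function(o) align_row(sh_start + o, 22, "+", 110))))
  cl <- call_clusters(al, c(s1 = 1e6))
  hp <- classify_hairpins(cl, genome)
  expect_equal(nrow(hp), 1)
  expect_lt(abs(hp$start - hp_start), 30)
  expect_gte(hp$pairing_fraction, 0.95)
  expect_gte(hp$arm_len, 150)
  # arm coordinates flank the loop
  expect_true(hp$arm5_end <= hp$loop_start && hp$loop_end <= hp$arm3_start)

  # same structure but mixed strands: rejected no matter the sequence
  al_mix <- al[1:3, ]
  al_mix$strand <- c("+", "-", "+")
  al_mix$count <- c(55, 45, 10)   # strand fraction 0.59
  cl_mix <- call_clusters(al_mix, c(s1 = 1e6))
  expect_equal(nrow(classify_hairpins(cl_mix, genome)), 0)
})

test_that("differential calls are symmetric and threshold-gated", {
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  lib <- c(a1 = 1e6, a2 = 1e6, b1 = 1e6, b2 = 1e6)
  al <- do.call(rbind, lapply(names(groups), function(s) {
    rbind(align_row(100, 22, "+", if (groups[[s]] == "A") 400 else 50,
                    sample = s),
          align_row(5000, 22, "+", 100, sample = s),
          align_row(9000, 24, "+", if (groups[[s]] == "A") 30 else 240,
                    sample = s))
  }))
  cl <- call_clusters(al, lib)
  dr <- differential_clusters(cl, groups)
  dr <- dr[order(dr$start), ]
  expect_equal(dr$call, c("up", "ns", "down"))
  # 8x CPM ratio gives log2FC 3 (pseudocount-damped, still >= 2)
  expect_gt(dr$log2fc[1], 2.9)
  expect_equal(dr$log2fc[2], 0, tolerance = 0.01)

  swapped <- differential_clusters(cl, groups[c("b1", "b2", "a1", "a2")])
  swapped <- swapped[order(swapped$start), ]
  expect_equal(swapped$call, c("down", "ns", "up"))
  expect_equal(swapped$log2fc, -dr$log2fc, tolerance = 1e-12)
  expect_equal(swapped$p, dr$p, tolerance = 1e-12)

  expect_error(differential_clusters(cl, c(a1 = "A", a2 = "A")), "group")
})

test_that("planted differential loci are recovered at high specificity", {
  cfg <- synth_config()
  cfg$srna$n_up_sirna <- 50
  cfg$srna$n_hairpin <- 5
  cfg$srna$n_sirna <- 150
  set.seed(20)
  sr <- gen_srna_readset(cfg)
  cl <- call_clusters(sr$alignments, sr$lib_sizes)
  dr <- differential_clusters(cl, sr$groups)
  truth_idx <- vapply(seq_len(nrow(dr)), function(i) {
    j <- which(sr$truth$start < dr$end[i] & sr$truth$end > dr$start[i])
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  up_truth <- sr$truth$up[truth_idx]
  recall <- sum(dr$call == "up" & up_truth, na.rm = TRUE) /
    sum(sr$truth$up)
  expect_gte(recall, 0.9)
  fp <- sum(dr$call != "ns" & !up_truth, na.rm = TRUE)
  expect_lte(fp / sum(!up_truth, na.rm = TRUE), 0.01)
})

test_that("clusters inherit the class of their maximal-overlap feature", {
  feats <- data.frame(chrom = "c1",
                      start = c(0, 800, 2000), end = c(1000, 1200, 2400),
                      strand = "+",
                      type = c("gene", "transposable_element", "gene"),
                      ID = c("g1", "te1", "g2"),
                      classification = c("gene", "PIF_Harbinger", "gene"))
  al <- rbind(align_row(850, 22, "+", 100),    # overlaps g1 more than te1?
              align_row(2100, 22, "+", 60),
              align_row(5000, 22, "+", 40))
  cl <- call_clusters(al, c(s1 = 1e6))
  ann <- annotate_cluster_targets(cl, feats)
  ann$clusters <- ann$clusters[order(ann$clusters$start), ]
  # cluster [850, 872) lies inside both g1 and te1: overlap ties at 22,
  # tie breaks toward the longer feature (g1)
  expect_equal(ann$clusters$feature_class, c("gene", "gene", "intergenic"))
  s <- ann$summary
  expect_equal(sum(s$frac[s$class != "hairpin"]), 1)
  expect_equal(s$read_frac[s$class == "intergenic"], 40 / 200)

  # read-weighted hairpin fraction on the synthetic readset
  cfg <- synth_config()
  cfg$srna$n_background <- 0
  set.seed(21)
  sr <- gen_srna_readset(cfg)
  cl2 <- call_clusters(sr$alignments, sr$lib_sizes)
  hp <- classify_hairpins(cl2, sr$genome)
  ann2 <- annotate_cluster_targets(cl2, feats[0, ], hairpins = hp)
  truth_hp <- sr$truth[sr$truth$type == "hairpin", ]
  al2 <- sr$alignments
  in_hp <- rowSums(outer(al2$start, truth_hp$start, ">=") &
                     outer(al2$end, truth_hp$end, "<=")) > 0
  want <- sum(al2$count[in_hp]) / sum(al2$count)
  got <- ann2$summary$read_frac[ann2$summary$class == "hairpin"]
  expect_lt(abs(got - want), 0.02)
})
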