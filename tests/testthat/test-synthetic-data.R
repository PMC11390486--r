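# Generators: parameter recovery of their own declared statistical
# structure, plus reproducibility under a fixed seed.

test_that("marker panels respect density and truth blocks", {
  cfg <- synth_config(marker_density = 1e-4)
  set.seed(1)
  panel <- gen_marker_panel(cfg)
  n_exp <- sum(cfg$chrom_lengths) * cfg$marker_density
  expect_lt(abs(nrow(panel$markers) - n_exp) / n_exp, 0.05)
  # fraction of markers inside blocks matches the block share of the genome
  frac_blocks <- sum(panel$blocks$end - panel$blocks$start) /
    sum(cfg$chrom_lengths)
  expect_lt(abs(mean(!is.na(panel$markers$block)) - frac_blocks), 0.02)
  expect_true(all(panel$markers$ref != panel$markers$alt))

  cfg$blocks <- data.frame(chrom = c("chr5", "chr5"),
                           start = c(1e6, 2e6), end = c(3e6, 4e6),
                           tag_locus = c("a", "b"),
                           donor_allele = "x", driven = FALSE)
  expect_error(gen_marker_panel(cfg), "overlapping")

  cfg2 <- synth_config(blocks = default_truth_blocks()[0, ])
  set.seed(2)
  all_ref <- gen_marker_panel(cfg2)
  expect_true(all(is.na(all_ref$markers$block)))
})

test_that("pollen call noise follows the declared dropout/error model", {
  cfg <- synth_config(dropout = 0.3, error = 0.01, n_pollen = 100)
  set.seed(3)
  pv <- gen_pollen_vcf(cfg)
  n <- length(pv$calls)
  miss <- mean(pv$calls == 0)
  expect_lt(abs(miss - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  obs <- pv$calls != 0
  err <- mean(pv$calls[obs] != pv$truth[obs])
  expect_lt(abs(err - 0.01), 3 * sqrt(0.01 * 0.99 / sum(obs)))

  # noise-free calls equal the truth haplotypes
  cfg0 <- synth_config(dropout = 0, error = 0, n_pollen = 20)
  set.seed(4)
  pv0 <- gen_pollen_vcf(cfg0)
  expect_identical(pv0$calls, pv0$truth)

  # every surviving grain carries the intact drive haplotype
  expect_true(all(pv$gametes$Tpd1 == "Tpd1"))
  expect_true(all(pv$gametes$Tpd2 == "Tpd2"))
  expect_true(all(pv$gametes$dcl2 == "dcl2T"))
})

test_that("bulk pools carry the expected enrichment structure", {
  cfg <- synth_config()
  set.seed(5)
  bp <- gen_bulk_pools(cfg)
  tr <- bp$truth
  tpd1_markers <- bp$markers$id[!is.na(bp$markers$block) &
                                  bp$markers$block == 1]
  # every sterile individual carries the toxin haplotype (heterozygous)
  st <- tr[tr$pool == "sterile" & tr$marker %in% tpd1_markers, ]
  expect_true(all(st$carrier_freq == 1))
  expect_true(all(st$allele_freq == 0.5))
  fe <- tr[tr$pool == "fertile" & tr$marker %in% tpd1_markers, ]
  expect_true(all(fe$allele_freq == 0))
  # unlinked neutral block: both pools near 0.25 allele frequency
  nb <- tr[tr$marker %in% bp$markers$id[!is.na(bp$markers$block) &
                                          bp$markers$block == 3], ]
  expect_true(all(abs(nb$allele_freq - 0.25) < 0.15))
  # read counts are binomial at the configured depth
  cnt <- bp$counts
  expect_true(all(cnt$ref + cnt$alt == cfg$pool_depth))
  sel <- cnt$pool == "sterile" & cnt$marker %in% tpd1_markers
  expect_lt(abs(mean(cnt$alt[sel]) / cfg$pool_depth - 0.5), 0.02)
  v <- var(cnt$alt[sel])
  expect_lt(abs(v - cfg$pool_depth * 0.25) / (cfg$pool_depth * 0.25), 0.25)
})

test_that("planted small-RNA loci have the declared structure", {
  cfg <- synth_config()
  set.seed(6)
  sr <- gen_srna_readset(cfg)
  hp <- sr$truth[sr$truth$type == "hairpin", ]
  expect_equal(nrow(hp), cfg$srna$n_hairpin)
  # arms are near-perfect inverted repeats by construction
  for (i in seq_len(5)) {
    a5 <- substr(sr$genome[["srna1"]], hp$arm5_start[i] + 1, hp$arm5_end[i])
    a3 <- substr(sr$genome[["srna1"]], hp$arm3_start[i] + 1, hp$arm3_end[i])
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(a3, "")[[1]]), collapse = ""))
    ident <- mean(strsplit(a5, "")[[1]] == strsplit(rc, "")[[1]])
    expect_gte(ident, 0.95)
  }
  # hairpin reads are dominantly 22 nt and single-stranded
  al <- sr$alignments
  for (i in seq_len(3)) {
    sel <- al$start >= hp$start[i] & al$end <= hp$end[i]
    expect_gte(sum(al$count[sel & al$length == 22]) / sum(al$count[sel]),
               0.8)
    sf <- max(sum(al$count[sel & al$strand == "+"]),
              sum(al$count[sel & al$strand == "-"])) / sum(al$count[sel])
    expect_gte(sf, 0.85)
  }
  # background loci stay under the CPM cut-off in every library
  bg <- sr$truth[sr$truth$type == "background", ]
  for (s in names(sr$lib_sizes)) {
    sa <- al[al$sample == s, ]
    for (i in seq_len(nrow(bg))) {
      sel <- sa$start >= bg$start[i] & sa$end <= bg$end[i]
      cpm <- sum(sa$count[sel]) / sr$lib_sizes[[s]] * 1e6
      expect_lt(cpm, 5)
    }
  }
})

test_that("planted target sites pair their declared degradome signal", {
  cfg <- synth_config()
  set.seed(7)
  ts <- gen_target_system(cfg)
  L <- cfg$targets$guide_len
  for (i in seq_len(nrow(ts$truth))) {
    tr <- ts$truth[i, ]
    peak <- ts$degradome[ts$degradome$transcript == tr$transcript &
                           ts$degradome$count > 0, ]
    on_site <- peak$pos >= tr$site_start & peak$pos < tr$site_start + L
    if (tr$mode == "cleavage") {
      # 5' end of the 3' fragment: the base paired to guide position 10
      expect_true(any(peak$pos == tr$site_start + L - 10))
    } else {
      expect_false(any(on_site & peak$pos == tr$site_start + L - 10))
    }
  }
  # the immune allele removes the seed pairing region in frame
  expect_equal((nchar(ts$immune$ref_seq) - nchar(ts$immune$alt_seq)) %% 3, 0)
  ci <- which(ts$truth$mode == "cleavage" &
                ts$truth$transcript == ts$immune$transcript)[1]
  seed_seq <- substr(ts$immune$ref_seq,
                     ts$truth$site_start[ci] + L - 13 + 1,
                     ts$truth$site_start[ci] + L - 2 + 1)
  expect_false(grepl(seed_seq, ts$immune$alt_seq, fixed = TRUE))

  expect_error({
    cfg2 <- synth_config(targets = modifyList(cfg$targets,
                                              list(guide_len = 18)))
    gen_target_system(cfg2)
  }, ">= 19")
})

test_that("generators are reproducible under a fixed seed", {
  cfg <- synth_config(n_pollen = 20)
  a <- gen_pollen_vcf(cfg, seed = 11)
  b <- gen_pollen_vcf(cfg, seed = 11)
  expect_identical(a$calls, b$calls)
  expect_identical(a$markers, b$markers)

  cfg$popgen <- modifyList(cfg$popgen,
                           list(n_hap = 30, genome_len = 2e6, mu = 2,
                                generations = 120))
  h1 <- gen_popgen_haplotypes(cfg, seed = 12)
  h2 <- gen_popgen_haplotypes(cfg, seed = 12)
  expect_identical(h1$haplotypes, h2$haplotypes)
  expect_identical(h1$positions, h2$positions)
})

test_that("popgen generator validates its sweep plan", {
  cfg <- synth_config()
  cfg$popgen$n_hap <- 31
  expect_error(gen_popgen_haplotypes(cfg), "even")
  cfg <- synth_config()
  cfg$popgen$sweep <- TRUE
  cfg$popgen$sweep_freq <- 1.2
  expect_error(gen_popgen_haplotypes(cfg), "frequency")
})
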