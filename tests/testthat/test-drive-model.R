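# The gamete simulator and viability engine against enumeration oracles and
# the published segregation behaviour of the system.

test_that("homozygous parents yield a single gamete class", {
  m <- toy_model()
  g <- make_gametes(wild_type(m), m)
  expect_equal(nrow(g), 1)
  expect_equal(g$prob, 1)
})

test_that("analytic enumeration matches linkage expectations", {
  m <- toy_model(r_linked = 0.187)
  het <- toy_heterozygote(m)
  g <- make_gametes(het, m)
  # recombinant classes between dcl2 and Tpd1 total r = 0.187
  rec <- (g$dcl2 == "dcl2T") != (g$Tpd1 == "Tpd1")
  expect_equal(sum(g$prob[rec]), 0.187, tolerance = 1e-12)
  expect_equal(sum(g$prob), 1, tolerance = 1e-9)

  # three unlinked heterozygous loci enumerate to 8 classes of 1/8
  loci <- rbind(locus_def("A", "c1", 1, "marker", c("a0", "a1")),
                locus_def("B", "c2", 1, "marker", c("b0", "b1")),
                locus_def("C", "c3", 1, "marker", c("c0", "c1")))
  m3 <- drive_model(loci, rules = viability_rules(toxin_locus = "A",
                                                  toxin_allele = "none",
                                                  dicer_locus = NULL,
                                                  antidote_groups = list(),
                                                  responder = NULL, b = 0))
  d3 <- diploid(haplotype(m3, A = "a1", B = "b1", C = "c1"), haplotype(m3))
  g3 <- make_gametes(d3, m3)
  expect_equal(nrow(g3), 8)
  expect_equal(g3$prob, rep(1 / 8, 8))
})

test_that("analytic mode refuses more than 12 heterozygous loci", {
  loci <- do.call(rbind, lapply(1:13, function(i) {
    locus_def(paste0("L", i), paste0("c", i), 1, "marker", c("x", "y"))
  }))
  m <- drive_model(loci, rules = viability_rules(toxin_locus = "L1",
                                                 toxin_allele = "none",
                                                 dicer_locus = NULL,
                                                 antidote_groups = list(),
                                                 responder = NULL, b = 0))
  h1 <- do.call(haplotype, c(list(m), setNames(rep("y", 13),
                                               paste0("L", 1:13))))
  het <- diploid(h1, haplotype(m))
  expect_error(make_gametes(het, m), "simulation mode")
  expect_silent(g <- make_gametes(het, m, n = 100, seed = 1))
  expect_equal(sum(g$count), 100)
})

test_that("survival follows (1 - T(1-A))(1 - b) with crisp default rules", {
  m <- toy_model(b = 0)
  het <- toy_heterozygote(m)
  v <- apply_viability(make_gametes(het, m), het, m)
  # survivors need dcl2T AND Tpd2: exactly 1/4 of meiotic products
  expect_equal(attr(v, "viable_fraction"), 0.25, tolerance = 1e-12)
  surv1 <- v$survival[v$dcl2 == "dcl2T" & v$Tpd2 == "Tpd2"]
  expect_true(all(surv1 == 1))
  expect_true(all(v$survival[v$Tpd2 == "tpd2"] == 0))

  # sporophyte lacking the toxin: everything survives at 1 - b
  mb <- toy_model(b = 0.1)
  wt <- wild_type(mb)
  vw <- apply_viability(make_gametes(wt, mb), wt, mb)
  expect_equal(attr(vw, "viable_fraction"), 0.9, tolerance = 1e-12)

  # Dicer-dead sporophyte makes no toxin even when Tpd1 is present
  mu <- diploid(haplotype(m, Tpd1 = "Tpd1", dcl2 = "dcl2_mu1"),
                haplotype(m, dcl2 = "dcl2_mu1"))
  vm <- apply_viability(make_gametes(mu, m), mu, m)
  expect_equal(attr(vm, "viable_fraction"), 1, tolerance = 1e-12)
})

test_that("an allele combination missing from the efficacy table errors", {
  m <- toy_model()
  m$rules$antidote_groups$dicer_plus_unlinked$dcl2 <-
    c(dcl2T = 1, Dcl2 = 0)  # drop dcl2_mu1 from the table
  mu <- diploid(haplotype(m, dcl2 = "dcl2_mu1", Tpd1 = "Tpd1"),
                haplotype(m))
  expect_error(apply_viability(make_gametes(mu, m), mu, m),
               "missing from antidote efficacy table")
})

test_that("female transmission is meiotic; male transmission is driven", {
  m <- toy_model(b = 0)
  het <- toy_heterozygote(m)
  g <- make_gametes(het, m)
  fem <- transmit(g, het, m, "female")
  expect_equal(sum(fem$prob), 1)
  rec <- (fem$dcl2 == "dcl2T") != (fem$Tpd1 == "Tpd1")
  expect_equal(sum(fem$prob[rec]), 0.187, tolerance = 1e-12)

  v <- apply_viability(g, het, m)
  mal <- transmit(v, het, m, "male")
  expect_equal(sum(mal$prob), 1, tolerance = 1e-12)
  # every transmitted pollen grain carries the intact drive haplotype
  expect_true(all(mal$dcl2 == "dcl2T" & mal$Tpd1 == "Tpd1" &
                    mal$Tpd2 == "Tpd2"))

  # with competition disabled, surviving recombinants transmit pro rata
  m2 <- toy_model(b = 0)
  m2$rules$competition$enabled <- FALSE
  v2 <- apply_viability(g, het, m2)
  mal2 <- transmit(v2, het, m2, "male")
  # survivors: (dcl2T, Tpd2) gametes = 1/4 of meiosis; the recombinant
  # (dcl2T, tpd1, Tpd2) share among them is (r/4) / (1/4) = r
  rec2 <- mal2$dcl2 == "dcl2T" & mal2$Tpd1 == "tpd1"
  expect_equal(sum(mal2$prob[rec2]), 0.187, tolerance = 1e-9)

  # all classes dead -> explicit error
  sterile <- diploid(haplotype(m, Tpd1 = "Tpd1"), haplotype(m))
  vs <- apply_viability(make_gametes(sterile, m), sterile, m)
  expect_error(transmit(vs, sterile, m, "male"), "no transmissible")
})

test_that("increasing antidote efficacy never decreases survival", {
  m <- toy_model(b = 0)
  het <- toy_heterozygote(m)
  g <- make_gametes(het, m)
  base <- apply_viability(g, het, m)$survival
  set.seed(7)
  for (i in 1:20) {
    m2 <- toy_model(b = 0)
    gr <- m2$rules$antidote_groups
    gr$dicer_plus_unlinked$dcl2[] <-
      pmax(gr$dicer_plus_unlinked$dcl2, runif(3))
    gr$dicer_plus_unlinked$Tpd2[] <-
      pmax(gr$dicer_plus_unlinked$Tpd2, runif(2))
    m2$rules$antidote_groups <- gr
    up <- apply_viability(g, het, m2)$survival
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("Monte Carlo frequencies agree with enumeration within 3 SE", {
  m <- toy_model(b = 0)
  het <- toy_heterozygote(m)
  exact <- make_gametes(het, m)
  sim <- make_gametes(het, m, n = 10000, seed = 123)
  key <- function(g) paste(g$dcl2, g$Tpd1, g$Tpd2)
  p <- exact$prob[match(key(sim), key(exact))]
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(sim$prob - p) <= 3 * se))
})

test_that("simulated female gametes recover the map r within 0.02", {
  m <- toy_model(b = 0, r_linked = 0.187)
  het <- toy_heterozygote(m)
  g <- make_gametes(het, m, n = 2000, seed = 99)
  rec <- (g$dcl2 == "dcl2T") != (g$Tpd1 == "Tpd1")
  r_hat <- sum(g$count[rec]) / sum(g$count)
  expect_lt(abs(r_hat - 0.187), 0.02)
})

test_that("inversion suppresses recombination only in heterokaryotypes", {
  m <- tpd_model(b = 0)
  het <- tpd_heterozygote(m)  # Tpd1/tpd1: heterokaryotypic for the inversion
  g <- make_gametes(het, m)
  rec_inv <- (g$Tpd1 == "Tpd1") != (g$Bt1 == "Bt1")
  expect_equal(sum(g$prob[rec_inv]), 0)
  # homokaryotypic Tpd1/Tpd1 parent: the inversion interval recombines at
  # its map r again; observable between the flanking heterozygous loci
  # dcl2 (outside) and Bt1 (inside): switch = r1(1-r2) + r2(1-r1)
  hom <- diploid(haplotype(m, Tpd1 = "Tpd1", Bt1 = "Bt1", dcl2 = "dcl2T",
                           Tpd2 = "Tpd2"),
                 haplotype(m, Tpd1 = "Tpd1"))
  gh <- make_gametes(hom, m)
  rec_hom <- (gh$dcl2 == "dcl2T") != (gh$Bt1 == "Bt1")
  expect_equal(sum(gh$prob[rec_hom]),
               0.187 * (1 - 0.04) + 0.04 * (1 - 0.187), tolerance = 1e-12)
})

test_that("crosses reproduce the published segregation behaviour", {
  m <- tpd_model()
  het <- tpd_heterozygote(m)
  wt <- wild_type(m)

  # wild type x wild type: all fertile
  ww <- simulate_cross(wt, wt, m, 50, seed = 1)
  expect_true(all(ww$phenotype == "fertile"))

  # drive father: all progeny inherit Tpd1, dcl2T and Tpd2
  pat <- simulate_cross(wt, het, m, 500, seed = 2)
  expect_true(all(pat$Tpd1_pat == "Tpd1"))
  expect_true(all(pat$dcl2_pat == "dcl2T"))
  expect_true(all(pat$Tpd2_pat == "Tpd2"))
  # linked endosperm marker inside the inversion transmits at 100%
  expect_equal(unname(marker_transmission(pat, "Bt1", "father")["Bt1"]), 1)
  # unlinked-side marker recombines off the antidote at its map distance
  y1f <- marker_transmission(pat, "y1", "father")
  expect_lt(abs(y1f[["y1"]] - 0.215), 3 * sqrt(0.215 * 0.785 / 500))

  # drive mother: 2:1:1 fertile / semi-sterile (drive) / sterile classes,
  # with genotypic classes at the two unlinked loci near 1:1:1:1
  mat <- simulate_cross(het, wt, m, 4000, seed = 3)
  counts <- table(mat$phenotype)
  expect_lt(abs(counts[["fertile"]] / 4000 - 0.5),
            3 * sqrt(0.25 / 4000))
  cls <- table(paste(mat$Tpd1_mat, mat$Tpd2_mat))
  expect_equal(length(cls), 4)
  for (k in cls) expect_lt(abs(k / 4000 - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))

  # neutral unlinked marker through the female side segregates 1:1
  y1m <- marker_transmission(mat, "y1", "mother")
  expect_lt(abs(y1m[["Y1"]] - 0.5), 3 * sqrt(0.25 / 4000))
})
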