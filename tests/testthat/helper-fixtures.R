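# Shared fixtures built in code at test time.

# Two-locus toy model: one toxin/antidote pair fully linked on chrA plus the
# unlinked antidote on chrB. Crisp default rules, b = 0 unless asked.
toy_model <- function(b = 0, r_linked = 0.187) {
  loci <- rbind(
    locus_def("dcl2", "chrA", 1e6, "antidote_primary",
              c("Dcl2", "dcl2T", "dcl2_mu1")),
    locus_def("Tpd1", "chrA", 5e6, "toxin", c("tpd1", "Tpd1")),
    locus_def("Tpd2", "chrB", 1e6, "antidote_unlinked", c("tpd2", "Tpd2")))
  drive_model(loci, c("dcl2:Tpd1" = r_linked),
              rules = viability_rules(b = b, responder = NULL))
}

toy_heterozygote <- function(model) {
  diploid(haplotype(model, Tpd1 = "Tpd1", dcl2 = "dcl2T", Tpd2 = "Tpd2"),
          haplotype(model))
}

# hand-written 5-line VCF used by the reader tests
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\tm1\tA\tT\t.\tPASS\t.\tGT\t0\t1\t.",
    "chr1\t200\tm2\tC\tG\t.\tPASS\t.\tGT\t1\t./.\t0",
    "chr1\t300\tm3\tG\tA\t.\tPASS\t.\tGT\t0\t0\t1",
    "chr1\t400\tmx\tG\tA,C\t.\tPASS\t.\tGT\t0\t0\t1"), path)
  path
}

toy_markers <- function() {
  marker_panel(chrom = c("chr1", "chr1"), pos = c(100, 200),
               ref = c("A", "C"), alt = c("T", "G"), id = c("m1", "m2"))
}

# independent brute-force expectation scorer used as oracle against
# score_sites(): direct per-window, per-position loop
brute_force_scores <- function(guide, transcript) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g <- strsplit(chartr("U", "T", toupper(guide)), "")[[1]]
  t <- strsplit(chartr("U", "T", toupper(transcript)), "")[[1]]
  L <- length(g)
  vapply(0:(length(t) - L), function(s) {
    E <- 0
    for (p in seq_len(L)) {
      tb <- t[s + L - p + 1]
      pen <- if (tb == comp[[g[p]]]) 0
      else if ((g[p] == "G" && tb == "T") || (g[p] == "T" && tb == "G")) 0.5
      else 1
      if (p >= 2 && p <= 13) pen <- pen * 2
      E <- E + pen
    }
    E
  }, numeric(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
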