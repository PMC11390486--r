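## siRNA target-site scoring on transcripts: expectation-score scanning
## with seed weighting and G:U wobble, AGO sorting by 5' nucleotide,
## cleavage vs translational mode calls, degradome (PARE) support, and
## allele comparison.
##
## Pairing geometry: the guide is written 5'->3'; at a site occupying
## transcript coordinates [s, s+L) (0-based half-open) guide position p
## pairs with target position s + L - p, so the guide 5' end faces the
## target 3' end. AGO-mediated cleavage falls between the target bases
## paired to guide positions 10 and 11; the 5'-monophosphate of the 3'
## cleavage fragment sits at the base paired to guide position 10, i.e.
## transcript coordinate s + L - 10, which is the convention used for
## `cleavage_pos` throughout.

.check_nt <- function(s, what) {
  if (grepl("[^ACGT]", s)) stop(what, " contains non-nucleotide characters")
}

#' Score target sites of one guide on a transcript
#'
#' Every ungapped window is scored with the classic expectation penalty
#' scheme: mismatch 1.0, G:U wobble 0.5, both doubled within the seed
#' (guide positions 2-13). Windows with `E <= max_E` are returned sorted
#' by E then position.
#'
#' @param guide guide sequence, 5'->3' (RNA or DNA alphabet; length
#'   20-24 nt).
#' @param transcript transcript sequence (5'->3').
#' @param max_E maximum expectation score (default 5.0).
#' @param guide_id,transcript_id optional labels carried into the result.
#' @return data.frame of sites: `start`, `end` (0-based half-open
#'   transcript coordinates), `E`, `seed_intact` (no seed mismatch),
#'   `cleavage_pos`, `mode` (see [call_mode()]), `pairing` (string over
#'   guide positions 1..L: `|` match, `o` G:U, `x` mismatch).
#' @export
score_sites <- function(guide, transcript, max_E = 5.0, guide_id = NA,
                        transcript_id = NA) {
  guide <- chartr("Uu", "Tt", toupper(guide))
  transcript <- chartr("Uu", "Tt", toupper(transcript))
  .check_nt(guide, "guide"); .check_nt(transcript, "transcript")
  L <- nchar(guide)
  if (L < 20 || L > 24) stop("guide length must be 20-24 nt")
  n <- nchar(transcript)
  if (n < L) stop("transcript shorter than guide")
  g <- strsplit(guide, "")[[1]]
  t <- strsplit(transcript, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_win <- n - L + 1
  E <- numeric(n_win)
  state <- matrix("x", n_win, L)   # per guide position
  for (p in seq_len(L)) {
    ti <- seq.int(L - p + 1, n - p + 1)   # 1-based target index per window
    tb <- t[ti]
    is_match <- tb == comp[g[p]]
    is_gu <- (g[p] == "G" & tb == "T") | (g[p] == "T" & tb == "G")
    pen <- ifelse(is_match, 0, ifelse(is_gu, 0.5, 1))
    if (p >= 2 && p <= 13) pen <- pen * 2
    E <- E + pen
    state[, p] <- ifelse(is_match, "|", ifelse(is_gu, "o", "x"))
  }
  keep <- which(E <= max_E)
  if (!length(keep)) {
    return(data.frame(guide = character(), transcript = character(),
                      start = numeric(), end = numeric(), E = numeric(),
                      seed_intact = logical(), cleavage_pos = numeric(),
                      mode = character(), pairing = character()))
  }
  seed_ok <- apply(state[keep, 2:13, drop = FALSE], 1,
                   function(x) !any(x == "x"))
  pairing <- apply(state[keep, , drop = FALSE], 1, paste, collapse = "")
  out <- data.frame(guide = guide_id, transcript = transcript_id,
                    start = keep - 1, end = keep - 1 + L, E = E[keep],
                    seed_intact = seed_ok,
                    cleavage_pos = keep - 1 + L - 10,
                    pairing = pairing)
  out$mode <- vapply(pairing, function(s) {
    if (substr(s, 10, 10) == "|" && substr(s, 11, 11) == "|") "cleavage"
    else "translational"
  }, character(1), USE.NAMES = FALSE)
  out <- out[order(out$E, out$start), ]
  rownames(out) <- NULL
  out
}

#' Score a guide set against a transcript set
#'
#' @param guides data.frame with `id`, `seq` (optionally `abundance`).
#' @param transcripts named character vector.
#' @param max_E expectation cutoff.
#' @return row-bound site table from [score_sites()].
#' @export
score_all_sites <- function(guides, transcripts, max_E = 5.0) {
  res <- list()
  for (i in seq_len(nrow(guides))) {
    for (tx in names(transcripts)) {
      s <- score_sites(guides$seq[i], transcripts[[tx]], max_E,
                       guide_id = guides$id[i], transcript_id = tx)
      if (nrow(s)) res[[length(res) + 1]] <- s
    }
  }
  if (!length(res)) {
    return(data.frame(guide = character(), transcript = character(),
                      start = numeric(), end = numeric(), E = numeric(),
                      seed_intact = logical(), cleavage_pos = numeric(),
                      pairing = character(), mode = character()))
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Predict the AGO clade loading of a guide from its 5' nucleotide
#'
#' 5'C guides load Ago5, 5'A guides Ago2, 5'U guides Ago1; 5'G guides are
#' unassigned.
#'
#' @param guide guide sequence (RNA or DNA alphabet).
#' @return one of `"Ago5"`, `"Ago2"`, `"Ago1"`, `"unassigned"`.
#' @export
ago_sort <- function(guide) {
  nt <- toupper(substr(guide, 1, 1))
  switch(nt, C = "Ago5", A = "Ago2", U = "Ago1", T = "Ago1",
         "unassigned")
}

#' Call silencing mode of a target site
#'
#' Cleavage requires perfect Watson-Crick pairing at guide positions 10
#' and 11; any mismatch, G:U wobble or bulge there predicts translational
#' repression instead.
#'
#' @param site one site row from [score_sites()] (uses `pairing`).
#' @return `"cleavage"` or `"translational"`.
#' @export
call_mode <- function(site) {
  st <- substr(site$pairing, 10, 11)
  if (st == "||") "cleavage" else "translational"
}

#' Degradome (iPARE) support of a target site
#'
#' Sums the CPM-normalized 5'-end counts at `cleavage_pos` plus/minus
#' `flank` on the site's transcript.
#'
#' @param site one site row from [score_sites()].
#' @param track degradome table: `transcript`, `pos` (0-based), `count`.
#' @param flank positions either side of the cleavage site (default 1).
#' @param min_count support threshold (default 0: any signal supports).
#' @return list with `ipare_count` and `supported`.
#' @export
ipare_support <- function(site, track, flank = 1, min_count = 0) {
  if (!site$transcript %in% track$transcript) {
    stop("transcript absent from degradome track: ", site$transcript)
  }
  sel <- track$transcript == site$transcript &
    abs(track$pos - site$cleavage_pos) <= flank
  cnt <- sum(track$count[sel])
  list(ipare_count = cnt, supported = cnt > min_count)
}

#' Compare target sites between two alleles of a transcript
#'
#' Rescoring of every guide on a reference and an alternate transcript
#' haplotype: reports per guide whether its best site is lost (present at
#' `E <= max_E` in the reference, absent or failing in the alternate),
#' whether the predicted mode changes or E worsens, and whether any length
#' difference between the alleles is frame-preserving.
#'
#' @param guides data.frame with `id`, `seq`.
#' @param ref_seq,alt_seq the two transcript alleles.
#' @param max_E expectation cutoff (default 5.0).
#' @return data.frame per guide: `status` (`lost`/`retained`/`none`),
#'   `E_ref`, `E_alt`, `mode_ref`, `mode_alt`, `delta_len`, `in_frame`.
#' @export
evaluate_allele <- function(guides, ref_seq, alt_seq, max_E = 5.0) {
  dl <- nchar(alt_seq) - nchar(ref_seq)
  out <- lapply(seq_len(nrow(guides)), function(i) {
    r <- score_sites(guides$seq[i], ref_seq, max_E, guide_id = guides$id[i])
    a <- score_sites(guides$seq[i], alt_seq, max_E, guide_id = guides$id[i])
    status <- if (nrow(r) == 0) "none" else if (nrow(a) == 0) "lost"
    else "retained"
    data.frame(guide = guides$id[i], status = status,
               E_ref = if (nrow(r)) r$E[1] else NA_real_,
               E_alt = if (nrow(a)) a$E[1] else NA_real_,
               mode_ref = if (nrow(r)) r$mode[1] else NA_character_,
               mode_alt = if (nrow(a)) a$mode[1] else NA_character_,
               delta_len = dl, in_frame = dl %% 3 == 0)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
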