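## Multi-locus toxin-antidote pollen drive model.
##
## The genetic system: a sporophytically expressed toxin locus (a hairpin
## producing 22-nt siRNAs) poisons all four meiotic products of any plant
## carrying it, by silencing an essential pollen gene (the responder). Only
## gametes that themselves carry antidote alleles survive: the default rules
## require BOTH a reduced-secondary-siRNA Dicer allele (dcl2T or dcl2-mu1)
## AND the unlinked antidote Tpd2, except that an amplifier-null allele
## (rgd1) or an immune/null responder allele rescues on its own. Toxin
## production additionally requires a Dicer-competent sporophyte, so
## dcl2-mu1 homozygotes make no toxin at all.
##
## Survival of a gamete class is (1 - T * (1 - A)) * (1 - b) with
## T in {0,1} the sporophytic toxin exposure, A in [0,1] the combined
## antidote efficacy of the gamete's own alleles, and b a background
## abortion rate applied independently to every class.

#' Define the loci of a drive model
#'
#' @param name locus name.
#' @param chrom chromosome.
#' @param pos position in bp.
#' @param role one of `"toxin"`, `"antidote_primary"`, `"antidote_unlinked"`,
#'   `"amplifier"`, `"responder"`, `"marker"`.
#' @param alleles character vector of allele labels (unique within locus).
#' @return a one-row locus definition (data.frame with an `alleles`
#'   list-column).
#' @export
locus_def <- function(name, chrom, pos, role, alleles) {
  roles <- c("toxin", "antidote_primary", "antidote_unlinked", "amplifier",
             "responder", "marker")
  if (!role %in% roles) stop("unknown locus role: ", role)
  if (anyDuplicated(alleles)) stop("allele labels must be unique within locus")
  out <- data.frame(name = name, chrom = as.character(chrom),
                    pos = as.numeric(pos), role = role)
  out$alleles <- list(alleles)
  out
}

#' Convert map distance in centimorgans to a recombination fraction
#'
#' Uses the Haldane map function `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param cm distance in cM.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(cm) (1 - exp(-2 * cm / 100)) / 2

#' Assemble a drive model
#'
#' Loci are sorted by (chrom, pos); `r` gives the recombination fraction for
#' each adjacent same-chromosome locus pair, named `"locusA:locusB"`.
#' Unspecified intervals default to `r = 0.5` (free recombination); loci on
#' different chromosomes always assort independently.
#'
#' @param loci data.frame from rbind-ing [locus_def()] rows.
#' @param r named numeric vector of recombination fractions in `[0, 0.5]`;
#'   names `"A:B"` refer to adjacent loci A, B in map order. Values given in
#'   cM can be converted with [haldane_r()].
#' @param inversions optional data.frame with columns `chrom`, `start`,
#'   `end`, `tag_locus`, `tag_allele`: a haplotype carries the inversion iff
#'   it holds `tag_allele` at `tag_locus`; in heterokaryotypic sporophytes
#'   recombination is suppressed (`r = 0`) between adjacent loci lying
#'   inside the inversion interval.
#' @param rules viability rules from [viability_rules()].
#' @return an object of class `"drive_model"`.
#' @export
drive_model <- function(loci, r = numeric(), inversions = NULL,
                        rules = viability_rules()) {
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  if (anyDuplicated(loci$name)) stop("locus names must be unique")
  n <- nrow(loci)
  r_next <- rep(NA_real_, n)   # r between locus i and i+1 (same chrom only)
  for (i in seq_len(max(n - 1, 0))) {
    if (loci$chrom[i] == loci$chrom[i + 1]) {
      key <- paste0(loci$name[i], ":", loci$name[i + 1])
      r_next[i] <- if (key %in% names(r)) r[[key]] else 0.5
    }
  }
  if (any(r_next < 0 | r_next > 0.5, na.rm = TRUE)) {
    stop("recombination fractions must lie in [0, 0.5]")
  }
  bad <- setdiff(names(r),
                 paste0(loci$name[-n], ":", loci$name[-1])[loci$chrom[-n] == loci$chrom[-1]])
  if (length(bad)) stop("r names do not match adjacent map intervals: ",
                        paste(bad, collapse = ", "))
  structure(list(loci = loci, r_next = r_next, inversions = inversions,
                 rules = rules),
            class = "drive_model")
}

#' Print a compact summary of a drive model
#' @param x a `"drive_model"`.
#' @param ... passed to `print.data.frame`.
#' @return `x`, invisibly.
#' @method print drive_model
#' @export
print.drive_model <- function(x, ...) {
  cat("drive_model with", nrow(x$loci), "loci on",
      length(unique(x$loci$chrom)), "chromosome(s)\n")
  df <- x$loci[, c("name", "chrom", "pos", "role")]
  df$r_next <- round(x$r_next, 4)
  print(df, ...)
  invisible(x)
}

#' Viability and transmission rules for a drive model
#'
#' Gamete survival is `(1 - T * (1 - A)) * (1 - b)`. `T` is sporophytic:
#' 1 iff the parent plant carries `toxin_allele` at the toxin locus and at
#' least one Dicer-competent allele at `dicer_locus`. `A` is gametophytic:
#' the maximum over antidote groups of the product of per-locus efficacies
#' of the gamete's own alleles (so a group listing two loci requires both
#' antidotes, while a single-locus group rescues alone). Gametes carrying a
#' null responder allele are inviable regardless of toxin (the responder
#' product itself is required for pollen function).
#'
#' @param toxin_locus,toxin_allele locus and allele whose sporophytic
#'   presence produces the toxin.
#' @param dicer_locus,dicer_competent locus whose alleles must be able to
#'   process the hairpin for toxin production; `NULL` to make toxin
#'   production unconditional.
#' @param antidote_groups list of groups; each group is a named list of
#'   per-locus efficacy vectors (`list(dcl2 = c(dcl2T = 1, Dcl2 = 0), ...)`).
#'   Within a group the efficacies multiply; across groups the maximum is
#'   taken. Every allele a gamete can carry at a group locus must appear in
#'   the table: a missing allele is an error, never a silent default.
#' @param responder optional list `list(locus=, sensitivity=)` where
#'   `sensitivity` maps alleles to `"sensitive"`, `"immune"` or `"null"`.
#'   Immune alleles contribute antidote efficacy 1 on their own; null
#'   alleles make the gamete inviable outright.
#' @param b background abortion probability in `[0, 1]`, applied
#'   independently to every gamete class.
#' @param competition list controlling male pollination competition:
#'   `enabled` (default TRUE) excludes from transmission any surviving
#'   gamete whose allele combination at `locus_pair` is non-parental;
#'   `coef`, if non-NULL, is instead a function(named allele vector) ->
#'   weight in \[0,1\] applied multiplicatively before renormalization.
#' @return an object of class `"viability_rules"`.
#' @export
viability_rules <- function(toxin_locus = "Tpd1", toxin_allele = "Tpd1",
                            dicer_locus = "dcl2",
                            dicer_competent = c("Dcl2", "dcl2T"),
                            antidote_groups = default_antidote_groups(),
                            responder = list(
                              locus = "Tdr1",
                              sensitivity = c(Tdr1 = "sensitive",
                                              Tdr1_del = "immune",
                                              tdr1_fs = "null")),
                            b = 0.0602,
                            competition = list(
                              enabled = TRUE,
                              locus_pair = c("dcl2", "Tpd1"),
                              coef = NULL)) {
  if (b < 0 || b > 1) stop("background abortion b must lie in [0, 1]")
  for (g in antidote_groups) {
    for (eff in g) {
      if (any(eff < 0 | eff > 1)) stop("antidote efficacies must lie in [0, 1]")
    }
  }
  structure(list(toxin_locus = toxin_locus, toxin_allele = toxin_allele,
                 dicer_locus = dicer_locus, dicer_competent = dicer_competent,
                 antidote_groups = antidote_groups, responder = responder,
                 b = b, competition = competition),
            class = "viability_rules")
}

#' Default antidote efficacy table
#'
#' Crisp (0/1) efficacies: survival requires a reduced-secondary-siRNA
#' Dicer allele together with the unlinked antidote, while an amplifier-null
#' allele rescues alone. Continuous overrides are permitted by editing the
#' returned list.
#'
#' @return list of antidote groups (see [viability_rules()]).
#' @export
default_antidote_groups <- function() {
  list(
    dicer_plus_unlinked = list(
      dcl2 = c(dcl2T = 1, dcl2_mu1 = 1, Dcl2 = 0),
      Tpd2 = c(Tpd2 = 1, tpd2 = 0)),
    amplifier_null = list(
      rgd1 = c(rgd1 = 1, Rgd1 = 0))
  )
}

#' The default teosinte pollen drive model
#'
#' Five-chromosome layout abstracting the mapped system: on chromosome 5 the
#' responder (`Tdr1`), the Dicer antidote locus (`dcl2`, 18.7 cM female
#' distance from the hairpin), the toxin hairpin (`Tpd1`, anchored inside a
#' 13-Mb paracentric inversion) and the endosperm marker `Bt1` (inside the
#' inversion); on chromosome 6 the unlinked antidote `Tpd2` and the marker
#' `y1` at recombination fraction 0.215; on chromosome 1 the amplifier
#' (`rgd1`).
#'
#' @param b background abortion rate (default 0.0602, the wild-type
#'   baseline).
#' @param r_dcl2_tpd1 female recombination fraction between `dcl2` and
#'   `Tpd1` (default 0.187).
#' @param competition enable the pollination-competition exclusion of
#'   toxin-interval recombinants among surviving pollen (default TRUE).
#' @return a `"drive_model"`.
#' @export
tpd_model <- function(b = 0.0602, r_dcl2_tpd1 = 0.187, competition = TRUE) {
  ## first allele of each locus = the wild-type/tester default
  loci <- rbind(
    locus_def("rgd1", "chr1", 50e6, "amplifier", c("Rgd1", "rgd1")),
    locus_def("Tdr1", "chr5", 15e6, "responder",
              c("Tdr1", "Tdr1_del", "tdr1_fs")),
    locus_def("dcl2", "chr5", 30e6, "antidote_primary",
              c("Dcl2", "dcl2T", "dcl2_mu1")),
    locus_def("Tpd1", "chr5", 118e6, "toxin", c("tpd1", "Tpd1")),
    locus_def("Bt1", "chr5", 122e6, "marker", c("bt1", "Bt1")),
    locus_def("y1", "chr6", 140e6, "marker", c("y1", "Y1")),
    locus_def("Tpd2", "chr6", 160e6, "antidote_unlinked", c("tpd2", "Tpd2")))
  r <- c("Tdr1:dcl2" = 0.10, "dcl2:Tpd1" = r_dcl2_tpd1, "Tpd1:Bt1" = 0.04,
         "y1:Tpd2" = 0.215)
  inv <- data.frame(chrom = "chr5", start = 115316812, end = 124884039,
                    tag_locus = "Tpd1", tag_allele = "Tpd1")
  rules <- viability_rules(b = b)
  rules$competition$enabled <- competition
  drive_model(loci, r, inversions = inv, rules = rules)
}

#' Build a haplotype for a model
#'
#' @param model a `"drive_model"`.
#' @param ... allele assignments by locus name (e.g. `Tpd1 = "Tpd1"`).
#'   Unspecified loci take the first (wild-type/reference) allele.
#' @return named character vector in map order, class `"haplotype"`.
#' @export
haplotype <- function(model, ...) {
  assign <- list(...)
  loci <- model$loci
  hap <- vapply(seq_len(nrow(loci)), function(i) {
    nm <- loci$name[i]
    a <- if (nm %in% names(assign)) assign[[nm]] else loci$alleles[[i]][1]
    if (!a %in% loci$alleles[[i]]) {
      stop("allele '", a, "' not defined for locus ", nm)
    }
    a
  }, character(1))
  names(hap) <- loci$name
  class(hap) <- "haplotype"
  hap
}

#' Pair two haplotypes into a diploid genotype
#'
#' @param hap1,hap2 haplotypes from [haplotype()] (same model).
#' @return list of class `"diploid"` with elements `hap1`, `hap2`.
#' @export
diploid <- function(hap1, hap2) {
  if (!identical(names(hap1), names(hap2))) {
    stop("haplotypes do not share locus order")
  }
  structure(list(hap1 = unclass(hap1), hap2 = unclass(hap2)),
            class = "diploid")
}

#' The canonical drive heterozygote (Tpd1-dcl2T/tpd1; Tpd2/tpd2)
#' @param model a `"drive_model"` (default [tpd_model()]).
#' @return a `"diploid"`.
#' @export
tpd_heterozygote <- function(model = tpd_model()) {
  drive_args <- list(Tpd1 = "Tpd1", dcl2 = "dcl2T", Tpd2 = "Tpd2",
                     Bt1 = "Bt1", y1 = "Y1")
  drive_args <- drive_args[names(drive_args) %in% model$loci$name]
  diploid(do.call(haplotype, c(list(model), drive_args)),
          haplotype(model))
}

#' A wild-type (all-reference) diploid
#' @param model a `"drive_model"` (default [tpd_model()]).
#' @return a `"diploid"`.
#' @export
wild_type <- function(model = tpd_model()) {
  diploid(haplotype(model), haplotype(model))
}

## Effective recombination fractions for a given sporophyte: inversion
## intervals drop to r = 0 when the parent is heterokaryotypic.
.effective_r <- function(parent, model) {
  r <- model$r_next
  inv <- model$inversions
  if (is.null(inv) || nrow(inv) == 0) return(r)
  loci <- model$loci
  for (k in seq_len(nrow(inv))) {
    tl <- inv$tag_locus[k]
    carried <- c(parent$hap1[[tl]], parent$hap2[[tl]]) == inv$tag_allele[k]
    if (sum(carried) != 1) next  # only heterokaryotypic sporophytes
    inside <- loci$chrom == inv$chrom[k] & loci$pos >= inv$start[k] &
      loci$pos <= inv$end[k]
    idx <- which(inside[-length(inside)] & inside[-1])  # interval i = (i, i+1)
    r[idx[!is.na(r[idx])]] <- 0
  }
  r
}

#' Generate the gamete distribution of a diploid parent
#'
#' In analytic mode all haplotype classes over heterozygous loci are
#' enumerated exactly (recombinant class frequencies follow the map's
#' effective recombination fractions; at most 12 heterozygous loci). In
#' simulation mode `n` meiotic products are drawn.
#'
#' @param parent a `"diploid"`.
#' @param model a `"drive_model"`.
#' @param n number of gametes to simulate; `NULL` (default) for analytic
#'   enumeration.
#' @param seed optional RNG seed for simulation mode.
#' @return a `"gamete_dist"`: data.frame of gamete classes (one column per
#'   locus) with `prob` (analytic) and/or `count` (simulated).
#' @export
make_gametes <- function(parent, model, n = NULL, seed = NULL) {
  loci <- model$loci
  if (!identical(names(parent$hap1), loci$name)) {
    stop("parent loci do not match model map")
  }
  r_eff <- .effective_r(parent, model)
  het <- which(parent$hap1 != parent$hap2)
  if (is.null(n)) {
    if (length(het) > 12) {
      stop("more than 12 heterozygous loci: use simulation mode (n = ...)")
    }
    gd <- .enumerate_gametes(parent, r_eff, het, loci)
  } else {
    if (!is.null(seed)) set.seed(seed)
    gd <- .simulate_gametes(parent, r_eff, n, loci)
  }
  class(gd) <- c("gamete_dist", "data.frame")
  gd
}

## Switch probability between consecutive heterozygous loci: probability of
## an odd number of crossovers across the intervening intervals.
.het_switch_probs <- function(r_eff, het, loci) {
  if (length(het) < 2) return(numeric())
  vapply(seq_len(length(het) - 1), function(j) {
    i0 <- het[j]; i1 <- het[j + 1]
    segs <- r_eff[i0:(i1 - 1)]
    if (anyNA(segs)) return(0.5)            # spans a chromosome boundary
    (1 - prod(1 - 2 * segs)) / 2
  }, numeric(1))
}

.enumerate_gametes <- function(parent, r_eff, het, loci) {
  nl <- nrow(loci)
  if (length(het) == 0) {
    out <- as.data.frame(as.list(parent$hap1), stringsAsFactors = FALSE)
    names(out) <- loci$name
    out$prob <- 1
    return(out)
  }
  sw <- .het_switch_probs(r_eff, het, loci)
  k <- length(het)
  choices <- as.matrix(expand.grid(rep(list(c(1L, 2L)), k)))
  probs <- apply(choices, 1, function(ch) {
    p <- 0.5
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        p <- p * if (ch[j + 1] != ch[j]) sw[j] else 1 - sw[j]
      }
    }
    p
  })
  alle <- matrix(rep(parent$hap1, each = nrow(choices)), nrow(choices), nl)
  for (j in seq_len(k)) {
    take2 <- choices[, j] == 2L
    alle[take2, het[j]] <- parent$hap2[[het[j]]]
  }
  out <- as.data.frame(alle, stringsAsFactors = FALSE)
  names(out) <- loci$name
  out$prob <- probs
  ## collapse identical classes (possible when alleles coincide)
  key <- do.call(paste, c(out[loci$name], sep = "\r"))
  if (anyDuplicated(key)) {
    agg <- rowsum(out$prob, key)
    out <- out[!duplicated(key), , drop = FALSE]
    out$prob <- agg[match(do.call(paste, c(out[loci$name], sep = "\r")),
                          rownames(agg)), 1]
  }
  rownames(out) <- NULL
  out
}

.simulate_gametes <- function(parent, r_eff, n, loci) {
  nl <- nrow(loci)
  ## haplotype index walk along the map; chromosome boundaries switch at 1/2
  p_switch <- ifelse(is.na(r_eff), 0.5, r_eff)[seq_len(max(nl - 1, 0))]
  sw <- matrix(stats::runif(n * (nl - 1)) < rep(p_switch, each = n), n, nl - 1)
  hapidx <- matrix(0L, n, nl)
  hapidx[, 1] <- as.integer(stats::runif(n) < 0.5)
  if (nl > 1) {
    for (i in 2:nl) hapidx[, i] <- (hapidx[, i - 1] + sw[, i - 1]) %% 2L
  }
  alle <- matrix("", n, nl)
  for (i in seq_len(nl)) {
    alle[, i] <- ifelse(hapidx[, i] == 0L, parent$hap1[[i]], parent$hap2[[i]])
  }
  key <- do.call(paste, c(as.data.frame(alle, stringsAsFactors = FALSE),
                          list(sep = "\r")))
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- loci$name
  out$count <- as.integer(tab)
  out$prob <- out$count / n
  rownames(out) <- NULL
  out
}

## --- viability -------------------------------------------------------------

.toxin_exposure <- function(sporophyte, rules) {
  tox <- any(c(sporophyte$hap1[[rules$toxin_locus]],
               sporophyte$hap2[[rules$toxin_locus]]) == rules$toxin_allele)
  if (!tox) return(0)
  if (!is.null(rules$dicer_locus)) {
    competent <- any(c(sporophyte$hap1[[rules$dicer_locus]],
                       sporophyte$hap2[[rules$dicer_locus]]) %in%
                       rules$dicer_competent)
    if (!competent) return(0)   # no functional Dicer: toxin not produced
  }
  1
}

## Combined antidote efficacy of one gamete's alleles: max over groups of
## the product of per-locus efficacies. Immune responder alleles count as a
## full antidote on their own.
.antidote_efficacy <- function(alleles, rules) {
  effs <- vapply(rules$antidote_groups, function(group) {
    if (!all(names(group) %in% names(alleles))) return(0)  # group inapplicable
    prod(vapply(names(group), function(loc) {
      a <- alleles[[loc]]
      tab <- group[[loc]]
      if (!a %in% names(tab)) {
        stop("allele '", a, "' at locus ", loc,
             " missing from antidote efficacy table")
      }
      tab[[a]]
    }, numeric(1)))
  }, numeric(1))
  resp <- rules$responder
  if (!is.null(resp) && resp$locus %in% names(alleles)) {
    a <- alleles[[resp$locus]]
    if (!a %in% names(resp$sensitivity)) {
      stop("allele '", a, "' missing from responder sensitivity map")
    }
    if (resp$sensitivity[[a]] == "immune") effs <- c(effs, 1)
  }
  max(c(effs, 0))
}

.responder_null <- function(alleles, rules) {
  resp <- rules$responder
  if (is.null(resp) || !resp$locus %in% names(alleles)) return(FALSE)
  identical(resp$sensitivity[[alleles[[resp$locus]]]], "null")
}

#' Apply toxin/antidote viability to a gamete distribution
#'
#' Adds per-class `survival` (the probability `(1 - T (1 - A)) (1 - b)`,
#' zeroed for responder-null gametes) and `viable_prob`
#' (`prob * survival`, renormalized to the meiotic total, i.e. summing to
#' the surviving fraction). In simulated mode survivors are drawn
#' binomially per class.
#'
#' @param gametes a `"gamete_dist"` from [make_gametes()].
#' @param sporophyte the parent `"diploid"` (determines toxin exposure).
#' @param model a `"drive_model"` (its `rules` are used unless overridden).
#' @param rules optional `"viability_rules"` override.
#' @param seed optional RNG seed (simulated mode).
#' @return the distribution with `survival`, `viable_prob` and (simulated)
#'   `viable_count` columns; attribute `viable_fraction`.
#' @export
apply_viability <- function(gametes, sporophyte, model, rules = NULL,
                            seed = NULL) {
  rules <- rules %||% model$rules
  loci <- model$loci$name
  T_exp <- .toxin_exposure(sporophyte, rules)
  surv <- vapply(seq_len(nrow(gametes)), function(i) {
    alleles <- as.list(gametes[i, loci, drop = FALSE])
    alleles <- stats::setNames(as.character(unlist(alleles)), loci)
    if (.responder_null(alleles, rules)) return(0)
    A <- .antidote_efficacy(alleles, rules)
    (1 - T_exp * (1 - A)) * (1 - rules$b)
  }, numeric(1))
  gametes$survival <- surv
  gametes$viable_prob <- gametes$prob * surv
  if ("count" %in% names(gametes)) {
    if (!is.null(seed)) set.seed(seed)
    gametes$viable_count <- stats::rbinom(nrow(gametes), gametes$count, surv)
    attr(gametes, "viable_fraction") <-
      sum(gametes$viable_count) / sum(gametes$count)
  } else {
    attr(gametes, "viable_fraction") <- sum(gametes$viable_prob)
  }
  gametes
}

#' Transmit gametes to the next generation
#'
#' Female transmission passes all meiotic products unchanged (the toxin does
#' not act through the female side). Male transmission keeps survivors only,
#' removes pollination-competition-excluded classes (by default, gametes
#' whose allele pair at the toxin-interval loci is non-parental), and
#' renormalizes.
#'
#' @param gametes for `sex = "male"`, a distribution that has been through
#'   [apply_viability()]; for `"female"`, any gamete distribution.
#' @param sporophyte the parent `"diploid"` (defines the parental allele
#'   combinations for the competition rule).
#' @param model a `"drive_model"`.
#' @param sex `"male"` or `"female"`.
#' @param rules optional `"viability_rules"` override.
#' @return a `"gamete_dist"` with `prob` summing to 1.
#' @export
transmit <- function(gametes, sporophyte, model, sex = c("male", "female"),
                     rules = NULL) {
  sex <- match.arg(sex)
  rules <- rules %||% model$rules
  loci <- model$loci$name
  if (sex == "female") {
    out <- gametes[, c(loci, "prob"), drop = FALSE]
    class(out) <- c("gamete_dist", "data.frame")
    return(out)
  }
  if (!"viable_prob" %in% names(gametes)) {
    stop("male transmission requires apply_viability() first")
  }
  w <- if ("viable_count" %in% names(gametes)) {
    gametes$viable_count
  } else gametes$viable_prob
  comp <- rules$competition
  if (isTRUE(comp$enabled) && is.null(comp$coef)) {
    pair <- comp$locus_pair
    if (all(pair %in% loci)) {
      parental <- c(paste(sporophyte$hap1[[pair[1]]], sporophyte$hap1[[pair[2]]]),
                    paste(sporophyte$hap2[[pair[1]]], sporophyte$hap2[[pair[2]]]))
      combo <- paste(gametes[[pair[1]]], gametes[[pair[2]]])
      w[!combo %in% parental] <- 0
    }
  } else if (!is.null(comp$coef)) {
    cf <- vapply(seq_len(nrow(gametes)), function(i) {
      comp$coef(stats::setNames(as.character(unlist(gametes[i, loci])), loci))
    }, numeric(1))
    w <- w * cf
  }
  if (sum(w) <= 0) stop("no transmissible gametes")
  out <- gametes[w > 0, loci, drop = FALSE]
  out$prob <- w[w > 0] / sum(w)
  rownames(out) <- NULL
  class(out) <- c("gamete_dist", "data.frame")
  out
}

#' Simulate a cross and classify progeny phenotypes
#'
#' Maternal gametes are meiotic products (all transmitted); paternal gametes
#' pass through viability and pollination competition. Each progeny's
#' phenotype class is assigned from the viability rules applied to its own
#' future pollen: `fertile` when it produces no toxin or its pollen is
#' essentially fully viable, `sterile` when (almost) no pollen survives,
#' `semi_sterile` (the drive class) otherwise. Background abortion is
#' ignored for classification.
#'
#' @param mother,father `"diploid"` parents.
#' @param model a `"drive_model"`.
#' @param n_progeny number of progeny (>= 1).
#' @param seed optional RNG seed.
#' @param fertile_min,sterile_max viable-pollen-fraction thresholds for the
#'   fertile (>=) and sterile (<=) classes.
#' @return data.frame with one row per progeny: maternal and paternal
#'   alleles per locus (`<locus>_mat`, `<locus>_pat`) and `phenotype`.
#' @export
simulate_cross <- function(mother, father, model, n_progeny, seed = NULL,
                           fertile_min = 0.9, sterile_max = 0.05) {
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  if (!identical(names(mother$hap1), names(father$hap1))) {
    stop("incompatible parent maps")
  }
  if (!is.null(seed)) set.seed(seed)
  loci <- model$loci$name
  mg <- transmit(make_gametes(mother, model), mother, model, "female")
  pg_raw <- apply_viability(make_gametes(father, model), father, model)
  pg <- transmit(pg_raw, father, model, "male")
  mi <- sample.int(nrow(mg), n_progeny, replace = TRUE, prob = mg$prob)
  pi <- sample.int(nrow(pg), n_progeny, replace = TRUE, prob = pg$prob)
  mat <- mg[mi, loci, drop = FALSE]
  pat <- pg[pi, loci, drop = FALSE]
  names(mat) <- paste0(loci, "_mat")
  names(pat) <- paste0(loci, "_pat")
  out <- cbind(mat, pat)
  rownames(out) <- NULL
  ## classify per distinct progeny genotype (cache: analytic pollen fraction)
  key <- paste(do.call(paste, c(mat, sep = "|")),
               do.call(paste, c(pat, sep = "|")), sep = "||")
  uk <- !duplicated(key)
  pheno_map <- vapply(which(uk), function(i) {
    h1 <- stats::setNames(as.character(unlist(mat[i, ])), loci)
    h2 <- stats::setNames(as.character(unlist(pat[i, ])), loci)
    .classify_phenotype(diploid(structure(h1, class = "haplotype"),
                                structure(h2, class = "haplotype")),
                        model, fertile_min, sterile_max)
  }, character(1))
  names(pheno_map) <- key[uk]
  out$phenotype <- unname(pheno_map[key])
  out
}

.classify_phenotype <- function(geno, model, fertile_min, sterile_max) {
  rules <- model$rules
  rules$b <- 0   # background abortion plays no part in phenotype classes
  if (.toxin_exposure(geno, rules) == 0) return("fertile")
  g <- make_gametes(geno, model)
  v <- attr(apply_viability(g, geno, model, rules = rules), "viable_fraction")
  if (v >= fertile_min) "fertile" else if (v <= sterile_max) "sterile"
  else "semi_sterile"
}

#' Transmitted allele frequencies at a marker locus
#'
#' @param cross progeny table from [simulate_cross()].
#' @param locus locus name.
#' @param parent which transmitted allele to tabulate: `"father"`,
#'   `"mother"`, or `"both"`.
#' @return named numeric vector of allele frequencies.
#' @export
marker_transmission <- function(cross, locus, parent = c("father", "mother",
                                                         "both")) {
  parent <- match.arg(parent)
  cols <- switch(parent,
                 father = paste0(locus, "_pat"),
                 mother = paste0(locus, "_mat"),
                 both = paste0(locus, c("_mat", "_pat")))
  if (!all(cols %in% names(cross))) stop("locus not present in cross result: ",
                                         locus)
  al <- unlist(cross[cols], use.names = FALSE)
  tab <- table(al)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}
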