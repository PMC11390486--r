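## Readers/writers for the standard formats the pipeline touches.
##
## Internal coordinate convention: everything is 0-based half-open.
## VCF (1-based) and GFF3 (1-based closed) are converted at the boundary and
## converted back on write, so round trips are lossless.

#' Construct a table of genomic intervals
#'
#' Light-weight validated container used throughout the package: a
#' `data.frame` with columns `chrom`, `start`, `end`, `strand` (0-based,
#' half-open) plus any extra columns passed through.
#'
#' @param chrom character vector of chromosome/sequence names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand one of `"+"`, `"-"`, `"."` per interval (recycled).
#' @param ... further equal-length columns (e.g. `score`, `name`).
#' @return a `data.frame` of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  strand <- rep_len(as.character(strand), length(chrom))
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, ...)
}

#' Define a biallelic marker panel
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (as in VCF).
#' @param ref,alt reference and alternate allele strings (`ref != alt`).
#' @param id optional marker identifiers (default `chrom_pos`).
#' @return data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
marker_panel <- function(chrom, pos, ref, alt, id = NULL) {
  pos <- as.numeric(pos)
  if (any(pos < 1)) stop("marker pos is 1-based and must be >= 1")
  if (any(ref == alt)) stop("marker ref and alt alleles must differ")
  if (is.null(id)) id <- paste0(chrom, "_", pos)
  data.frame(id = id, chrom = as.character(chrom), pos = pos,
             ref = as.character(ref), alt = as.character(alt))
}

#' Read genotype calls from a VCF at a fixed set of marker sites
#'
#' Parses a VCF (plain text or bgzipped) and returns one row per
#' sample x retained marker with the genotype collapsed to
#' `"ref"`/`"alt"`/`"het"`/`"missing"`. Only biallelic records whose
#' `(chrom, pos)` is present in `markers` are kept; multi-allelic sites are
#' skipped with a warning giving the count.
#'
#' @param path VCF file path.
#' @param markers marker panel from [marker_panel()].
#' @return data.frame with columns `sample`, `marker`, `chrom`, `pos`,
#'   `call`, `depth` (NA when the VCF carries no DP format field).
#' @export
read_vcf_calls <- function(path, markers) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(sample = character(), marker = character(),
                      chrom = character(), pos = numeric(),
                      call = character(), depth = numeric()))
  }
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
  }
  key <- paste0(fix$CHROM, ":", fix$POS)
  mkey <- paste0(markers$chrom, ":", markers$pos)
  keep <- !multi & key %in% mkey
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(sample = character(), marker = character(),
                      chrom = character(), pos = numeric(),
                      call = character(), depth = numeric()))
  }
  samples <- colnames(gt)
  marker_id <- markers$id[match(key[idx], mkey)]
  out <- expand.grid(sample = samples, row = seq_along(idx),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- gt[idx, , drop = FALSE]
  calls <- vapply(seq_len(nrow(out)), function(i) {
    .gt_to_call(g[out$row[i], out$sample[i]])
  }, character(1))
  depth <- rep(NA_real_, nrow(out))
  if (!is.null(dp)) {
    d <- dp[idx, , drop = FALSE]
    depth <- vapply(seq_len(nrow(out)),
                    function(i) as.numeric(d[out$row[i], out$sample[i]]),
                    numeric(1))
  }
  data.frame(sample = out$sample,
             marker = marker_id[out$row],
             chrom = fix$CHROM[idx][out$row],
             pos = as.numeric(fix$POS[idx])[out$row],
             call = calls,
             depth = depth)
}

.gt_to_call <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  al <- strsplit(gt, "[/|]")[[1]]
  al <- al[al != "."]
  if (length(al) == 0) return("missing")
  if (all(al == "0")) return("ref")
  if (all(al == "1")) return("alt")
  "het"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write haploid genotype calls as a minimal VCF
#'
#' @param calls matrix of haploid calls coded 1 (alt), -1 (ref), 0 (missing);
#'   rows are markers (in `markers` order), columns are samples.
#' @param markers marker panel ([marker_panel()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_haploid <- function(calls, markers, path) {
  stopifnot(nrow(calls) == nrow(markers))
  samples <- colnames(calls)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  gt <- matrix(".", nrow(calls), ncol(calls))
  gt[calls == 1] <- "1"
  gt[calls == -1] <- "0"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(markers$chrom, markers$pos, markers$id, markers$ref,
                markers$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED track (3-6 columns) as 0-based half-open intervals
#'
#' Records with `start >= end` abort with an error naming the line number.
#'
#' @param path BED file path.
#' @return interval data.frame with `chrom`, `start`, `end`, `strand` and,
#'   when present, `name` and `score`.
#' @export
read_bed_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  }
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line ", which(nf < 3)[1], " has fewer than 3 fields")
  start <- as.numeric(vapply(fields, `[`, "", 2))
  end <- as.numeric(vapply(fields, `[`, "", 3))
  bad <- which(!(start < end))
  if (length(bad)) stop("BED line ", bad[1], ": start >= end")
  out <- data.frame(chrom = vapply(fields, `[`, "", 1), start = start,
                    end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(fields, `[`, "", 4)
  if (all(nf >= 5)) {
    sc <- vapply(fields, `[`, "", 5)
    out$score <- suppressWarnings(as.numeric(ifelse(sc == ".", NA, sc)))
  }
  out$strand <- if (all(nf >= 6)) {
    s <- vapply(fields, `[`, "", 6)
    ifelse(s %in% c("+", "-"), s, ".")
  } else "."
  out
}

#' Write intervals as BED
#'
#' @param x interval data.frame (0-based half-open) with optional `name`,
#'   `score` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), ".", x$score) else "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  writeLines(paste(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   name, score, strand, sep = "\t"), path)
  invisible(path)
}

#' Read features from a GFF3 file
#'
#' Coordinates are converted from GFF3 1-based closed to internal 0-based
#' half-open. Feature classification is taken from the `ID`/`Name` and
#' `classification` attributes when present.
#'
#' @param path GFF3 file path.
#' @param feature_types character vector of `type` values to keep (e.g.
#'   `c("gene", "transposable_element")`). Requesting only absent types
#'   returns an empty table with a warning.
#' @return interval data.frame with `type`, `ID` and `classification` columns.
#' @export
read_gff3_features <- function(path, feature_types) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- df$type %in% feature_types
  if (!any(keep)) {
    warning("no features of requested type(s) found: ",
            paste(feature_types, collapse = ", "))
  }
  df <- df[keep, , drop = FALSE]
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1, end = df$end,
                    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                                    as.character(df$strand), "."),
                    type = as.character(df$type))
  out$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  out$classification <- if ("classification" %in% names(df)) {
    as.character(df$classification)
  } else out$type
  rownames(out) <- NULL
  out
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; with `rna_to_dna = TRUE` any `U` is rewritten to
#' `T` so RNA and DNA inputs share one alphabet.
#'
#' @param path FASTA file path.
#' @param rna_to_dna replace U with T (default TRUE).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, rna_to_dna = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (rna_to_dna) seqs <- chartr("U", "T", seqs)
  names(seqs) <- nm
  seqs
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a table as TSV with '#'-prefixed header comment lines
#'
#' @param x data.frame.
#' @param path output path.
#' @param comments character vector of comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_commented <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
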