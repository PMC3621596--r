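# Codon-level annotation of SNVs against intronless gene models: coding vs
# promoter-proximal (upstream) classification, codon arithmetic, and
# verification of reported amino-acid changes against the standard genetic
# code by exhaustive codon enumeration.

# Standard nuclear genetic code, codon -> one-letter amino acid ('*' stop).
# Cross-checked in the test suite against Biostrings::GENETIC_CODE.
standard_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  # amino acids in TCAG x TCAG x TCAG order (first base slowest,
  # third fastest)
  aa <- unlist(strsplit(paste0(
    "FFLLSSSSYY**CC*W", # TTT..TGG
    "LLLLPPPPHHQQRRRR", # CTT..CGG
    "IIIMTTTTNNKKSSRR", # ATT..AGG
    "VVVVAAAADDEEGGGG"  # GTT..GGG
  ), ""))
  codons <- character(64)
  idx <- 1L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons[idx] <- paste0(b1, b2, b3)
    idx <- idx + 1L
  }
  stats::setNames(aa, codons)
}

GENETIC_CODE_TABLE <- standard_genetic_code()

#' Codon number and within-codon offset of a coding position
#'
#' For an intronless open reading frame, coding nucleotide `cds_pos`
#' (1-based) lies in codon `ceiling(cds_pos / 3)` at offset
#' `((cds_pos - 1) %% 3) + 1` (1, 2 or 3). So codon `n` occupies coding
#' positions `3n - 2 ... 3n`.
#'
#' @param cds_pos 1-based position(s) within the coding sequence.
#' @return data frame with columns `codon_no` and `codon_offset`.
#' @examples
#' codon_index(1518) # codon 506, offset 3
#' @export
codon_index <- function(cds_pos) {
  check_that(all(cds_pos >= 1), "cds_pos must be >= 1")
  cds_pos <- as.integer(cds_pos)
  data.frame(codon_no = as.integer(ceiling(cds_pos / 3)),
             codon_offset = as.integer((cds_pos - 1L) %% 3L + 1L))
}

#' Check a nucleotide change against a reported amino-acid change
#'
#' Verifies, by exhaustive enumeration over the 64 codons of the standard
#' genetic code, whether a single-nucleotide substitution at coding position
#' `cds_pos` is compatible with the reported amino-acid change. The verdict
#' is `position_mismatch` when the codon containing `cds_pos` differs from
#' the reported codon number; otherwise `consistent` when there exists a
#' codon that (a) encodes the reported reference amino acid, (b) carries the
#' reference base at the computed within-codon offset, and (c) encodes the
#' reported alternate amino acid after the substitution; else `inconsistent`.
#'
#' "Consistent" therefore means compatible-with-some-codon: without the
#' reference sequence the true codon is unknown, and the check is an
#' existence statement, not a proof.
#'
#' @param ref_base,alt_base reference and alternate bases (A/C/G/T).
#' @param cds_pos 1-based coding position of the substitution.
#' @param ref_aa,alt_aa reported one-letter amino acids (`*` for stop).
#' @param aa_pos reported 1-based codon (residue) number.
#' @param code named codon table (default: standard nuclear genetic code).
#' @return one of `"consistent"`, `"inconsistent"`, `"position_mismatch"`.
#' @examples
#' consistency_check("G", "C", 1518, "K", "N", 506) # consistent (AAG -> AAC)
#' @export
consistency_check <- function(ref_base, alt_base, cds_pos, ref_aa, alt_aa,
                              aa_pos, code = GENETIC_CODE_TABLE) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  check_that(ref_base %in% c("A", "C", "G", "T") &&
               alt_base %in% c("A", "C", "G", "T"),
             "ref_base and alt_base must be one of A, C, G, T")
  check_that(ref_base != alt_base, "ref and alt bases must differ")
  aa_ok <- c(unique(unname(code)), "*")
  if (!(ref_aa %in% aa_ok) || !(alt_aa %in% aa_ok)) {
    stop("unknown amino-acid symbol: ", ref_aa, " or ", alt_aa,
         call. = FALSE)
  }
  ci <- codon_index(cds_pos)
  if (ci$codon_no != aa_pos) {
    return("position_mismatch")
  }
  offset <- ci$codon_offset
  candidates <- names(code)[code == ref_aa]
  for (codon in candidates) {
    if (substr(codon, offset, offset) != ref_base) next
    mutated <- codon
    substr(mutated, offset, offset) <- alt_base
    if (code[[mutated]] == alt_aa) {
      return("consistent")
    }
  }
  "inconsistent"
}

#' Construct a gene-model table
#'
#' Minimal intronless gene models: one CDS interval per gene with strand.
#'
#' @param gene gene symbols.
#' @param chrom chromosome ids.
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end 1-based inclusive CDS bounds
#'   (`cds_start <= cds_end` in genomic coordinates, either strand).
#' @param upstream_window promoter-proximal window in bp (default 1000,
#'   recycled).
#' @return data frame of class `gene_models`.
#' @export
gene_models <- function(gene, chrom, strand, cds_start, cds_end,
                        upstream_window = 1000) {
  check_that(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  check_that(all(cds_start <= cds_end), "cds_start must be <= cds_end")
  df <- data.frame(gene = as.character(gene), chrom = as.character(chrom),
                   strand = as.character(strand),
                   cds_start = as.integer(cds_start),
                   cds_end = as.integer(cds_end),
                   upstream_window = rep_len(as.integer(upstream_window),
                                             length(gene)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

revcomp_base <- function(b) {
  stats::setNames(c("T", "G", "C", "A"), c("A", "C", "G", "T"))[toupper(b)]
}

# genomic position -> cds position for one model (NA when outside CDS)
genomic_to_cds <- function(pos, model) {
  if (pos < model$cds_start || pos > model$cds_end) return(NA_integer_)
  if (model$strand == "+") {
    as.integer(pos - model$cds_start + 1L)
  } else {
    as.integer(model$cds_end - pos + 1L)
  }
}

# cds position -> genomic position (inverse of genomic_to_cds)
cds_to_genomic <- function(cds_pos, model) {
  if (model$strand == "+") {
    as.integer(model$cds_start + cds_pos - 1L)
  } else {
    as.integer(model$cds_end - cds_pos + 1L)
  }
}

# upstream distance of a genomic position 5' of the start codon; NA if not
# within the window. Distance 1 = base immediately 5' of the A of ATG.
upstream_distance <- function(pos, model) {
  if (model$strand == "+") {
    d <- model$cds_start - pos
  } else {
    d <- pos - model$cds_end
  }
  if (d >= 1 && d <= model$upstream_window) as.integer(d) else NA_integer_
}

#' Classify variant calls against gene models
#'
#' Each call is classified as `coding` when its position falls inside a CDS
#' (converted to a coding position respecting strand, with ref/alt
#' reverse-complemented on minus-strand models), `upstream` when it lies
#' within the promoter-proximal window 5' of a start codon (distance 1 is
#' the base immediately 5' of the ATG), and `intergenic` otherwise. A call
#' overlapping several models is annotated against each and flagged
#' ambiguous.
#'
#' @param calls a [variant_calls()] table.
#' @param models a [gene_models()] table on the same reference coordinates.
#' @return data frame with one row per (call, matching model) — or a single
#'   `intergenic` row for unmatched calls — with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `location_class`, `cds_pos`, `codon_no`,
#'   `codon_offset`, `cds_ref`, `cds_alt`, `upstream_distance`, `ambiguous`.
#' @export
classify_location <- function(calls, models) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    matched <- list()
    for (j in seq_len(nrow(models))) {
      model <- models[j, ]
      if (model$chrom != call$chrom) next
      cds_pos <- genomic_to_cds(call$pos, model)
      if (!is.na(cds_pos)) {
        if (model$strand == "+") {
          cr <- call$ref; ca <- call$alt
        } else {
          cr <- revcomp_base(call$ref); ca <- revcomp_base(call$alt)
        }
        ci <- codon_index(cds_pos)
        matched[[length(matched) + 1L]] <- data.frame(
          chrom = call$chrom, pos = call$pos, ref = call$ref,
          alt = call$alt, gene = model$gene, location_class = "coding",
          cds_pos = cds_pos, codon_no = ci$codon_no,
          codon_offset = ci$codon_offset, cds_ref = unname(cr),
          cds_alt = unname(ca), upstream_distance = NA_integer_,
          stringsAsFactors = FALSE)
        next
      }
      d <- upstream_distance(call$pos, model)
      if (!is.na(d)) {
        matched[[length(matched) + 1L]] <- data.frame(
          chrom = call$chrom, pos = call$pos, ref = call$ref,
          alt = call$alt, gene = model$gene, location_class = "upstream",
          cds_pos = NA_integer_, codon_no = NA_integer_,
          codon_offset = NA_integer_, cds_ref = NA_character_,
          cds_alt = NA_character_, upstream_distance = d,
          stringsAsFactors = FALSE)
      }
    }
    if (length(matched) == 0) {
      matched[[1L]] <- data.frame(
        chrom = call$chrom, pos = call$pos, ref = call$ref, alt = call$alt,
        gene = NA_character_, location_class = "intergenic",
        cds_pos = NA_integer_, codon_no = NA_integer_,
        codon_offset = NA_integer_, cds_ref = NA_character_,
        cds_alt = NA_character_, upstream_distance = NA_integer_,
        stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, matched)
    block$ambiguous <- nrow(block) > 1L
    rows[[length(rows) + 1L]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count coding vs non-coding annotated variants
#'
#' @param annotated output of [classify_location()], optionally with a
#'   `strain` column.
#' @param strain optional strain id to filter on.
#' @return named integer vector `c(n_coding, n_noncoding)`.
#' @export
count_by_class <- function(annotated, strain = NULL) {
  if (!is.null(strain)) {
    check_that("strain" %in% names(annotated),
               "annotated variants lack a strain column")
    annotated <- annotated[annotated$strain == strain, , drop = FALSE]
  }
  n_coding <- sum(annotated$location_class == "coding")
  c(n_coding = n_coding, n_noncoding = nrow(annotated) - n_coding)
}
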