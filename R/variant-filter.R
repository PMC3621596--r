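# Post-calling SNV filter chain: indel exclusion, ambiguous-base removal,
# quality and depth thresholds, and allele-aware subtraction of variants
# shared with the non-evolved parental strain.

#' Construct a variant call table
#'
#' Normalizes a data frame of variant calls. Multi-allelic records (comma
#' in `alt`) are split into one row per alternate allele before any
#' filtering.
#'
#' @param chrom chromosome ids.
#' @param pos 1-based positions.
#' @param ref reference allele strings.
#' @param alt alternate allele strings (may contain commas).
#' @param qual Phred-scaled variant qualities (probability the call is
#'   wrong is `10^(-qual/10)`).
#' @param depth read depths covering the site.
#' @param id optional record ids.
#' @return data frame of class `variant_calls` with one row per allele.
#' @export
variant_calls <- function(chrom, pos, ref, alt, qual, depth,
                          id = NA_character_) {
  n <- length(pos)
  check_that(all(lengths(list(chrom, ref, alt, qual, depth)) == n),
             "all fields must have the same length")
  check_that(all(pos >= 1), "pos must be >= 1")
  check_that(all(qual >= 0), "qual must be >= 0")
  check_that(all(depth >= 0), "depth must be >= 0")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   id = rep_len(as.character(id), n),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   qual = as.numeric(qual), depth = as.integer(depth),
                   stringsAsFactors = FALSE)
  # split multi-allelic rows
  multi <- grepl(",", df$alt, fixed = TRUE)
  if (any(multi)) {
    pieces <- strsplit(df$alt, ",", fixed = TRUE)
    df <- df[rep(seq_len(nrow(df)), lengths(pieces)), , drop = FALSE]
    df$alt <- unlist(pieces)
  }
  rownames(df) <- NULL
  class(df) <- c("variant_calls", "data.frame")
  df
}

filter_config_default <- function() {
  filter_config()
}

#' Filter-chain configuration
#'
#' @param min_qual minimum Phred variant quality kept (default 20;
#'   the boundary is inclusive: "at least 20").
#' @param min_depth minimum read depth kept, inclusive (default 10; calls
#'   with depth below 10 are discarded).
#' @param max_depth maximum read depth kept, inclusive (default 400,
#'   mirroring a 400x read-depth cap).
#' @param allowed_bases unambiguous base alphabet (default A, C, G, T).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 20, min_depth = 10, max_depth = 400,
                          allowed_bases = c("A", "C", "G", "T")) {
  check_that(is_number(min_qual) && min_qual >= 0, "min_qual must be >= 0")
  check_that(is_number(min_depth) && is_number(max_depth) &&
               min_depth <= max_depth,
             "min_depth must not exceed max_depth")
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_depth = max_depth,
                 allowed_bases = toupper(allowed_bases)),
            class = "filter_config")
}

# per-rule predicates: TRUE = the call passes the rule --------------------

passes_snv <- function(calls, config) {
  nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
}

passes_ambiguous <- function(calls, config) {
  ok <- config$allowed_bases
  toupper(calls$ref) %in% ok & toupper(calls$alt) %in% ok
}

passes_quality <- function(calls, config) {
  calls$qual >= config$min_qual
}

passes_depth <- function(calls, config) {
  calls$depth >= config$min_depth & calls$depth <= config$max_depth
}

allele_key <- function(calls) {
  paste(calls$chrom, calls$pos, toupper(calls$ref), toupper(calls$alt),
        sep = ":")
}

#' Remove calls with ambiguous bases
#'
#' A call is kept iff both `ref` and `alt` are non-empty strings over the
#' unambiguous alphabet {A, C, G, T} (case-insensitive); IUPAC ambiguity
#' codes such as N or R are removed.
#'
#' @param calls a [variant_calls()] table.
#' @param config a [filter_config()].
#' @return list with elements `kept` and `removed`.
#' @export
filter_ambiguous <- function(calls, config = filter_config()) {
  keep <- passes_ambiguous(calls, config)
  list(kept = calls[keep, , drop = FALSE],
       removed = calls[!keep, , drop = FALSE])
}

#' Apply quality and depth thresholds
#'
#' A call is kept iff `qual >= min_qual` and
#' `min_depth <= depth <= max_depth`; all boundaries inclusive.
#'
#' @inheritParams filter_ambiguous
#' @return list with elements `kept` and `removed`.
#' @export
filter_thresholds <- function(calls, config = filter_config()) {
  keep <- passes_quality(calls, config) & passes_depth(calls, config)
  list(kept = calls[keep, , drop = FALSE],
       removed = calls[!keep, , drop = FALSE])
}

#' Subtract variants shared with the parental strain
#'
#' A call is removed iff a parental call matches on
#' `(chrom, pos, ref, alt)` — the subtraction is allele-aware, so a
#' genuinely different allele at a site that is also variant in the parent
#' is retained. If the two call sets share no chromosome names a
#' coordinate-system mismatch warning is raised.
#'
#' @param calls evolved-strain [variant_calls()].
#' @param parental_calls parental-strain [variant_calls()] on the same
#'   reference coordinates.
#' @return list with elements `kept` and `removed`.
#' @export
subtract_parental <- function(calls, parental_calls) {
  if (nrow(parental_calls) == 0 || nrow(calls) == 0) {
    return(list(kept = calls, removed = calls[0, , drop = FALSE]))
  }
  if (length(intersect(unique(calls$chrom),
                       unique(parental_calls$chrom))) == 0) {
    warning("evolved and parental call sets share no chromosome names; ",
            "possible coordinate-system mismatch", call. = FALSE)
  }
  shared <- allele_key(calls) %in% allele_key(parental_calls)
  list(kept = calls[!shared, , drop = FALSE],
       removed = calls[shared, , drop = FALSE])
}

#' Run the full SNV filter chain
#'
#' Applies, in canonical order: indel exclusion (non-single-base alleles,
#' flagged with a distinct provenance tag), (i) ambiguous-base removal,
#' (ii) quality threshold, (iii) depth window, (iv) allele-aware parental
#' subtraction. Every removed call is tagged with the first rule it fails
#' under this order; survivors are sorted by `(chrom, pos)`.
#'
#' @param calls evolved-strain [variant_calls()].
#' @param parental parental-strain [variant_calls()] (may be empty).
#' @param config a [filter_config()].
#' @return list of class `filter_report`: `survivors`, `removed` (with a
#'   `rule` column), `counts` (named removal counts incl. `survivors`),
#'   `n_input`.
#' @export
run_filter_chain <- function(calls, parental = NULL,
                             config = filter_config()) {
  if (is.null(parental)) {
    parental <- calls[0, , drop = FALSE]
  }
  n_input <- nrow(calls)
  rule <- rep(NA_character_, n_input)

  fail_indel <- !passes_snv(calls, config)
  fail_ambig <- !passes_ambiguous(calls, config)
  fail_qual <- !passes_quality(calls, config)
  fail_depth <- !passes_depth(calls, config)
  fail_parent <- if (nrow(parental) > 0) {
    allele_key(calls) %in% allele_key(parental)
  } else {
    rep(FALSE, n_input)
  }

  # first-failing rule under the canonical order
  rule[fail_parent] <- "parental_shared"
  rule[fail_depth] <- "depth"
  rule[fail_qual] <- "quality"
  rule[fail_ambig] <- "ambiguous_base"
  rule[fail_indel] <- "indel"

  keep <- is.na(rule)
  survivors <- calls[keep, , drop = FALSE]
  survivors <- survivors[order(survivors$chrom, survivors$pos), ,
                         drop = FALSE]
  rownames(survivors) <- NULL
  removed <- calls[!keep, , drop = FALSE]
  removed$rule <- rule[!keep]
  rownames(removed) <- NULL

  rules <- c("indel", "ambiguous_base", "quality", "depth",
             "parental_shared")
  counts <- vapply(rules, function(r) sum(removed$rule == r), integer(1))
  counts <- c(counts, survivors = nrow(survivors))

  structure(list(survivors = survivors, removed = removed,
                 counts = counts, n_input = n_input,
                 config = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("SNV filter chain: %d calls in, %d survivors\n",
              x$n_input, nrow(x$survivors)))
  for (r in setdiff(names(x$counts), "survivors")) {
    cat(sprintf("  removed by %-16s: %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}
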