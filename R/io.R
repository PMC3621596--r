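# Readers and writers for the interchange formats: minimal VCF v4 for
# variant payloads, tab-separated dialects for everything else (header row,
# '#' comments), an OBO-lite ontology subset, and YAML pipeline configs.
# Readers reject rather than guess: malformed lines are collected into an
# error report attached to the result.

#' Read a minimal VCF v4 file
#'
#' Parses the eight fixed VCF columns, taking the Phred variant quality
#' from QUAL and the read depth from the `DP=` key of INFO. Multi-allelic
#' records are split into one call per ALT allele. Malformed data lines
#' (wrong column count, non-numeric POS/QUAL, missing DP) are not silently
#' dropped: they are collected into the `errors` attribute of the result
#' (a data frame of line numbers and messages).
#'
#' @param path file path.
#' @return a [variant_calls()] table with attribute `errors`.
#' @export
read_vcf_min <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^#CHROM\\t", lines))) {
    stop("not a VCF file: missing #CHROM header line", call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  errors <- list()
  rows <- list()
  for (ln in seq_along(body)) {
    f <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      errors[[length(errors) + 1L]] <-
        data.frame(line = ln, message = "fewer than 8 columns",
                   stringsAsFactors = FALSE)
      next
    }
    pos <- suppressWarnings(as.integer(f[2]))
    qual <- suppressWarnings(as.numeric(f[6]))
    dp <- regmatches(f[8], regexpr("(?<=^DP=|;DP=)[0-9]+", f[8],
                                   perl = TRUE))
    if (is.na(pos) || is.na(qual) || length(dp) == 0) {
      errors[[length(errors) + 1L]] <-
        data.frame(line = ln,
                   message = "non-numeric POS/QUAL or missing INFO DP",
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1], pos = pos, id = f[3], ref = f[4], alt = f[5],
      qual = qual, depth = as.integer(dp), stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), qual = numeric(),
               depth = integer(), stringsAsFactors = FALSE)
  calls <- variant_calls(df$chrom, df$pos, df$ref, df$alt, df$qual,
                         df$depth, id = df$id)
  attr(calls, "errors") <- if (length(errors) > 0) {
    do.call(rbind, errors)
  } else {
    data.frame(line = integer(), message = character(),
               stringsAsFactors = FALSE)
  }
  calls
}

#' Write variant calls as minimal VCF v4
#'
#' @param calls a [variant_calls()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  id <- ifelse(is.na(calls$id), ".", calls$id)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\tDP=%d",
                  calls$chrom, calls$pos, id, calls$ref, calls$alt,
                  format(calls$qual, trim = TRUE, digits = 10),
                  calls$depth)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the variant-call TSV dialect
#'
#' Tab-separated equivalent of the minimal VCF: columns `chrom`, `pos`,
#' `ref`, `alt`, `qual`, `depth` (optional `id`), header row, `#` comments.
#' The two formats round-trip.
#'
#' @param path file path.
#' @return a [variant_calls()] table.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  check_that(all(need %in% names(df)),
             paste("variant TSV is missing columns:",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  id <- if ("id" %in% names(df)) df$id else NA_character_
  variant_calls(df$chrom, df$pos, df$ref, df$alt, df$qual, df$depth,
                id = id)
}

#' @rdname read_variants_tsv
#' @param calls a [variant_calls()] table to write.
#' @export
write_variants_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls)[c("chrom", "pos", "id", "ref",
                                            "alt", "qual", "depth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write long-format plate tables
#'
#' Long-format plate-reader output: one row per well and time point with
#' columns `strain`, `well`, `concentration`, `time_h`, `od660`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_plate_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("strain", "well", "concentration", "time_h", "od660")
  check_that(all(need %in% names(df)),
             paste("plate TSV is missing columns:",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' @rdname read_plate_tsv
#' @param plate long-format plate data frame to write.
#' @export
write_plate_tsv <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from TSV or GFF3 CDS lines
#'
#' The TSV surrogate has columns `gene`, `chrom`, `strand`, `cds_start`,
#' `cds_end` (optional `upstream_window`). `read_gene_models_gff()` imports
#' CDS features from a GFF3 file via rtracklayer (one intronless CDS per
#' gene; the gene symbol is taken from the `gene`, `Name` or `ID`
#' attribute) with the same semantics.
#'
#' @param path file path.
#' @param upstream_window promoter-proximal window in bp when the file does
#'   not carry one (default 1000).
#' @return a [gene_models()] table.
#' @export
read_gene_models_tsv <- function(path, upstream_window = 1000) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "cds_start", "cds_end")
  check_that(all(need %in% names(df)),
             paste("gene-model TSV is missing columns:",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  uw <- if ("upstream_window" %in% names(df)) df$upstream_window else
    upstream_window
  gene_models(df$gene, df$chrom, df$strand, df$cds_start, df$cds_end,
              upstream_window = uw)
}

#' @rdname read_gene_models_tsv
#' @param models a [gene_models()] table to write.
#' @export
write_gene_models_tsv <- function(models, path) {
  utils::write.table(as.data.frame(models), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_gene_models_tsv
#' @export
read_gene_models_gff <- function(path, upstream_window = 1000) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_models_gff requires the rtracklayer package",
         call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  md <- as.data.frame(gr)
  sym <- md$gene
  if (is.null(sym)) sym <- md$Name
  if (is.null(sym)) sym <- md$ID
  check_that(!is.null(sym), "GFF3 CDS lines carry no gene/Name/ID attribute")
  gene_models(as.character(sym), as.character(md$seqnames),
              as.character(md$strand), md$start, md$end,
              upstream_window = upstream_window)
}

#' Read a two-column gene-annotation TSV (GAF-lite)
#'
#' @param path file path to a TSV with columns `gene`, `term`.
#' @return data frame with columns `gene`, `term`.
#' @export
read_gaf_lite <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  check_that(all(c("gene", "term") %in% names(df)),
             "annotation TSV must have columns gene, term")
  df[c("gene", "term")]
}

#' Read an OBO-lite ontology
#'
#' Parses the `[Term]` stanzas of an OBO file, keeping `id:`, `name:` and
#' `is_a:` tags (optionally `relationship: part_of` edges). Everything else
#' in the OBO spec is ignored.
#'
#' @param path file path.
#' @param include_part_of also treat `relationship: part_of` as a parent
#'   edge (default FALSE).
#' @return list with `parents` (data frame `child`, `parent`) and
#'   `term_names` (named character vector).
#' @export
read_obo_lite <- function(path, include_part_of = FALSE) {
  lines <- trimws(readLines(path))
  parents <- list()
  term_names <- character()
  cur <- NULL
  in_term <- FALSE
  for (l in lines) {
    if (l == "[Term]") {
      in_term <- TRUE
      cur <- NULL
      next
    }
    if (startsWith(l, "[")) { # some other stanza type
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(l)) next
    if (startsWith(l, "id:")) {
      cur <- trimws(sub("^id:", "", l))
    } else if (startsWith(l, "name:") && !is.null(cur)) {
      term_names[cur] <- trimws(sub("^name:", "", l))
    } else if (startsWith(l, "is_a:") && !is.null(cur)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
      parents[[length(parents) + 1L]] <-
        data.frame(child = cur, parent = parent, stringsAsFactors = FALSE)
    } else if (include_part_of &&
               startsWith(l, "relationship: part_of") && !is.null(cur)) {
      parent <- trimws(sub("!.*$", "",
                           sub("^relationship: part_of", "", l)))
      parents[[length(parents) + 1L]] <-
        data.frame(child = cur, parent = parent, stringsAsFactors = FALSE)
    }
  }
  list(parents = if (length(parents) > 0) do.call(rbind, parents) else
         data.frame(child = character(), parent = character(),
                    stringsAsFactors = FALSE),
       term_names = term_names)
}

#' Read a pipeline configuration file
#'
#' YAML-style key/value configuration; see [default_replay_config()] for
#' the recognized fields.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
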