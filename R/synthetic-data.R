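# Synthetic-data generators: planted-truth deletion screens, variant call
# tables with rule-violating noise, and GO annotation tables with planted
# enriched categories. All generators take explicit seeds and are
# bit-reproducible.

# dose-response parameter sets for each planted sensitivity class.
# Plateau fractions at 1% butanol are chosen so the noise-free BSI lands in
# the middle of each screening band: reference-like at BSI 2 (the anchor
# calibration), tolerant ~1.4, sensitive ~5, hypersensitive = no growth.
class_params <- function(class, noise_sd = 0) {
  switch(class,
    reference_like = calibrate_reference(2.0, 1.45, noise_sd = noise_sd),
    tolerant = calibrate_reference(1.43, 1.57, noise_sd = noise_sd),
    sensitive = calibrate_reference(5.0, 1.25, noise_sd = noise_sd),
    hypersensitive = dose_response_params(c_max = 0.8, h = 2,
                                          noise_sd = noise_sd),
    stop("unknown sensitivity class: ", class, call. = FALSE)
  )
}

#' Specification of a synthetic deletion screen
#'
#' @param n_strains number of deletion strains.
#' @param class_proportions named fractions over the planted classes
#'   (`reference_like`, `tolerant`, `sensitive`, `hypersensitive`), summing
#'   to 1. Counts are apportioned by largest remainder so they sum exactly
#'   to `n_strains`.
#' @param replicates wells per strain and condition (default 8 replicate
#'   tests).
#' @param noise_sd multiplicative lognormal OD noise (default 0.02).
#' @param seed integer seed.
#' @return list of class `screen_spec`.
#' @export
screen_spec <- function(n_strains,
                        class_proportions = c(reference_like = 1),
                        replicates = 8, noise_sd = 0.02, seed = 1) {
  check_that(is_number(n_strains) && n_strains >= 1,
             "n_strains must be >= 1")
  check_that(abs(sum(class_proportions) - 1) < 1e-8,
             "class proportions must sum to 1")
  check_that(all(names(class_proportions) %in%
                   setdiff(sensitivity_classes(), "indeterminate")),
             "unknown class name in class_proportions")
  check_that(is_number(replicates) && replicates >= 1,
             "replicates must be >= 1")
  structure(list(n_strains = as.integer(n_strains),
                 class_proportions = class_proportions,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "screen_spec")
}

# largest-remainder apportionment of n into named fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a planted-truth deletion screen
#'
#' Simulates replicate growth curves at 0% and 1% butanol for `n_strains`
#' deletion strains whose dose-response class is planted according to
#' `spec$class_proportions`, and returns the long-format plate table
#' together with the truth table. Identical seeds reproduce identical
#' output.
#'
#' @param spec a [screen_spec()].
#' @param duration,interval curve duration (hours) and sampling interval
#'   (minutes); defaults 48 h every 30 min.
#' @return list with `plate` (columns `strain`, `well`, `concentration`,
#'   `time_h`, `od660`) and `truth` (columns `strain`, `class`).
#' @export
generate_screen <- function(spec, duration = 48, interval = 30) {
  stopifnot(inherits(spec, "screen_spec"))
  counts <- apportion(spec$n_strains, spec$class_proportions)
  classes <- rep(names(counts), counts)
  strains <- sprintf("strain%05d", seq_len(spec$n_strains))
  truth <- data.frame(strain = strains, class = classes,
                      stringsAsFactors = FALSE)

  times <- seq(0, duration, by = interval / 60)
  nt <- length(times)
  params_by_class <- lapply(
    stats::setNames(nm = unique(classes)),
    function(cl) class_params(cl, noise_sd = spec$noise_sd))

  with_seed(spec$seed, {
    blocks <- vector("list", length(unique(classes)))
    bi <- 1L
    plate_rows <- list()
    for (cl in unique(classes)) {
      p <- params_by_class[[cl]]
      idx <- which(classes == cl)
      # noise-free trajectories per condition, shared by all strains of
      # the class; noise drawn per well
      for (conc in c(0, 1)) {
        base_od <- logistic_od(p, conc, times)
        n_wells <- length(idx) * spec$replicates
        od <- rep(base_od, n_wells)
        if (spec$noise_sd > 0) {
          od <- od * exp(stats::rnorm(length(od), 0, spec$noise_sd))
        }
        plate_rows[[length(plate_rows) + 1L]] <- data.frame(
          strain = rep(strains[idx], each = spec$replicates * nt),
          well = rep(sprintf("w%02d", seq_len(spec$replicates)),
                     each = nt, times = length(idx)),
          concentration = conc,
          time_h = rep(times, n_wells),
          od660 = od,
          stringsAsFactors = FALSE)
      }
      bi <- bi + 1L
    }
    plate <- do.call(rbind, plate_rows)
    rownames(plate) <- NULL
    list(plate = plate, truth = truth)
  })
}

#' Specification of a synthetic variant table
#'
#' @param genome_length named integer vector: chromosome name -> length.
#' @param n_evolved_specific clean evolved-specific SNVs.
#' @param n_parental_shared clean SNVs present in both evolved and parental
#'   call sets.
#' @param n_noise_calls calls each violating exactly one filter rule
#'   (ambiguous base, low quality, low depth, excessive depth, cycled in
#'   that order).
#' @param seed integer seed.
#' @return list of class `variant_spec`.
#' @export
variant_spec <- function(genome_length = c(chr1 = 200000, chr2 = 300000,
                                           chr3 = 250000, chr4 = 400000),
                         n_evolved_specific = 4, n_parental_shared = 10,
                         n_noise_calls = 12, seed = 1) {
  check_that(length(genome_length) >= 1 && all(genome_length >= 1),
             "genome_length must name at least one chromosome")
  check_that(!is.null(names(genome_length)),
             "genome_length must be a named vector")
  check_that(all(c(n_evolved_specific, n_parental_shared,
                   n_noise_calls) >= 0), "all counts must be >= 0")
  structure(list(genome_length = genome_length,
                 n_evolved_specific = as.integer(n_evolved_specific),
                 n_parental_shared = as.integer(n_parental_shared),
                 n_noise_calls = as.integer(n_noise_calls),
                 seed = as.integer(seed)),
            class = "variant_spec")
}

noise_rule_cycle <- c("ambiguous_base", "quality", "depth_low", "depth_high")

#' Generate evolved and parental variant call sets with planted truth
#'
#' Draws unique positions across the configured chromosomes and emits:
#' clean evolved-specific SNVs (quality 30-60, depth 20-200, unambiguous
#' bases, absent from the parent), parental-shared SNVs (clean, present in
#' both call sets), and noise calls each violating exactly one filter rule
#' while passing all the others. Truth labels partition the evolved call
#' set.
#'
#' @param spec a [variant_spec()].
#' @param max_retries attempts to resolve position collisions before
#'   failing (default 100).
#' @return list with `evolved` ([variant_calls()]), `parental`
#'   ([variant_calls()]), `truth` (data frame `chrom`, `pos`, `ref`, `alt`,
#'   `label`).
#' @export
generate_variants <- function(spec, max_retries = 100) {
  stopifnot(inherits(spec, "variant_spec"))
  n_total <- spec$n_evolved_specific + spec$n_parental_shared +
    spec$n_noise_calls
  with_seed(spec$seed, {
    chroms <- names(spec$genome_length)
    # rejection-sample unique (chrom, pos) pairs
    sites <- NULL
    for (attempt in seq_len(max_retries)) {
      ch <- sample(chroms, n_total, replace = TRUE,
                   prob = spec$genome_length / sum(spec$genome_length))
      pos <- vapply(ch, function(c1) {
        sample.int(spec$genome_length[[c1]], 1L)
      }, integer(1))
      key <- paste(ch, pos)
      if (!anyDuplicated(key)) {
        sites <- data.frame(chrom = ch, pos = pos,
                            stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(sites)) {
      stop("could not draw unique variant positions after ", max_retries,
           " attempts; enlarge the genome or reduce the counts",
           call. = FALSE)
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    qual <- stats::runif(n_total, 30, 60)
    depth <- sample(20:200, n_total, replace = TRUE)

    label <- c(rep("evolved_specific", spec$n_evolved_specific),
               rep("parental_shared", spec$n_parental_shared),
               if (spec$n_noise_calls > 0) {
                 rep_len(noise_rule_cycle, spec$n_noise_calls)
               })
    # noise calls: perturb exactly one property each
    for (i in which(!label %in% c("evolved_specific", "parental_shared"))) {
      switch(label[i],
        ambiguous_base = { alt[i] <- sample(c("N", "R", "Y", "W"), 1L) },
        quality = { qual[i] <- stats::runif(1, 0, 19.5) },
        depth_low = { depth[i] <- sample(0:9, 1L) },
        depth_high = { depth[i] <- sample(401:1200, 1L) }
      )
    }

    evolved <- variant_calls(sites$chrom, sites$pos, ref, alt, qual, depth)
    shared <- label == "parental_shared"
    parental <- variant_calls(sites$chrom[shared], sites$pos[shared],
                              ref[shared], alt[shared],
                              stats::runif(sum(shared), 30, 60),
                              sample(20:200, sum(shared), replace = TRUE))
    truth <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                        alt = alt, label = label, stringsAsFactors = FALSE)
    list(evolved = evolved, parental = parental, truth = truth)
  })
}

#' Generate a GO annotation table with planted enriched categories
#'
#' Builds a background population of `n_genes` synthetic gene symbols plus
#' any genes named in `planted`, annotates each planted term to its listed
#' genes plus `background_per_term` random background genes, adds
#' `n_random_terms` purely random terms, and wires every term under a
#' single root via is_a so propagation is exercised.
#'
#' @param population character vector of background gene symbols.
#' @param planted named list: term id -> character vector of genes the term
#'   is planted on.
#' @param background_per_term random background genes added to each planted
#'   term (default 35).
#' @param n_random_terms number of unplanted random terms (default 40).
#' @param genes_per_random_term annotation size of each random term
#'   (default 30).
#' @param term_names optional named character vector of term names.
#' @param seed integer seed.
#' @return a [go_annotation_table()] (not yet propagated).
#' @export
generate_go_annotations <- function(population, planted = list(),
                                    background_per_term = 35,
                                    n_random_terms = 40,
                                    genes_per_random_term = 30,
                                    term_names = NULL, seed = 1) {
  population <- unique(as.character(population))
  with_seed(seed, {
    ann <- list()
    for (term in names(planted)) {
      genes <- planted[[term]]
      extra <- sample(setdiff(population, genes),
                      min(background_per_term,
                          length(setdiff(population, genes))))
      ann[[length(ann) + 1L]] <- data.frame(
        gene = c(genes, extra), term = term, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_random_terms)) {
      term <- sprintf("GO:R%04d", i)
      genes <- sample(population, min(genes_per_random_term,
                                      length(population)))
      ann[[length(ann) + 1L]] <- data.frame(
        gene = genes, term = term, stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann)
    terms <- unique(annotations$term)
    parents <- data.frame(child = terms, parent = "GO:ROOT",
                          stringsAsFactors = FALSE)
    go_annotation_table(annotations, parents, term_names = term_names)
  })
}
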