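# Marker-assisted backcross simulation: meiosis with Haldane recombination,
# 2:2 tetrad segregation, marker-constrained spore selection,
# phenotype-based segregant selection over repeated cycles, and Monte Carlo
# estimation of causal vs neutral allele retention.

#' Haldane map function
#'
#' Converts a map distance in centiMorgan to a recombination fraction under
#' the no-interference (Poisson crossover) model:
#' `r = 0.5 * (1 - exp(-2 d / 100))`. Loci on different chromosomes
#' (`d = Inf`) assort independently with `r = 0.5`.
#'
#' @param d map distance in centiMorgan, >= 0 (may be `Inf`).
#' @return recombination fraction in `[0, 0.5]`.
#' @examples
#' recombination_fraction(10) # ~0.0906
#' @export
recombination_fraction <- function(d) {
  check_that(all(d >= 0), "map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Locus map for a backcross scenario
#'
#' @param id allele names (unique), e.g. `"rpn4-1"`.
#' @param chrom chromosome ids.
#' @param map_pos positions in centiMorgan along each chromosome, >= 0.
#' @param role one of `"causal"`, `"neutral"`, `"marker"` per locus.
#' @return data frame of class `locus_map`, sorted by `(chrom, map_pos)`.
#' @export
locus_map <- function(id, chrom, map_pos, role) {
  check_that(!anyDuplicated(id), "locus ids must be unique")
  check_that(all(map_pos >= 0), "map_pos must be >= 0")
  check_that(all(role %in% c("causal", "neutral", "marker")),
             "role must be causal, neutral or marker")
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   map_pos = as.numeric(map_pos),
                   role = as.character(role), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$map_pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("locus_map", "data.frame")
  df
}

#' Haploid genotype over a locus map
#'
#' @param loci a [locus_map()].
#' @param alleles named character vector over `loci$id` with values
#'   `"evolved"` or `"naive"`, or a single value recycled to all loci.
#' @param mating_type `"a"` or `"alpha"`.
#' @return list of class `haploid_genotype` with elements `alleles` (named,
#'   in map order) and `mating_type`.
#' @export
haploid_genotype <- function(loci, alleles, mating_type = "a") {
  stopifnot(inherits(loci, "locus_map"))
  check_that(mating_type %in% c("a", "alpha"),
             "mating_type must be 'a' or 'alpha'")
  if (length(alleles) == 1L && is.null(names(alleles))) {
    alleles <- stats::setNames(rep(alleles, nrow(loci)), loci$id)
  }
  check_that(setequal(names(alleles), loci$id),
             "alleles must assign a state to every locus")
  check_that(all(alleles %in% c("evolved", "naive")),
             "allele states must be 'evolved' or 'naive'")
  structure(list(alleles = alleles[loci$id], mating_type = mating_type),
            class = "haploid_genotype")
}

#' Phenotype model for segregant selection
#'
#' @param rule `"all_causal_required"` (a segregant matches the evolved
#'   phenotype iff it carries every causal allele — the synergistic model)
#'   or `"additive_threshold"` (a segregant matches iff the sum of effect
#'   sizes over its evolved causal alleles is within `epsilon` of the full
#'   evolved score).
#' @param causal character vector of causal locus ids (non-empty).
#' @param effects named non-negative effect sizes (additive mode only).
#' @param epsilon additive-mode tolerance (default 0).
#' @return list of class `phenotype_model`.
#' @export
phenotype_model <- function(rule = c("all_causal_required",
                                     "additive_threshold"),
                            causal, effects = NULL, epsilon = 0) {
  rule <- match.arg(rule)
  check_that(length(causal) > 0, "causal locus set must be non-empty")
  if (rule == "additive_threshold") {
    check_that(!is.null(effects) && all(causal %in% names(effects)),
               "additive rule needs an effect size for every causal locus")
    check_that(all(effects >= 0), "effect sizes must be non-negative")
  }
  structure(list(rule = rule, causal = as.character(causal),
                 effects = effects, epsilon = epsilon),
            class = "phenotype_model")
}

#' Backcross series configuration
#'
#' @param n_cycles number of backcross cycles (default 3).
#' @param marker_locus id of the selectable marker locus (e.g. the native
#'   URA3 allele carried by the evolved parent while the recurrent parents
#'   are deletants), or `NULL` to disable marker selection.
#' @param max_tetrads tetrads sampled per cycle before declaring failure
#'   (default 1000).
#' @return list of class `backcross_config`.
#' @export
backcross_config <- function(n_cycles = 3, marker_locus = NULL,
                             max_tetrads = 1000) {
  check_that(is_number(n_cycles) && n_cycles >= 1, "n_cycles must be >= 1")
  check_that(is_number(max_tetrads) && max_tetrads >= 1,
             "max_tetrads must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles),
                 marker_locus = marker_locus,
                 max_tetrads = as.integer(max_tetrads)),
            class = "backcross_config")
}

#' Simulate one meiosis (tetrad)
#'
#' Generates the four spores of one meiosis from a diploid formed by two
#' haploid parents. Per chromosome, the first spore's allele chain starts
#' from a random parental strand and switches between strands across each
#' inter-locus interval with the Haldane recombination fraction of its map
#' length; the second spore is drawn independently; spores three and four
#' are the complements of the first two. Every heterozygous locus therefore
#' segregates exactly 2:2 and adjacent-locus recombination fractions follow
#' the map.
#'
#' Uses the current RNG stream; seed the caller (e.g. via
#' [estimate_retention()]) for reproducibility.
#'
#' @param parent1,parent2 [haploid_genotype()] objects over the same map.
#' @param loci the [locus_map()].
#' @return list of four `haploid_genotype` spores (mating types assigned
#'   2:2 at random).
#' @export
meiosis <- function(parent1, parent2, loci) {
  stopifnot(inherits(parent1, "haploid_genotype"),
            inherits(parent2, "haploid_genotype"))
  ids <- loci$id
  a1 <- parent1$alleles[ids]
  a2 <- parent2$alleles[ids]

  draw_gamete <- function() {
    take1 <- logical(length(ids))
    for (ch in unique(loci$chrom)) {
      idx <- which(loci$chrom == ch)
      r <- recombination_fraction(diff(loci$map_pos[idx]))
      strand <- stats::runif(1) < 0.5
      for (kk in seq_along(idx)) {
        if (kk > 1L && stats::runif(1) < r[kk - 1L]) strand <- !strand
        take1[idx[kk]] <- strand
      }
    }
    take1
  }

  g1 <- draw_gamete()
  g2 <- draw_gamete()
  pick <- function(take1) {
    stats::setNames(ifelse(take1, a1, a2), ids)
  }
  spores <- list(pick(g1), pick(g2), pick(!g1), pick(!g2))
  mt <- sample(c("a", "a", "alpha", "alpha"))
  lapply(seq_len(4), function(i) {
    structure(list(alleles = spores[[i]], mating_type = mt[i]),
              class = "haploid_genotype")
  })
}

# does a spore satisfy marker selection and the evolved phenotype?
spore_eligible <- function(spore, phenotype, config) {
  if (!is.null(config$marker_locus) &&
      spore$alleles[[config$marker_locus]] != "evolved") {
    return(FALSE)
  }
  causal_state <- spore$alleles[phenotype$causal]
  if (phenotype$rule == "all_causal_required") {
    all(causal_state == "evolved")
  } else {
    score <- sum(phenotype$effects[phenotype$causal][
      causal_state == "evolved"])
    full <- sum(phenotype$effects[phenotype$causal])
    score >= full - phenotype$epsilon
  }
}

#' Select a tolerant segregant from a tetrad
#'
#' Returns one uniformly chosen spore among those passing marker selection
#' and matching the evolved phenotype, or `NULL` when the tetrad contains
#' no eligible spore (the caller then sporulates further tetrads).
#'
#' @param spores list of four spores from [meiosis()].
#' @param phenotype a [phenotype_model()].
#' @param config a [backcross_config()].
#' @return a `haploid_genotype` or `NULL`.
#' @export
select_segregant <- function(spores, phenotype, config) {
  ok <- which(vapply(spores, spore_eligible, logical(1),
                     phenotype = phenotype, config = config))
  if (length(ok) == 0) return(NULL)
  spores[[ok[sample.int(length(ok), 1L)]]]
}

#' Run one backcross series
#'
#' Crosses the evolved haploid to a naive-background partner, sporulates,
#' selects a marker- and phenotype-eligible segregant, and repeats for
#' `n_cycles` cycles (the recurrent parent is always fully naive except for
#' the marker convention; mating types alternate implicitly). Records the
#' selected segregant of each generation and which evolved alleles remain
#' in the final one.
#'
#' @param evolved [haploid_genotype()] carrying the evolved allele at every
#'   locus (and the functional marker).
#' @param naive [haploid_genotype()] of the recurrent parent (naive at every
#'   locus except that marker selection conventionally requires the
#'   *evolved* state at the marker locus, i.e. the functional allele).
#' @param loci the [locus_map()].
#' @param phenotype a [phenotype_model()]; every causal locus must carry
#'   the evolved allele in `evolved`.
#' @param config a [backcross_config()].
#' @param seed optional integer seed.
#' @return list of class `backcross_series`: `generations` (selected
#'   segregant per cycle, F1..Fn), `retained` (named logical over loci:
#'   evolved allele present in the final segregant), `n_cycles`.
#' @export
run_backcross_series <- function(evolved, naive, loci, phenotype,
                                 config = backcross_config(), seed = NULL) {
  check_that(all(evolved$alleles[phenotype$causal] == "evolved"),
             "phenotype unsatisfiable: evolved genotype lacks a causal allele")
  with_seed(seed, {
    current <- evolved
    generations <- vector("list", config$n_cycles)
    for (cycle in seq_len(config$n_cycles)) {
      selected <- NULL
      for (t in seq_len(config$max_tetrads)) {
        spores <- meiosis(current, naive, loci)
        selected <- select_segregant(spores, phenotype, config)
        if (!is.null(selected)) break
      }
      if (is.null(selected)) {
        stop("no eligible segregant found within max_tetrads tetrads ",
             "(cycle ", cycle, ")", call. = FALSE)
      }
      generations[[cycle]] <- selected
      current <- selected
    }
    names(generations) <- paste0("F", seq_len(config$n_cycles))
    final <- generations[[config$n_cycles]]
    structure(list(generations = generations,
                   retained = final$alleles == "evolved",
                   n_cycles = config$n_cycles),
              class = "backcross_series")
  })
}

#' Monte Carlo allele-retention frequencies across replicate series
#'
#' Repeats [run_backcross_series()] `n_replicates` times and reports, per
#' locus, the frequency with which the evolved allele is retained in the
#' final generation, with exact binomial 95% confidence intervals. Causal
#' loci are retained with frequency 1 by construction (selection requires
#' them); an unlinked neutral locus is expected at `(1/2)^n_cycles`; a
#' neutral locus at recombination fraction `r` from a selected causal locus
#' at `(1 - r)^n_cycles`.
#'
#' @param evolved,naive,loci,phenotype,config as in
#'   [run_backcross_series()].
#' @param n_replicates number of replicate series (>= 1).
#' @param seed integer seed for the whole experiment.
#' @return data frame with columns `locus`, `role`, `n_cycles`,
#'   `retention`, `ci_low`, `ci_high`, `n_replicates`.
#' @export
estimate_retention <- function(evolved, naive, loci, phenotype,
                               config = backcross_config(),
                               n_replicates = 1000, seed = NULL) {
  check_that(is_number(n_replicates) && n_replicates >= 1,
             "n_replicates must be >= 1")
  with_seed(seed, {
    hits <- stats::setNames(numeric(nrow(loci)), loci$id)
    for (rep_i in seq_len(n_replicates)) {
      series <- run_backcross_series(evolved, naive, loci, phenotype,
                                     config, seed = NULL)
      hits <- hits + as.numeric(series$retained[loci$id])
    }
    ci <- t(vapply(hits, function(x) {
      as.numeric(stats::binom.test(round(x), n_replicates)$conf.int)
    }, numeric(2)))
    data.frame(locus = loci$id, role = loci$role,
               n_cycles = config$n_cycles,
               retention = unname(hits) / n_replicates,
               ci_low = ci[, 1], ci_high = ci[, 2],
               n_replicates = as.integer(n_replicates),
               stringsAsFactors = FALSE)
  })
}
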