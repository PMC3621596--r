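# End-to-end replay: synthetic screen -> BSI triage -> GO enrichment on the
# confirmed gene set -> synthetic variant generation -> filter chain ->
# codon-level annotation -> backcross simulation for both evolved lineages.
# One consolidated, seeded, byte-reproducible report.

#' Default replay configuration
#'
#' Stage parameters for [run_replay()]. The defaults keep the replay light
#' (a 300-strain screen at coarse sampling and 2000 backcross replicates)
#' while exercising every stage; raise `screen$n_strains` to the full
#' collection size (5154) and `backcross$n_replicates` to 10000 for
#' higher-resolution runs.
#'
#' @param seed global integer seed; every stage derives its own stream from
#'   it.
#' @return named list of class `replay_config`.
#' @export
default_replay_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    screen = list(n_strains = 300,
                  class_proportions = c(reference_like = 0.90,
                                        sensitive = 0.055,
                                        hypersensitive = 0.035,
                                        tolerant = 0.01),
                  replicates = 8, noise_sd = 0.02, interval = 240),
    enrichment = list(alpha = 0.05, population_size = 5154),
    filter = list(min_qual = 20, min_depth = 10, max_depth = 400),
    variants = list(lineage1 = list(n_evolved_specific = 4,
                                    n_parental_shared = 10,
                                    n_noise_calls = 12),
                    lineage2 = list(n_evolved_specific = 7,
                                    n_parental_shared = 10,
                                    n_noise_calls = 12)),
    backcross = list(n_cycles = 3, n_replicates = 2000)
  ), class = "replay_config")
}

#' Replay the whole reverse-engineering pipeline on synthetic data
#'
#' Executes every stage of the tolerance reverse-engineering cycle against
#' generated data plus the packaged reference tables and returns one
#' consolidated report: screen classification vs planted truth and the
#' triage bookkeeping; enrichment of the confirmed 35-gene set against a
#' synthetic annotated background with planted proteasome and
#' multivesicular-body categories; filter-chain survivor counts for
#' synthetic replicas of both evolved lineages; codon-consistency verdicts
#' and coding/non-coding counts for the packaged variant table; and
#' Monte Carlo allele-retention frequencies for both backcross scenarios.
#'
#' Two runs with the same configuration produce identical reports; the
#' report embeds the seed and a configuration fingerprint.
#'
#' @param config a [default_replay_config()]-shaped list.
#' @param out_dir optional directory; when given, per-stage TSV outputs are
#'   written there (deterministically for a fixed config).
#' @param stages character subset of
#'   `c("screen", "enrich", "variants", "annotate", "backcross")` to run
#'   (default all).
#' @return nested list of class `replay_report`.
#' @export
run_replay <- function(config = default_replay_config(), out_dir = NULL,
                       stages = c("screen", "enrich", "variants",
                                  "annotate", "backcross")) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed
  report <- list(seed = seed, config_hash = object_hash(config))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# seed=%d config_hash=%s", seed,
                       report$config_hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }

  if ("screen" %in% stages) {
    sc <- config$screen
    spec <- screen_spec(sc$n_strains, sc$class_proportions,
                        replicates = sc$replicates,
                        noise_sd = sc$noise_sd, seed = seed)
    screen <- generate_screen(spec, interval = sc$interval)
    records <- summarize_screen(screen$plate)
    agreement <- mean(as.character(records$sensitivity_class[
      match(screen$truth$strain, records$strain)]) == screen$truth$class)
    triage <- triage_example()
    report$screen <- list(
      n_strains = sc$n_strains,
      class_counts = table(records$sensitivity_class),
      truth_agreement = agreement,
      n_tested = triage$n_tested, n_viable = triage$n_viable,
      n_confirmed = triage$n_confirmed)
    emit(records, "screen_records")
  }

  if ("enrich" %in% stages) {
    en <- config$enrichment
    study <- load_fixture("table1_genes")$gene
    population <- union(study,
                        sprintf("YOR%04dW",
                                seq_len(en$population_size - length(study))))
    planted <- list(
      "GO:PROTEASOME" = c("PRE9", "UMP1", "YLR224W", "UBP3", "BRE5"),
      "GO:MVB" = c("STP22", "SNF8", "DID4", "BRO1"))
    tab <- generate_go_annotations(
      population, planted,
      term_names = c("GO:PROTEASOME" = "proteasome complex",
                     "GO:MVB" = "multivesicular body",
                     "GO:ROOT" = "root"),
      seed = seed + 1L)
    res <- enrich(study, population, tab, alpha = en$alpha)
    report$enrichment <- list(
      results = res,
      planted_enriched = res$enriched[match(names(planted), res$term)])
    emit(res, "enrichment")
  }

  if ("variants" %in% stages) {
    survivor_counts <- list()
    for (lineage in names(config$variants)) {
      v <- config$variants[[lineage]]
      spec <- variant_spec(n_evolved_specific = v$n_evolved_specific,
                           n_parental_shared = v$n_parental_shared,
                           n_noise_calls = v$n_noise_calls,
                           seed = seed + match(lineage,
                                               names(config$variants)))
      gen <- generate_variants(spec)
      fc <- config$filter
      chain <- run_filter_chain(gen$evolved, gen$parental,
                                filter_config(fc$min_qual, fc$min_depth,
                                              fc$max_depth))
      survivor_counts[[lineage]] <- list(
        n_input = chain$n_input,
        n_survivors = nrow(chain$survivors),
        counts = chain$counts)
      emit(chain$survivors, paste0("survivors_", lineage))
    }
    report$variants <- survivor_counts
  }

  if ("annotate" %in% stages) {
    ann <- classify_location(table2_calls(), table2_gene_models())
    ann$strain <- table2_calls()$strain[match(paste(ann$chrom, ann$pos),
                                              paste(table2_calls()$chrom,
                                                    table2_calls()$pos))]
    report$annotation <- list(
      counts_IMS0344 = count_by_class(ann, "IMS0344"),
      counts_IMS0351 = count_by_class(ann, "IMS0351"),
      consistency = table2_consistency())
    emit(ann, "annotated_variants")
  }

  if ("backcross" %in% stages) {
    bc <- config$backcross
    retention <- list()
    for (i in seq_along(c("IMS0344", "IMS0351"))) {
      strain <- c("IMS0344", "IMS0351")[i]
      sc <- lineage_scenario(strain, n_cycles = bc$n_cycles)
      retention[[strain]] <- estimate_retention(
        sc$evolved, sc$naive, sc$loci, sc$phenotype, sc$config,
        n_replicates = bc$n_replicates, seed = seed + 10L + i)
      emit(retention[[strain]], paste0("retention_", strain))
    }
    report$backcross <- retention
    report$attrition <- list(
      IMS0350 = f3_attrition("IMS0344", "IMS0350"),
      IMS0357 = f3_attrition("IMS0351", "IMS0357"))
  }

  structure(report, class = "replay_report")
}

#' @export
print.replay_report <- function(x, ...) {
  cat(sprintf("Replay report (seed %d, config %s)\n", x$seed,
              x$config_hash))
  if (!is.null(x$screen)) {
    cat(sprintf("  screen: %d strains, %.1f%% truth agreement; ",
                x$screen$n_strains, 100 * x$screen$truth_agreement))
    cat(sprintf("triage %d tested / %d viable / %d confirmed\n",
                x$screen$n_tested, x$screen$n_viable,
                x$screen$n_confirmed))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: %d terms tested, %d enriched\n",
                nrow(x$enrichment$results),
                sum(x$enrichment$results$enriched)))
  }
  if (!is.null(x$variants)) {
    for (l in names(x$variants)) {
      cat(sprintf("  variants %s: %d calls -> %d survivors\n", l,
                  x$variants[[l]]$n_input, x$variants[[l]]$n_survivors))
    }
  }
  if (!is.null(x$annotation)) {
    cat(sprintf("  annotation: IMS0344 (%d coding, %d non-coding); ",
                x$annotation$counts_IMS0344[["n_coding"]],
                x$annotation$counts_IMS0344[["n_noncoding"]]))
    cat(sprintf("IMS0351 (%d coding, %d non-coding)\n",
                x$annotation$counts_IMS0351[["n_coding"]],
                x$annotation$counts_IMS0351[["n_noncoding"]]))
  }
  if (!is.null(x$backcross)) {
    for (l in names(x$backcross)) {
      r <- x$backcross[[l]]
      neutral <- r[r$role == "neutral", ]
      cat(sprintf("  backcross %s: neutral retention %s\n", l,
                  paste(sprintf("%s=%.3f", neutral$locus,
                                neutral$retention), collapse = ", ")))
    }
  }
  invisible(x)
}
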