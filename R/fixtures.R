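# Packaged reference tables (confirmed-sensitive gene set, evolved-strain
# SNVs, strain genotypes) and helpers that turn them into pipeline inputs:
# synthetic toy gene models placed to reproduce the published coordinates,
# genomic call tables, the triage bookkeeping example, and the
# backcross-attrition comparison.

#' Load a packaged reference table
#'
#' Three tab-separated fixtures ship with the package: `table1_genes` (the
#' 35 genes whose deletion confers butanol sensitivity in both genetic
#' backgrounds), `table2_variants` (the single-nucleotide variations of the
#' two evolved strains, with parsed nucleotide/amino-acid fields), and
#' `table3_genotypes` (the strains of the study with their mutated-allele
#' genotypes across the backcross generations).
#'
#' @param name one of `"table1_genes"`, `"table2_variants"`,
#'   `"table3_genotypes"`.
#' @return a data frame.
#' @export
load_fixture <- function(name = c("table1_genes", "table2_variants",
                                  "table3_genotypes")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "evotol")
  check_that(nzchar(path), paste("fixture not installed:", name))
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

# dubious ORFs excluded from re-testing, the arbitrarily added picks, and
# the deletions that yielded no transformants in the second background
screen_followup_sets <- function() {
  list(
    dubious_orfs = c("YKL118W", "YPL062W", "YBL094C", "YLR338W", "YDR157W"),
    extra_picks = c("STP11", "DID4"),
    transformation_failures = c("GON7", "UAF30", "OCH1")
  )
}

#' Reconstruct the deletion-screen triage example
#'
#' Builds a hit/exclusion/confirmation set structure consistent with the
#' published bookkeeping — 50 hypersensitive hits (including the five
#' dubious ORFs and the three genes that later failed transformation), two
#' arbitrarily added picks, and the 35-gene confirmed set — and runs
#' [triage_screen()] on it. Filler hit symbols are synthetic.
#'
#' @return a `triage_summary` (see [triage_screen()]).
#' @export
triage_example <- function() {
  sets <- screen_followup_sets()
  confirmed <- load_fixture("table1_genes")$gene
  # DID4 entered through the extra picks, not the hypersensitive list
  hits_core <- setdiff(confirmed, sets$extra_picks)
  hits <- c(hits_core, sets$dubious_orfs, sets$transformation_failures)
  filler <- sprintf("YFL%03dW", seq_len(50 - length(hits)))
  triage_screen(hits = c(hits, filler),
                dubious_orfs = sets$dubious_orfs,
                extra_picks = sets$extra_picks,
                transformation_failures = sets$transformation_failures,
                confirmed = confirmed)
}

#' Synthetic gene models for the evolved-strain variant table
#'
#' Toy intronless gene models (one gene per chromosome, plus strand, CDS
#' starting at genomic position 1001) sized to contain every coding
#' position in the packaged variant table, with a stop codon's worth of
#' margin. These are synthetic placements — the published coordinates are
#' ORF-internal, so any model that preserves the coding offsets reproduces
#' the annotation.
#'
#' @return a [gene_models()] table.
#' @export
table2_gene_models <- function() {
  t2 <- load_fixture("table2_variants")
  genes <- unique(t2$gene)
  cds_len <- vapply(genes, function(g) {
    pos <- t2$cds_pos[t2$gene == g]
    maxp <- if (all(is.na(pos))) 0L else max(pos, na.rm = TRUE)
    as.integer(3 * ceiling(maxp / 3) + 300) # margin, multiple of 3
  }, integer(1))
  gene_models(gene = genes,
              chrom = paste0("chr_", genes),
              strand = "+",
              cds_start = 1001L,
              cds_end = 1000L + cds_len,
              upstream_window = 1000L)
}

#' Genomic variant calls for the evolved-strain variant table
#'
#' Places each packaged variant on the synthetic models of
#' [table2_gene_models()]: coding rows at `cds_start + cds_pos - 1`,
#' upstream rows at `cds_start - upstream_distance`. Quality and depth are
#' set to clean, filter-passing values.
#'
#' @param strain optional strain id (`"IMS0344"` or `"IMS0351"`) to subset.
#' @return a [variant_calls()] table with an extra `strain` column.
#' @export
table2_calls <- function(strain = NULL) {
  t2 <- load_fixture("table2_variants")
  if (!is.null(strain)) t2 <- t2[t2$strain == strain, , drop = FALSE]
  models <- table2_gene_models()
  pos <- integer(nrow(t2))
  for (i in seq_len(nrow(t2))) {
    m <- models[models$gene == t2$gene[i], ]
    pos[i] <- if (t2$location[i] == "coding") {
      m$cds_start + t2$cds_pos[i] - 1L
    } else {
      m$cds_start - t2$upstream_distance[i]
    }
  }
  n <- nrow(t2)
  calls <- variant_calls(chrom = paste0("chr_", t2$gene), pos = pos,
                         ref = t2$ref, alt = t2$alt,
                         qual = rep(50, n), depth = rep(80L, n),
                         id = t2$allele)
  calls$strain <- t2$strain
  calls
}

#' Codon-consistency verdicts for the evolved-strain variant table
#'
#' Runs every coding row of the packaged variant table through
#' [consistency_check()] against the standard genetic code.
#'
#' @return data frame with columns `strain`, `allele`, `nt_change`,
#'   `aa_change`, `codon_no`, `verdict`.
#' @export
table2_consistency <- function() {
  t2 <- load_fixture("table2_variants")
  t2 <- t2[t2$location == "coding", , drop = FALSE]
  verdict <- character(nrow(t2))
  codon_no <- integer(nrow(t2))
  for (i in seq_len(nrow(t2))) {
    codon_no[i] <- codon_index(t2$cds_pos[i])$codon_no
    verdict[i] <- consistency_check(t2$ref[i], t2$alt[i], t2$cds_pos[i],
                                    t2$aa_ref[i], t2$aa_alt[i],
                                    t2$aa_pos[i])
  }
  data.frame(strain = t2$strain, allele = t2$allele,
             nt_change = t2$nt_change,
             aa_change = paste0(t2$aa_ref, t2$aa_pos, t2$aa_alt),
             codon_no = codon_no, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Allele attrition between an evolved strain and its F3 segregant
#'
#' Compares the mutated-allele set of an evolved strain (from the packaged
#' variant table) with the genotype of a backcross segregant (from the
#' packaged strain table): alleles present in both were retained through
#' selection, the set difference was lost.
#'
#' @param evolved_strain evolved strain id (e.g. `"IMS0351"`).
#' @param segregant_strain segregant id (e.g. `"IMS0357"`).
#' @return list with `retained`, `lost`, `n_retained`, `n_lost`.
#' @export
f3_attrition <- function(evolved_strain, segregant_strain) {
  t2 <- load_fixture("table2_variants")
  evolved_alleles <- t2$allele[t2$strain == evolved_strain]
  check_that(length(evolved_alleles) > 0,
             paste("no variants recorded for strain", evolved_strain))
  t3 <- load_fixture("table3_genotypes")
  row <- t3[t3$strain == segregant_strain, , drop = FALSE]
  check_that(nrow(row) == 1,
             paste("unknown segregant strain", segregant_strain))
  seg_alleles <- strsplit(row$mutated_alleles, ";", fixed = TRUE)[[1]]
  retained <- intersect(evolved_alleles, seg_alleles)
  lost <- setdiff(evolved_alleles, seg_alleles)
  list(retained = retained, lost = lost,
       n_retained = length(retained), n_lost = length(lost))
}

#' Backcross scenario for an evolved lineage
#'
#' Builds the locus map, genotypes, phenotype model and configuration for
#' simulating the backcross series of one evolved lineage: each mutated
#' allele sits on its own chromosome (the mutated genes lie on different
#' chromosomes, so the unlinked closed form applies), the causal set is the
#' pair of transcription-factor alleles retained in both lineages, and an
#' unlinked URA3 marker locus enforces native-marker spore selection.
#'
#' @param evolved_strain `"IMS0344"` or `"IMS0351"`.
#' @param n_cycles backcross cycles (default 3).
#' @return list with `loci`, `evolved`, `naive`, `phenotype`, `config`.
#' @export
lineage_scenario <- function(evolved_strain = c("IMS0344", "IMS0351"),
                             n_cycles = 3) {
  evolved_strain <- match.arg(evolved_strain)
  t2 <- load_fixture("table2_variants")
  alleles <- t2$allele[t2$strain == evolved_strain]
  causal <- alleles[grepl("^(rpn4|rtg1)", alleles)]
  loci <- locus_map(
    id = c(alleles, "URA3"),
    chrom = paste0("chr", seq_len(length(alleles) + 1)),
    map_pos = 0,
    role = c(ifelse(alleles %in% causal, "causal", "neutral"), "marker"))
  evolved <- haploid_genotype(loci, "evolved", mating_type = "a")
  naive <- haploid_genotype(loci, "naive", mating_type = "alpha")
  list(loci = loci, evolved = evolved, naive = naive,
       phenotype = phenotype_model("all_causal_required", causal = causal),
       config = backcross_config(n_cycles = n_cycles,
                                 marker_locus = "URA3"))
}
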