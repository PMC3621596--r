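test_that("codon arithmetic maps coding positions to codons", {
  ci <- codon_index(c(1, 2, 3, 4, 1518, 3974))
  expect_equal(ci$codon_no, c(1, 1, 1, 2, 506, 1325))
  expect_equal(ci$codon_offset, c(1, 2, 3, 1, 3, 2))
  # property over a large range: (codon_no-1)*3 < pos <= codon_no*3
  pos <- seq_len(1e6)
  ci <- codon_index(pos)
  expect_true(all((ci$codon_no - 1) * 3 < pos & pos <= ci$codon_no * 3))
  expect_true(all(ci$codon_offset %in% 1:3))
  expect_error(codon_index(0), ">= 1")
})

test_that("the built-in genetic code matches the Biostrings table", {
  skip_if_not_installed("Biostrings")
  code <- evotol:::GENETIC_CODE_TABLE
  ref <- Biostrings::GENETIC_CODE
  expect_setequal(names(code), names(ref))
  # as.character drops Biostrings' extra attributes before comparison
  expect_identical(unname(code[names(ref)]), as.character(ref))
})

test_that("consistency check verifies reported amino-acid changes", {
  # K506N from G1518C: K codons {AAA, AAG}; only AAG has G at offset 3
  expect_equal(consistency_check("G", "C", 1518, "K", "N", 506),
               "consistent")
  # Q516* from C1546T: CAA->TAA and CAG->TAG are both stops
  expect_equal(consistency_check("C", "T", 1546, "Q", "*", 516),
               "consistent")
  # nt 2543 lies in codon 848, not 736
  expect_equal(consistency_check("T", "G", 2543, "F", "V", 736),
               "position_mismatch")
  # no serine codon with G at offset 1 can yield proline
  expect_equal(consistency_check("G", "C", 4, "S", "P", 2),
               "inconsistent")
  expect_error(consistency_check("A", "G", 3, "K", "B", 1), "unknown")
})

test_that("consistency verdict agrees with exhaustive 64-codon oracle", {
  code <- evotol:::GENETIC_CODE_TABLE
  bases <- c("A", "C", "G", "T")
  withr::with_seed(31, cases <- replicate(200, {
    codon <- sample(names(code), 1)
    offset <- sample(1:3, 1)
    ref_b <- substr(codon, offset, offset)
    alt_b <- sample(setdiff(bases, ref_b), 1)
    mutated <- codon
    substr(mutated, offset, offset) <- alt_b
    codon_no <- sample(1:500, 1)
    c(ref_b, alt_b, (codon_no - 1) * 3 + offset,
      code[[codon]], code[[mutated]], codon_no)
  }, simplify = FALSE))
  for (cs in cases) {
    verdict <- consistency_check(cs[1], cs[2], as.integer(cs[3]),
                                 cs[4], cs[5], as.integer(cs[6]))
    # constructed from a real codon, so always consistent
    expect_equal(verdict, "consistent")
  }
  # verdict depends only on existence: an aa pair impossible for every
  # codon at that offset is inconsistent
  expect_equal(consistency_check("A", "C", 1, "M", "K", 1), "inconsistent")
})

test_that("location classification handles both strands and upstream", {
  models <- gene_models(gene = c("PLUS", "MINUS"),
                        chrom = c("c1", "c2"), strand = c("+", "-"),
                        cds_start = c(1001, 2001), cds_end = c(1900, 2900))
  calls <- variant_calls(chrom = c("c1", "c1", "c2"),
                         pos = c(1003, 705, 2898),
                         ref = c("A", "G", "A"), alt = c("G", "C", "C"),
                         qual = rep(50, 3), depth = rep(50, 3))
  ann <- classify_location(calls, models)
  expect_equal(ann$location_class, c("coding", "upstream", "coding"))
  expect_equal(ann$cds_pos[1], 3L)
  expect_equal(ann$upstream_distance[2], 296L)
  # minus strand: cds_pos from the 3' end, alleles reverse-complemented
  expect_equal(ann$cds_pos[3], 3L)
  expect_equal(ann$cds_ref[3], "T")
  expect_equal(ann$cds_alt[3], "G")
  # unmatched positions are intergenic
  far <- variant_calls("c1", 50000, "A", "G", 50, 50)
  expect_equal(classify_location(far, models)$location_class, "intergenic")
})

test_that("cds coordinate conversion round-trips on both strands", {
  models <- gene_models(gene = c("P", "M"), chrom = c("c", "c"),
                        strand = c("+", "-"),
                        cds_start = c(101, 5001), cds_end = c(400, 5300))
  for (j in 1:2) {
    m <- models[j, ]
    for (pos in c(m$cds_start, m$cds_start + 7, m$cds_end)) {
      cds <- evotol:::genomic_to_cds(pos, m)
      expect_equal(evotol:::cds_to_genomic(cds, m), pos)
    }
  }
})

test_that("overlapping models annotate against all and flag ambiguity", {
  models <- gene_models(gene = c("A", "B"), chrom = c("c", "c"),
                        strand = c("+", "+"),
                        cds_start = c(100, 150), cds_end = c(400, 450))
  call <- variant_calls("c", 200, "A", "G", 50, 50)
  ann <- classify_location(call, models)
  expect_equal(nrow(ann), 2L)
  expect_true(all(ann$ambiguous))
})

test_that("packaged variant table annotates to the published counts", {
  tc <- table2_calls()
  ann <- classify_location(tc, table2_gene_models())
  ann$strain <- tc$strain[match(paste(ann$chrom, ann$pos),
                                paste(tc$chrom, tc$pos))]
  expect_equal(unname(count_by_class(ann, "IMS0344")), c(4L, 0L))
  expect_equal(unname(count_by_class(ann, "IMS0351")), c(5L, 2L))
  expect_equal(unname(count_by_class(ann[0, ])), c(0L, 0L))
  # upstream distances match the published placements
  up <- ann[ann$location_class == "upstream", ]
  expect_setequal(up$upstream_distance, c(296L, 984L))
  # every coding verdict is consistent except the known codon mismatch
  cons <- table2_consistency()
  expect_equal(nrow(cons), 9L)
  expect_false(any(cons$verdict == "inconsistent"))
  expect_equal(cons$verdict[cons$allele == "sto1-2"], "position_mismatch")
  expect_true(all(cons$verdict[cons$allele != "sto1-2"] == "consistent"))
})
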