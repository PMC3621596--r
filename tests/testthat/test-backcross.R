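two_locus_map <- function(d = Inf) {
  if (is.finite(d)) {
    locus_map(id = c("A", "B"), chrom = c("c1", "c1"),
              map_pos = c(0, d), role = c("causal", "neutral"))
  } else {
    locus_map(id = c("A", "B"), chrom = c("c1", "c2"),
              map_pos = c(0, 0), role = c("causal", "neutral"))
  }
}

test_that("Haldane map function has the right endpoints and values", {
  expect_equal(recombination_fraction(0), 0)
  expect_equal(recombination_fraction(Inf), 0.5)
  expect_equal(recombination_fraction(10), 0.5 * (1 - exp(-0.2)))
  expect_error(recombination_fraction(-1), "non-negative")
})

test_that("every tetrad segregates 2:2 at heterozygous loci", {
  loci <- two_locus_map(10)
  ev <- haploid_genotype(loci, "evolved")
  na <- haploid_genotype(loci, "naive")
  withr::with_seed(7, {
    for (i in 1:200) {
      spores <- meiosis(ev, na, loci)
      for (locus in loci$id) {
        states <- vapply(spores, function(s) s$alleles[[locus]], "")
        expect_equal(sum(states == "evolved"), 2L)
      }
      # mating types also 2:2
      mts <- vapply(spores, function(s) s$mating_type, "")
      expect_equal(sum(mts == "a"), 2L)
    }
  })
})

test_that("unlinked loci assort independently, linked per the map", {
  spore_classes <- function(loci, n, seed) {
    ev <- haploid_genotype(loci, "evolved")
    na <- haploid_genotype(loci, "naive")
    withr::with_seed(seed, {
      out <- character(0)
      for (i in seq_len(n)) {
        spores <- meiosis(ev, na, loci)
        out <- c(out, vapply(spores, function(s) {
          paste(s$alleles[c("A", "B")], collapse = "/")
        }, ""))
      }
      out
    })
  }
  # independent assortment: 1:1:1:1 over the four spore classes
  cls <- spore_classes(two_locus_map(Inf), 2500, seed = 11)
  chi <- chisq.test(table(cls))
  expect_gt(chi$p.value, 0.001)

  # 10 cM linkage: recombinant frequency ~ 0.0906
  cls10 <- spore_classes(two_locus_map(10), 2500, seed = 13)
  recomb <- mean(cls10 %in% c("evolved/naive", "naive/evolved"))
  # 3 MC standard errors on ~5000 effective independent spores
  expect_lt(abs(recomb - recombination_fraction(10)), 0.013)
})

test_that("segregant selection honours phenotype and marker rules", {
  loci <- locus_map(id = c("caus", "neut", "URA3"),
                    chrom = c("c1", "c2", "c3"), map_pos = 0,
                    role = c("causal", "neutral", "marker"))
  phen <- phenotype_model("all_causal_required", causal = "caus")
  config <- backcross_config(marker_locus = "URA3")
  mk <- function(caus, ura) {
    haploid_genotype(loci, c(caus = caus, neut = "naive", URA3 = ura))
  }
  good <- mk("evolved", "evolved")
  no_marker <- mk("evolved", "naive")
  no_causal <- mk("naive", "evolved")
  withr::with_seed(3, {
    sel <- select_segregant(list(good, no_marker, no_causal), phen, config)
    expect_identical(sel$alleles, good$alleles)
    expect_null(select_segregant(list(no_marker, no_causal), phen, config))
  })
  # additive phenotype: spore within epsilon of the full score is eligible
  aphen <- phenotype_model("additive_threshold", causal = "caus",
                           effects = c(caus = 1), epsilon = 0)
  withr::with_seed(3, {
    expect_null(select_segregant(list(no_causal), aphen, config))
    expect_identical(select_segregant(list(good), aphen, config)$alleles,
                     good$alleles)
  })
  # unsatisfiable phenotype is a config error
  expect_error(run_backcross_series(no_causal, mk("naive", "naive"), loci,
                                    phen, config), "unsatisfiable")
})

test_that("retention matches the Mendelian closed forms", {
  sc <- lineage_scenario("IMS0344")
  ret <- estimate_retention(sc$evolved, sc$naive, sc$loci, sc$phenotype,
                            sc$config, n_replicates = 3000, seed = 5)
  # causal loci and the selected marker are retained always
  expect_true(all(ret$retention[ret$role %in% c("causal", "marker")] == 1))
  # unlinked neutral loci: (1/2)^3 within 3 MC standard errors
  se <- sqrt(0.125 * 0.875 / 3000)
  neutral <- ret$retention[ret$role == "neutral"]
  expect_true(all(abs(neutral - 0.125) <= 3 * se))
  # single cycle: 0.5
  sc1 <- lineage_scenario("IMS0344", n_cycles = 1)
  ret1 <- estimate_retention(sc1$evolved, sc1$naive, sc1$loci,
                             sc1$phenotype, sc1$config,
                             n_replicates = 3000, seed = 6)
  se1 <- sqrt(0.25 / 3000)
  expect_true(all(abs(ret1$retention[ret1$role == "neutral"] - 0.5)
                  <= 3 * se1))
  # seeded reproducibility
  ret_again <- estimate_retention(sc$evolved, sc$naive, sc$loci,
                                  sc$phenotype, sc$config,
                                  n_replicates = 100, seed = 5)
  ret_again2 <- estimate_retention(sc$evolved, sc$naive, sc$loci,
                                   sc$phenotype, sc$config,
                                   n_replicates = 100, seed = 5)
  expect_identical(ret_again, ret_again2)
})

test_that("neutral retention decreases with cycles, rises with linkage", {
  base <- function(d, cycles, seed) {
    loci <- locus_map(id = c("caus", "neut", "URA3"),
                      chrom = c("c1", if (is.finite(d)) "c1" else "c2",
                                "c3"),
                      map_pos = c(0, if (is.finite(d)) d else 0, 0),
                      role = c("causal", "neutral", "marker"))
    ev <- haploid_genotype(loci, "evolved")
    na <- haploid_genotype(loci, "naive")
    ret <- estimate_retention(ev, na, loci,
                              phenotype_model(causal = "caus"),
                              backcross_config(n_cycles = cycles,
                                               marker_locus = "URA3"),
                              n_replicates = 1500, seed = seed)
    ret$retention[ret$locus == "neut"]
  }
  # monotone in cycles (unlinked)
  r_by_cycle <- vapply(1:3, function(n) base(Inf, n, 40 + n), numeric(1))
  expect_true(all(diff(r_by_cycle) < 0))
  # monotone in linkage at fixed cycles: closer means better retained
  r_by_d <- vapply(c(5, 25, Inf), function(d) base(d, 3, 50), numeric(1))
  expect_true(all(diff(r_by_d) < 0))
  # linked closed form: (1 - r)^3 at 10 cM
  r10 <- base(10, 3, 77)
  expected <- (1 - recombination_fraction(10))^3
  expect_equal(r10, expected, tolerance = 0.05)
})
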