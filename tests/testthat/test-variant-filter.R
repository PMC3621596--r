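toy_calls <- function() {
  variant_calls(
    chrom = rep("chr2", 6), pos = c(100, 200, 300, 400, 500, 600),
    ref = rep("A", 6),
    alt = c("G", "G", "G", "N", "G", "G"),
    qual = c(19, 30, 30, 30, 30, 30),
    depth = c(30, 9, 450, 30, 30, 30))
}

toy_parental <- function() {
  variant_calls(chrom = "chr2", pos = 500, ref = "A", alt = "G",
                qual = 40, depth = 50)
}

test_that("each filter rule keeps and removes the right calls", {
  calls <- toy_calls()
  amb <- filter_ambiguous(calls)
  expect_equal(amb$removed$pos, 400) # alt = N
  expect_true(all(amb$kept$alt %in% c("A", "C", "G", "T")))
  # IUPAC purine code is removed too
  r <- filter_ambiguous(variant_calls("c", 1, "A", "R", 30, 30))
  expect_equal(nrow(r$kept), 0L)

  thr <- filter_thresholds(calls)
  expect_setequal(thr$removed$pos, c(100, 200, 300))
  # boundary values are kept: qual 20, depth 10 and 400 inclusive
  b <- filter_thresholds(variant_calls(rep("c", 3), 1:3, rep("A", 3),
                                       rep("G", 3), c(20, 30, 30),
                                       c(30, 10, 400)))
  expect_equal(nrow(b$kept), 3L)

  par <- subtract_parental(calls, toy_parental())
  expect_equal(par$removed$pos, 500)
  # allele-aware: a different alt at the shared site is kept
  other <- variant_calls("chr2", 500, "A", "T", 40, 50)
  expect_equal(nrow(subtract_parental(other, toy_parental())$kept), 1L)
  # empty parental set keeps everything
  expect_equal(nrow(subtract_parental(calls, toy_parental()[0, ])$kept),
               nrow(calls))
  expect_warning(subtract_parental(
    variant_calls("chrX", 1, "A", "G", 30, 30), toy_parental()),
    "coordinate")
})

test_that("the full chain removes one call per rule on the toy set", {
  report <- run_filter_chain(toy_calls(), toy_parental())
  expect_equal(nrow(report$survivors), 1L)
  expect_equal(report$survivors$pos, 600)
  expect_equal(unname(report$counts[c("ambiguous_base", "quality",
                                      "depth", "parental_shared")]),
               c(1L, 1L, 2L, 1L))
  # removal counts plus the survivors entry account for every input call
  expect_equal(sum(report$counts), report$n_input)
  # all-clean input passes through untouched
  clean <- variant_calls(rep("chr1", 3), c(10, 20, 30), rep("A", 3),
                         rep("G", 3), rep(30, 3), rep(30, 3))
  expect_equal(nrow(run_filter_chain(clean)$survivors), 3L)
})

test_that("multi-allelic records are split before filtering", {
  calls <- variant_calls("chr1", 100, "A", "G,T", 30, 50)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt, c("G", "T"))
  # insertions/deletions get the distinct indel tag
  indel <- variant_calls("chr1", 5, "A", "AT", 30, 50)
  rep <- run_filter_chain(indel)
  expect_equal(rep$removed$rule, "indel")
})

test_that("chain is idempotent, order-invariant and shrinking", {
  key <- function(calls) paste(calls$chrom, calls$pos, calls$ref,
                               calls$alt)
  # full-strength property run over many random call sets
  n_sets <- 120
  for (i in seq_len(n_sets)) {
    calls <- random_call_set(n = 40, seed = 1000 + i)
    parental <- random_call_set(n = 15, seed = 2000 + i)
    rep1 <- suppressWarnings(run_filter_chain(calls, parental))
    # survivors are a subset of the input
    expect_true(all(key(rep1$survivors) %in% key(calls)))
    # idempotence
    rep2 <- suppressWarnings(run_filter_chain(rep1$survivors, parental))
    expect_equal(key(rep2$survivors), key(rep1$survivors))
    expect_equal(nrow(rep2$removed), 0L)
    # removals + survivors partition the input
    expect_equal(nrow(rep1$survivors) + nrow(rep1$removed), nrow(calls))
    # every removed call carries exactly one provenance rule
    expect_false(anyNA(rep1$removed$rule))
  }
})

test_that("survivor set is invariant to rule application order", {
  config <- filter_config()
  rules <- list(
    ambig = function(calls) filter_ambiguous(calls, config)$kept,
    thresh = function(calls) filter_thresholds(calls, config)$kept
  )
  key <- function(calls) sort(paste(calls$chrom, calls$pos, calls$ref,
                                    calls$alt))
  for (i in 1:30) {
    calls <- random_call_set(n = 50, seed = 3000 + i)
    parental <- random_call_set(n = 10, seed = 4000 + i)
    chain_out <- key(suppressWarnings(
      run_filter_chain(calls, parental))$survivors)
    # apply the standalone rules in a random order, then indel/parental
    withr::with_seed(i, ord <- sample(names(rules)))
    staged <- calls
    for (r in ord) staged <- rules[[r]](staged)
    staged <- staged[nchar(staged$ref) == 1 & nchar(staged$alt) == 1, ]
    staged <- suppressWarnings(subtract_parental(staged, parental)$kept)
    expect_equal(key(staged), chain_out)
  }
})

test_that("generated variant tables survive the chain per their labels", {
  spec <- variant_spec(n_evolved_specific = 5, n_parental_shared = 3,
                       n_noise_calls = 4, seed = 7)
  gen <- generate_variants(spec)
  expect_equal(nrow(gen$truth), 12L)
  report <- run_filter_chain(gen$evolved, gen$parental)
  expect_equal(nrow(report$survivors), 5L)
  # labels partition the call set
  expect_equal(sort(table(gen$truth$label), decreasing = TRUE)[["evolved_specific"]], 5L)
  # each noise call is removed by exactly the rule it was planted with
  removed <- merge(report$removed, gen$truth,
                   by = c("chrom", "pos", "ref", "alt"))
  noise <- removed[!removed$label %in% c("parental_shared"), ]
  rule_map <- c(ambiguous_base = "ambiguous_base", quality = "quality",
                depth_low = "depth", depth_high = "depth")
  expect_equal(noise$rule, unname(rule_map[noise$label]))
  # no noise, no parental: everything passes
  all_clean <- generate_variants(variant_spec(n_evolved_specific = 6,
                                              n_parental_shared = 0,
                                              n_noise_calls = 0, seed = 2))
  expect_equal(nrow(run_filter_chain(all_clean$evolved,
                                     all_clean$parental)$survivors), 6L)
  # reproducibility
  expect_identical(gen, generate_variants(spec))
})
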