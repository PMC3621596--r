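test_that("hypergeometric tail matches hand-enumerated tables", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1.0)
  expect_equal(hypergeom_tail(2, 2, 2, 10), 1 / 45)
  # brute-force sum over i = 3, 4, 5: 1126/15504
  expect_equal(hypergeom_tail(3, 5, 5, 20), 1126 / 15504)
  expect_error(hypergeom_tail(3, 2, 2, 10), "impossible")
})

test_that("log-space tail agrees with direct enumeration and phyper", {
  for (N in c(8, 17, 30)) {
    for (K in seq(0, N, by = 3)) {
      for (n in seq(1, N, by = 4)) {
        for (k in seq(max(0, n + K - N), min(K, n))) {
          p <- hypergeom_tail(k, K, n, N)
          expect_equal(p, hyper_tail_bruteforce(k, K, n, N),
                       tolerance = 1e-12)
          expect_equal(p, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("annotation propagation closes over is_a with set semantics", {
  parents <- data.frame(child = c("c", "p"), parent = c("p", "root"))
  tab <- go_annotation_table(
    data.frame(gene = "g1", term = "c"), parents)
  prop <- propagate_annotations(tab)
  expect_setequal(prop$annotations$term[prop$annotations$gene == "g1"],
                  c("c", "p", "root"))
  # idempotent
  expect_identical(propagate_annotations(prop)$annotations,
                   prop$annotations)
  # diamond: two paths to the root count once per gene
  diamond <- data.frame(child = c("d", "d", "l", "r"),
                        parent = c("l", "r", "top", "top"))
  dtab <- propagate_annotations(go_annotation_table(
    data.frame(gene = "g", term = "d"), diamond))
  expect_equal(sum(dtab$annotations$term == "top"), 1L)
  expect_setequal(dtab$annotations$term, ancestors_dfs("d", diamond))
  # cycles are rejected
  expect_error(go_annotation_table(
    data.frame(gene = "g", term = "a"),
    data.frame(child = c("a", "b"), parent = c("b", "a"))), "cycle")
})

test_that("propagated per-term counts are monotone child to ancestor", {
  withr::with_seed(21, {
    terms <- paste0("t", 1:15)
    parents <- data.frame(child = terms,
                          parent = c("root", sample(c("root", terms[1:5]),
                                                    14, replace = TRUE)))
    # drop self edges if sampled
    parents <- parents[parents$child != parents$parent, ]
    ann <- data.frame(gene = sample(paste0("g", 1:40), 60, replace = TRUE),
                      term = sample(terms, 60, replace = TRUE))
  })
  tab <- propagate_annotations(go_annotation_table(ann, parents))
  counts <- table(tab$annotations$term)
  for (i in seq_len(nrow(parents))) {
    ch <- parents$child[i]; pa <- parents$parent[i]
    n_ch <- if (ch %in% names(counts)) counts[[ch]] else 0
    n_pa <- if (pa %in% names(counts)) counts[[pa]] else 0
    expect_gte(n_pa, n_ch)
  }
})

test_that("BH step-up matches the hand calculation and p.adjust", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  withr::with_seed(8, p <- runif(200)^2)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  # permutation invariance modulo re-ordering
  perm <- sample(seq_along(p))
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted terms are flagged enriched, degenerate studies are not", {
  population <- c(paste0("g", 1:5154))
  study <- paste0("g", 1:35)
  planted_genes <- paste0("g", 1:9)
  tab <- generate_go_annotations(
    population, planted = list("GO:PLANT" = planted_genes),
    background_per_term = 31, seed = 4)
  res <- enrich(study, population, tab)
  row <- res[res$term == "GO:PLANT", ]
  expect_equal(row$k, 9L)
  expect_equal(row$K, 40L)
  expect_true(row$enriched)
  # study == population: all p = 1, nothing enriched
  res_all <- enrich(population, population, tab)
  expect_true(all(res_all$p == 1))
  expect_false(any(res_all$enriched))
  # study genes outside the population are reported by name
  expect_error(enrich(c("g1", "absent"), population, tab), "absent")
})

test_that("p-values are valid under the null", {
  population <- paste0("g", 1:400)
  withr::with_seed(99, {
    terms <- lapply(1:40, function(i) sample(population, 25))
    names(terms) <- paste0("GO:N", 1:40)
    ann <- do.call(rbind, lapply(names(terms), function(t) {
      data.frame(gene = terms[[t]], term = t)
    }))
    tab <- propagate_annotations(go_annotation_table(ann))
    pvals <- unlist(lapply(1:50, function(rep) {
      study <- sample(population, 30)
      enrich(study, population, tab)$p
    }))
  })
  alpha <- 0.05
  mc_err <- sqrt(alpha * (1 - alpha) / length(pvals))
  expect_lte(mean(pvals < alpha), alpha + 3 * mc_err)
})
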