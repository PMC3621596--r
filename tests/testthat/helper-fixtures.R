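# Shared test helpers: random call-set builder and brute-force oracles.

# random variant call set with a mix of clean and rule-violating calls
random_call_set <- function(n, seed) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(c(bases, "N"), n, replace = TRUE,
                  prob = c(rep(0.23, 4), 0.08))
    alt <- vapply(ref, function(r) {
      sample(c(setdiff(bases, r), "R", "AT"), 1L,
             prob = c(rep(0.28, length(setdiff(bases, r))), 0.08, 0.08))
    }, character(1))
    variant_calls(
      chrom = sample(paste0("chr", 1:4), n, replace = TRUE),
      pos = sample.int(1e6, n),
      ref = ref, alt = alt,
      qual = stats::runif(n, 0, 80),
      depth = sample.int(600, n))
  })
}

# brute-force upper-tail hypergeometric by direct summation of
# choose() products (no log space) -- the enumeration oracle
hyper_tail_bruteforce <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# naive DFS ancestor closure used as oracle for annotation propagation
ancestors_dfs <- function(term, parents) {
  out <- term
  stack <- term
  while (length(stack) > 0) {
    t <- stack[[1]]
    stack <- stack[-1]
    ps <- parents$parent[parents$child == t]
    new <- setdiff(ps, out)
    out <- c(out, new)
    stack <- c(stack, new)
  }
  sort(out)
}
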