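# Hypergeometric (one-sided Fisher exact) GO-term enrichment with
# annotation propagation over an is_a hierarchy and Benjamini-Hochberg
# false-discovery-rate control.

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeom(N, K, n)` — the one-sided Fisher
#' exact p-value for over-representation in a 2x2 table with `k` study genes
#' annotated to the term, `K` population genes annotated, study size `n` and
#' population size `N`. The sum is accumulated in log space
#' (log-binomial coefficients + log-sum-exp) for numerical stability.
#'
#' @param k study genes annotated to the term.
#' @param K population genes annotated to the term.
#' @param n study-set size.
#' @param N population size.
#' @return the upper-tail p-value in `[0, 1]`.
#' @examples
#' hypergeom_tail(2, 2, 2, 10) # 1/45
#' @export
hypergeom_tail <- function(k, K, n, N) {
  check_that(is_number(k) && is_number(K) && is_number(n) && is_number(N),
             "k, K, n, N must be single numbers")
  check_that(K <= N && n <= N, "K and n must not exceed N")
  check_that(k >= 0 && k <= min(K, n), "impossible 2x2 table: need 0 <= k <= min(K, n)")
  if (k <= max(0, n + K - N)) return(1)
  i <- seq(k, min(K, n))
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(1, p)
}

#' Construct a GO annotation table
#'
#' @param annotations data frame with columns `gene`, `term` (one row per
#'   direct annotation).
#' @param parents data frame with columns `child`, `parent` giving is_a
#'   edges, or `NULL` for a flat vocabulary.
#' @param term_names optional named character vector mapping term id to a
#'   human-readable name.
#' @return object of class `go_annotation_table`.
#' @export
go_annotation_table <- function(annotations, parents = NULL,
                                term_names = NULL) {
  check_that(all(c("gene", "term") %in% names(annotations)),
             "annotations must have columns gene, term")
  if (is.null(parents)) {
    parents <- data.frame(child = character(), parent = character(),
                          stringsAsFactors = FALSE)
  }
  check_that(all(c("child", "parent") %in% names(parents)),
             "parents must have columns child, parent")
  ancestors <- term_ancestors(parents) # also detects cycles
  known <- union(union(parents$child, parents$parent), names(ancestors))
  if (nrow(parents) > 0) {
    missing <- setdiff(unique(annotations$term), known)
    if (length(missing) > 0) {
      stop("annotated terms absent from the hierarchy: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(annotations = unique(annotations[c("gene", "term")]),
                 parents = unique(parents[c("child", "parent")]),
                 term_names = term_names,
                 propagated = FALSE),
            class = "go_annotation_table")
}

# reflexive-transitive ancestor sets over is_a edges; stops on cycles.
# Returns a named list term -> character vector of ancestors (term included).
term_ancestors <- function(parents) {
  terms <- unique(c(parents$child, parents$parent))
  parent_of <- split(parents$parent, parents$child)
  anc <- stats::setNames(vector("list", length(terms)), terms)
  state <- stats::setNames(integer(length(terms)), terms) # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) {
      stop("cycle detected in term hierarchy at ", t, call. = FALSE)
    }
    state[[t]] <<- 1L
    out <- t
    for (p in parent_of[[t]]) out <- union(out, visit(p))
    anc[[t]] <<- out
    state[[t]] <<- 2L
    out
  }
  for (t in terms) visit(t)
  anc
}

#' Propagate annotations up the term hierarchy
#'
#' Extends every gene's annotation set with all is_a ancestors of its
#' directly annotated terms (reflexive-transitive closure). Set semantics:
#' in a diamond hierarchy an ancestor reachable by two paths is counted once
#' per gene. The operation is idempotent.
#'
#' @param table a [go_annotation_table()].
#' @return the table with closed annotations and `propagated = TRUE`.
#' @export
propagate_annotations <- function(table) {
  stopifnot(inherits(table, "go_annotation_table"))
  if (nrow(table$parents) == 0) {
    table$propagated <- TRUE
    return(table)
  }
  anc <- term_ancestors(table$parents)
  ann <- table$annotations
  expand <- lapply(seq_len(nrow(ann)), function(i) {
    t <- ann$term[i]
    a <- anc[[t]]
    if (is.null(a)) a <- t
    data.frame(gene = ann$gene[i], term = a, stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, expand))
  rownames(out) <- NULL
  table$annotations <- out
  table$propagated <- TRUE
  table
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Step-up FDR adjustment: for sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (Q_FDR) in the input order.
#' @export
bh_fdr <- function(pvalues) {
  check_that(is.numeric(pvalues), "pvalues must be numeric")
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(scaled))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' GO-term over-representation analysis of a study gene set
#'
#' For every term annotated in the population (after propagation), builds
#' the 2x2 table of study vs population annotation counts, computes the
#' one-sided hypergeometric p-value with [hypergeom_tail()], and controls
#' the false discovery rate with [bh_fdr()]. A term is flagged enriched when
#' its adjusted value falls below `alpha`.
#'
#' @param study_set character vector of study genes; must be a subset of
#'   `population`.
#' @param population character vector of background genes (typically every
#'   strain screened, not the whole genome).
#' @param table a [go_annotation_table()]; propagated automatically if not
#'   already.
#' @param alpha FDR threshold (default 0.05).
#' @param min_population_count terms annotated to fewer than this many
#'   population genes are skipped as degenerate (default 2).
#' @return data frame sorted by `(q, p)` with columns `term`, `name`, `k`,
#'   `K`, `n`, `N`, `p`, `q`, `enriched`.
#' @export
enrich <- function(study_set, population, table, alpha = 0.05,
                   min_population_count = 2) {
  stopifnot(inherits(table, "go_annotation_table"))
  study_set <- unique(as.character(study_set))
  population <- unique(as.character(population))
  offenders <- setdiff(study_set, population)
  if (length(offenders) > 0) {
    stop("study genes absent from population: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  if (!table$propagated) table <- propagate_annotations(table)
  ann <- table$annotations
  ann <- ann[ann$gene %in% population, , drop = FALSE]
  N <- length(population)
  n <- length(study_set)
  K_tab <- table(ann$term)
  terms <- names(K_tab)[K_tab >= min_population_count]
  if (length(terms) == 0) {
    return(data.frame(term = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  in_study <- ann$gene %in% study_set
  k_tab <- table(factor(ann$term[in_study], levels = terms))
  K <- as.integer(K_tab[terms])
  k <- as.integer(k_tab[terms])
  p <- vapply(seq_along(terms),
              function(i) hypergeom_tail(k[i], K[i], n, N), numeric(1))
  q <- bh_fdr(p)
  nm <- if (is.null(table$term_names)) rep(NA_character_, length(terms)) else
    unname(table$term_names[terms])
  res <- data.frame(term = terms, name = nm, k = k, K = K, n = n, N = N,
                    p = p, q = q, enriched = q < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
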