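#' Build the weighted k-bounded selector hypergraph
#'
#' Enumerates, for every event, every candidate parent set of size
#' `0..k-1` drawn from the other events, and scores each candidate
#' hyperedge by its log-likelihood and BIC contribution. The empty parent
#' set stands for the edge whose parents are all root parents: its weight
#' depends only on the child's marginal, and hyperedges mixing real and
#' root parents need not be materialized because root parents are ignored
#' in the weight.
#'
#' Candidates are ordered children-ascending, then by parent-set size,
#' then lexicographically — a reproducible variable order for the
#' optimizer.
#'
#' @param data Binary matrix (see [as_binary_matrix()]).
#' @param k Hyperedge bound (child plus at most `k - 1` parents),
#'   `2 <= k <= n`.
#' @param flavor,epsilon Progression-network constraint applied when
#'   scoring (see [constrain_cpd()]).
#' @param score Which weight the optimizer maximizes: `"bic"` (default) or
#'   `"loglik"`.
#' @return A `selector_graph`: a tibble with one row per candidate and
#'   columns `child` (integer), `parents` (list of integer vectors),
#'   `size`, `loglik`, `bic`, `weight`; attributes `n`, `k`, `flavor`,
#'   `epsilon`, `score`, `event_names`.
#' @export
build_selector <- function(data, k, flavor = c("monotone", "semimonotone", "general"),
                           epsilon = 0.2, score = c("bic", "loglik")) {
  flavor <- match.arg(flavor)
  score <- match.arg(score)
  d <- as_binary_matrix(data)
  n <- ncol(d)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > n) {
    stop("`k` must satisfy 2 <= k <= n (n = ", n, ")", call. = FALSE)
  }
  m <- nrow(d)
  penalty <- log(m) / 2
  rows <- vector("list", n)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    sets <- list(integer())
    for (j in seq_len(k - 1L)) {
      if (j > length(others)) break
      combs <- if (length(others) == 1L) list(others) else
        utils::combn(others, j, simplify = FALSE)  # lexicographic order
      sets <- c(sets, combs)
    }
    ll <- vapply(sets, function(p) {
      edge_loglik_weight(d, v, p, flavor = flavor, epsilon = epsilon)
    }, numeric(1))
    bic <- ll - penalty * 2^lengths(sets)
    rows[[v]] <- tibble::tibble(
      child = v, parents = sets, size = lengths(sets),
      loglik = ll, bic = bic
    )
  }
  out <- dplyr::bind_rows(rows)
  out$weight <- if (score == "bic") out$bic else out$loglik
  structure(out,
            class = c("selector_graph", class(out)),
            n = n, k = k, flavor = flavor, epsilon = epsilon,
            score = score, event_names = colnames(d))
}

selector_attr <- function(s, what) attr(s, what, exact = TRUE)

#' Drop candidates dominated by a subset with a better weight
#'
#' A candidate `(v, P)` is dominated when some proper subset `P'` of `P`
#' has weight at least as large: any acyclic selection using `P` stays
#' acyclic (and scores no worse) after swapping in `P'`, so removing the
#' dominated candidate never changes the optimum. Root-attached (empty)
#' candidates are never removed. Off by default in [learn_network()];
#' useful to shrink large programs.
#'
#' @param s A `selector_graph`.
#' @return A `selector_graph` with dominated rows removed.
#' @export
prune_dominated <- function(s) {
  stopifnot(inherits(s, "selector_graph"))
  keep <- rep(TRUE, nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$size[i] == 0L) next
    same_child <- which(s$child == s$child[i] & s$size < s$size[i])
    for (j in same_child) {
      if (all(s$parents[[j]] %in% s$parents[[i]]) && s$weight[j] >= s$weight[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- s[keep, ]
  attributes(out)[c("n", "k", "flavor", "epsilon", "score", "event_names")] <-
    attributes(s)[c("n", "k", "flavor", "epsilon", "score", "event_names")]
  class(out) <- class(s)
  out
}

#' Write a selector graph as TSV (debug dump)
#'
#' Columns: child name, comma-joined parent names, loglik, bic.
#'
#' @param s A `selector_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selector <- function(s, path) {
  stopifnot(inherits(s, "selector_graph"))
  nm <- selector_attr(s, "event_names")
  df <- tibble::tibble(
    child = nm[s$child],
    parents = vapply(s$parents, function(p) paste(nm[p], collapse = ","),
                     character(1)),
    loglik = s$loglik,
    bic = s$bic
  )
  readr::write_tsv(df, path)
  invisible(path)
}
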