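edge_keys <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character())
  unique(paste(edges$from, edges$to, sep = "\r"))
}

#' Structure-recovery metrics between true and learned edge sets
#'
#' All metrics compare the underlying simple digraphs (one directed edge
#' per parent-child pair of a hyperedge; see [underlying_graph()]).
#' `recovered_edge_pct` is 100 |M ∩ L| / |M|; the relative symmetric
#' difference is F = (|M \\ L| + |L \\ M|) / (|M| + |L|), zero iff the
#' sets coincide and one for disjoint nonempty sets; FDR = |L \\ M| / |L|
#' (0 for empty L), FNR = |M \\ L| / |M|.
#'
#' @param truth,learned Edge tables with columns `from`, `to` (as returned
#'   by [underlying_graph()]), over the same vertex universe.
#' @return `edge_metrics()`: a tibble with `recovered_pct`, `F`, `fdr`,
#'   `fnr`, `n_true_edges`, `n_learned_edges`. The scalar helpers return
#'   single numbers.
#' @export
edge_metrics <- function(truth, learned) {
  M <- edge_keys(truth)
  L <- edge_keys(learned)
  if (length(M) == 0L) {
    stop("metrics are undefined for an empty true edge set", call. = FALSE)
  }
  tp <- length(intersect(M, L))
  fp <- length(setdiff(L, M))
  fn <- length(setdiff(M, L))
  tibble::tibble(
    recovered_pct = 100 * tp / length(M),
    F = (fn + fp) / (length(M) + length(L)),
    fdr = if (length(L) == 0L) 0 else fp / length(L),
    fnr = fn / length(M),
    n_true_edges = length(M),
    n_learned_edges = length(L)
  )
}

#' @rdname edge_metrics
#' @export
recovered_edge_pct <- function(truth, learned) {
  edge_metrics(truth, learned)$recovered_pct
}

#' @rdname edge_metrics
#' @export
relative_symmetric_difference <- function(truth, learned) {
  M <- edge_keys(truth)
  L <- edge_keys(learned)
  if (length(M) + length(L) == 0L) {
    stop("relative symmetric difference is undefined for two empty edge sets",
         call. = FALSE)
  }
  (length(setdiff(M, L)) + length(setdiff(L, M))) / (length(M) + length(L))
}

#' @rdname edge_metrics
#' @export
fdr_fnr <- function(truth, learned) {
  met <- edge_metrics(truth, learned)
  c(fdr = met$fdr, fnr = met$fnr)
}

#' Build a partial order of events from precedence pairs
#'
#' Takes `a` before `b` pairs and computes the reflexive-transitive
#' closure by repeated-squaring reachability; an antisymmetry violation
#' (both `a` before `b` and `b` before `a` derivable) is an error.
#'
#' @param pairs Data frame with columns `before`, `after` (event names),
#'   or a two-column TSV path.
#' @param events Optional universe of events; defaults to those appearing
#'   in `pairs`. Events outside any pair are incomparable to everything.
#' @return A `partial_order`: list with `events` and the logical closure
#'   matrix `precedes` (`precedes[a, b]` true iff a strictly precedes b).
#' @export
partial_order <- function(pairs, events = NULL) {
  if (is.character(pairs) && length(pairs) == 1L) {
    pairs <- readr::read_tsv(pairs, col_names = c("before", "after"),
                             col_types = "cc", progress = FALSE)
  }
  stopifnot(all(c("before", "after") %in% names(pairs)))
  events <- sort(unique(c(events, pairs$before, pairs$after)))
  n <- length(events)
  adj <- matrix(FALSE, n, n, dimnames = list(events, events))
  adj[cbind(match(pairs$before, events), match(pairs$after, events))] <- TRUE
  # transitive closure: iterate boolean squaring to fixpoint
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  if (any(adj & t(adj))) {
    stop("precedence pairs are not antisymmetric (a cycle exists)",
         call. = FALSE)
  }
  structure(list(events = events, precedes = adj), class = "partial_order")
}

#' Percentage of learned edges contradicting a reference partial order
#'
#' An edge `u -> v` is *bad* when the reference order places `v` strictly
#' before `u`; edges between incomparable events are not bad. The
#' denominator counts every learned hyperedge-incidence including
#' root-attached hyperedges (one root edge per parentless event), which
#' can only dilute the percentage.
#'
#' @param fit A `pn_fit`, a `progression_network`, a `hyperdag`, or an
#'   edge table with columns `from`, `to` (in which case `n_root_edges`
#'   supplies the root-attached count).
#' @param ref A `partial_order` whose universe covers the learned events.
#' @param n_root_edges Root-attached edge count when `fit` is a bare edge
#'   table; ignored otherwise.
#' @return Percentage in `[0, 100]`.
#' @export
bad_edge_pct <- function(fit, ref, n_root_edges = 0) {
  stopifnot(inherits(ref, "partial_order"))
  if (inherits(fit, "pn_fit")) fit <- fit$network
  if (inherits(fit, "progression_network")) fit <- fit$hyperdag
  if (inherits(fit, "hyperdag")) {
    n_root_edges <- sum(vapply(fit$edges, function(e) length(e$parents) == 0L,
                               logical(1)))
    edges <- underlying_graph(fit)
  } else {
    edges <- fit
  }
  total <- nrow(edges) + n_root_edges
  if (total == 0L) return(0)
  used <- unique(c(edges$from, edges$to))
  unmapped <- setdiff(used, ref$events)
  if (length(unmapped)) {
    stop("events absent from the reference order: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  bad <- 0L
  if (nrow(edges)) {
    bad <- sum(ref$precedes[cbind(match(edges$to, ref$events),
                                  match(edges$from, ref$events))])
  }
  100 * bad / total
}

#' Calibrate epsilon against a reference partial order
#'
#' Learns one network per grid value of epsilon and returns the value
#' minimizing the bad-edge percentage (ties broken toward the smallest
#' epsilon), together with the full calibration curve. This reproduces
#' the procedure of anchoring the free MPN/SMPN parameter to prior
#' knowledge of progression pathways.
#'
#' @param data Binary matrix.
#' @param ref A `partial_order` over the data's events.
#' @param k,flavor,score Learner settings.
#' @param epsilon_grid Candidate epsilons in (0, 1).
#' @return List with `epsilon` (chosen value) and `curve` (tibble:
#'   `epsilon`, `bad_pct`, `n_learned_edges`, `objective`).
#' @export
calibrate_epsilon <- function(data, ref, k = 3, flavor = "monotone",
                              epsilon_grid = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                              score = "bic") {
  if (!length(epsilon_grid)) stop("`epsilon_grid` is empty", call. = FALSE)
  if (any(epsilon_grid <= 0 | epsilon_grid >= 1)) {
    stop("grid values must lie in (0, 1)", call. = FALSE)
  }
  curve <- purrr::map(sort(epsilon_grid), function(eps) {
    fit <- learn_network(data, k = k, flavor = flavor, epsilon = eps,
                         score = score)
    tibble::tibble(
      epsilon = eps,
      bad_pct = bad_edge_pct(fit, ref),
      n_learned_edges = nrow(underlying_graph(fit$network$hyperdag)),
      objective = fit$objective
    )
  }) |> dplyr::bind_rows()
  best <- curve$epsilon[which.min(curve$bad_pct)]   # ties -> smallest eps
  structure(list(epsilon = best, curve = curve),
            class = "epsilon_calibration")
}

#' @export
print.epsilon_calibration <- function(x, ...) {
  cat("<epsilon_calibration> chosen epsilon =", x$epsilon, "\n")
  print(x$curve)
  invisible(x)
}
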