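#' Sample a random k-bounded hyperDAG
#'
#' Draws a uniform vertex permutation, then lets each vertex pick a
#' parent-set size uniformly from `0..min(k - 1, #predecessors)` and that
#' many distinct parents uniformly among its permutation predecessors.
#' Acyclicity and k-boundedness hold by construction; a fixed seed gives a
#' bit-identical structure.
#'
#' @param n Number of events, `>= 2`.
#' @param k Hyperedge bound, `2 <= k <= n`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param names Optional event names.
#' @return A `hyperdag` with exactly one hyperedge per vertex (empty
#'   parent sets for roots).
#' @export
random_hyperdag <- function(n, k, seed = NULL, names = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (is.na(k) || k < 2L || k > n) {
    stop("`k` must satisfy 2 <= k <= n", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  edges <- vector("list", n)
  for (pos in seq_len(n)) {
    v <- perm[pos]
    preds <- perm[seq_len(pos - 1L)]
    j <- sample.int(min(k - 1L, length(preds)) + 1L, 1L) - 1L
    pa <- if (j > 0L) preds[sample.int(length(preds), j)] else integer()
    edges[[v]] <- hyperedge(v, pa)
  }
  hyperdag(n, edges, names)
}

runif_row <- function(lo, hi, size) stats::runif(size, lo, hi)

#' Attach random CPDs of a given flavor to a hyperDAG
#'
#' Distributional design: rows where the flavor allows the child to fire
#' ("signal") draw from `Uniform(signal[1], signal[2])`, rows the flavor
#' suppresses draw from `Uniform(0, epsilon)`, and general-flavor rows
#' draw from `Uniform(0.05, 0.95)`. Parentless vertices in
#' monotone/semi-monotone networks draw from the signal range so
#' progressions can start.
#'
#' @param h A `hyperdag` with one hyperedge per vertex.
#' @param flavor `"monotone"`, `"semimonotone"`, or `"general"`.
#' @param epsilon Suppressed-row bound, in (0, 1); default 0.2.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param signal Length-2 range for permitted rows; default `c(0.5, 0.95)`.
#' @return A `progression_network` (hyperdag + one `cpd_table` per vertex
#'   + flavor + epsilon).
#' @export
random_cpds <- function(h, flavor = c("monotone", "semimonotone", "general"),
                        epsilon = 0.2, seed = NULL, signal = c(0.5, 0.95)) {
  stopifnot(inherits(h, "hyperdag"))
  flavor <- match.arg(flavor)
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1) {
    stop("`epsilon` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  parent_sets <- stats::setNames(rep(list(integer()), h$n), seq_len(h$n))
  for (e in h$edges) parent_sets[[e$child]] <- e$parents
  cpds <- lapply(seq_len(h$n), function(v) {
    pa <- parent_sets[[v]]
    j <- length(pa)
    n_rows <- 2^j
    if (j == 0L) {
      p <- if (flavor == "general") runif_row(0.05, 0.95, 1) else
        runif_row(signal[1], signal[2], 1)
    } else if (flavor == "general") {
      p <- runif_row(0.05, 0.95, n_rows)
    } else {
      suppressed <- if (flavor == "monotone") {
        seq_len(n_rows) != n_rows       # all rows but all-ones
      } else {
        seq_len(n_rows) == 1L           # all-zeros row
      }
      p <- numeric(n_rows)
      p[suppressed] <- runif_row(0, epsilon, sum(suppressed))
      p[!suppressed] <- runif_row(signal[1], signal[2], sum(!suppressed))
    }
    structure(list(
      child = h$names[v], parents = h$names[pa], prob1 = p,
      observed = rep(TRUE, n_rows), n_obs = rep(NA_integer_, n_rows)
    ), class = "cpd_table")
  })
  structure(list(hyperdag = h, cpds = cpds, flavor = flavor,
                 epsilon = epsilon), class = "progression_network")
}

#' Forward-sample cross-sectional data from a progression network
#'
#' Vertices are visited in topological order; each is drawn
#' `Bernoulli(theta(parent assignment))` row-wise. A fixed seed gives a
#' bit-identical matrix.
#'
#' @param net A `progression_network` with CPDs.
#' @param m Number of samples, `>= 1`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An `m x n` binary matrix of class `prognet_data`, columns named
#'   by event.
#' @export
sample_data <- function(net, m, seed = NULL) {
  stopifnot(inherits(net, "progression_network"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  h <- net$hyperdag
  ord <- topological_order(h)
  out <- matrix(0L, nrow = m, ncol = h$n, dimnames = list(NULL, h$names))
  for (v in ord) {
    cpd <- net$cpds[[v]]
    pa <- match(cpd$parents, h$names)
    j <- length(pa)
    u <- if (j == 0L) rep(1L, m) else
      as.vector(out[, pa, drop = FALSE] %*% (2^(seq_len(j) - 1))) + 1L
    out[, v] <- as.integer(stats::runif(m) < cpd$prob1[u])
  }
  class(out) <- c("prognet_data", "matrix", "array")
  out
}

#' Run the synthetic structure-recovery benchmark
#'
#' For each combination of bound `k`, network size `n`, generating flavor,
#' and sample size `m`, and for each replicate: draw a random network,
#' forward-sample `m` observations, learn it back with each learner
#' flavor, and score the recovery of the underlying directed edges.
#' Replicate seeds are `seed + replicate index`, giving independent,
#' reproducible streams.
#'
#' @param n_values,k_values,flavors,sample_sizes Grid axes. Defaults are a
#'   small smoke grid; the full study design is `k` in 2:3, `n` in
#'   c(10, 20, 30), `m` in c(500, 2000, 10000), 50 replicates.
#' @param learn_flavors Flavors to learn each dataset with (default: all
#'   three).
#' @param replicates Replicates per cell.
#' @param epsilon Generation and learning bound; default 0.2.
#' @param score Learner score; default `"bic"`.
#' @param seed Base seed.
#' @return A tibble with one row per (cell, replicate, learner flavor):
#'   grid columns, `recovered_pct`, `F`, `fdr`, `fnr`, `objective`,
#'   `status`, `solve_seconds`. Solver failures are recorded as `NA`
#'   metric rows, not raised. Summarize with [summarize_benchmark()].
#' @export
run_benchmark <- function(n_values = 10, k_values = 2,
                          flavors = c("monotone", "semimonotone", "general"),
                          sample_sizes = c(500, 2000),
                          learn_flavors = c("monotone", "semimonotone", "general"),
                          replicates = 5, epsilon = 0.2, score = "bic",
                          seed = 1) {
  grid <- tidyr::expand_grid(
    n = n_values, k = k_values, gen_flavor = flavors, m = sample_sizes,
    replicate = seq_len(replicates)
  )
  rows <- purrr::pmap(grid, function(n, k, gen_flavor, m, replicate) {
    rep_seed <- seed + replicate
    truth <- random_cpds(random_hyperdag(n, k, seed = rep_seed),
                         flavor = gen_flavor, epsilon = epsilon,
                         seed = rep_seed + 1L)
    d <- sample_data(truth, m, seed = rep_seed + 2L)
    true_edges <- underlying_graph(truth$hyperdag)
    purrr::map(learn_flavors, function(lf) {
      res <- tryCatch(
        learn_network(d, k = k, flavor = lf, epsilon = epsilon, score = score),
        error = function(e) NULL
      )
      base <- tibble::tibble(
        n = n, k = k, gen_flavor = gen_flavor, m = m, replicate = replicate,
        learn_flavor = lf
      )
      if (is.null(res) || is.null(res$network)) {
        return(dplyr::mutate(base, recovered_pct = NA_real_, F = NA_real_,
                             fdr = NA_real_, fnr = NA_real_,
                             objective = NA_real_, status = "failed",
                             solve_seconds = NA_real_))
      }
      learned_edges <- underlying_graph(res$network$hyperdag)
      # an edgeless truth leaves recovery undefined; record NA metrics
      met <- if (nrow(true_edges) == 0L) {
        tibble::tibble(recovered_pct = NA_real_, F = NA_real_,
                       fdr = NA_real_, fnr = NA_real_)
      } else {
        edge_metrics(true_edges, learned_edges)
      }
      dplyr::mutate(base, recovered_pct = met$recovered_pct, F = met$F,
                    fdr = met$fdr, fnr = met$fnr,
                    objective = res$objective, status = res$status,
                    solve_seconds = res$solve_seconds)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Per-cell means and standard deviations of benchmark metrics
#'
#' @param results Output of [run_benchmark()].
#' @return A tibble with one row per (grid cell, learner flavor, metric):
#'   `mean` and `sd` across replicates.
#' @export
summarize_benchmark <- function(results) {
  results |>
    tidyr::pivot_longer(c("recovered_pct", "F", "fdr", "fnr"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$n, .data$k, .data$gen_flavor, .data$m,
                    .data$learn_flavor, .data$metric) |>
    dplyr::summarize(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
}
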