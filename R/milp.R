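#' Formulate maximum-weight acyclic subhypergraph selection as a MILP
#'
#' One binary variable `x_e` per candidate hyperedge and one order
#' variable `o_v` in `[0, n - 1]` per event. The objective maximizes the
#' total selected weight subject to (1) each event selecting exactly one
#' candidate parent set and (2) big-M ordering constraints
#' `o_child - o_parent >= 1 - n (1 - x_e)` for every (candidate, parent)
#' pair, which force a topological order on the selected edges and hence
#' acyclicity. Root-attached candidates induce no ordering constraints.
#' Order variables are continuous: integrality is unnecessary for
#' acyclicity.
#'
#' @param s A `selector_graph` from [build_selector()].
#' @return A `milp_program`: list with the selector, variable names,
#'   per-child equality constraint groups, the ordering-constraint table
#'   (`candidate`, `parent`, `child`), and the big-M constant.
#' @export
build_milp <- function(s) {
  stopifnot(inherits(s, "selector_graph"))
  n <- selector_attr(s, "n")
  x_names <- vapply(seq_len(nrow(s)), function(i) {
    paste0("x_", s$child[i],
           if (s$size[i]) paste0("_", paste(s$parents[[i]], collapse = ".")) else "_root")
  }, character(1))
  eq_groups <- split(seq_len(nrow(s)), s$child)
  ord <- purrr::map(which(s$size > 0L), function(i) {
    tibble::tibble(candidate = i, parent = s$parents[[i]], child = s$child[i])
  })
  ord <- dplyr::bind_rows(ord)
  if (nrow(ord) == 0L) {
    ord <- tibble::tibble(candidate = integer(), parent = integer(),
                          child = integer())
  }
  structure(list(
    selector = s,
    n = n,
    x_names = x_names,
    o_names = paste0("o_", seq_len(n)),
    objective = s$weight,
    eq_groups = eq_groups,
    order_constraints = ord,
    big_m = n
  ), class = "milp_program")
}

#' @export
print.milp_program <- function(x, ...) {
  cat("<milp_program> ", length(x$x_names), " binary edge variables, ",
      x$n, " order variables\n  ", length(x$eq_groups),
      " selection equalities, ", nrow(x$order_constraints),
      " ordering constraints (big-M = ", x$big_m, ")\n", sep = "")
  invisible(x)
}

#' Export a program in CPLEX LP format
#'
#' For inspection or for handing the exact same program to an external
#' solver.
#'
#' @param milp A `milp_program`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lp <- function(milp, path) {
  stopifnot(inherits(milp, "milp_program"))
  s <- milp$selector
  obj_terms <- paste0(ifelse(milp$objective < 0, " - ", " + "),
                      format(abs(milp$objective), digits = 12),
                      " ", milp$x_names)
  lines <- c("Maximize", paste0(" obj:", paste(obj_terms, collapse = "")),
             "Subject To")
  for (v in names(milp$eq_groups)) {
    idx <- milp$eq_groups[[v]]
    lines <- c(lines, paste0(" sel_", v, ": ",
                             paste(milp$x_names[idx], collapse = " + "),
                             " = 1"))
  }
  oc <- milp$order_constraints
  if (nrow(oc)) {
    # o_child - o_parent + n x_e >= 1 - n + n  <=>  o_c - o_u - n(1-x) >= 1-n
    for (i in seq_len(nrow(oc))) {
      lines <- c(lines, paste0(
        " ord_", i, ": o_", oc$child[i], " - o_", oc$parent[i], " - ",
        milp$big_m, " ", milp$x_names[oc$candidate[i]],
        " >= ", 1 - milp$big_m))
    }
  }
  lines <- c(lines, "Bounds",
             paste0(" 0 <= o_", seq_len(milp$n), " <= ", milp$n - 1),
             "Binaries", paste0(" ", milp$x_names), "End")
  writeLines(lines, path)
  invisible(path)
}

decode_selection <- function(s, chosen) {
  nm <- selector_attr(s, "event_names")
  n <- selector_attr(s, "n")
  edges <- purrr::map(seq_len(n), function(v) {
    i <- chosen[v]
    hyperedge(s$child[i], s$parents[[i]])
  })
  hyperdag(n, edges, nm)
}

new_learn_result <- function(network, objective, status, gap, seconds,
                             selector, data, backend) {
  structure(list(
    network = network, objective = objective, status = status,
    gap = gap, solve_seconds = seconds, selector = selector,
    score = selector_attr(selector, "score"),
    flavor = selector_attr(selector, "flavor"),
    epsilon = selector_attr(selector, "epsilon"),
    k = selector_attr(selector, "k"),
    m = if (!is.null(data)) nrow(data) else NA_integer_,
    backend = backend
  ), class = "pn_fit")
}

#' Solve a formulated program
#'
#' Backends (both exact, both authored for this selection structure):
#' * `"dp"` (default): dynamic programming over vertex subsets; always
#'   returns a provably optimal solution (`gap = 0`). Practical up to
#'   about 20 events.
#' * `"bnb"`: depth-first branch-and-bound on the hyperedge variables with
#'   a per-child relaxation bound; honors `time_limit` and `mip_gap` and
#'   returns the best incumbent with its optimality gap when interrupted.
#'
#' The returned network always satisfies the ordering constraints, i.e. is
#' acyclic, and each event carries exactly one parent set.
#'
#' @param milp A `milp_program`.
#' @param data Optional binary matrix used to attach constrained-ML CPDs
#'   to the decoded network.
#' @param backend `"dp"` or `"bnb"`.
#' @param time_limit Seconds allowed (`bnb` only; `Inf` default).
#' @param mip_gap Relative gap at which `bnb` may stop early (default 0).
#' @param seed Unused by the deterministic backends; kept for interface
#'   stability.
#' @return A `pn_fit`: the decoded `progression_network`, `objective`,
#'   `status` (`"optimal"`, `"incumbent"`, or `"timeout-no-solution"`),
#'   `gap`, and `solve_seconds`.
#' @export
solve_milp <- function(milp, data = NULL, backend = c("dp", "bnb"),
                       time_limit = Inf, mip_gap = 0, seed = NULL) {
  stopifnot(inherits(milp, "milp_program"))
  backend <- match.arg(backend)
  s <- milp$selector
  n <- milp$n
  t0 <- proc.time()[["elapsed"]]
  if (backend == "dp") {
    if (n > 22L) {
      stop("dp backend supports up to 22 events; use backend = 'bnb'",
           call. = FALSE)
    }
    mask <- vapply(s$parents, function(p) sum(2^(p - 1L)), numeric(1))
    res <- dp_solve_selection(n, s$child, as.integer(mask), s$weight)
    chosen <- res$chosen
    objective <- res$objective
    status <- "optimal"
    gap <- 0
  } else {
    res <- bnb_solve(s, n, time_limit = time_limit, mip_gap = mip_gap)
    chosen <- res$chosen
    objective <- res$objective
    status <- res$status
    gap <- res$gap
    if (status == "timeout-no-solution") {
      return(new_learn_result(NULL, NA_real_, status, NA_real_,
                              proc.time()[["elapsed"]] - t0, s, data, backend))
    }
  }
  h <- decode_selection(s, chosen)
  net <- fit_cpds(h, data, selector_attr(s, "flavor"),
                  selector_attr(s, "epsilon"))
  out <- new_learn_result(net, objective, status, gap,
                          proc.time()[["elapsed"]] - t0, s, data, backend)
  stopifnot(is_acyclic(h))    # contract: ordering constraints hold
  out
}

# attach flavor-constrained ML CPDs; without data, a bare network
fit_cpds <- function(h, data, flavor, epsilon) {
  cpds <- NULL
  if (!is.null(data)) {
    d <- as_binary_matrix(data)
    parent_sets <- stats::setNames(rep(list(integer()), h$n), h$names)
    for (e in h$edges) parent_sets[[e$child]] <- e$parents
    cpds <- lapply(seq_len(h$n), function(v) {
      cn <- match(h$names[v], colnames(d))
      pa <- match(h$names[parent_sets[[v]]], colnames(d))
      constrain_cpd(ml_cpd(d, cn, pa), flavor, epsilon)
    })
  }
  structure(list(hyperdag = h, cpds = cpds, flavor = flavor,
                 epsilon = epsilon), class = "progression_network")
}

# Depth-first branch-and-bound over per-child candidate choices.
# Bound: current weight + sum over unassigned children of their best
# candidate weight (acyclicity relaxed). Feasibility: incremental cycle
# check via reachability on the selected simple edges.
bnb_solve <- function(s, n, time_limit = Inf, mip_gap = 0) {
  by_child <- lapply(seq_len(n), function(v) {
    idx <- which(s$child == v)
    idx[order(-s$weight[idx], idx)]
  })
  best_per_child <- vapply(by_child, function(idx) s$weight[idx[1]], numeric(1))
  suffix_best <- rev(cumsum(rev(best_per_child)))
  suffix_best <- c(suffix_best, 0)
  incumbent <- -Inf
  incumbent_sel <- NULL
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE
  root_bound <- suffix_best[1]

  reach <- matrix(FALSE, n, n)      # reach[u, v]: path u -> v in selection
  sel <- integer(n)

  recurse <- function(v, cur, reach) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      timed_out <<- TRUE
      return()
    }
    if (v > n) {
      if (cur > incumbent) {
        incumbent <<- cur
        incumbent_sel <<- sel
      }
      return()
    }
    for (i in by_child[[v]]) {
      if (timed_out) return()
      w <- s$weight[i]
      bound <- cur + w + suffix_best[v + 1]
      if (bound <= incumbent) break   # candidates sorted: rest no better
      pa <- s$parents[[i]]
      # cycle iff v already reaches one of the new parents
      if (length(pa) && any(reach[v, pa])) next
      r2 <- reach
      if (length(pa)) {
        anc <- unique(c(pa, which(apply(r2[, pa, drop = FALSE], 1, any))))
        dsc <- c(v, which(r2[v, ]))
        r2[anc, dsc] <- TRUE
      }
      sel[v] <<- i
      recurse(v + 1, cur + w, r2)
      if (!is.finite(mip_gap) || mip_gap <= 0) next
      if (is.finite(incumbent) &&
          (root_bound - incumbent) <= mip_gap * abs(incumbent)) return()
    }
  }
  recurse(1L, 0, reach)
  if (is.null(incumbent_sel)) {
    return(list(chosen = NULL, objective = NA_real_,
                status = "timeout-no-solution", gap = NA_real_))
  }
  gap <- if (timed_out) {
    max(0, (root_bound - incumbent) / max(abs(incumbent), 1e-12))
  } else 0
  list(chosen = incumbent_sel, objective = incumbent,
       status = if (timed_out) "incumbent" else "optimal", gap = gap)
}

#' Learn a progression network from binary data
#'
#' Full pipeline: score all candidate parent sets ([build_selector()]),
#' formulate the acyclic-selection program ([build_milp()]), solve it
#' exactly ([solve_milp()]), and attach flavor-constrained ML CPDs to the
#' selected structure.
#'
#' @param data Binary matrix or data frame of 0/1 aberration calls,
#'   columns named by event.
#' @param k Hyperedge bound: each event may select at most `k - 1`
#'   parents. Default 3.
#' @param flavor `"monotone"` (child needs all parents), `"semimonotone"`
#'   (child needs at least one parent), or `"general"` (unconstrained).
#' @param epsilon Escape probability bound for monotone/semi-monotone
#'   CPDs; default 0.2.
#' @param score `"bic"` (default) or `"loglik"`.
#' @param prune Apply [prune_dominated()] before solving. Default `FALSE`.
#' @param backend,time_limit,mip_gap,seed Passed to [solve_milp()].
#' @return A `pn_fit`; see [solve_milp()]. Use [tidy.pn_fit()] for the
#'   edge table and [glance.pn_fit()] for the fit summary.
#' @examples
#' d <- sample_data(random_cpds(random_hyperdag(5, 2, seed = 1),
#'                              "monotone", seed = 1), m = 200, seed = 1)
#' fit <- learn_network(d, k = 2, flavor = "monotone")
#' glance(fit)
#' @export
learn_network <- function(data, k = 3, flavor = c("monotone", "semimonotone", "general"),
                          epsilon = 0.2, score = c("bic", "loglik"),
                          prune = FALSE, backend = c("dp", "bnb"),
                          time_limit = Inf, mip_gap = 0, seed = NULL) {
  flavor <- match.arg(flavor)
  score <- match.arg(score)
  d <- as_binary_matrix(data)
  s <- build_selector(d, k, flavor, epsilon, score)
  if (prune) s <- prune_dominated(s)
  milp <- build_milp(s)
  solve_milp(milp, data = d, backend = match.arg(backend),
             time_limit = time_limit, mip_gap = mip_gap, seed = seed)
}

#' Exhaustive structure search (test oracle)
#'
#' Enumerates every assignment of one candidate parent set per event,
#' discards cyclic assignments, and returns the maximum-score network.
#' Deliberately independent of the optimizer; exponential, guarded to
#' `n <= 7`.
#'
#' @inheritParams learn_network
#' @return A `pn_fit` with `status = "optimal"`.
#' @export
brute_force_learn <- function(data, k = 3, flavor = c("monotone", "semimonotone", "general"),
                              epsilon = 0.2, score = c("bic", "loglik")) {
  flavor <- match.arg(flavor)
  score <- match.arg(score)
  d <- as_binary_matrix(data)
  n <- ncol(d)
  if (n > 7L) stop("exhaustive search is guarded to n <= 7", call. = FALSE)
  s <- build_selector(d, k, flavor, epsilon, score)
  by_child <- lapply(seq_len(n), function(v) which(s$child == v))
  t0 <- proc.time()[["elapsed"]]
  best <- -Inf
  best_sel <- NULL
  sel <- integer(n)
  # recursive product enumeration with a running acyclicity check
  recurse <- function(v, cur, reach) {
    if (v > n) {
      if (cur > best) {
        best <<- cur
        best_sel <<- sel
      }
      return()
    }
    for (i in by_child[[v]]) {
      pa <- s$parents[[i]]
      if (length(pa) && any(reach[v, pa])) next   # would close a cycle
      r2 <- reach
      if (length(pa)) {
        anc <- unique(c(pa, which(apply(r2[, pa, drop = FALSE], 1, any))))
        dsc <- c(v, which(r2[v, ]))
        r2[anc, dsc] <- TRUE
      }
      sel[v] <<- i
      recurse(v + 1, cur + s$weight[i], r2)
    }
  }
  recurse(1L, 0, matrix(FALSE, n, n))
  h <- decode_selection(s, best_sel)
  net <- fit_cpds(h, d, flavor, epsilon)
  new_learn_result(net, best, "optimal", 0,
                   proc.time()[["elapsed"]] - t0, s, d, "exhaustive")
}

#' @export
print.pn_fit <- function(x, ...) {
  cat("<pn_fit> ", x$flavor, " network, k = ", x$k, ", score = ", x$score,
      " (epsilon = ", x$epsilon, ")\n", sep = "")
  cat("  objective ", format(x$objective, digits = 8), ", status ",
      x$status, ", gap ", format(x$gap, digits = 3), "\n", sep = "")
  if (!is.null(x$network)) print(x$network$hyperdag)
  invisible(x)
}

#' @export
print.progression_network <- function(x, ...) {
  cat("<progression_network> flavor ", x$flavor, ", epsilon ", x$epsilon,
      "\n", sep = "")
  print(x$hyperdag)
  invisible(x)
}
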