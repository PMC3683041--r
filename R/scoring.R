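#' Coerce a data frame or matrix of binary aberration calls
#'
#' Accepts a data frame or matrix whose columns are events (chromosome-arm
#' gains/losses, pathway hits, ...) and whose rows are samples, with every
#' entry 0 or 1. Column names are required and must be unique.
#'
#' @param data A data frame or matrix of 0/1 values with column names.
#' @return An integer matrix of class `c("prognet_data", "matrix")`.
#' @export
as_binary_matrix <- function(data) {
  if (inherits(data, "prognet_data")) return(data)
  m <- as.matrix(data)
  if (is.null(colnames(m)) || any(!nzchar(colnames(m)))) {
    stop("data must have (non-empty) column names for the events",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("event names must be unique", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  bad <- which(is.na(m) | (m != 0L & m != 1L), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary entry at row ", bad[1, 1], ", column '",
         colnames(m)[bad[1, 2]], "'", call. = FALSE)
  }
  if (nrow(m) < 1L) stop("data must contain at least one sample", call. = FALSE)
  class(m) <- c("prognet_data", "matrix", "array")
  m
}

#' Read a binary data matrix from delimited text
#'
#' Expects a header row of event names followed by 0/1 rows; the delimiter
#' is inferred from the file extension (`.csv` comma, otherwise tab).
#' Non-binary cells are rejected with the offending row and column named.
#'
#' @param path TSV or CSV file path.
#' @param delim Optional delimiter override.
#' @return An integer matrix of class `prognet_data`.
#' @export
read_binary_matrix <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_integer()
  ), progress = FALSE)
  as_binary_matrix(df)
}

#' Count samples matching a partial assignment
#'
#' Number of rows agreeing with `assignment` on the named events; an empty
#' assignment matches every row, so the count equals the sample size.
#'
#' @param data Binary matrix (see [as_binary_matrix()]).
#' @param assignment Named integer vector of 0/1 values, names drawn from
#'   the event names (or integer column indices via `vars`/`values`).
#' @return Integer count.
#' @export
count_matching <- function(data, assignment = integer()) {
  d <- as_binary_matrix(data)
  if (length(assignment) == 0L) return(nrow(d))
  vars <- names(assignment)
  if (is.null(vars)) stop("`assignment` must be named", call. = FALSE)
  unknown <- setdiff(vars, colnames(d))
  if (length(unknown)) {
    stop("unknown event(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sub <- d[, vars, drop = FALSE]
  sum(rowSums(sub == rep(assignment, each = nrow(sub))) == length(assignment))
}

# joint counts of (parent assignment, child value): returns a 2 x 2^j
# matrix; column u+1 is the parent bitvector with parents[1] as the least
# significant bit, rows are child = 0, 1.
joint_counts <- function(d, child, parents) {
  j <- length(parents)
  if (j == 0L) {
    n1 <- sum(d[, child])
    return(matrix(c(nrow(d) - n1, n1), nrow = 2))
  }
  idx <- as.vector(d[, parents, drop = FALSE] %*% (2^(seq_len(j) - 1))) + 1L
  counts <- matrix(0L, nrow = 2, ncol = 2^j)
  tab <- table(factor(d[, child], levels = 0:1),
               factor(idx, levels = seq_len(2^j)))
  counts[] <- as.integer(tab)
  counts
}

#' Maximum-likelihood CPD of a child given parents
#'
#' For each parent assignment u, the estimate is
#' \eqn{\hat\theta(u) = N(child=1, pa=u) / N(pa=u)}. Assignments never
#' observed in the data carry \eqn{\hat\theta = 0} and are flagged
#' `observed = FALSE`; their data contribution to any weight is zero.
#'
#' Assignment rows are ordered by the parent bitvector read with the first
#' stored parent as the least significant bit, i.e. row `u + 1` holds
#' assignment integer `u`.
#'
#' @param data Binary matrix.
#' @param child Event name or column index of the child.
#' @param parents Event names or column indices of the parents (possibly
#'   empty).
#' @return A `cpd_table`: list with `child`, `parents` (names),
#'   `prob1` (numeric, length `2^|parents|`), `observed` (logical),
#'   `n_obs` (integer counts per assignment).
#' @export
ml_cpd <- function(data, child, parents = character()) {
  d <- as_binary_matrix(data)
  child <- resolve_events(d, child)
  parents <- resolve_events(d, parents)
  if (child %in% parents) stop("child cannot be among parents", call. = FALSE)
  counts <- joint_counts(d, child, parents)
  n_u <- colSums(counts)
  prob1 <- ifelse(n_u > 0, counts[2, ] / n_u, 0)
  structure(list(
    child = colnames(d)[child],
    parents = colnames(d)[parents],
    prob1 = as.numeric(prob1),
    observed = n_u > 0,
    n_obs = as.integer(n_u)
  ), class = "cpd_table")
}

resolve_events <- function(d, x) {
  if (length(x) == 0L) return(integer())
  if (is.character(x)) {
    idx <- match(x, colnames(d))
    if (anyNA(idx)) {
      stop("unknown event(s): ", paste(x[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    idx
  } else {
    as.integer(x)
  }
}

#' @export
print.cpd_table <- function(x, ...) {
  j <- length(x$parents)
  cat("<cpd_table> P(", x$child, " = 1 | ",
      if (j) paste(x$parents, collapse = ", ") else "-", ")\n", sep = "")
  bits <- assignment_bits(j)
  for (u in seq_along(x$prob1)) {
    cat("  ", if (j) paste(bits[u, ], collapse = "") else "()",
        " : ", format(x$prob1[u], digits = 4),
        if (!x$observed[u]) "  (unobserved)" else "", "\n", sep = "")
  }
  invisible(x)
}

# matrix of parent bit assignments; row u+1 = bits of integer u, LSB first
assignment_bits <- function(j) {
  if (j == 0L) return(matrix(integer(), nrow = 1, ncol = 0))
  u <- 0:(2^j - 1)
  vapply(seq_len(j), function(b) bitwAnd(bitwShiftR(u, b - 1L), 1L),
         integer(2^j))
}

#' Constrain a CPD to a progression-network flavor
#'
#' Monotone networks bound the probability of the child occurring by
#' `epsilon` unless *all* parents have occurred; semi-monotone networks
#' bound it unless *at least one* parent has occurred. The cap is the
#' constrained-ML projection `min(theta, epsilon)`: estimates already
#' below the bound are kept. A general network is returned unchanged.
#'
#' @param cpd A `cpd_table` from [ml_cpd()].
#' @param flavor One of `"monotone"`, `"semimonotone"`, `"general"`.
#' @param epsilon Upper bound in (0, 1]; must be positive so capped
#'   log-probabilities stay finite.
#' @return A `cpd_table` with capped `prob1`.
#' @export
constrain_cpd <- function(cpd, flavor = c("monotone", "semimonotone", "general"),
                          epsilon = 0.2) {
  flavor <- match.arg(flavor)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be > 0 (a zero bound gives -Inf log-probabilities)",
         call. = FALSE)
  }
  if (flavor == "general") return(cpd)
  j <- length(cpd$parents)
  if (j == 0L) return(cpd)      # root-attached: no rows to cap
  capped <- switch(flavor,
    monotone = seq_along(cpd$prob1) != 2^j,      # all rows but all-ones
    semimonotone = seq_along(cpd$prob1) == 1L    # the all-zeros row only
  )
  cpd$prob1[capped] <- pmin(cpd$prob1[capped], epsilon)
  cpd
}

#' Log-likelihood weight of a hyperedge
#'
#' The contribution of a single hyperedge to the decomposable network
#' log-likelihood:
#' \deqn{w(e) = \sum_{u} \sum_{x \in \{0,1\}} N(c = x, pa = u)\,
#'   \log \hat P(c = x \mid u),}
#' with \eqn{\hat P} the flavor-constrained ML estimate and the convention
#' \eqn{0 \log 0 = 0}. Root parents carry no data, so a root-attached edge
#' scores by the marginal of the child (the parent-free case). Natural
#' logarithms throughout.
#'
#' @param data Binary matrix.
#' @param child,parents Event names or column indices; `parents` is the
#'   non-root parent set (root parents are ignored by definition).
#' @param flavor,epsilon See [constrain_cpd()].
#' @return A non-positive real; zero iff every used probability is 1.
#' @export
edge_loglik_weight <- function(data, child, parents = character(),
                               flavor = "general", epsilon = 0.2) {
  d <- as_binary_matrix(data)
  child <- resolve_events(d, child)
  parents <- resolve_events(d, parents)
  counts <- joint_counts(d, child, parents)
  cpd <- constrain_cpd(ml_cpd(d, child, parents), flavor, epsilon)
  p1 <- cpd$prob1
  weight_from_counts(counts, p1)
}

weight_from_counts <- function(counts, p1) {
  p <- rbind(1 - p1, p1)
  terms <- counts * log(p)
  terms[counts == 0] <- 0       # 0 log 0 := 0
  sum(terms)
}

#' BIC weight of a hyperedge
#'
#' The log-likelihood weight penalized by `(log m / 2)` per independent
#' parameter; a binary child given `j` binary (non-root) parents has
#' `2^j` independent parameters.
#'
#' @inheritParams edge_loglik_weight
#' @return A real number, at most the log-likelihood weight for `m >= 2`.
#' @export
edge_bic_weight <- function(data, child, parents = character(),
                            flavor = "general", epsilon = 0.2) {
  d <- as_binary_matrix(data)
  w <- edge_loglik_weight(d, child, parents, flavor, epsilon)
  j <- length(resolve_events(d, parents))
  w - (log(nrow(d)) / 2) * 2^j
}

#' Score a progression network on data
#'
#' Sums per-hyperedge weights over the network's edges: with the
#' log-likelihood score and (constrained) ML CPDs this equals the log of
#' the joint probability of the data under the network, by score
#' decomposability. Every vertex must carry exactly one hyperedge (possibly
#' root-attached).
#'
#' @param data Binary matrix whose columns match the network's vertex
#'   names.
#' @param network A `progression_network` (see [random_cpds()] or
#'   [learn_network()]) or a bare `hyperdag`; for a bare hyperdag, vertices
#'   without an edge are treated as root-attached.
#' @param score `"loglik"` or `"bic"`.
#' @param flavor,epsilon Flavor constraint applied to the ML CPDs; for a
#'   `progression_network` these default to the network's own.
#' @return Scalar score (sum of edge weights).
#' @export
network_score <- function(data, network, score = c("loglik", "bic"),
                          flavor = NULL, epsilon = NULL) {
  score <- match.arg(score)
  d <- as_binary_matrix(data)
  h <- if (inherits(network, "progression_network")) network$hyperdag else network
  stopifnot(inherits(h, "hyperdag"))
  if (is.null(flavor)) {
    flavor <- if (inherits(network, "progression_network")) network$flavor else "general"
  }
  if (is.null(epsilon)) {
    epsilon <- if (inherits(network, "progression_network")) network$epsilon else 0.2
  }
  parent_sets <- stats::setNames(rep(list(integer()), h$n), h$names)
  for (e in h$edges) parent_sets[[e$child]] <- e$parents
  wfun <- if (score == "loglik") edge_loglik_weight else edge_bic_weight
  total <- 0
  for (v in seq_len(h$n)) {
    cn <- match(h$names[v], colnames(d))
    if (is.na(cn)) stop("event '", h$names[v], "' absent from data", call. = FALSE)
    pa <- match(h$names[parent_sets[[v]]], colnames(d))
    total <- total + wfun(d, cn, pa, flavor = flavor, epsilon = epsilon)
  }
  total
}

#' Joint log-likelihood evaluated row by row
#'
#' Direct (non-decomposed) evaluation: for each sample, the log joint
#' probability of its full event vector under the network's CPDs, summed
#' over samples. Used as an independent cross-check of score
#' decomposability; CPDs are the flavor-constrained ML estimates fitted on
#' `data` when `refit = TRUE` (default), else the network's stored CPDs.
#'
#' @inheritParams network_score
#' @param refit Fit constrained-ML CPDs on `data` before evaluating.
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(data, network, flavor = NULL, epsilon = NULL,
                         refit = TRUE) {
  d <- as_binary_matrix(data)
  h <- if (inherits(network, "progression_network")) network$hyperdag else network
  if (is.null(flavor)) {
    flavor <- if (inherits(network, "progression_network")) network$flavor else "general"
  }
  if (is.null(epsilon)) {
    epsilon <- if (inherits(network, "progression_network")) network$epsilon else 0.2
  }
  parent_sets <- stats::setNames(rep(list(integer()), h$n), h$names)
  for (e in h$edges) parent_sets[[e$child]] <- e$parents
  total <- 0
  for (v in seq_len(h$n)) {
    cn <- match(h$names[v], colnames(d))
    pa <- match(h$names[parent_sets[[v]]], colnames(d))
    cpd <- if (refit) {
      constrain_cpd(ml_cpd(d, cn, pa), flavor, epsilon)
    } else {
      network$cpds[[v]]
    }
    j <- length(pa)
    u <- if (j == 0L) {
      rep(1L, nrow(d))
    } else {
      as.vector(d[, pa, drop = FALSE] %*% (2^(seq_len(j) - 1))) + 1L
    }
    p1 <- cpd$prob1[u]
    p_row <- ifelse(d[, cn] == 1L, p1, 1 - p1)
    lp <- log(p_row)
    lp[p_row == 0] <- -Inf
    total <- total + sum(lp)
  }
  total
}
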