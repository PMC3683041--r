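#' Construct a directed hyperedge
#'
#' A hyperedge has a single child vertex and a (possibly empty) set of
#' parent vertices. In a progression network the edge encodes which earlier
#' aberrations make the child aberration favorable.
#'
#' @param child Integer vertex index of the child.
#' @param parents Integer vector of parent vertex indices; may be empty.
#'   Duplicates are removed; the child may not appear among the parents.
#' @return An object of class `hyperedge`: a list with fields `child` and
#'   `parents` (sorted).
#' @export
hyperedge <- function(child, parents = integer()) {
  child <- as.integer(child)
  parents <- sort(unique(as.integer(parents)))
  if (length(child) != 1L || is.na(child)) {
    stop("`child` must be a single vertex index", call. = FALSE)
  }
  if (child %in% parents) {
    stop("child vertex ", child, " cannot be its own parent", call. = FALSE)
  }
  structure(list(child = child, parents = parents), class = "hyperedge")
}

#' Construct a directed hypergraph over named vertices
#'
#' Vertices are indexed `1..n`; `names` keeps the event labels (for tumor
#' data, typically chromosome-arm gains/losses such as `"3p-"` or `"5q+"`).
#' The object is not required to be acyclic at construction; use
#' [is_acyclic()] to test, or [validate_hyperdag()] to assert.
#'
#' @param n_vertices Number of vertices.
#' @param edges List of [hyperedge()] objects.
#' @param names Character vector of vertex names (default `v1..vn`).
#' @return An object of class `hyperdag` with fields `n`, `names`, `edges`.
#' @export
hyperdag <- function(n_vertices, edges = list(), names = NULL) {
  n <- as.integer(n_vertices)
  if (is.na(n) || n < 1L) stop("`n_vertices` must be >= 1", call. = FALSE)
  if (is.null(names)) names <- paste0("v", seq_len(n))
  names <- as.character(names)
  if (length(names) != n) stop("`names` must have length ", n, call. = FALSE)
  if (anyDuplicated(names)) stop("vertex names must be unique", call. = FALSE)
  edges <- lapply(edges, function(e) {
    if (!inherits(e, "hyperedge")) e <- hyperedge(e$child, e$parents)
    ids <- c(e$child, e$parents)
    if (any(ids < 1L | ids > n)) {
      stop("edge references unknown vertex id (n = ", n, ")", call. = FALSE)
    }
    e
  })
  structure(list(n = n, names = names, edges = edges), class = "hyperdag")
}

#' @export
print.hyperdag <- function(x, ...) {
  cat("<hyperdag> ", x$n, " vertices, ", length(x$edges), " hyperedges\n",
      sep = "")
  for (e in x$edges) {
    pa <- if (length(e$parents)) {
      paste(x$names[e$parents], collapse = ",")
    } else {
      "(root)"
    }
    cat("  ", pa, " -> ", x$names[e$child], "\n", sep = "")
  }
  invisible(x)
}

#' Test acyclicity of a directed hypergraph
#'
#' True iff a linear order on the vertices exists that places every parent
#' strictly before its child; computed by topological sort (Kahn's
#' algorithm) on the underlying simple digraph, which is equivalent.
#'
#' @param h A `hyperdag`.
#' @return Logical scalar.
#' @export
is_acyclic <- function(h) {
  stopifnot(inherits(h, "hyperdag"))
  !is.null(topo_sort_internal(h))
}

#' Test k-boundedness
#'
#' A hypergraph is k-bounded when every hyperedge contains at most `k`
#' vertices, i.e. a child plus at most `k - 1` parents.
#'
#' @param h A `hyperdag`.
#' @param k Bound, an integer >= 2.
#' @return Logical scalar.
#' @export
is_k_bounded <- function(h, k) {
  stopifnot(inherits(h, "hyperdag"))
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  all(vapply(h$edges, function(e) length(e$parents) + 1L <= k, logical(1)))
}

#' Underlying simple digraph of a hypergraph
#'
#' For each parent and child of a hyperedge there is a directed edge from
#' the parent to the child; pairs appearing in several hyperedges are kept
#' once. Root-attached hyperedges (empty parent set) contribute nothing.
#'
#' @param h A `hyperdag`.
#' @param named Return vertex names (default) rather than indices.
#' @return A tibble with columns `from`, `to`, one row per directed edge.
#' @export
underlying_graph <- function(h, named = TRUE) {
  stopifnot(inherits(h, "hyperdag"))
  pairs <- purrr::map(h$edges, function(e) {
    if (length(e$parents) == 0L) return(NULL)
    tibble::tibble(from = e$parents, to = e$child)
  })
  out <- dplyr::distinct(dplyr::bind_rows(pairs))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(from = integer(), to = integer())
  }
  out <- dplyr::arrange(out, .data$from, .data$to)
  if (named) {
    out$from <- h$names[out$from]
    out$to <- h$names[out$to]
  }
  out
}

# Kahn topological sort on the underlying digraph; ties broken by vertex
# index. Returns NULL on a cycle.
topo_sort_internal <- function(h) {
  n <- h$n
  succ <- rep(list(integer()), n)
  for (e in h$edges) {
    for (u in e$parents) {
      succ[[u]] <- c(succ[[u]], e$child)
    }
  }
  # dedupe parallel simple edges so in-degrees count distinct predecessors
  pred <- rep(list(integer()), n)
  for (u in seq_len(n)) succ[[u]] <- unique(succ[[u]])
  for (u in seq_len(n)) for (v in succ[[u]]) pred[[v]] <- c(pred[[v]], u)
  indeg <- lengths(pred)
  order <- integer(0)
  avail <- which(indeg == 0L)
  indeg_left <- indeg
  while (length(avail)) {
    v <- min(avail)            # deterministic tie-break
    avail <- setdiff(avail, v)
    order <- c(order, v)
    for (w in succ[[v]]) {
      indeg_left[w] <- indeg_left[w] - 1L
      if (indeg_left[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) < n) NULL else order
}

#' Topological order of an acyclic hypergraph
#'
#' Deterministic for a fixed input: among vertices simultaneously
#' available, the smallest index is emitted first, so an edgeless graph
#' returns `1..n`.
#'
#' @param h A `hyperdag`; must be acyclic.
#' @return Integer vector: a permutation of `1..n` with every parent before
#'   its child.
#' @export
topological_order <- function(h) {
  stopifnot(inherits(h, "hyperdag"))
  ord <- topo_sort_internal(h)
  if (is.null(ord)) {
    # name one offending edge for the error message
    bad <- h$edges[[find_cyclic_edge(h)]]
    stop("hypergraph is cyclic; e.g. edge with child ",
         h$names[bad$child], " lies on a cycle", call. = FALSE)
  }
  ord
}

# index of some hyperedge participating in a cycle (first edge whose child
# is not placeable); used only for error reporting
find_cyclic_edge <- function(h) {
  ord <- topo_sort_internal(h)
  placed <- if (is.null(ord)) integer() else ord
  for (i in seq_along(h$edges)) {
    if (!(h$edges[[i]]$child %in% placed)) return(i)
  }
  1L
}

#' Validate a hyperdag (acyclicity + structural invariants)
#'
#' @param h A `hyperdag`.
#' @return `h`, invisibly; errors on violation.
#' @export
validate_hyperdag <- function(h) {
  stopifnot(inherits(h, "hyperdag"))
  if (!is_acyclic(h)) stop("hypergraph contains a cycle", call. = FALSE)
  invisible(h)
}

#' Read / write hyperedge lists
#'
#' Plain-text edge-list format: one line per hyperedge,
#' `child<TAB>parent1,parent2,...`, the parent field empty for
#' root-attached edges. Names are resolved against `names` when given,
#' otherwise collected from the file.
#'
#' @param path File path.
#' @param names Optional character vector fixing the vertex universe and
#'   order.
#' @return `read_hyperedges()`: a `hyperdag`. `write_hyperedges()`: `path`,
#'   invisibly.
#' @export
read_hyperedges <- function(path, names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  children <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  parent_str <- vapply(parts, function(p) {
    if (length(p) >= 2L) trimws(p[[2]]) else ""
  }, character(1))
  parent_list <- lapply(parent_str, function(s) {
    if (!nzchar(s)) character() else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  if (is.null(names)) {
    names <- unique(c(children, unlist(parent_list)))
  }
  lookup <- stats::setNames(seq_along(names), names)
  unknown <- setdiff(c(children, unlist(parent_list)), names)
  if (length(unknown)) {
    stop("unknown vertex names in edge list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  edges <- purrr::map2(children, parent_list, function(ch, pa) {
    hyperedge(lookup[[ch]], unname(lookup[pa]))
  })
  hyperdag(length(names), edges, names)
}

#' @rdname read_hyperedges
#' @param h A `hyperdag` to write.
#' @export
write_hyperedges <- function(h, path) {
  stopifnot(inherits(h, "hyperdag"))
  lines <- vapply(h$edges, function(e) {
    paste0(h$names[e$child], "\t",
           paste(h$names[e$parents], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export the underlying digraph in DOT format
#'
#' @param h A `hyperdag`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(h, path) {
  eg <- underlying_graph(h)
  quote_id <- function(x) paste0('"', gsub('"', '\\"', x, fixed = TRUE), '"')
  body <- c(
    "digraph network {",
    paste0("  ", quote_id(h$names), ";"),
    if (nrow(eg)) paste0("  ", quote_id(eg$from), " -> ", quote_id(eg$to), ";"),
    "}"
  )
  writeLines(body, path)
  invisible(path)
}
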