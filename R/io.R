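#' Write a learned network as JSON
#'
#' CPD rows are keyed by explicit parent-assignment bitstrings ordered by
#' the stored parent list (first parent = leftmost bit character,
#' least-significant position), so the file is unambiguous without the
#' code.
#'
#' @param fit A `pn_fit` or `progression_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(fit, path) {
  net <- if (inherits(fit, "pn_fit")) fit$network else fit
  stopifnot(inherits(net, "progression_network"))
  h <- net$hyperdag
  edges <- lapply(h$edges, function(e) {
    list(child = h$names[e$child],
         parents = as.list(h$names[e$parents]))
  })
  cpds <- NULL
  if (!is.null(net$cpds)) {
    cpds <- lapply(net$cpds, function(cpd) {
      j <- length(cpd$parents)
      bits <- assignment_bits(j)
      keys <- if (j == 0L) "" else
        apply(bits, 1, paste, collapse = "")
      list(child = cpd$child, parents = as.list(cpd$parents),
           prob_child_1 = as.list(stats::setNames(cpd$prob1, keys)))
    })
  }
  obj <- list(
    events = as.list(h$names),
    flavor = net$flavor,
    epsilon = net$epsilon,
    hyperedges = edges,
    cpds = cpds
  )
  if (inherits(fit, "pn_fit")) {
    obj$edge_weights <- lapply(seq_len(nrow(tidy(fit))), function(i) {
      as.list(tidy(fit)[i, ])
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a binary data matrix as TSV
#'
#' @param data Binary matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_binary_matrix <- function(data, path) {
  d <- as_binary_matrix(data)
  readr::write_tsv(tibble::as_tibble(unclass(d)[, , drop = FALSE]), path)
  invisible(path)
}

#' Write a simple edge list as TSV
#'
#' @param edges Tibble with `from`, `to`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("from", "to")], path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

run_manifest <- function(config, extra = list()) {
  c(list(
    package = "prognet",
    version = as.character(utils::packageVersion("prognet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), config, extra)
}

#' Learn a network from files (CLI worker)
#'
#' Reads a binary matrix, learns a network, and writes the learned
#' structure as hyperedge-list TSV, JSON (with CPDs and per-edge weights),
#' and DOT, plus a JSON manifest recording the configuration, objective,
#' status, and gap — enough to reproduce the run.
#'
#' @param input Path of the data matrix (TSV/CSV).
#' @param out_dir Output directory (created if needed).
#' @param k,flavor,epsilon,score,backend,time_limit,mip_gap,seed Passed to
#'   [learn_network()].
#' @return The `pn_fit`, invisibly.
#' @export
cmd_learn <- function(input, out_dir, k = 3, flavor = "monotone",
                      epsilon = 0.2, score = "bic", backend = "dp",
                      time_limit = Inf, mip_gap = 0, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- read_binary_matrix(input)
  fit <- learn_network(d, k = k, flavor = flavor, epsilon = epsilon,
                       score = score, backend = backend,
                       time_limit = time_limit, mip_gap = mip_gap,
                       seed = seed)
  write_hyperedges(fit$network$hyperdag, file.path(out_dir, "network.tsv"))
  write_network_json(fit, file.path(out_dir, "network.json"))
  write_dot(fit$network$hyperdag, file.path(out_dir, "network.dot"))
  manifest <- run_manifest(
    list(subcommand = "learn", input = input, k = k, flavor = flavor,
         epsilon = epsilon, score = score, backend = backend,
         time_limit = time_limit, mip_gap = mip_gap, seed = seed),
    list(objective = fit$objective, status = fit$status, gap = fit$gap,
         solve_seconds = fit$solve_seconds)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Simulate a network and dataset to files (CLI worker)
#'
#' @param out_dir Output directory.
#' @param n,k,flavor,epsilon,m,seed Generation settings (see
#'   [random_hyperdag()], [random_cpds()], [sample_data()]).
#' @return The `progression_network`, invisibly.
#' @export
cmd_simulate <- function(out_dir, n = 10, k = 3, flavor = "monotone",
                         epsilon = 0.2, m = 500, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- random_hyperdag(n, k, seed = seed)
  net <- random_cpds(h, flavor = flavor, epsilon = epsilon, seed = seed + 1L)
  d <- sample_data(net, m, seed = seed + 2L)
  write_hyperedges(h, file.path(out_dir, "true_network.tsv"))
  write_network_json(net, file.path(out_dir, "true_network.json"))
  write_binary_matrix(d, file.path(out_dir, "data.tsv"))
  manifest <- run_manifest(list(subcommand = "simulate", n = n, k = k,
                                flavor = flavor, epsilon = epsilon, m = m,
                                seed = seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(net)
}

#' Evaluate learned against true edges to files (CLI worker)
#'
#' @param truth,learned Paths of simple-edge-list TSVs (`from`, `to`).
#' @param out Output TSV path for the metric report.
#' @return The metrics tibble, invisibly.
#' @export
cmd_evaluate <- function(truth, learned, out) {
  met <- edge_metrics(read_edge_list(truth), read_edge_list(learned))
  readr::write_tsv(met, out)
  invisible(met)
}

#' Run a benchmark grid to files (CLI worker)
#'
#' Writes the per-instance tidy table and the per-cell mean/sd summary;
#' a rerun pointed at the same directory skips cells already present in
#' the instance table (resume semantics).
#'
#' @param out_dir Output directory.
#' @param ... Passed to [run_benchmark()].
#' @return The summary tibble, invisibly.
#' @export
cmd_benchmark <- function(out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inst_path <- file.path(out_dir, "instances.tsv")
  res <- run_benchmark(...)
  if (file.exists(inst_path)) {
    prev <- readr::read_tsv(inst_path, show_col_types = FALSE)
    keycols <- c("n", "k", "gen_flavor", "m", "replicate", "learn_flavor")
    res <- dplyr::anti_join(res, prev, by = keycols)
    res <- dplyr::bind_rows(prev, res)
  }
  readr::write_tsv(res, inst_path)
  summ <- summarize_benchmark(res)
  readr::write_tsv(summ, file.path(out_dir, "summary.tsv"))
  manifest <- run_manifest(list(subcommand = "benchmark",
                                args = paste(deparse(substitute(list(...))),
                                             collapse = "")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}
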