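#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a learned network into an edge table
#'
#' One row per selected hyperedge with its per-edge log-likelihood and BIC
#' contributions pulled from the selector graph.
#'
#' @param x A `pn_fit` from [learn_network()].
#' @param ... Unused.
#' @return A tibble: `child`, `parents` (comma-joined names, `""` for
#'   root-attached), `n_parents`, `loglik`, `bic`.
#' @export
tidy.pn_fit <- function(x, ...) {
  if (is.null(x$network)) {
    return(tibble::tibble(child = character(), parents = character(),
                          n_parents = integer(), loglik = numeric(),
                          bic = numeric()))
  }
  h <- x$network$hyperdag
  s <- x$selector
  rows <- purrr::map(h$edges, function(e) {
    hit <- which(s$child == e$child &
                   vapply(s$parents, function(p) identical(p, e$parents),
                          logical(1)))[1]
    tibble::tibble(
      child = h$names[e$child],
      parents = paste(h$names[e$parents], collapse = ","),
      n_parents = length(e$parents),
      loglik = s$loglik[hit],
      bic = s$bic[hit]
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$child)
}

#' One-row summary of a learned network
#'
#' @param x A `pn_fit`.
#' @param ... Unused.
#' @return A tibble: `objective`, `status`, `gap`, `k`, `flavor`,
#'   `epsilon`, `score`, `m`, `n_events`, `n_edges` (underlying directed
#'   edges), `n_root_attached`, `solve_seconds`, `backend`.
#' @export
glance.pn_fit <- function(x, ...) {
  n_edges <- if (is.null(x$network)) NA_integer_ else
    nrow(underlying_graph(x$network$hyperdag))
  n_root <- if (is.null(x$network)) NA_integer_ else
    sum(vapply(x$network$hyperdag$edges,
               function(e) length(e$parents) == 0L, logical(1)))
  tibble::tibble(
    objective = x$objective, status = x$status, gap = x$gap,
    k = x$k, flavor = x$flavor, epsilon = x$epsilon, score = x$score,
    m = x$m,
    n_events = if (is.null(x$network)) NA_integer_ else x$network$hyperdag$n,
    n_edges = n_edges, n_root_attached = n_root,
    solve_seconds = x$solve_seconds, backend = x$backend
  )
}

#' Plot a learned network
#'
#' Events are placed left-to-right in topological order (so all arrows
#' point rightward) and spread vertically; directed edges of the
#' underlying simple graph are drawn as arrows.
#'
#' @param object A `pn_fit` or `progression_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pn_fit <- function(object, ...) {
  net <- if (inherits(object, "pn_fit")) object$network else object
  h <- net$hyperdag
  ord <- topological_order(h)
  pos <- tibble::tibble(
    event = h$names[ord],
    x = seq_along(ord),
    y = ((seq_along(ord) - 1L) %% 3L) - 1L
  )
  eg <- underlying_graph(h)
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(eg)) {
    seg <- dplyr::left_join(eg, pos, by = c(from = "event")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(pos, by = c(to = "event"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      color = "grey40"
    )
  }
  p +
    ggplot2::geom_label(ggplot2::aes(label = .data$event)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0(net$flavor, " progression network"))
}

#' @rdname autoplot.pn_fit
#' @export
autoplot.progression_network <- autoplot.pn_fit

#' Plot benchmark recovery against sample size
#'
#' Mean recovered-edge percentage per sample size and learner flavor, with
#' one-standard-deviation error bars across replicates.
#'
#' @param results Output of [run_benchmark()].
#' @param metric Metric column to display (default `"recovered_pct"`).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, metric = "recovered_pct") {
  summ <- summarize_benchmark(results) |>
    dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$m), y = .data$mean,
                                     color = .data$learn_flavor,
                                     group = .data$learn_flavor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::facet_grid(gen_flavor ~ n + k,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "samples", y = metric, color = "learned as")
}

#' Plot an epsilon calibration curve
#'
#' @param object An `epsilon_calibration` from [calibrate_epsilon()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epsilon_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$epsilon, y = .data$bad_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$epsilon, linetype = 2) +
    ggplot2::labs(x = "epsilon", y = "bad edges (%)")
}
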