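# in-code fixtures shared across test files

# tiny deterministic matrix: 3 events, 8 samples
tiny_matrix <- function() {
  m <- matrix(c(
    1, 1, 0,
    1, 0, 0,
    0, 0, 0,
    1, 1, 1,
    0, 1, 0,
    1, 1, 1,
    0, 0, 1,
    1, 1, 0
  ), ncol = 3, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c")))
  as_binary_matrix(m)
}

chain_hyperdag <- function() {
  hyperdag(3, list(hyperedge(1), hyperedge(2, 1), hyperedge(3, 2)),
           names = c("a", "b", "c"))
}

# a random learning instance: (truth network, data)
random_instance <- function(n, k, m, flavor, seed, epsilon = 0.2) {
  h <- random_hyperdag(n, k, seed = seed)
  net <- random_cpds(h, flavor = flavor, epsilon = epsilon, seed = seed + 1L)
  list(truth = net, data = sample_data(net, m, seed = seed + 2L))
}

edge_tbl <- function(...) {
  pairs <- list(...)
  tibble::tibble(from = vapply(pairs, `[[`, "", 1),
                 to = vapply(pairs, `[[`, "", 2))
}
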