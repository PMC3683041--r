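test_that("edge metrics reproduce hand-computed cases", {
  truth <- edge_tbl(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"))
  learned <- edge_tbl(c("a", "b"), c("b", "c"), c("x", "y"), c("y", "z"))
  expect_equal(recovered_edge_pct(truth, learned), 50)
  expect_equal(recovered_edge_pct(truth, truth), 100)
  expect_equal(recovered_edge_pct(truth, edge_tbl(c("q", "r"))), 0)
  # |M|=|L|=4 with 2 shared -> F = 4/8
  expect_equal(relative_symmetric_difference(truth, learned), 0.5)
  expect_equal(relative_symmetric_difference(truth, truth), 0)
  expect_equal(relative_symmetric_difference(edge_tbl(c("a", "b")),
                                             edge_tbl(c("b", "a"))), 1)
  expect_equal(unname(fdr_fnr(truth, truth)), c(0, 0))
  empty <- edge_tbl()[0, ]
  expect_equal(unname(fdr_fnr(truth, empty)), c(0, 1))
  M <- edge_tbl(c("a", "b"), c("b", "c"))
  L <- edge_tbl(c("a", "b"), c("c", "a"))
  expect_equal(unname(fdr_fnr(M, L)), c(0.5, 0.5))
  expect_error(edge_metrics(empty, learned), "empty true")
  expect_error(relative_symmetric_difference(empty, empty), "undefined")
})

test_that("metric identities hold on random edge-set pairs", {
  set.seed(202)
  labels <- letters[1:8]
  rand_edges <- function() {
    n <- sample(0:10, 1)
    if (n == 0) return(edge_tbl()[0, ])
    from <- sample(labels, n, replace = TRUE)
    to <- sample(labels, n, replace = TRUE)
    keep <- from != to
    unique(tibble::tibble(from = from[keep], to = to[keep]))
  }
  checked <- 0L
  for (i in 1:1200) {
    M <- rand_edges()
    L <- rand_edges()
    if (nrow(M) + nrow(L) == 0L) next
    f <- relative_symmetric_difference(M, L)
    expect_equal(f, relative_symmetric_difference(L, M))   # symmetry
    if (nrow(M) > 0L) {
      met <- edge_metrics(M, L)
      expect_equal(met$recovered_pct + 100 * met$fnr, 100)
      expect_identical(f == 0,
                       met$fdr == 0 && met$fnr == 0)       # F=0 <=> equal
      expect_true(all(c(met$F, met$fdr, met$fnr) >= 0 &
                        c(met$F, met$fdr, met$fnr) <= 1))
      # invariance under consistent relabeling
      perm <- sample(labels)
      relab <- function(x) {
        x$from <- perm[match(x$from, labels)]
        x$to <- perm[match(x$to, labels)]
        x
      }
      expect_equal(edge_metrics(relab(M), relab(L)), met)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 1000L)
})

test_that("partial orders close transitively and reject cycles", {
  po <- partial_order(tibble::tibble(before = c("a", "b"), after = c("b", "c")))
  expect_true(po$precedes["a", "c"])     # derived by transitivity
  expect_false(po$precedes["c", "a"])
  expect_error(partial_order(tibble::tibble(before = c("a", "b"),
                                            after = c("b", "a"))),
               "antisymmetric")
})

test_that("bad-edge percentage counts root-attached edges in the denominator", {
  po <- partial_order(tibble::tibble(
    before = c("a", "b", "c", "a"), after = c("b", "c", "d", "e")))
  # network: a root-attached; edges a->b, b->c, c->d concordant; e->a bad
  h <- hyperdag(5, list(hyperedge(1), hyperedge(2, 1), hyperedge(3, 2),
                        hyperedge(4, 3), hyperedge(5)),
                names = c("a", "b", "c", "d", "e"))
  # move e: make the bad edge by a child with parent e ... build explicitly
  h_bad <- hyperdag(5, list(hyperedge(1, 5), hyperedge(2, 1), hyperedge(3, 2),
                            hyperedge(4, 3), hyperedge(5)),
                    names = c("a", "b", "c", "d", "e"))
  # 1 bad (e->a contradicts a<e), 3 concordant, 1 root-attached -> 1/5
  expect_equal(bad_edge_pct(h_bad, po), 20)
  expect_equal(bad_edge_pct(h, po), 0)
  one_bad <- edge_tbl(c("b", "a"))
  expect_equal(bad_edge_pct(one_bad, po), 100)
  # incomparable events are never bad: d vs e
  expect_equal(bad_edge_pct(edge_tbl(c("e", "d")), po), 0)
  expect_error(bad_edge_pct(edge_tbl(c("zz", "a")), po), "zz")
})

test_that("epsilon calibration scans the grid and returns a member", {
  inst <- random_instance(6, 2, 300, "monotone", 77)
  eg <- underlying_graph(inst$truth$hyperdag)
  ref <- partial_order(tibble::tibble(before = eg$from, after = eg$to))
  cal <- calibrate_epsilon(inst$data, ref, k = 2, flavor = "monotone",
                           epsilon_grid = c(0.1, 0.2, 0.5))
  expect_true(cal$epsilon %in% c(0.1, 0.2, 0.5))
  expect_identical(nrow(cal$curve), 3L)
  expect_true(all(cal$curve$bad_pct >= 0 & cal$curve$bad_pct <= 100))
  one <- calibrate_epsilon(inst$data, ref, k = 2, flavor = "monotone",
                           epsilon_grid = 0.2)
  expect_identical(one$epsilon, 0.2)
  expect_error(calibrate_epsilon(inst$data, ref, epsilon_grid = numeric()),
               "empty")
})
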