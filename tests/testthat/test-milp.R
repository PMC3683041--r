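test_that("program dimensions match the construction", {
  d <- random_instance(3, 2, 50, "general", 1)$data
  milp <- build_milp(build_selector(d, 2, "general"))
  expect_identical(length(milp$x_names), 9L)    # binary edge variables
  expect_identical(length(milp$o_names), 3L)    # order variables
  expect_identical(length(milp$eq_groups), 3L)  # one equality per child
  # 6 singleton-parent candidates, one order constraint per (edge, parent)
  expect_identical(nrow(milp$order_constraints), 6L)
  expect_identical(milp$big_m, 3L)
})

test_that("LP export carries objective, equalities, ordering and bounds", {
  d <- random_instance(3, 2, 50, "general", 2)$data
  milp <- build_milp(build_selector(d, 2, "general"))
  path <- withr::local_tempfile(fileext = ".lp")
  write_lp(milp, path)
  txt <- readLines(path)
  expect_identical(sum(grepl("^ sel_", txt)), 3L)
  expect_identical(sum(grepl("^ ord_", txt)), 6L)
  expect_true(any(grepl("Binaries", txt)))
  expect_true(any(grepl("0 <= o_1 <= 2", txt)))
})

test_that("a unique hand-built optimum is found", {
  # x independent-ish noise, y nearly a copy of x: with loglik score and a
  # forced edge weight landscape the solver must pick the dependent edge
  set.seed(42)
  x <- rep(c(0L, 1L), each = 50)
  y <- x
  y[1:3] <- 1L - y[1:3]
  d <- as_binary_matrix(cbind(x = x, y = y))
  fit <- learn_network(d, k = 2, flavor = "general", score = "bic")
  eg <- underlying_graph(fit$network$hyperdag)
  expect_identical(nrow(eg), 1L)   # one directed edge, either orientation
  expect_setequal(unlist(eg), c("x", "y"))
  # score-equivalent pair: both orientations score identically
  s <- build_selector(d, 2, "general")
  w_xy <- s$weight[s$child == 2 & s$size == 1][1] + s$weight[s$child == 1 & s$size == 0]
  w_yx <- s$weight[s$child == 1 & s$size == 1][1] + s$weight[s$child == 2 & s$size == 0]
  expect_equal(w_xy, w_yx, tolerance = 1e-9)
  expect_equal(fit$objective, w_xy, tolerance = 1e-9)
})

test_that("independence is recovered under BIC", {
  set.seed(7)
  d <- as_binary_matrix(cbind(u = rbinom(300, 1, 0.5),
                              v = rbinom(300, 1, 0.4)))
  fit <- learn_network(d, k = 2, flavor = "general", score = "bic")
  expect_identical(nrow(underlying_graph(fit$network$hyperdag)), 0L)
  # hand computation: the BIC gain of the dependent candidate is negative
  s <- build_selector(d, 2, "general")
  gain <- max(s$weight[s$child == 1 & s$size == 1]) -
    s$weight[s$child == 1 & s$size == 0]
  expect_lt(gain, 0)
})

test_that("dp optimizer agrees with the exhaustive oracle", {
  flavors <- c("monotone", "semimonotone", "general")
  for (seed in 1:12) {
    n <- 3 + (seed %% 3)
    k <- 2 + (seed %% 2)
    fl <- flavors[1 + (seed %% 3)]
    sc <- c("bic", "loglik")[1 + (seed %% 2)]
    inst <- random_instance(n, k, 100, fl, seed * 13)
    fit <- learn_network(inst$data, k = k, flavor = fl, score = sc)
    oracle <- brute_force_learn(inst$data, k = k, flavor = fl, score = sc)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-6)
    # objective equals the independently recomputed network score
    expect_equal(fit$objective,
                 network_score(inst$data, fit$network, sc, fl, 0.2),
                 tolerance = 1e-9)
  }
})

test_that("branch-and-bound backend matches dp and honors its contract", {
  for (seed in 1:6) {
    inst <- random_instance(5, 2, 100, "general", seed * 31)
    s <- build_selector(inst$data, 2, "general")
    milp <- build_milp(s)
    a <- solve_milp(milp, inst$data, backend = "dp")
    b <- solve_milp(milp, inst$data, backend = "bnb")
    expect_equal(a$objective, b$objective, tolerance = 1e-9)
    expect_identical(b$status, "optimal")
    expect_identical(b$gap, 0)
  }
})

test_that("every returned network satisfies the structural contract", {
  for (seed in 1:8) {
    fl <- c("monotone", "semimonotone", "general")[1 + seed %% 3]
    k <- 2 + seed %% 2
    inst <- random_instance(5, k, 120, fl, seed * 3)
    fit <- learn_network(inst$data, k = k, flavor = fl, epsilon = 0.2)
    h <- fit$network$hyperdag
    expect_true(is_acyclic(h))
    expect_true(is_k_bounded(h, k))
    expect_identical(sort(vapply(h$edges, `[[`, 0L, "child")), 1:5)
    # flavor bound on capped CPD rows
    for (cpd in fit$network$cpds) {
      j <- length(cpd$parents)
      if (j == 0L) next
      if (fl == "monotone") {
        expect_true(all(cpd$prob1[-2^j] <= 0.2 + 1e-12))
      } else if (fl == "semimonotone") {
        expect_lte(cpd$prob1[1], 0.2 + 1e-12)
      }
    }
  }
})

test_that("solution is reproducible and exhaustive search is guarded", {
  inst <- random_instance(4, 2, 90, "monotone", 99)
  f1 <- learn_network(inst$data, k = 2, flavor = "monotone", seed = 5)
  f2 <- learn_network(inst$data, k = 2, flavor = "monotone", seed = 5)
  expect_identical(f1$objective, f2$objective)
  expect_identical(underlying_graph(f1$network$hyperdag),
                   underlying_graph(f2$network$hyperdag))
  big <- random_instance(8, 2, 50, "general", 1)$data
  expect_error(brute_force_learn(big, k = 2), "n <= 7")
})

test_that("loglik score with k = n tends toward full connectivity", {
  # strongly dependent chain data: any sparser structure scores no better
  inst <- random_instance(4, 2, 300, "monotone", 17)
  oracle <- brute_force_learn(inst$data, k = 4, flavor = "general",
                              score = "loglik")
  n_edges <- sum(vapply(oracle$network$hyperdag$edges,
                        function(e) length(e$parents), integer(1)))
  # maximum possible simple-edge incidences for a DAG on 4 vertices is 6
  sparser <- brute_force_learn(inst$data, k = 2, flavor = "general",
                               score = "loglik")
  expect_gte(oracle$objective, sparser$objective - 1e-9)
  expect_gte(n_edges, 3L)
})
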