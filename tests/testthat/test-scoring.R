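test_that("binary matrix validation names the offending cell", {
  bad <- matrix(c(0, 1, 2, 0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(as_binary_matrix(bad), "row 1, column 'b'")
  expect_error(as_binary_matrix(matrix(0, 2, 2)), "column names")
})

test_that("count_matching counts rows agreeing with a partial assignment", {
  d <- tiny_matrix()
  expect_identical(count_matching(d, c(a = 1L)), 5L)
  expect_identical(count_matching(d, c(a = 1L, b = 1L)), 4L)
  expect_identical(count_matching(d), 8L)                 # empty = m
  expect_identical(count_matching(d, c(a = 1L)) + count_matching(d, c(a = 0L)),
                   nrow(d))                                # partition
  expect_error(count_matching(d, c(zz = 1L)), "unknown")
})

test_that("ml_cpd reproduces count ratios and flags unobserved rows", {
  d <- tiny_matrix()
  cpd <- ml_cpd(d, "b", "a")
  expect_equal(cpd$prob1, c(1 / 3, 4 / 5))   # rows: a=0, a=1
  marg <- ml_cpd(d, "a")
  expect_equal(marg$prob1, 5 / 8)            # parent-free marginal
  # child identically zero
  d0 <- as_binary_matrix(cbind(tiny_matrix(), z = 0L))
  expect_equal(ml_cpd(d0, "z", "a")$prob1, c(0, 0))
  # unobserved parent assignment: b=1,c=1 never co-occurs with a=0
  d2 <- as_binary_matrix(matrix(c(1, 1, 1, 0, 0, 0), ncol = 3,
                                dimnames = list(NULL, c("a", "b", "c"))))
  cpd2 <- ml_cpd(d2, "a", c("b", "c"))
  expect_false(all(cpd2$observed))
  expect_equal(cpd2$prob1[!cpd2$observed], rep(0, sum(!cpd2$observed)))
})

test_that("flavor constraint caps exactly the rows its definition names", {
  base <- structure(list(child = "c", parents = c("a", "b"),
                         prob1 = c(0.5, 0.5, 0.5, 0.9),
                         observed = rep(TRUE, 4), n_obs = rep(10L, 4)),
                    class = "cpd_table")
  mono <- constrain_cpd(base, "monotone", 0.2)
  expect_equal(mono$prob1, c(0.2, 0.2, 0.2, 0.9))
  semi <- constrain_cpd(base, "semimonotone", 0.2)
  expect_equal(semi$prob1, c(0.2, 0.5, 0.5, 0.9))
  expect_equal(constrain_cpd(base, "general", 0.2)$prob1, base$prob1)
  expect_equal(constrain_cpd(base, "monotone", 1)$prob1, base$prob1)
  # min(theta, eps): estimates below the cap are kept
  low <- base
  low$prob1 <- c(0.05, 0.5, 0.5, 0.9)
  expect_equal(constrain_cpd(low, "monotone", 0.2)$prob1[1], 0.05)
  expect_error(constrain_cpd(base, "monotone", 0), "epsilon")
})

test_that("log-likelihood weight matches closed forms", {
  d <- tiny_matrix()
  # marginal edge: k of m ones
  w <- edge_loglik_weight(d, "a")
  expect_equal(w, 5 * log(5 / 8) + 3 * log(3 / 8), tolerance = 1e-12)
  # perfect determinism scores zero
  dd <- as_binary_matrix(matrix(c(1, 1, 0, 0, 1, 1, 0, 0), ncol = 2,
                                dimnames = list(NULL, c("x", "y"))))
  expect_identical(edge_loglik_weight(dd, "y", "x"), 0)
  # identity: w = -m * empirical conditional entropy (nats)
  cond_entropy <- function(d, child, parents) {
    m <- nrow(d)
    j <- length(parents)
    u <- as.vector(d[, parents, drop = FALSE] %*% (2^(seq_len(j) - 1)))
    h <- 0
    for (uu in unique(u)) {
      rows <- u == uu
      p1 <- mean(d[rows, child])
      for (p in c(p1, 1 - p1)) if (p > 0) h <- h - sum(rows) / m * p * log(p)
    }
    h
  }
  for (seed in 1:5) {
    inst <- random_instance(4, 2, 60, "general", seed)
    dR <- inst$data
    expect_equal(edge_loglik_weight(dR, 1, c(2, 3)),
                 -nrow(dR) * cond_entropy(dR, 1, c(2, 3)),
                 tolerance = 1e-9)
  }
})

test_that("weights are non-positive and ordered across flavors", {
  for (seed in 1:10) {
    inst <- random_instance(5, 3, 80, "monotone", seed)
    d <- inst$data
    wg <- edge_loglik_weight(d, 1, c(2, 3), "general")
    wm <- edge_loglik_weight(d, 1, c(2, 3), "monotone", 0.2)
    ws <- edge_loglik_weight(d, 1, c(2, 3), "semimonotone", 0.2)
    expect_lte(wg, 0)
    expect_lte(wm, wg)    # capping only reduces fit
    expect_lte(ws, wg)
    expect_true(is.finite(wm))
  }
})

test_that("BIC weight applies the Schwarz penalty per independent parameter", {
  d <- tiny_matrix()
  m <- nrow(d)
  expect_equal(edge_bic_weight(d, "a"),
               edge_loglik_weight(d, "a") - log(m) / 2)
  expect_equal(edge_bic_weight(d, "c", c("a", "b")),
               edge_loglik_weight(d, "c", c("a", "b")) - log(m) / 2 * 4)
  # penalty is o(m): per-sample BIC approaches per-sample loglik
  inst_small <- random_instance(3, 2, 100, "general", 11)
  inst_big <- random_instance(3, 2, 10000, "general", 11)
  gap <- function(d) {
    (edge_loglik_weight(d, 1, 2) - edge_bic_weight(d, 1, 2)) / nrow(d)
  }
  expect_lt(gap(inst_big$data), gap(inst_small$data))
  expect_lt(gap(inst_big$data), 0.01)
})

test_that("network score decomposes into the joint log-likelihood", {
  for (seed in 1:8) {
    n <- 3 + (seed %% 4)
    inst <- random_instance(n, 2, 150, c("monotone", "general")[1 + seed %% 2],
                            seed * 7)
    net <- inst$truth
    d <- inst$data
    expect_equal(network_score(d, net, "loglik"),
                 joint_loglik(d, net),
                 tolerance = 1e-9)
  }
})

test_that("adding a parent never decreases the loglik weight", {
  for (seed in 1:6) {
    inst <- random_instance(5, 3, 100, "general", seed + 100)
    d <- inst$data
    w0 <- edge_loglik_weight(d, 1)
    w1 <- edge_loglik_weight(d, 1, 2)
    w2 <- edge_loglik_weight(d, 1, c(2, 3))
    expect_gte(w1, w0 - 1e-12)
    expect_gte(w2, w1 - 1e-12)
  }
})
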