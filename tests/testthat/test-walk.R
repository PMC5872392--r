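test_that("single-kind fallback and phi split shape the transition columns", {
  # h1-h2, h1-h3 equal-weight herb edges; h1 also targets p1; h2, h3 have
  # no targets
  he <- association_table(c("h1", "h2", "h3"), c("e1", "e1", "e1"))
  pp <- association_table(c("p1", "p2"), c("w1", "w2"))
  ht <- association_table("h1", "p1")
  net <- build_hetero_network(build_layer_network(cosine_similarity(he)),
                              build_layer_network(cosine_similarity(pp)),
                              ht)
  cfg <- walk_config(phi = 0.9, alpha = 10, beta = 10)
  M <- as.matrix(build_transition(net, cfg)$M)

  # h2 has two equal-weight herb neighbors and no targets: 0.5 each
  expect_equal(M[c("h1", "h3"), "h2"], c(h1 = 0.5, h3 = 0.5))
  # h1 has herb neighbors and one target: phi to the target
  expect_equal(M["p1", "h1"], 0.9)
  expect_equal(M["h2", "h1"] + M["h3", "h1"], 0.1)
  # p1 has no protein neighbors (w1 unshared) but one herb: all mass to h1
  expect_equal(M["h1", "p1"], 1)
})

test_that("every non-dangling column of the transition operator sums to 1", {
  fx <- random_hetero(8, 12, seed = 4)
  tr <- build_transition(fx$net, walk_config(alpha = 3, beta = 4))
  cs <- Matrix::colSums(tr$M)
  expect_true(all(abs(cs[!tr$dangling] - 1) < 1e-12))
  expect_true(all(cs[tr$dangling] == 0))
})

test_that("sparse transition matches the dense node-by-node construction", {
  for (seed in 1:3) {
    fx <- random_hetero(6, 9, seed)
    cfg <- walk_config(phi = 0.7, alpha = 100, beta = 100)  # no pruning
    tr <- build_transition(fx$net, cfg)
    M2 <- oracle_transition(as.matrix(fx$net$H), as.matrix(fx$net$G),
                            as.matrix(fx$net$R), 0.7)
    expect_lt(max(abs(as.matrix(tr$M) - M2)), 1e-12)
  }
})

test_that("initial state places mass per the seeding rules", {
  fx <- random_hetero(6, 8, seed = 2)
  q <- fx$net$herb_ids[1]
  cfg <- walk_config(eta = 0.5)

  p0 <- initial_state(fx$net, q, character(), cfg)
  expect_equal(unname(p0$u[q]), 1)
  expect_equal(sum(p0$u) + sum(p0$v), 1)

  seeds <- fx$net$protein_ids[1:2]
  p1 <- initial_state(fx$net, q, seeds, cfg)
  expect_equal(unname(p1$u[q]), 0.5)
  expect_equal(unname(p1$v[seeds]), c(0.25, 0.25))

  # eta = 0 collapses to the NoTarget seeding
  p2 <- initial_state(fx$net, q, seeds, walk_config(eta = 0))
  expect_equal(p2$u, p0$u)
  expect_equal(p2$v, p0$v)

  expect_error(initial_state(fx$net, "nosuch", character(), cfg), "unknown")
})

test_that("pure restart (theta = 1) returns the initial state", {
  fx <- random_hetero(5, 7, seed = 3)
  cfg <- walk_config(theta = 1, alpha = 100, beta = 100)
  tr <- build_transition(fx$net, cfg)
  p0 <- initial_state(fx$net, fx$net$herb_ids[1], character(), cfg)
  st <- propagate(tr, p0, cfg)
  expect_equal(st$u, p0$u)
  expect_equal(st$v, p0$v)
})

test_that("iteration matches the closed-form linear solve on small fixtures", {
  for (seed in 1:4) {
    fx <- random_hetero(sample(4:8, 1), sample(5:12, 1), seed)
    cfg <- walk_config(theta = 0.4, phi = 0.8, alpha = 3, beta = 4,
                       epsilon = 1e-12)
    tr <- build_transition(fx$net, cfg)
    p0 <- initial_state(fx$net, fx$net$herb_ids[1], character(), cfg)
    st <- propagate(tr, p0, cfg)
    pstar <- oracle_stationary(tr$M, c(p0$u, p0$v), 0.4)
    expect_lt(max(abs(c(st$u, st$v) - pstar)), 1e-8)
    expect_equal(sum(st$u) + sum(st$v), 1, tolerance = 1e-9)
  }
})

test_that("probability mass is conserved at every iteration", {
  fx <- random_hetero(7, 10, seed = 6)
  cfg <- walk_config(theta = 0.3, alpha = 3, beta = 3)
  tr <- build_transition(fx$net, cfg)
  p0 <- initial_state(fx$net, fx$net$herb_ids[2], character(), cfg)
  p0vec <- c(p0$u, p0$v)
  p <- p0vec
  for (it in 1:50) {
    q <- as.numeric(tr$M %*% p)
    p <- (1 - cfg$theta) * (q + sum(p[tr$dangling]) * p0vec) +
      cfg$theta * p0vec
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("convergence obeys the geometric contraction bound", {
  fx <- random_hetero(8, 10, seed = 8)
  cfg <- walk_config(theta = 0.4, epsilon = 1e-9, alpha = 3, beta = 4)
  tr <- build_transition(fx$net, cfg)
  p0 <- initial_state(fx$net, fx$net$herb_ids[1], character(), cfg)
  st <- propagate(tr, p0, cfg)
  expect_true(st$converged)
  bound <- ceiling(log(cfg$epsilon) / log(1 - cfg$theta)) + 5
  expect_lte(st$iterations, bound)
})

test_that("mass never leaks into a disconnected component", {
  # two disjoint herb/protein blocks in one network
  he <- association_table(c("h1", "h2", "h3", "h4"),
                          c("e1", "e1", "e2", "e2"))
  pp <- association_table(c("p1", "p2", "p3", "p4"),
                          c("w1", "w1", "w2", "w2"))
  ht <- association_table(c("h1", "h3"), c("p1", "p3"))
  net <- build_hetero_network(build_layer_network(cosine_similarity(he)),
                              build_layer_network(cosine_similarity(pp)),
                              ht)
  cfg <- walk_config()
  tr <- build_transition(net, cfg)
  st <- propagate(tr, initial_state(net, "h1", character(), cfg), cfg)
  expect_equal(unname(st$u[c("h3", "h4")]), c(0, 0))
  expect_equal(unname(st$v[c("p3", "p4")]), c(0, 0))
})

test_that("ranking sorts by score with lexicographic tie-break and exclusion", {
  st <- structure(list(u = c(h1 = 1),
                       v = c(tb = 0.2, t1 = 0.3, ta = 0.2, t2 = 0.1),
                       iterations = 1L, converged = TRUE),
                  class = "prob_state")
  r <- rank_targets(st)
  expect_equal(r$protein, c("t1", "ta", "tb", "t2"))
  r2 <- rank_targets(st, exclude = c("t1", "ta"))
  expect_equal(r2$protein, c("tb", "t2"))
  expect_equal(r2$rank, 1:2)
})

test_that("a planted target outranks background proteins", {
  tabs <- generate_tables(synth_config(rng_seed = 11))
  res <- predict_targets(tabs$herb_efficacy, tabs$protein_pathway,
                         tabs$herb_target, "herb001",
                         cfg = walk_config(alpha = 5, beta = 10))
  mod <- tabs$truth$protein_module[res$ranking$protein]
  coupled <- tabs$truth$module_coupling[tabs$truth$herb_module["herb001"]]
  # mean rank of coupled-module proteins beats the rest
  expect_lt(mean(res$ranking$rank[mod == coupled]),
            mean(res$ranking$rank[mod != coupled]))
})
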