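test_that("networks link species to patches at the presence threshold", {
  m <- matrix(c(5, 0, 0, 2), 2, 2,
              dimnames = list(c("sp1", "sp2"), c("p1", "p2")))
  n1 <- build_network(m, 1)
  expect_setequal(paste(n1$links$species, n1$links$patch),
                  c("sp1 p1", "sp2 p2"))
  n3 <- build_network(m, 3)
  expect_equal(nrow(n3$links), 1L)
  expect_equal(n3$species_nodes, "sp1")   # sp2 and p2 dropped
  empty <- build_network(matrix(0, 2, 2,
                                dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(nrow(empty$links), 0L)
  expect_length(empty$species_nodes, 0L)
})

test_that("connectance counts realized links and grows when links are added", {
  full <- network_from_links(c("s1", "s1", "s2", "s2"),
                             c("p1", "p2", "p1", "p2"))
  expect_equal(connectance(full), 1)
  half <- network_from_links(c("s1", "s2"), c("p1", "p2"))
  expect_equal(connectance(half), 0.5)
  nine <- network_from_links(c("s1", "s1", "s2", "s3", "s3", "s2"),
                             c("p1", "p2", "p3", "p1", "p3", "p2"))
  # 6 links on 3x3; remove two later for the 4/9 case
  m <- nine$incidence
  m[cbind(c(3, 2), c(3, 2))] <- 0L
  n49 <- build_network(m, keep_isolated = TRUE)
  expect_equal(connectance(n49), 4 / 9)
  expect_equal(connectance(n49), oracle_connectance(n49$incidence))
  # adding one link strictly increases connectance
  m2 <- n49$incidence; m2[3, 3] <- 1L
  expect_gt(connectance(build_network(m2, keep_isolated = TRUE)),
            connectance(n49))
  expect_error(connectance(build_network(matrix(0, 1, 1,
    dimnames = list("a", "b")))), "empty")
})

test_that("NODF scores staircases, checkerboards, and the worked example", {
  stair <- network_from_links(c("r1", "r1", "r1", "r2", "r2", "r3"),
                              c("p1", "p2", "p3", "p1", "p2", "p1"))
  expect_equal(nodf(stair), 100)
  diag2 <- network_from_links(c("r1", "r2"), c("p1", "p2"))
  expect_equal(nodf(diag2), 0)
  ex <- network_from_links(c("r1", "r1", "r2", "r2", "r3"),
                           c("p1", "p2", "p2", "p3", "p3"))
  expect_equal(nodf(ex), 200 / 6)
  expect_equal(nodf(ex), oracle_nodf(ex$incidence))
  expect_error(nodf(build_network(matrix(c(1, 1), 1, 2,
    dimnames = list("a", c("x", "y"))))), "at least 2")
})

test_that("NODF matches the brute-force oracle and vegan on random networks", {
  set.seed(42)
  for (i in 1:30) {
    inc <- random_incidence(sample(3:7, 1), sample(3:7, 1), runif(1, 0.3, 0.7))
    net <- build_network(inc, keep_isolated = TRUE)
    if (length(net$species_nodes) < 2 || length(net$patch_nodes) < 2) next
    expect_equal(nodf(net), oracle_nodf(net$incidence), tolerance = 1e-12)
    # class symmetry: transposing the matrix swaps row/column pair sets
    tn <- build_network(t(net$incidence), keep_isolated = TRUE)
    expect_equal(nodf(net), nodf(tn), tolerance = 1e-12)
  }
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:10) {
    inc <- random_incidence(6, 6, 0.5)
    net <- suppressWarnings(build_network(inc))
    if (length(net$species_nodes) < 2 || length(net$patch_nodes) < 2) next
    v <- vegan::nestednodf(net$incidence, order = TRUE)$statistic[["NODF"]]
    expect_equal(nodf(net), v, tolerance = 1e-8)
  }
})

test_that("Barber modularity finds the known optima and is reproducible", {
  blocks <- network_from_links(
    c("a1", "a1", "a2", "a2", "b1", "b1", "b2", "b2"),
    c("pa1", "pa2", "pa1", "pa2", "pb1", "pb2", "pb1", "pb2"))
  r <- modularity(blocks, seed = 1)
  expect_equal(r$q, 0.5)
  expect_equal(length(unique(r$partition)), 2L)
  expect_equal(r$q, oracle_barber_best(blocks$incidence), tolerance = 1e-12)

  full <- network_from_links(rep(c("s1", "s2"), each = 2),
                             rep(c("p1", "p2"), 2))
  rf <- modularity(full, seed = 1)
  expect_equal(rf$q, 0)
  expect_equal(length(unique(rf$partition)), 1L)

  single <- network_from_links("s1", "p1")
  expect_equal(modularity(single, seed = 1)$q, 0)

  expect_identical(modularity(blocks, seed = 9), modularity(blocks, seed = 9))
  expect_error(modularity(build_network(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))), "no links")
})

test_that("the modularity heuristic attains the exhaustive optimum on small networks", {
  set.seed(5)
  tried <- 0
  while (tried < 5) {
    inc <- random_incidence(sample(3:5, 1), sample(3:5, 1), 0.5)
    net <- build_network(inc)
    if (nrow(net$links) == 0 ||
        length(net$species_nodes) + length(net$patch_nodes) > 9) next
    tried <- tried + 1
    q <- modularity(net, seed = tried, restarts = 30)$q
    expect_gte(q, 0)
    expect_equal(q, max(0, oracle_barber_best(net$incidence)),
                 tolerance = 1e-10)
  }
})

test_that("cnodf is a z-score against the focal-node null", {
  full <- network_from_links(rep(c("s1", "s2", "s3"), each = 2),
                             rep(c("p1", "p2"), 3))
  expect_equal(cnodf(full, "s1"), 0)   # randomization cannot change anything

  stair <- network_from_links(c("r1", "r1", "r1", "r2", "r2", "r3"),
                              c("p1", "p2", "p3", "p1", "p2", "p1"))
  # focal row with 3 possible partner sets: sampling converges to the
  # exhaustive-null z-score
  z_exact <- oracle_cnodf_exhaustive(stair, "r2")
  z_mc <- cnodf(stair, "r2", n_random = 4000, seed = 3)
  expect_equal(z_mc, z_exact, tolerance = 0.15)

  expect_identical(cnodf(stair, "r2", n_random = 50, seed = 7),
                   cnodf(stair, "r2", n_random = 50, seed = 7))
  expect_error(cnodf(stair, "nope"), "not found")
})

test_that("node metric series tracks degree and flags sparse nodes", {
  nets <- list(
    network_from_links(c("s1", "s1", "s2"), c("p1", "p2", "p1"), period = "t1"),
    network_from_links(c("s1", "s2"), c("p1", "p2"), period = "t2"),
    network_from_links(c("s1", "s1"), c("p1", "p2"), period = "t3")
  )
  out <- node_metric_series(nets, with_cnodf = FALSE)
  s1 <- out[out$node_id == "s1", ]
  expect_equal(unlist(s1[paste0("degree_", c("t1", "t2", "t3"))],
                      use.names = FALSE), c(2, 1, 2))
  expect_equal(s1$cv_degree, sd(c(2, 1, 2)) / mean(c(2, 1, 2)))
  # constant series has zero variability
  p2 <- out[out$node_id == "p2", ]
  expect_equal(unlist(p2[paste0("degree_", c("t1", "t2", "t3"))],
                      use.names = FALSE), c(1, 1, 1))
  expect_equal(p2$cv_degree, 0)
  # a node present once has undefined variability
  only_once <- node_metric_series(list(
    network_from_links(c("s1", "s9"), c("p1", "p9"), period = "a"),
    network_from_links("s1", "p1", period = "b")
  ), with_cnodf = FALSE)
  expect_true(is.na(only_once$cv_degree[only_once$node_id == "s9"]))
})

test_that("sample CV matches the hand-computed series", {
  x <- c(2, 4, 6, 8)
  expect_equal(sd(x) / mean(x), 0.5163978, tolerance = 1e-6)
  nets <- lapply(1:4, function(t) {
    sp <- paste0("s", 1:8)
    network_from_links(c(rep("focal", x[t]), sp),
                       c(paste0("p", seq_len(x[t])), paste0("p", 1:8)),
                       period = paste0("t", t))
  })
  out <- node_metric_series(nets, with_cnodf = FALSE)
  expect_equal(out$cv_degree[out$node_id == "focal"], 0.5163978,
               tolerance = 1e-6)
})

test_that("rank-sum comparison matches pair counting and wilcox.test", {
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  sep <- rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$u, 0)

  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:6, sample(3:8, 1), replace = TRUE)
    b <- sample(1:6, sample(3:8, 1), replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    r <- rank_sum_compare(a, b)
    expect_equal(r$u, oracle_mwu_u(a, b))
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
    expect_equal(r$u, unname(w$statistic))
    expect_equal(r$p, w$p.value, tolerance = 1e-9)
  }
  expect_error(rank_sum_compare(c(2, 2), c(2, 2, 2)), "degenerate")
})
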