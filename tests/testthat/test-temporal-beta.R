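test_that("temporal beta is the Jaccard dissimilarity of link sets", {
  n1 <- network_from_links(c("s1", "s1"), c("p1", "p2"))
  n2 <- network_from_links(c("s1", "s2"), c("p1", "p1"))
  expect_equal(beta_temporal(n1, n1), 0)
  disjoint <- network_from_links(c("s9", "s9"), c("p8", "p9"))
  expect_equal(beta_temporal(n1, disjoint), 1)
  expect_equal(beta_temporal(n1, n2), 2 / 3)   # a=1, b=1, c=1

  e1 <- build_network(matrix(0, 1, 1, dimnames = list("a", "b")))
  expect_error(beta_temporal(e1, e1), "empty")
})

test_that("extinction/colonization partition splits lost and gained links", {
  n1 <- network_from_links(c("s1", "s1"), c("p1", "p2"))
  n2 <- network_from_links(c("s1", "s2"), c("p1", "p1"))
  same <- partition_extinction_colonization(n1, n1)
  expect_equal(same$beta_extinction, 0)
  expect_equal(same$beta_colonization, 0)

  only_loss <- partition_extinction_colonization(
    network_from_links("s1", "p1"),
    build_network(matrix(0, 1, 1, dimnames = list("s1", "p1"))))
  expect_equal(only_loss$beta_extinction, 1)
  expect_equal(only_loss$beta_colonization, 0)

  ec <- partition_extinction_colonization(n1, n2)
  expect_equal(ec$beta_extinction, 1 / 3)
  expect_equal(ec$beta_colonization, 1 / 3)
})

test_that("component partition classifies changed links by node persistence", {
  # all nodes persist: purely local turnover
  a1 <- network_from_links(c("s1", "s2", "s1"), c("p1", "p2", "p2"))
  a2 <- network_from_links(c("s1", "s2", "s2"), c("p1", "p2", "p1"))
  ca <- partition_components(a1, a2)
  expect_equal(ca$beta_local, 0.5)
  expect_equal(ca$beta_regional + ca$beta_landscape + ca$beta_rl, 0)

  # s2 appears, p2 disappears: one regional and one landscape link
  b1 <- network_from_links(c("s1", "s1"), c("p1", "p2"))
  b2 <- network_from_links(c("s1", "s2"), c("p1", "p1"))
  cb <- partition_components(b1, b2)
  expect_equal(cb$beta_local, 0)
  expect_equal(cb$beta_regional, 1 / 3)
  expect_equal(cb$beta_landscape, 1 / 3)
  expect_equal(cb$beta_rl, 0)

  # complete turnover of both classes
  c1 <- network_from_links("s1", "p1")
  c2 <- network_from_links("s2", "p2")
  cc <- partition_components(c1, c2)
  expect_equal(cc$beta_rl, 1)
  expect_equal(cc$beta_local + cc$beta_regional + cc$beta_landscape, 0)
})

test_that("roster overrides let surveyed-but-empty nodes count as persistent", {
  n1 <- network_from_links(c("s1", "s1"), c("p1", "p2"))
  n2 <- network_from_links("s1", "p1")
  default <- partition_components(n1, n2)
  expect_equal(default$beta_landscape, 0.5)   # p2 lost its only link
  roster <- partition_components(n1, n2, persistent_patches = "p2")
  expect_equal(roster$beta_local, 0.5)
  expect_equal(roster$beta_landscape, 0)
})

test_that("beta_matrix enumerates ordered pairs deterministically", {
  nets <- lapply(1:4, function(i)
    network_from_links(paste0("s", c(1, i)), c("p1", "p2"),
                       period = paste0("t", i)))
  bm <- beta_matrix(nets)
  expect_equal(nrow(bm), 6L)
  expect_equal(bm$pair[1:3], c("t1->t2", "t1->t3", "t1->t4"))

  two <- beta_matrix(list(nets[[2]], nets[[2]]))
  expect_equal(nrow(two), 1L)
  expect_equal(two$beta_temporal, 0)
  expect_error(beta_matrix(nets[1]), "at least 2")
})

test_that("both partitions are additive and symmetric on random networks", {
  set.seed(77)
  for (i in 1:200) {
    n1 <- random_network(sample(2:8, 1), sample(2:8, 1), runif(1, 0.2, 0.8))
    n2 <- random_network(sample(2:8, 1), sample(2:8, 1), runif(1, 0.2, 0.8))
    if (nrow(n1$links) + nrow(n2$links) == 0) next
    bp <- beta_pair(n1, n2)
    expect_equal(bp$beta_extinction + bp$beta_colonization, bp$beta_temporal,
                 tolerance = 1e-12)
    expect_equal(bp$beta_local + bp$beta_regional + bp$beta_landscape +
                   bp$beta_rl, bp$beta_temporal, tolerance = 1e-12)
    expect_true(all(unlist(bp[2:8]) >= 0))
    expect_equal(bp$beta_temporal,
                 (bp$b_lost + bp$c_gained) /
                   (bp$a_shared + bp$b_lost + bp$c_gained))
    # symmetry: reversing time swaps extinction and colonization
    rev <- beta_pair(n2, n1)
    expect_equal(rev$beta_temporal, bp$beta_temporal)
    expect_equal(rev$beta_extinction, bp$beta_colonization)
    expect_equal(rev$beta_colonization, bp$beta_extinction)
  }
})

test_that("all beta components match the independent set-algebra oracle", {
  set.seed(99)
  for (i in 1:60) {
    n1 <- random_network(sample(2:6, 1), sample(2:6, 1), 0.5)
    n2 <- random_network(sample(2:6, 1), sample(2:6, 1), 0.5)
    if (nrow(n1$links) + nrow(n2$links) == 0) next
    bp <- beta_pair(n1, n2)
    or <- oracle_beta(n1$links, n2$links)
    for (f in names(or)) expect_equal(bp[[f]], or[[f]], tolerance = 1e-12)
  }
})

test_that("adding a shared link never increases temporal beta", {
  set.seed(55)
  for (i in 1:30) {
    n1 <- random_network(4, 4, 0.5)
    n2 <- random_network(4, 4, 0.5)
    if (nrow(n1$links) + nrow(n2$links) == 0) next
    b0 <- beta_temporal(n1, n2)
    pad <- function(m) {
      out <- matrix(0L, nrow(m) + 1L, ncol(m) + 1L,
                    dimnames = list(c(rownames(m), "sx"),
                                    c(colnames(m), "px")))
      if (nrow(m) > 0L) out[rownames(m), colnames(m)] <- m
      out["sx", "px"] <- 1L
      out
    }
    add1 <- pad(n1$incidence)
    add2 <- pad(n2$incidence)
    expect_lte(beta_temporal(build_network(add1), build_network(add2)), b0)
  }
})

test_that("component link counts partition the symmetric difference", {
  set.seed(31)
  for (i in 1:40) {
    n1 <- random_network(sample(2:8, 1), sample(2:8, 1), 0.4)
    n2 <- random_network(sample(2:8, 1), sample(2:8, 1), 0.4)
    if (nrow(n1$links) + nrow(n2$links) == 0) next
    bp <- beta_pair(n1, n2)
    tot <- bp$a_shared + bp$b_lost + bp$c_gained
    comp_links <- (bp$beta_local + bp$beta_regional + bp$beta_landscape +
                     bp$beta_rl) * tot
    expect_equal(comp_links, bp$b_lost + bp$c_gained, tolerance = 1e-9)
  }
})
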