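dn <- function(n) { codes <- paste0("V", seq_len(n)); list(codes, codes) }

test_that("the interception threshold is mean plus population sigma", {
  const <- matrix(0.2, 3, 3, dimnames = dn(3))
  th <- compute_threshold(const)
  expect_equal(th$mean, 0.2)
  expect_equal(th$sd, 0)
  expect_equal(th$lambda, 0.2)

  # hand evaluation on a 2x2 with a single entry 0.1
  m <- matrix(c(0, 0, 0.1, 0), 2, 2, dimnames = dn(2))
  th <- compute_threshold(m)
  expect_equal(th$mean, 0.025, tolerance = 1e-15)
  expect_equal(th$sd, sqrt(0.001875), tolerance = 1e-15)
  expect_equal(th$lambda, 0.025 + sqrt(0.001875), tolerance = 1e-15)
})

test_that("binarization is strict and monotone in the threshold", {
  set.seed(7)
  Tm <- matrix(runif(25), 5, 5, dimnames = dn(5))
  th <- compute_threshold(Tm)
  A <- binarize(Tm, th)
  expect_true(all(A %in% c(0L, 1L)))
  expect_identical(unname(A), unname((Tm > th$lambda) + 0L))
  # equality at the threshold is NOT an edge
  Tm2 <- Tm; Tm2[1, 2] <- th$lambda
  expect_identical(binarize(Tm2, th)[1, 2], 0L)
  # raising lambda never adds an edge
  for (bump in c(0.01, 0.1, 0.3))
    expect_true(all(binarize(Tm, th$lambda + bump) <= A))
  # lambda above the maximum entry gives the empty graph
  expect_true(all(binarize(Tm, max(Tm) + 1) == 0L))
})

test_that("Boolean reachability equals the Floyd-Warshall closure and is idempotent", {
  set.seed(11)
  for (i in 1:25) {
    A <- random_adjacency(sample(2:8, 1), p = runif(1, 0.1, 0.5))
    rs <- compute_reachability(A)
    expect_identical(rs$R, fw_closure(A))
    expect_true(all(((rs$R %*% rs$R) > 0) == (rs$R > 0)))  # R . R = R
    expect_true(all(diag(rs$R) == 1))
  }
  # empty graph: R = I, all components singletons
  A0 <- matrix(0L, 4, 4, dimnames = dn(4))
  rs0 <- compute_reachability(A0)
  expect_true(all(rs0$R == diag(4)))
  expect_true(all(lengths(rs0$sccs) == 1))
})

test_that("loop detection agrees with an independent SCC algorithm", {
  set.seed(13)
  for (i in 1:20) {
    A <- random_adjacency(sample(3:8, 1), p = runif(1, 0.15, 0.5))
    rs <- compute_reachability(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    ig <- igraph::components(g, mode = "strong")$membership
    ours <- rs$membership[names(ig)]
    # same partition: equal pairwise co-membership
    expect_identical(outer(ours, ours, "=="), outer(ig, ig, "=="))
  }
})

test_that("skeleton reduction deletes repeated paths and closure restores R'", {
  # textbook case: chain 1->2->3 plus shortcut 1->3; the shortcut goes
  A <- matrix(0L, 3, 3, dimnames = dn(3))
  A["V1", "V2"] <- A["V2", "V3"] <- A["V1", "V3"] <- 1L
  sk <- compute_skeleton(compute_reachability(A))
  expect_identical(sk$S_general["V1", "V3"], 0L)
  expect_identical(sk$S_general["V1", "V2"], 1L)
  expect_identical(sk$S_general["V2", "V3"], 1L)

  set.seed(17)
  for (i in 1:25) {
    A <- random_dag(sample(3:9, 1))
    rs <- compute_reachability(A)
    sk <- compute_skeleton(rs)
    closed <- fw_closure(sk$S_condensed)
    expect_identical(unname(closed), unname(rs$R_condensed))
  }
})

test_that("loop re-expansion builds a factor-order cycle and lowest-index attachments", {
  # two-node loop with an external sink reached from both members
  A <- matrix(0L, 3, 3, dimnames = dn(3))
  A["V1", "V2"] <- A["V2", "V1"] <- 1L
  A["V1", "V3"] <- A["V2", "V3"] <- 1L
  rs <- compute_reachability(A)
  sk <- compute_skeleton(rs)
  expect_identical(sk$S_general["V1", "V2"], 1L)
  expect_identical(sk$S_general["V2", "V1"], 1L)
  # attachment uses the lowest source index V1, not V2
  expect_identical(sk$S_general["V1", "V3"], 1L)
  expect_identical(sk$S_general["V2", "V3"], 0L)
  # closure of the re-expanded skeleton reproduces full reachability
  expect_identical(fw_closure(sk$S_general), rs$R)
})

test_that("valued skeletons carry T on edges and mark loop cliques", {
  fx <- nssi_fixture()
  Tm <- compute_total_influence(normalize_direct_matrix(fx$O))
  rs <- compute_reachability(binarize(Tm))
  sk <- compute_skeleton(rs)
  vs <- build_valued_skeleton(Tm, sk, rs)
  # TS zero exactly off the skeleton support
  expect_identical(unname(vs$TS != 0), unname(sk$S_general == 1L))
  on_edges <- which(sk$S_general == 1L)
  expect_equal(vs$TS[on_edges], Tm[on_edges], tolerance = 1e-15)
  # WS differs from TS only inside loops
  diff_cells <- which(vs$WS != vs$TS, arr.ind = TRUE)
  memb <- rs$membership
  expect_true(all(memb[rownames(Tm)[diff_cells[, 1]]] ==
                  memb[rownames(Tm)[diff_cells[, 2]]]))

  # loop-free system: WS is TS
  A <- random_dag(6)
  Td <- matrix(runif(36, 0.05, 0.2), 6, 6, dimnames = dimnames(A)) * A
  rsd <- compute_reachability(A)
  skd <- compute_skeleton(rsd)
  vsd <- build_valued_skeleton(Td, skd, rsd)
  expect_identical(vsd$WS, vsd$TS)
})
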