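dn <- function(n) { codes <- paste0("V", seq_len(n)); list(codes, codes) }

test_that("factor sets are reflexive and nested", {
  rs <- fixture_pipeline()$reachability
  fs <- factor_sets(rs$R)
  for (code in names(fs)) {
    expect_true(code %in% fs[[code]]$reachable)
    expect_true(code %in% fs[[code]]$antecedent)
    expect_true(all(fs[[code]]$common %in% fs[[code]]$reachable))
    expect_true(all(fs[[code]]$common %in% fs[[code]]$antecedent))
  }
  expect_identical(sort(fs$B7$common), sort(c("B7", "B8", "B9")))
})

test_that("both extraction modes partition the factors and keep loops together", {
  set.seed(19)
  for (i in 1:20) {
    A <- random_adjacency(sample(3:9, 1), p = runif(1, 0.15, 0.5))
    rs <- compute_reachability(A)
    for (mode in c("UP", "DOWN")) {
      part <- extract_levels(rs, mode)
      flat <- unlist(part$levels)
      expect_identical(sort(flat), sort(rownames(A)))   # exact partition
      expect_identical(anyDuplicated(flat), 0L)
      for (scc in Filter(function(s) length(s) > 1, rs$sccs)) {
        lv <- vapply(part$levels, function(l) any(scc %in% l), logical(1))
        expect_identical(sum(lv), 1L)                   # never split
      }
    }
  }
})

test_that("UP level 0 collects exactly the sinks of a closed acyclic system", {
  set.seed(23)
  for (i in 1:10) {
    A <- random_dag(sample(3:9, 1))
    rs <- compute_reachability(A)
    up <- extract_levels(rs, "UP")
    sinks <- rownames(rs$R)[rowSums(rs$R) == 1]
    expect_identical(sort(up$levels[[1]]), sort(sinks))
  }
})

test_that("on a chain UP and DOWN coincide and no factor is active", {
  O <- degenerate_cases()$chain$O
  rs <- compute_reachability((O > 0) + 0L)
  up <- extract_levels(rs, "UP")
  down <- extract_levels(rs, "DOWN")
  expect_identical(up$levels, down$levels)
  expect_length(identify_active_elements(up, down), 0)
  # brackets never appear in a loop-free chain
  expect_false(grepl("\\[", format(full_causal_series(up, rs))))
})

test_that("skeleton edges never point against the UP hierarchy", {
  rp <- fixture_pipeline()
  idx <- base::rep(seq_along(rp$up$levels) - 1L, lengths(rp$up$levels))
  lvl_of <- setNames(idx, unlist(rp$up$levels))
  edges <- which(rp$skeleton$S_general == 1L, arr.ind = TRUE)
  codes <- rp$system$codes
  for (k in seq_len(nrow(edges))) {
    from <- codes[edges[k, 1]]; to <- codes[edges[k, 2]]
    expect_true(lvl_of[[from]] >= lvl_of[[to]])  # influence flows upward
  }
})

test_that("layer classification partitions deep systems and degrades per rule", {
  set.seed(29)
  for (i in 1:15) {
    A <- random_adjacency(sample(4:9, 1), p = runif(1, 0.15, 0.4))
    rs <- compute_reachability(A)
    up <- extract_levels(rs, "UP"); down <- extract_levels(rs, "DOWN")
    cl <- classify_layers(up, down)
    expect_identical(sort(union(union(cl$root, cl$intermediate), cl$result)),
                     sort(rownames(A)))
    # per-rule definitions hold exactly
    expect_setequal(cl$root, union(up$levels[[length(up$levels)]],
                                   down$levels[[length(down$levels)]]))
    expect_setequal(cl$result,
                    union(unlist(up$levels[seq_len(min(2, length(up$levels)))]),
                          unlist(down$levels[seq_len(min(2, length(down$levels)))])))
    expect_length(intersect(cl$intermediate, union(cl$root, cl$result)), 0)
  }

  # 2-factor chain: both rules claim the sink, per definition
  codes <- c("src", "snk")
  A <- matrix(c(0L, 0L, 1L, 0L), 2, 2, dimnames = list(codes, codes))
  rs <- compute_reachability(A)
  cl <- classify_layers(extract_levels(rs, "UP"), extract_levels(rs, "DOWN"))
  expect_identical(cl$root, "src")
  expect_setequal(cl$result, c("src", "snk"))
  expect_length(cl$intermediate, 0)
})

test_that("single-factor components sit alone and identical partitions give no active set", {
  part <- fixture_pipeline()$up
  expect_length(identify_active_elements(part, part), 0)
})
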