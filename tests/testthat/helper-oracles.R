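# Independent oracles and generators used across the suite.

# O(n^3) Floyd-Warshall transitive closure of (A + I), independent of the
# package's Boolean-power implementation.
fw_closure <- function(A) {
  n <- nrow(A)
  R <- (A > 0) + 0L
  diag(R) <- 1L
  for (k in seq_len(n))
    for (i in seq_len(n))
      if (R[i, k] == 1L) R[i, ] <- pmax(R[i, ], R[i, k] * R[k, ])
  dimnames(R) <- dimnames(A)
  R
}

# explicit partial Neumann sum N + N^2 + ... + N^k
neumann_partial <- function(N, k) {
  S <- N
  P <- N
  for (i in seq_len(k - 1)) {
    P <- P %*% N
    S <- S + P
  }
  S
}

# random binary digraph on n nodes (zero diagonal), density p
random_adjacency <- function(n, p = 0.3) {
  codes <- paste0("V", seq_len(n))
  A <- matrix(rbinom(n * n, 1, p), n, n, dimnames = list(codes, codes))
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

# random DAG: edges only from lower to higher index
random_dag <- function(n, p = 0.35) {
  A <- random_adjacency(n, p)
  A[lower.tri(A, diag = TRUE)] <- 0L
  A
}

fixture_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(nssi_fixture()$O)
    cache
  }
})
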