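#' Aggregate per-expert score tables into a direct influence matrix
#'
#' Sums the expert panel elementwise: entry (i, j) of the result is the sum
#' over experts of the 0-4 score given to "factor i influences factor j".
#' All tables must share one factor order; the diagonal stays zero.
#'
#' @param tables list of square integer matrices with identical factor-code
#'   dimnames, entries in 0..4, zero diagonal (e.g. from [generate_panel()]).
#' @return Integer direct influence matrix `O` with the same dimnames.
#' @examples
#' panel <- generate_panel(n_factors = 4, n_experts = 5, seed = 2)
#' O <- aggregate_expert_scores(panel$tables)
#' max(O)  # at most 4 * 5
#' @export
aggregate_expert_scores <- function(tables) {
  if (!is.list(tables) || length(tables) < 1)
    stop("need at least one expert score table", call. = FALSE)
  ref <- tables[[1]]
  check_system_matrix(ref, what = "expert score table")
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    check_system_matrix(tb, what = sprintf("expert score table %d", k))
    if (!identical(dimnames(tb), dimnames(ref)))
      stop("expert score table ", k, " uses a different factor set/order",
           call. = FALSE)
    if (any(tb != round(tb)) || any(tb < 0) || any(tb > 4))
      stop("expert score table ", k, " has entries outside the 0..4 scale",
           call. = FALSE)
    if (any(diag(tb) != 0))
      stop("expert score table ", k, " has a nonzero diagonal", call. = FALSE)
  }
  O <- Reduce(`+`, tables)
  storage.mode(O) <- "integer"
  dimnames(O) <- dimnames(ref)
  O
}

#' Normalize a direct influence matrix
#'
#' Scales the aggregated direct influence matrix `O` by the largest
#' Euclidean norm, over factors, of the pair (row sum, column sum):
#' \deqn{N_{ij} = O_{ij} / \max_i \sqrt{a_i^2 + b_i^2}}
#' where \eqn{a_i} and \eqn{b_i} are the i-th row and column sums of `O`.
#' This guarantees a spectral radius below one, so the Neumann series
#' behind [compute_total_influence()] converges.
#'
#' By default the normalized entries are carried at six decimal places
#' (`digits = 6`), the working precision at which the shipped worked
#' example's published threshold is reproduced exactly; set `digits = NULL`
#' to keep the exact quotients.
#'
#' @param O square nonnegative direct influence matrix with factor-code
#'   dimnames and at least one nonzero entry.
#' @param digits decimal places at which to carry `N`, or `NULL` for the
#'   exact quotient.
#' @return An object of class `dematel_normalized`: list with `N` (the
#'   normalized matrix), `denominator`, `row_sums`, `col_sums`, `digits`.
#' @examples
#' fx <- nssi_fixture()
#' nrm <- normalize_direct_matrix(fx$O)
#' nrm$denominator              # about 930.9635, attained at factor Y
#' round(nrm$N["A2", "A3"], 3)  # 0.072
#' @export
normalize_direct_matrix <- function(O, digits = 6) {
  check_system_matrix(O, what = "direct influence matrix")
  if (any(O < 0)) stop("direct influence matrix must be nonnegative",
                       call. = FALSE)
  if (all(O == 0))
    stop("cannot normalize an all-zero direct influence matrix (denominator would be zero)",
         call. = FALSE)
  a <- rowSums(O)
  b <- colSums(O)
  den <- max(sqrt(a^2 + b^2))
  N <- O / den
  if (!is.null(digits)) N <- round(N, digits)
  structure(list(N = N, denominator = den, row_sums = a, col_sums = b,
                 digits = digits),
            class = "dematel_normalized")
}

#' @export
print.dematel_normalized <- function(x, ...) {
  cat(sprintf("Normalized influence matrix (%d x %d), denominator %.4f\n",
              nrow(x$N), ncol(x$N), x$denominator))
  invisible(x)
}

# internal: accept either the normalization object or a bare matrix
as_N_matrix <- function(N) {
  if (inherits(N, "dematel_normalized")) N <- N$N
  check_system_matrix(N, what = "normalized influence matrix")
  N
}

#' Comprehensive (total) influence matrix
#'
#' Accumulates direct and all indirect influence along paths of every
#' length: \eqn{T = N + N^2 + N^3 + \dots = N (I - N)^{-1}}, evaluated in
#' closed form. The series converges only when the spectral radius of `N`
#' is strictly below one; a divergent input is refused.
#'
#' @param N a `dematel_normalized` object or a bare normalized matrix.
#' @return The total influence matrix `T` (square, factor-code dimnames).
#' @examples
#' fx <- nssi_fixture()
#' Tm <- compute_total_influence(normalize_direct_matrix(fx$O))
#' round(Tm["B5", "Y"], 3)  # 0.149
#' @export
compute_total_influence <- function(N) {
  N <- as_N_matrix(N)
  rho <- max(Mod(eigen(N, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("Neumann series diverges: spectral radius %.4f >= 1", rho),
         call. = FALSE)
  n <- nrow(N)
  Tm <- N %*% solve(diag(n) - N)
  dimnames(Tm) <- dimnames(N)
  Tm
}

#' Influence, influenced, centrality and cause degrees
#'
#' Per-factor DEMATEL statistics from the total influence matrix: the
#' influence degree `D` (row sum of `T`), the influenced degree `C`
#' (column sum), the centrality `M = D + C` (prominence of the factor in
#' the system) and the cause degree `Rc = D - C` (net driver when
#' positive, net receiver when negative). `(M, Rc)` pairs are the
#' coordinates of the cause-effect scatter diagram.
#'
#' @param T total influence matrix from [compute_total_influence()].
#' @return `data.frame` with columns `code`, `D`, `C`, `M`, `Rc`.
#' @examples
#' fx <- nssi_fixture()
#' Tm <- compute_total_influence(normalize_direct_matrix(fx$O))
#' ct <- compute_centrality(Tm)
#' round(ct[ct$code == "Y", -1], 3)  # D 0.336, C 1.611, M 1.947, Rc -1.275
#' @export
compute_centrality <- function(T) {
  check_system_matrix(T, what = "total influence matrix")
  D <- rowSums(T)
  C <- colSums(T)
  data.frame(code = rownames(T), D = unname(D), C = unname(C),
             M = unname(D + C), Rc = unname(D - C),
             stringsAsFactors = FALSE)
}
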