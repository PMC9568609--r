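#' Interception threshold for edge selection
#'
#' The threshold lambda above which a total influence value counts as a
#' structural edge: the arithmetic mean of all n^2 entries of `T`
#' (diagonal included) plus their population standard deviation
#' (divisor n^2).
#'
#' @param T total influence matrix.
#' @return Object of class `influence_threshold`: list with `mean`, `sd`,
#'   `lambda` and `n`.
#' @examples
#' th <- compute_threshold(matrix(c(0, 0.1, 0, 0), 2, 2,
#'                                dimnames = list(c("a", "b"), c("a", "b"))))
#' th$lambda  # 0.025 + sqrt(0.001875)
#' @export
compute_threshold <- function(T) {
  check_system_matrix(T, what = "total influence matrix")
  m <- mean(T)
  s <- sqrt(sum((T - m)^2) / length(T))
  structure(list(mean = m, sd = s, lambda = m + s, n = nrow(T)),
            class = "influence_threshold")
}

#' @export
print.influence_threshold <- function(x, ...) {
  cat(sprintf("Influence threshold: mean %.10f + sd %.10f = lambda %.10f (n = %d)\n",
              x$mean, x$sd, x$lambda, x$n))
  invisible(x)
}

#' Binary adjacency matrix from total influence
#'
#' Keeps an edge i -> j exactly when `t_ij` strictly exceeds lambda.
#'
#' @param T total influence matrix.
#' @param threshold an `influence_threshold` from [compute_threshold()] or
#'   a single positive number overriding it.
#' @return Binary (0/1 integer) adjacency matrix `A`.
#' @export
binarize <- function(T, threshold = compute_threshold(T)) {
  check_system_matrix(T, what = "total influence matrix")
  lambda <- if (inherits(threshold, "influence_threshold"))
    threshold$lambda else as.numeric(threshold)
  if (length(lambda) != 1 || is.na(lambda))
    stop("threshold must be an influence_threshold or a single number",
         call. = FALSE)
  A <- (T > lambda) + 0L
  storage.mode(A) <- "integer"
  dimnames(A) <- dimnames(T)
  A
}

# internal: Boolean matrix product
bool_mult <- function(X, Y) (X %*% Y > 0) + 0L

#' Reachability matrix, loops and condensation
#'
#' Computes the reachability matrix `R` as the stable Boolean power of
#' `B = A + I` (`B^(k-1) != B^k = B^(k+1) = R`), so `R` is reflexive and
#' transitive and `R[i, j] = 1` means factor j is reachable from factor i
#' along some directed path. Factors i, j with `R[i, j] = R[j, i] = 1` are
#' mutually reachable and form a loop (strongly connected component, SCC).
#' Loops are condensed to single nodes, giving the component-level
#' reachability `R_condensed`, a reflexive transitive partial order.
#'
#' @param A binary adjacency matrix from [binarize()].
#' @return Object of class `reachability_structure`: list with `R`, `A`,
#'   `sccs` (list of member-code vectors, ordered by first member),
#'   `membership` (named integer vector factor -> component), and
#'   `R_condensed` (binary matrix on components, named by their first
#'   member in factor order).
#' @examples
#' fx <- nssi_fixture()
#' Tm <- compute_total_influence(normalize_direct_matrix(fx$O))
#' rs <- compute_reachability(binarize(Tm))
#' Filter(function(s) length(s) > 1, rs$sccs)  # {B2,B3} and {B7,B8,B9}
#' @export
compute_reachability <- function(A) {
  check_system_matrix(A, what = "adjacency matrix")
  if (!all(A %in% c(0, 1)))
    stop("adjacency matrix must be binary", call. = FALSE)
  n <- nrow(A)
  B <- ((A + diag(n)) > 0) + 0L
  R <- B
  stable <- FALSE
  for (k in seq_len(n + 1)) {   # squaring doubles path length; n+1 is ample
    R_next <- bool_mult(R, R)
    if (identical(R_next, R)) { stable <- TRUE; break }
    R <- R_next
  }
  if (!stable) stop("Boolean closure failed to stabilize within n iterations",
                    call. = FALSE)
  dimnames(R) <- dimnames(A)

  mutual <- R * t(R)                      # 1 iff mutually reachable
  comp_id <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp_id[i] == 0L) {
      next_id <- next_id + 1L
      comp_id[mutual[i, ] == 1] <- next_id
    }
  }
  names(comp_id) <- rownames(A)
  sccs <- split(rownames(A), comp_id)
  sccs <- sccs[order(vapply(sccs, function(s)
    match(s[1], rownames(A)), 0L))]
  names(sccs) <- vapply(sccs, `[`, "", 1)
  comp_of <- stats::setNames(rep(names(sccs), lengths(sccs)),
                             unlist(sccs, use.names = FALSE))
  membership <- stats::setNames(match(comp_of[rownames(A)], names(sccs)),
                                rownames(A))

  reps <- vapply(sccs, `[`, "", 1)
  Rc <- R[reps, reps, drop = FALSE]       # any member represents its SCC
  dimnames(Rc) <- list(names(sccs), names(sccs))
  if (any(Rc + t(Rc) - diag(nrow(Rc)) > 1))
    stop("internal error: condensed reachability is not antisymmetric",
         call. = FALSE)
  structure(list(R = R, A = A, sccs = sccs, membership = membership,
                 R_condensed = Rc),
            class = "reachability_structure")
}

#' @export
print.reachability_structure <- function(x, ...) {
  loops <- Filter(function(s) length(s) > 1, x$sccs)
  cat(sprintf("Reachability over %d factors, %d components", nrow(x$R),
              length(x$sccs)))
  if (length(loops))
    cat("; loops:", paste(vapply(loops, function(s)
      paste0("{", paste(s, collapse = ","), "}"), ""), collapse = " "))
  cat("\n")
  invisible(x)
}

#' Skeleton (transitive reduction) matrices
#'
#' Reduces the condensed reachability to its minimal edge set
#' `S' = R' - (R' - I)^2 - I` in Boolean arithmetic (every edge implied by
#' a two-step path over the closed relation is a repeated path and is
#' deleted), then re-expands loops onto the original factors to give the
#' general skeleton `S`:
#' members of each loop are joined in a single directed cycle in factor
#' order, and every condensed edge is realized by the direct adjacency
#' edge between component members with the lowest (source, target) factor
#' indices.
#'
#' @param rs a `reachability_structure` from [compute_reachability()].
#' @return Object of class `skeleton_matrix`: list with `S_condensed`
#'   (binary, on components) and `S_general` (binary, on factors).
#' @export
compute_skeleton <- function(rs) {
  stopifnot(inherits(rs, "reachability_structure"))
  Rc <- rs$R_condensed
  m <- nrow(Rc)
  Q <- Rc; diag(Q) <- 0L                      # R' - I
  two_step <- bool_mult(Q, Q)                 # (R' - I)^2, Boolean
  Sc <- Q * (1L - two_step)                   # subtraction as and-not
  storage.mode(Sc) <- "integer"

  A <- rs$A
  codes <- rownames(A)
  Sg <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  for (scc in rs$sccs) {
    if (length(scc) > 1) {
      ord <- scc[order(match(scc, codes))]
      nxt <- c(ord[-1], ord[1])
      Sg[cbind(ord, nxt)] <- 1L
    }
  }
  comp_names <- names(rs$sccs)
  for (ci in seq_len(m)) for (cj in seq_len(m)) {
    if (Sc[ci, cj] == 1L) {
      src <- rs$sccs[[ci]]; dst <- rs$sccs[[cj]]
      cand <- which(A[src, dst, drop = FALSE] == 1L, arr.ind = TRUE)
      if (nrow(cand) == 0)
        stop("internal error: condensed skeleton edge ", comp_names[ci],
             " -> ", comp_names[cj], " has no direct adjacency edge",
             call. = FALSE)
      idx <- cbind(match(src[cand[, 1]], codes), match(dst[cand[, 2]], codes))
      pick <- order(idx[, 1], idx[, 2])[1]
      Sg[idx[pick, 1], idx[pick, 2]] <- 1L
    }
  }
  structure(list(S_condensed = Sc, S_general = Sg), class = "skeleton_matrix")
}

#' Influence-valued skeleton matrices TS and WS
#'
#' `TS` places the total influence value `t_ij` on every edge of the
#' general skeleton (zero elsewhere). `WS` replaces every ordered pair of
#' distinct factors inside one loop with 1, marking loop membership as a
#' clique, and keeps the `TS` values on all other edges.
#'
#' @param T total influence matrix.
#' @param sk a `skeleton_matrix` from [compute_skeleton()].
#' @param rs the `reachability_structure` the skeleton was derived from.
#' @return Object of class `valued_skeleton`: list with matrices `TS` and
#'   `WS`.
#' @export
build_valued_skeleton <- function(T, sk, rs) {
  check_system_matrix(T, what = "total influence matrix")
  stopifnot(inherits(sk, "skeleton_matrix"),
            inherits(rs, "reachability_structure"))
  if (!identical(dimnames(T), dimnames(sk$S_general)))
    stop("T and the skeleton use different factor systems", call. = FALSE)
  TS <- T * sk$S_general
  WS <- TS
  for (scc in rs$sccs) {
    if (length(scc) > 1) {
      blk <- matrix(1, length(scc), length(scc))
      diag(blk) <- 0
      WS[scc, scc] <- blk
    }
  }
  structure(list(TS = TS, WS = WS), class = "valued_skeleton")
}
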