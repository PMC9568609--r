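#' Reachable, antecedent and common sets per factor
#'
#' For each factor e_i of a reachability matrix: the reachable set (all j
#' with `R[i, j] = 1`), the antecedent set (all j with `R[j, i] = 1`) and
#' their intersection, the common set. Reflexivity puts every factor in
#' all three of its own sets.
#'
#' @param R binary reachability matrix (reflexive, transitive).
#' @return Named list per factor, each a list with `reachable`,
#'   `antecedent`, `common` (character vectors of codes).
#' @export
factor_sets <- function(R) {
  check_system_matrix(R, what = "reachability matrix")
  codes <- rownames(R)
  out <- lapply(seq_along(codes), function(i) {
    reach <- codes[R[i, ] == 1]
    ante <- codes[R[, i] == 1]
    list(reachable = reach, antecedent = ante,
         common = intersect(reach, ante))
  })
  stats::setNames(out, codes)
}

# internal: sanity-check reflexive + transitive before level extraction
assert_closed <- function(R) {
  if (any(diag(R) != 1))
    stop("reachability matrix must be reflexive", call. = FALSE)
  if (!identical(bool_mult(R, R), (R > 0) + 0L))
    stop("reachability matrix must be transitive (run compute_reachability first)",
         call. = FALSE)
}

#' Antagonistic level extraction (UP and DOWN)
#'
#' Partitions the factors into hierarchy levels from the reachability
#' matrix, in one of two antagonistic modes:
#' \describe{
#'   \item{UP (result priority)}{each round extracts every factor whose
#'     reachable set equals its common set; extracted batches are placed
#'     top-down, the first batch at level 0 (the result end).}
#'   \item{DOWN (cause priority)}{each round extracts every factor whose
#'     antecedent set equals its common set; batches are placed bottom-up,
#'     the last batch at level 0.}
#' }
#' Sets are recomputed on the residual system after every round, all
#' qualifying factors of a round are extracted together, and mutually
#' reachable factors (loops) always share a level.
#'
#' @param rs a `reachability_structure`, or a bare reachability matrix.
#' @param mode `"UP"` or `"DOWN"`.
#' @return Object of class `level_partition`: list with `mode` and
#'   `levels`, an ordered list of factor-code vectors, level 0 first
#'   (topmost).
#' @examples
#' fx <- nssi_fixture()
#' Tm <- compute_total_influence(normalize_direct_matrix(fx$O))
#' rs <- compute_reachability(binarize(Tm))
#' extract_levels(rs, "UP")$levels[[1]]  # "Y"
#' @export
extract_levels <- function(rs, mode = c("UP", "DOWN")) {
  mode <- match.arg(mode)
  R <- if (inherits(rs, "reachability_structure")) rs$R else rs
  check_system_matrix(R, what = "reachability matrix")
  assert_closed(R)
  codes <- rownames(R)
  residual <- codes
  batches <- list()
  while (length(residual) > 0) {
    Rr <- R[residual, residual, drop = FALSE]
    picked <- vapply(seq_along(residual), function(i) {
      reach <- which(Rr[i, ] == 1)
      ante <- which(Rr[, i] == 1)
      common <- intersect(reach, ante)
      if (mode == "UP") setequal(reach, common) else setequal(ante, common)
    }, logical(1))
    if (!any(picked))
      stop("level extraction stalled; reachability matrix is not transitively closed",
           call. = FALSE)
    batches[[length(batches) + 1]] <- residual[picked]
    residual <- residual[!picked]
  }
  levels <- if (mode == "UP") batches else rev(batches)
  structure(list(mode = mode, levels = levels), class = "level_partition")
}

#' @export
print.level_partition <- function(x, ...) {
  cat(sprintf("%s-mode level partition (%d levels)\n", x$mode,
              length(x$levels)))
  for (i in seq_along(x$levels))
    cat(sprintf("  L%d: %s\n", i - 1, paste(x$levels[[i]], collapse = ", ")))
  invisible(x)
}

# internal: named vector factor -> level index (0-based)
level_index <- function(partition) {
  stopifnot(inherits(partition, "level_partition"))
  idx <- rep(seq_along(partition$levels) - 1L, lengths(partition$levels))
  stats::setNames(idx, unlist(partition$levels, use.names = FALSE))
}

#' Active elements: factors whose UP and DOWN levels differ
#'
#' A factor placed at different levels by the result-priority and
#' cause-priority extractions has an extensible ("active") position in the
#' hierarchy.
#'
#' @param up,down `level_partition`s over the same factor set.
#' @return Character vector of active factor codes, in factor order.
#' @export
identify_active_elements <- function(up, down) {
  ui <- level_index(up)
  di <- level_index(down)
  if (!setequal(names(ui), names(di)))
    stop("UP and DOWN partitions cover different factor sets", call. = FALSE)
  codes <- names(ui)
  codes[ui[codes] != di[codes]]
}

#' Root, intermediate and result layers
#'
#' Classifies factors by hierarchy position: the root layer is the union
#' of the bottom level of the UP and DOWN partitions (the fundamental
#' drivers), the result layer is the union of the top two levels (0 and 1)
#' of both (the outcomes), and the intermediate layer is everything else.
#' For hierarchies of three or more levels the three sets partition the
#' factor set; in shallower systems the root and result rules can claim
#' the same factor (the sets are then reported per rule, overlapping) and
#' the intermediate layer is empty.
#'
#' @param up,down `level_partition`s over the same factor set.
#' @return Object of class `layer_classification`: list with `root`,
#'   `intermediate`, `result` and `active` factor-code vectors (factor
#'   order).
#' @export
classify_layers <- function(up, down) {
  ui <- level_index(up)
  di <- level_index(down)
  if (!setequal(names(ui), names(di)))
    stop("UP and DOWN partitions cover different factor sets", call. = FALSE)
  codes <- names(ui)   # UP partition preserves factor order per level batch
  codes <- codes[order(match(codes, names(ui)))]
  root <- union(up$levels[[length(up$levels)]],
                down$levels[[length(down$levels)]])
  result <- union(unlist(up$levels[seq_len(min(2, length(up$levels)))]),
                  unlist(down$levels[seq_len(min(2, length(down$levels)))]))
  inter <- setdiff(codes, union(root, result))
  ord <- function(x) x[order(match(x, codes))]
  structure(list(root = ord(root), intermediate = ord(inter),
                 result = ord(result),
                 active = identify_active_elements(up, down)),
            class = "layer_classification")
}

#' @export
print.layer_classification <- function(x, ...) {
  cat("Layer classification\n")
  cat("  root:        ", paste(x$root, collapse = ", "), "\n")
  cat("  intermediate:", paste(x$intermediate, collapse = ", "), "\n")
  cat("  result:      ", paste(x$result, collapse = ", "), "\n")
  cat("  active:      ", paste(x$active, collapse = ", "), "\n")
  invisible(x)
}

#' Full causal series of a level partition
#'
#' Lists the levels bottom-to-top as a causal chain, grouping mutually
#' reachable factors (loops) in brackets. Within one chain term, loops
#' come first (largest first, ties by factor order of the first member),
#' followed by singleton factors in factor order.
#'
#' @param partition a `level_partition`.
#' @param rs the `reachability_structure` the partition came from (source
#'   of the loop memberships).
#' @return Object of class `causal_series`: list with `mode` and `terms`;
#'   each term is a list of groups (character vectors; length > 1 marks a
#'   loop). `format()` renders the chain, e.g.
#'   `{B6, B10} > {[B7, B8, B9], [B2, B3], A3, B11} > ...`.
#' @export
full_causal_series <- function(partition, rs) {
  stopifnot(inherits(partition, "level_partition"),
            inherits(rs, "reachability_structure"))
  codes <- rownames(rs$R)
  terms <- lapply(rev(partition$levels), function(lv) {
    lv <- lv[order(match(lv, codes))]
    in_level <- Filter(function(s) length(s) > 1 && all(s %in% lv), rs$sccs)
    loop_members <- unlist(in_level, use.names = FALSE)
    if (length(in_level)) {
      ord <- order(-lengths(in_level),
                   vapply(in_level, function(s) match(s[1], codes), 0L))
      in_level <- in_level[ord]
    }
    singles <- setdiff(lv, loop_members)
    c(unname(in_level), as.list(singles))
  })
  structure(list(mode = partition$mode, terms = terms),
            class = "causal_series")
}

#' @export
format.causal_series <- function(x, ...) {
  fmt_grp <- function(g)
    if (length(g) > 1) paste0("[", paste(g, collapse = ", "), "]")
    else g
  fmt_term <- function(tm)
    paste0("{", paste(vapply(tm, fmt_grp, ""), collapse = ", "), "}")
  paste(vapply(x$terms, fmt_term, ""), collapse = " ≻ ")
}

#' @export
print.causal_series <- function(x, ...) {
  cat(x$mode, "causal series:\n  ", format(x), "\n")
  invisible(x)
}
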