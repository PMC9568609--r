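#' Generate a synthetic expert scoring panel
#'
#' Simulates the raw material of a DEMATEL survey: a panel of experts each
#' scoring every ordered factor pair on the 0-4 influence scale
#' (0 no impact ... 4 very strong impact), with a zero diagonal. Scores are
#' drawn independently per cell and expert from the categorical
#' distribution given by `score_weights`. The default emulates the study
#' design of the shipped worked example: 13 factors, 27 experts.
#'
#' @param n_factors number of factors (>= 2). Codes are `F1`, `F2`, ...
#' @param n_experts number of experts (>= 1).
#' @param score_weights nonnegative weights over the scores 0:4 (need not
#'   sum to one; must not be all zero).
#' @param seed integer seed; identical arguments and seed reproduce the
#'   panel exactly.
#' @return A list with `system` (a [factor_system]) and `tables`, a list of
#'   `n_experts` expert score tables; each table is an integer matrix with
#'   an `expert_id` attribute.
#' @examples
#' panel <- generate_panel(n_factors = 5, n_experts = 3, seed = 1)
#' panel$tables[[1]]
#' @export
generate_panel <- function(n_factors = 13, n_experts = 27,
                           score_weights = c(1, 1, 1, 1, 1), seed = NULL) {
  if (!is.numeric(n_factors) || length(n_factors) != 1 || n_factors < 2 ||
      n_factors != round(n_factors))
    stop("n_factors must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(n_experts) || length(n_experts) != 1 || n_experts < 1 ||
      n_experts != round(n_experts))
    stop("n_experts must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(score_weights) || length(score_weights) != 5 ||
      any(score_weights < 0) || all(score_weights == 0) ||
      anyNA(score_weights))
    stop("score_weights must be 5 nonnegative weights over scores 0..4, not all zero",
         call. = FALSE)
  n <- as.integer(n_factors)
  codes <- paste0("F", seq_len(n))
  system <- factor_system(codes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  off <- n * n - n
  tables <- lapply(seq_len(n_experts), function(e) {
    m <- matrix(0L, n, n, dimnames = list(codes, codes))
    m[row(m) != col(m)] <- sample(0:4, off, replace = TRUE,
                                  prob = score_weights / sum(score_weights))
    attr(m, "expert_id") <- paste0("expert_", e)
    m
  })
  list(system = system, tables = tables)
}
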