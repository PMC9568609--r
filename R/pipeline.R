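#' Run the full DEMATEL-TAISM pipeline
#'
#' Executes every stage in order on an aggregated direct influence matrix
#' (or a list of expert score tables): normalization, total influence,
#' centrality statistics, interception, reachability with loop
#' condensation, skeleton reduction and re-expansion, influence-valued
#' skeletons, UP and DOWN level extraction, active elements, layer
#' classification and both causal series.
#'
#' @param O direct influence matrix (square, nonnegative, factor-code
#'   dimnames). Alternatively give `tables`.
#' @param tables list of expert score tables, aggregated with
#'   [aggregate_expert_scores()] when `O` is missing.
#' @param system optional [factor_system] carrying labels; defaults to the
#'   codes of `O`.
#' @param threshold optional positive number overriding the computed
#'   intercept lambda.
#' @param digits working precision of the normalized matrix (see
#'   [normalize_direct_matrix()]).
#' @param precision report rounding: decimals for N/T/centrality.
#' @param precision_ts report rounding: decimals for TS/WS.
#' @param verbose log each stage (dimensions, lambda, loops, level counts)
#'   via `message()`.
#' @return Object of class `taism_report`: list with `system`, `O`,
#'   `normalized`, `T`, `threshold`, `A`, `reachability`, `skeleton`,
#'   `valued`, `centrality`, `up`, `down`, `layers`, `series_up`,
#'   `series_down`, `scatter` and `provenance`.
#' @examples
#' rep <- run_pipeline(nssi_fixture()$O)
#' rep$layers$root
#' @export
run_pipeline <- function(O = NULL, tables = NULL, system = NULL,
                         threshold = NULL, digits = 6,
                         precision = 3, precision_ts = 4,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(O)) {
    if (is.null(tables))
      stop("give either a direct influence matrix O or expert score tables",
           call. = FALSE)
    O <- stage("aggregate", aggregate_expert_scores(tables))
  }
  check_system_matrix(O, what = "direct influence matrix")
  if (is.null(system)) system <- system_of(O)
  if (!identical(system$codes, rownames(O)))
    stop("factor system does not match the matrix codes", call. = FALSE)
  if (!is.null(threshold) &&
      (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0))
    stop("threshold override must be a single positive number", call. = FALSE)
  say("direct influence matrix: %d x %d", nrow(O), ncol(O))

  nrm <- stage("normalize", normalize_direct_matrix(O, digits = digits))
  Tm <- stage("total influence", compute_total_influence(nrm))
  th <- stage("threshold", compute_threshold(Tm))
  lambda_used <- if (is.null(threshold)) th$lambda else threshold
  say("lambda = %.10f%s", lambda_used,
      if (is.null(threshold)) "" else " (override)")
  A <- stage("binarize", binarize(Tm, lambda_used))
  rs <- stage("reachability", compute_reachability(A))
  loops <- Filter(function(s) length(s) > 1, rs$sccs)
  say("%d components, %d loops", length(rs$sccs), length(loops))
  sk <- stage("skeleton", compute_skeleton(rs))
  vs <- stage("valued skeleton", build_valued_skeleton(Tm, sk, rs))
  ct <- stage("centrality", compute_centrality(Tm))
  up <- stage("levels UP", extract_levels(rs, "UP"))
  down <- stage("levels DOWN", extract_levels(rs, "DOWN"))
  say("UP levels: %d; DOWN levels: %d", length(up$levels),
      length(down$levels))
  layers <- stage("layers", classify_layers(up, down))

  structure(list(
    system = system, O = O, normalized = nrm, T = Tm, threshold = th,
    threshold_override = threshold, A = A, reachability = rs,
    skeleton = sk, valued = vs, centrality = ct, up = up, down = down,
    layers = layers,
    series_up = full_causal_series(up, rs),
    series_down = full_causal_series(down, rs),
    scatter = data.frame(code = ct$code, M = ct$M, Rc = ct$Rc,
                         stringsAsFactors = FALSE),
    provenance = list(
      package = "taism",
      version = as.character(utils::packageVersion("taism")),
      config = list(digits = digits, precision = precision,
                    precision_ts = precision_ts,
                    threshold_override = threshold))),
    class = "taism_report")
}

#' @export
print.taism_report <- function(x, ...) {
  cat("DEMATEL-TAISM report,", length(x$system$codes), "factors\n")
  print(x$threshold)
  print(x$reachability)
  cat("UP:  ", format(x$series_up), "\n")
  cat("DOWN:", format(x$series_down), "\n")
  print(x$layers)
  invisible(x)
}

# internal: matrix -> named list of named rows, rounded
matrix_rows <- function(m, digits = NULL) {
  if (!is.null(digits)) m <- round(m, digits)
  rows <- lapply(seq_len(nrow(m)), function(i)
    as.list(stats::setNames(m[i, ], colnames(m))))
  stats::setNames(rows, rownames(m))
}

#' Serialize a pipeline report to JSON
#'
#' Writes every artifact of the run: the input matrix, normalized and
#' total influence matrices (at report precision), threshold, adjacency,
#' reachability, loops, skeletons, TS/WS, the centrality table, both level
#' partitions, layer classification, causal chains, scatter coordinates
#' and provenance. Deterministic: identical inputs give byte-identical
#' files.
#'
#' @param report a `taism_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "taism_report"))
  p <- report$provenance$config$precision
  pts <- report$provenance$config$precision_ts
  obj <- list(
    provenance = report$provenance,
    factors = if (is.null(report$system$labels)) report$system$codes
              else report$system$labels,
    O = matrix_rows(report$O),
    N = matrix_rows(report$normalized$N, p),
    denominator = report$normalized$denominator,
    T = matrix_rows(report$T, p),
    threshold = list(mean = report$threshold$mean, sd = report$threshold$sd,
                     lambda = report$threshold$lambda,
                     override = report$threshold_override),
    A = matrix_rows(report$A),
    R = matrix_rows(report$reachability$R),
    loops = unname(Filter(function(s) length(s) > 1,
                          report$reachability$sccs)),
    S_condensed = matrix_rows(report$skeleton$S_condensed),
    S_general = matrix_rows(report$skeleton$S_general),
    TS = matrix_rows(report$valued$TS, pts),
    WS = matrix_rows(report$valued$WS, pts),
    centrality = {
      ct <- report$centrality
      ct[c("D", "C", "M", "Rc")] <- round(ct[c("D", "C", "M", "Rc")], p)
      ct
    },
    levels_up = report$up$levels,
    levels_down = report$down$levels,
    layers = unclass(report$layers),
    series_up = format(report$series_up),
    series_down = format(report$series_down),
    scatter = report$scatter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
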