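#' Export the layered influence topology as DOT or GraphML
#'
#' Writes the general skeleton as a directed graph whose nodes are factor
#' codes and whose edges carry the selected influence values (`TS`: total
#' influence on every skeleton edge; `WS`: loop edges marked 1). In DOT
#' output, nodes of one hierarchy level share a rank (result level 0 on
#' top) and mutually reachable factors are drawn with bidirectional
#' styling; GraphML output carries `level_up`, `level_down`, `name` node
#' attributes and `weight`, `loop` edge attributes.
#'
#' @param report a `taism_report` from [run_pipeline()].
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @param value_source `"TS"` or `"WS"`.
#' @param mode which partition ranks the DOT layout: `"UP"` or `"DOWN"`.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".dot")
#' export_topology(run_pipeline(nssi_fixture()$O), f)
#' @export
export_topology <- function(report, path, format = c("dot", "graphml"),
                            value_source = c("TS", "WS"),
                            mode = c("UP", "DOWN")) {
  stopifnot(inherits(report, "taism_report"))
  format <- match.arg(format)
  value_source <- match.arg(value_source)
  mode <- match.arg(mode)
  V <- report$valued[[value_source]]
  pts <- report$provenance$config$precision_ts
  codes <- report$system$codes
  memb <- report$reachability$membership
  same_scc <- function(i, j) memb[[i]] == memb[[j]]
  edges <- which(V != 0, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  part <- if (mode == "UP") report$up else report$down
  lvl <- level_index(part)

  if (format == "dot") {
    lines <- c("digraph taism {", "  rankdir=TB;",
               "  node [shape=box];")
    for (l in sort(unique(lvl))) {
      members <- codes[codes %in% names(lvl)[lvl == l]]
      lines <- c(lines, sprintf("  { rank=same; %s }",
                                paste0("\"", members, "\"",
                                       collapse = "; ")))
    }
    for (k in seq_len(nrow(edges))) {
      i <- codes[edges[k, 1]]; j <- codes[edges[k, 2]]
      attrs <- sprintf("label=\"%s\"",
                       formatC(V[i, j], format = "fg", digits = pts))
      if (same_scc(i, j)) attrs <- paste0(attrs, ", dir=both, style=bold")
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [%s];", i, j, attrs))
    }
    lines <- c(lines, "}")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    g <- igraph::graph_from_adjacency_matrix((V != 0) + 0,
                                             mode = "directed")
    up_lvl <- level_index(report$up)
    down_lvl <- level_index(report$down)
    igraph::V(g)$level_up <- unname(up_lvl[codes])
    igraph::V(g)$level_down <- unname(down_lvl[codes])
    if (!is.null(report$system$labels))
      igraph::V(g)$label <- report$system$labels$name
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- V[el]
    igraph::E(g)$loop <- vapply(seq_len(nrow(el)), function(k)
      same_scc(el[k, 1], el[k, 2]), logical(1))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
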