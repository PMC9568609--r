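# Published tables of the 13-factor NSSI worked example, frozen as CSV
# fixtures (3-decimal matrices N and T, binary adjacency, the centrality
# table, and the 4-decimal TS/WS skeleton matrices).

read_printed <- function(file) {
  df <- read.csv(test_path("fixtures", file), check.names = FALSE,
                 row.names = 1)
  as.matrix(df)
}

printed <- list(
  N = read_printed("printed_N.csv"),
  T = read_printed("printed_T.csv"),
  A = read_printed("printed_A.csv"),
  centrality = read_printed("printed_centrality.csv"),
  TS = read_printed("printed_TS.csv"),
  WS = read_printed("printed_WS.csv"))

# reachability of the worked example, reconstructed from the published
# reachable sets (row counts 3,4,5,5,2,3,6,6,6,6,9,4,1)
printed_R <- local({
  codes <- c("A2","A3","B2","B3","B4","B5","B6","B7","B8","B9","B10","B11","Y")
  reach <- list(
    A2 = c("A2", "B4", "Y"),
    A3 = c("A3", "A2", "B4", "Y"),
    B2 = c("B2", "B3", "B5", "B4", "Y"),
    B3 = c("B3", "B2", "B5", "B4", "Y"),
    B4 = c("B4", "Y"),
    B5 = c("B5", "B4", "Y"),
    B6 = c("B6", "B2", "B3", "B5", "B4", "Y"),
    B7 = c("B7", "B8", "B9", "B5", "B4", "Y"),
    B8 = c("B8", "B7", "B9", "B5", "B4", "Y"),
    B9 = c("B9", "B7", "B8", "B5", "B4", "Y"),
    B10 = c("B10", "B2", "B3", "B5", "B7", "B8", "B9", "B4", "Y"),
    B11 = c("B11", "B5", "B4", "Y"),
    Y = "Y")
  R <- matrix(0L, 13, 13, dimnames = list(codes, codes))
  for (i in codes) R[i, reach[[i]]] <- 1L
  R
})
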