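#' The 13-factor adolescent NSSI influence system
#'
#' The worked example shipped with the package: thirteen determinants of
#' adolescent non-suicidal self-injury (NSSI) spanning physiological,
#' cognitive, emotional, social-support and social-environment dimensions,
#' plus the NSSI outcome itself, together with the direct influence matrix
#' aggregated from a 27-member expert panel scoring every ordered factor
#' pair on a 0-4 scale.
#'
#' `nssi_factor_system()` returns the factor set and labels;
#' `nssi_fixture()` returns the system together with the aggregated direct
#' influence matrix `O` (nonnegative integers, zero diagonal).
#'
#' @return `nssi_factor_system()`: a [factor_system]. `nssi_fixture()`: a
#'   list with elements `system` (the factor system) and `O` (the 13 x 13
#'   integer direct influence matrix).
#' @examples
#' fx <- nssi_fixture()
#' fx$O["B2", "B3"]   # strongest single judgment sum: 102
#' rowSums(fx$O)
#' @export
nssi_factor_system <- function() {
  labels <- data.frame(
    code = c("A2", "A3", "B2", "B3", "B4", "B5", "B6", "B7", "B8", "B9",
             "B10", "B11", "Y"),
    name = c("Sleep", "Exercise", "Self-cognition", "Self-efficacy",
             "Emotional state", "Emotion regulation ability", "Peer support",
             "Family support", "School support", "Social support",
             "Social environment", "Leisure entertainment", "NSSI"),
    dimension = c("Physiological", "Physiological", "Cognitive", "Cognitive",
                  "Emotional", "Emotional", "Social support", "Social support",
                  "Social support", "Social support", "Social environment",
                  "Social environment", "NSSI"),
    stringsAsFactors = FALSE)
  factor_system(labels$code, labels)
}

#' @rdname nssi_factor_system
#' @export
nssi_fixture <- function() {
  system <- nssi_factor_system()
  O <- matrix(c(
     0, 67, 15, 18, 82, 35, 19, 12, 11, 11, 11, 16, 85,
    81,  0, 17, 18, 85, 32, 18, 12, 11, 11, 11, 15, 46,
    15, 13,  0,102, 23, 79, 59, 18, 17, 18, 18, 14, 82,
    15, 13, 84,  0, 18, 83, 62, 15, 16, 16, 12, 16, 78,
    43, 13, 22, 23,  0, 22, 20, 14, 14, 14, 14, 34, 94,
    43, 12, 20, 19, 85,  0, 24, 16, 12, 12, 12, 36, 97,
    21, 19, 42, 72, 30, 61,  0, 12, 13, 13, 13, 27, 74,
    12, 12, 19, 16, 18, 94, 21,  0, 71, 73, 17, 14, 75,
    11, 14, 18, 19, 21, 81, 22, 77,  0, 70, 18, 16, 62,
    11, 15, 20, 19, 21, 64, 20, 76, 72,  0, 13, 17, 65,
    11, 15, 72, 19, 21, 62, 21, 63, 76, 73,  0, 23, 70,
    20, 19, 18, 50, 22, 78, 21, 15, 19, 15, 15,  0, 85,
    25, 11, 21, 22, 18, 15, 10, 15, 12, 12, 11, 10,  0),
    nrow = 13, byrow = TRUE,
    dimnames = list(system$codes, system$codes))
  storage.mode(O) <- "integer"
  list(system = system, O = O)
}

#' Small named influence systems with known structure
#'
#' A collection of degenerate direct-influence systems used for
#' property-style testing: a pure chain, a system containing a directed
#' 3-cycle, a system with an isolated factor (all-zero row and column), and
#' a fully connected system.
#'
#' Each element is a list with `system` and `O`, shaped like
#' [nssi_fixture()].
#'
#' @return Named list of `(system, O)` pairs: `chain`, `cycle3`,
#'   `isolated`, `complete`.
#' @examples
#' degenerate_cases()$chain$O
#' @export
degenerate_cases <- function() {
  mk <- function(codes, edges, weight = 4L) {
    O <- matrix(0L, length(codes), length(codes),
                dimnames = list(codes, codes))
    for (e in edges) O[e[1], e[2]] <- weight
    list(system = factor_system(codes), O = O)
  }
  chain <- mk(c("C1", "C2", "C3"), list(c("C1", "C2"), c("C2", "C3")))
  cycle3 <- mk(c("L1", "L2", "L3", "Z"),
               list(c("L1", "L2"), c("L2", "L3"), c("L3", "L1"),
                    c("L1", "Z")))
  isolated <- mk(c("I1", "I2", "I3"), list(c("I1", "I2")))  # I3 untouched
  full_codes <- c("F1", "F2", "F3")
  complete <- mk(full_codes,
                 {
                   prs <- expand.grid(a = full_codes, b = full_codes,
                                      stringsAsFactors = FALSE)
                   prs <- prs[prs$a != prs$b, ]
                   lapply(seq_len(nrow(prs)),
                          function(i) c(prs$a[i], prs$b[i]))
                 },
                 weight = 2L)
  list(chain = chain, cycle3 = cycle3, isolated = isolated,
       complete = complete)
}
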