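---
title: "DEMATEL-TAISM: model, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEMATEL-TAISM: model, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taism)
```

## The problem

Complex behavioural systems — here the determinants of adolescent
non-suicidal self-injury (NSSI) — involve factors that influence one
another directly and through chains of mediation. Expert panels can score
direct pairwise influence, but the interesting questions (which factors
are fundamental drivers, which are outcomes, where are the feedback
loops?) concern the *total* influence structure. The package combines two
classical system-engineering tools:

* **DEMATEL** (Decision-Making Trial and Evaluation Laboratory) turns the
  aggregated direct-influence matrix into a total influence matrix and
  per-factor cause/effect statistics.
* **TAISM** (Total Adversarial Interpretive Structural Modeling)
  thresholds the total influence into a digraph, condenses feedback loops,
  reduces it to a minimal skeleton, and extracts a multilevel hierarchy —
  twice, under antagonistic rules (result-priority UP and cause-priority
  DOWN) — annotating the skeleton edges with the total-influence values.

## The model, step by step

Let $O$ be the $n \times n$ aggregated direct influence matrix: experts
score every ordered factor pair on a 0–4 scale (0 no impact … 4 very
strong) and scores are summed across the panel; the diagonal is zero.

**Normalization.** With $a_i$ and $b_i$ the $i$-th row and column sums of
$O$,
$$N = O \Big/ \max_i \sqrt{a_i^2 + b_i^2}.$$
The denominator bounds both the maximum row sum and the maximum column
sum of $N$ strictly below one whenever some factor has off-norm mass, so
the spectral radius of $N$ is below one and the influence series
converges. `compute_total_influence()` still verifies the spectral radius
explicitly and refuses divergent input rather than returning a
meaningless matrix.

**Total influence.** Direct plus all indirect influence:
$$T = N + N^2 + N^3 + \cdots = N (I - N)^{-1},$$
evaluated in closed form. $t_{ij}$ is the comprehensive influence of
factor $i$ on factor $j$.

**Centrality statistics.** $D_i = \sum_j t_{ij}$ (influence degree),
$C_i = \sum_j t_{ji}$ (influenced degree), centrality $M_i = D_i + C_i$
and cause degree $Rc_i = D_i - C_i$. Factors with positive $Rc$ are net
drivers, negative net receivers; $(M_i, Rc_i)$ are the coordinates of the
cause–effect scatter plot. By construction $\sum_i D_i = \sum_i C_i$ is
the grand total of $T$ and $\sum_i Rc_i = 0$.

**Interception.** An edge $i \to j$ is kept when $t_{ij}$ strictly
exceeds
$$\lambda = \bar x + \sigma, \qquad
  \sigma = \sqrt{\tfrac{1}{n^2} \sum (t_{ij} - \bar x)^2},$$
the mean plus *population* standard deviation over all $n^2$ entries of
$T$, diagonal included. The strict comparison is deliberate: ties at
$\lambda$ are measure-zero for real-valued $T$ and never occur in the
shipped example, and a strict rule keeps "no influence above threshold"
unambiguous.

**Reachability and loops.** $B = A + I$ is closed under Boolean powers
until stable ($B^{k-1} \neq B^k = B^{k+1} = R$; the implementation squares
the matrix, so at most $\lceil \log_2 n \rceil + 1$ products). Mutually
reachable factors ($R_{ij} = R_{ji} = 1$) form loops (strongly connected
components); condensing each loop to one node yields the component-level
partial order $R'$.

**Skeleton.** The minimal edge set with the same closure:
$$S' = R' - (R' - I)^2 - I$$
in Boolean arithmetic (an edge implied by a two-step path over the closed
relation is a repeated path and is dropped — for a transitively closed
DAG this is exactly the transitive reduction). Loops are then re-expanded
onto the original factors: members of a loop are joined in a single
directed cycle in factor order, and each condensed edge is realised by
the direct adjacency edge between component members with the lowest
(source, target) factor indices. Both conventions are identification
choices — any cycle through the members and any witnessing adjacency edge
would close to the same reachability — fixed this way to make output
deterministic and to match the published worked example. `TS` places
$t_{ij}$ on every skeleton edge; `WS` additionally marks every ordered
pair inside a loop with 1 (a clique, not just the drawn cycle, so loop
membership survives even where the cycle convention differs).

**Hierarchy extraction.** For factor $e_i$, the reachable set
$R(e_i)$, antecedent set $Q(e_i)$ and common set
$T(e_i) = R(e_i) \cap Q(e_i)$ are recomputed on the residual system each
round. UP (result priority) extracts every factor with
$R(e_i) = T(e_i)$, placing batches top-down from level 0; DOWN (cause
priority) extracts every factor with $Q(e_i) = T(e_i)$, placing batches
bottom-up with the final batch at level 0. All qualifying factors of a
round leave together, so loop members always share a level and the
procedure terminates in at most $n$ rounds. Factors whose UP and DOWN
levels differ are *active* — their hierarchical position is extensible,
which is where intervention sequencing has freedom.

**Layers.** Root = union of the bottom UP and DOWN levels; result = union
of levels 0–1 of both; intermediate = the rest. For hierarchies of depth
$\ge 3$ this partitions the factor set. In shallower or degenerate
systems (e.g. a two-factor chain, or an isolated factor that is
simultaneously a source and a sink) the root and result rules can claim
the same factor; the sets are then reported per rule, overlapping, rather
than silently re-assigned.

## Numerical and design choices

* **Working precision of `N` (`digits = 6`).** `normalize_direct_matrix()`
  carries the normalized matrix at six decimal places by default. This is
  the working precision at which the shipped worked example's published
  threshold is reproduced exactly ($\lambda = 0.08978444078272$, to all
  fourteen printed digits), indicating it was the precision of the
  original workflow; at $|N| \le 0.11$ the perturbation is $\le 5 \times
  10^{-7}$ per entry and is invisible at every reported precision.
  `digits = NULL` keeps the exact quotients.
* **Report precision.** Matrices `N`, `T` and the centrality table are
  reported at 3 decimals, `TS`/`WS` at 4, matching the conventions of the
  published tables; all statistics are computed from the working-precision
  matrices and rounded only at report time.
* **Reproduction tolerance.** Tests compare 3-decimal tables at ±0.0015
  absolute: half-ULP rounding (±0.0005) plus the source tables' own
  last-digit drift (the published centrality table prints 0.083 where its
  own printed columns difference to 0.082).
* **Strictness, ties, degenerate inputs.** Strict `>` at $\lambda$; an
  all-zero direct matrix is an error at normalization (the denominator
  would vanish); spectral radius $\ge 1$ is an error at the total-influence
  stage; the Boolean closure asserts stabilization instead of looping
  unbounded; a non-transitive matrix fed to level extraction is rejected.
* **Determinism.** `generate_panel()` draws every score from one seeded
  stream; `run_pipeline()` has no hidden state, and reports serialize
  byte-identically for identical inputs (provenance carries the package
  version and configuration, deliberately no wall-clock timestamp).

## The synthetic generator

`generate_panel()` emulates the survey design behind the worked example —
a 27-member expert panel scoring 13 factors on the 0–4 scale — with
i.i.d. categorical scores per cell and expert. Defaults are
`n_factors = 13`, `n_experts = 27`, uniform score weights. It emulates
the *format* of such a survey, not its psychology: real panels exhibit
inter-expert correlation, systematic leniency differences and structured
sparsity (most factor pairs judged irrelevant by most experts), none of
which the generator models. Property tests built on it therefore certify
the algebra and the structural invariants of the pipeline on arbitrary
dense systems, not the behaviour of the method under realistic expert
disagreement; the worked example carries the realism load.

Problem sizes used in the test suite — random digraphs up to 12 nodes,
hundreds of cases per invariant, panels up to dozens of experts — keep
each property readable and each run instantaneous while covering every
branch (loops, isolated factors, chains, complete graphs).

## Known limitations

* The 0–4 scale and the sum aggregation are fixed; expert weighting,
  consensus (Delphi-round) statistics, and fuzzy or grey DEMATEL variants
  are out of scope.
* The interception rule is mean-plus-sigma only; quantile thresholds and
  MICMAC driving/dependence analysis are not provided.
* Loop re-expansion conventions (factor-order cycle, lowest-index
  attachment) are identification choices; alternative conventions yield
  the same reachability and levels but different drawn edges.
* The scatter plot is emitted as data (`report$scatter`); rendering is
  left to the user.
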