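## Coherent modified-k-mer selection.  Training k-mers are chosen only in
## groups corresponding to whole methylated 11-mers, mirroring what a real
## sequencing experiment would produce; the choice is an integer program
## maximizing the frequency-weighted number of completed windows under a
## budget on unique k-mers.

#' k-mer budget for a completeness level
#'
#' The number of unique modified k-mers retained at completeness `p` is
#' `B = floor(p * |S| / 100)`, where `S` is the modified-k-mer universe.
#'
#' @param p Percentage in (0, 100].
#' @param universe_size Number of unique modified k-mers in the universe.
#' @return Non-negative integer budget.
#' @examples
#' compute_budget(5, 2669)   # 133
#' @export
compute_budget <- function(p, universe_size) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 100)
    stop("p must be a single percentage in (0, 100]")
  if (universe_size < 0) stop("universe_size must be >= 0")
  as.integer(floor(p * universe_size / 100))
}

#' Build a coherent selection problem from window counts
#'
#' Duplicate windows are aggregated by summing their counts; weights are the
#' normalized counts (frequencies of the methylated 11-mers in the training
#' data), or uniform if requested.  The k-mer universe is the union of the
#' windows' constituent k-mers, and the budget is `compute_budget(p, |S|)`.
#'
#' @param windows Character vector of methyl windows.
#' @param counts Non-negative counts, one per window (default all 1).
#' @param p Completeness percentage in (0, 100].
#' @param uniform_weights If `TRUE`, ignore `counts` for the weights (the
#'   aggregation still deduplicates windows).
#' @param k Pore context length (default 6).
#' @return An object of class `selection_problem` with fields `windows`,
#'   `weights`, `Vsets`, `universe`, `budget`, `p`, `k`.
#' @export
build_selection_problem <- function(windows, counts = NULL, p = 100,
                                    uniform_weights = FALSE, k = 6L) {
  if (is.null(counts)) counts <- rep(1, length(windows))
  if (length(counts) != length(windows))
    stop("counts must match windows")
  if (any(counts < 0) || all(counts == 0))
    stop("counts must be non-negative with at least one positive")
  bad <- !is_valid_window(windows, k = k)
  if (any(bad))
    stop("invalid window(s): ", paste(unique(windows[bad]), collapse = ", "))
  agg <- rowsum(counts, windows)
  win <- rownames(agg)
  cnt <- agg[, 1L]
  weights <- if (uniform_weights) rep(1 / length(win), length(win))
             else unname(cnt / sum(cnt))
  Vsets <- lapply(win, decompose_window, k = k)
  universe <- sort(unique(unlist(Vsets)))
  budget <- compute_budget(p, length(universe))
  if (budget < k)
    warning("budget ", budget, " is below k = ", k,
            ": no window can be completed")
  structure(list(windows = win, weights = weights, counts = cnt,
                 Vsets = Vsets, universe = universe, budget = budget,
                 p = p, k = as.integer(k)),
            class = "selection_problem")
}

#' @export
print.selection_problem <- function(x, ...) {
  cat("coherent selection problem: ", length(x$windows), " windows, |S| = ",
      length(x$universe), ", p = ", x$p, ", B = ", x$budget, "\n", sep = "")
  invisible(x)
}

selection_result <- function(prob, x, objective, status, nodes = NA_real_) {
  kmers <- prob$universe[x]
  y <- vapply(prob$Vsets, function(v) all(v %in% kmers), logical(1))
  structure(list(selected_kmers = kmers,
                 selected_windows = prob$windows[y],
                 y = y,
                 objective = sum(prob$weights[y]),
                 status = status,
                 budget = prob$budget,
                 universe_size = length(prob$universe),
                 nodes = nodes),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection (", x$status, "): ", length(x$selected_kmers), "/",
      x$budget, " k-mers, ", sum(x$y), " windows, objective ",
      format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Solve the coherent selection integer program exactly
#'
#' Maximizes the weighted number of completed windows, `sum_i w_i y_i`,
#' subject to the k-mer budget `sum_s x_s <= B` and the coherence constraint
#' `0 <= -k y_i + sum_{s in V_i} x_s <= k - 1` (equivalently, `y_i` is the
#' k-way AND of its constituent k-mer indicators).  The solver is an exact
#' branch-and-bound over window subsets with a fractional-knapsack dual
#' bound; if the node cap is reached the best incumbent is returned with
#' status `"feasible"` instead of `"optimal"`.
#'
#' @param prob A `selection_problem`.
#' @param node_cap Maximum number of search nodes (default 2e5).
#' @return A `selection_result` with fields `selected_kmers`,
#'   `selected_windows`, `y`, `objective`, `status`.
#' @export
solve_selection_ilp <- function(prob, node_cap = 2e5) {
  stopifnot(inherits(prob, "selection_problem"))
  ids <- lapply(prob$Vsets,
                function(v) match(v, prob$universe) - 1L)
  res <- .bb_select(ids, prob$weights, length(prob$universe),
                    prob$budget, node_cap)
  selection_result(prob, res$x, res$objective,
                   if (res$optimal) "optimal" else "feasible",
                   nodes = res$nodes)
}

#' Brute-force selection oracle
#'
#' Exhaustively enumerates all subsets of windows, taking each subset's
#' k-mer union as the selection when it fits the budget, and scoring the
#' windows covered by that union.  Exponential in the number of windows;
#' refuses instances with more than 16 windows or 30 unique k-mers.  Used
#' as an independent optimality oracle for [solve_selection_ilp()].
#'
#' @param prob A `selection_problem`.
#' @return A `selection_result` with status `"optimal"`.
#' @export
brute_force_selection <- function(prob) {
  stopifnot(inherits(prob, "selection_problem"))
  m <- length(prob$windows)
  S <- length(prob$universe)
  if (m > 16L || S > 30L)
    stop("instance too large for brute force (", m, " windows, |S| = ",
         S, ")")
  vm <- vapply(prob$Vsets, function(v)
    sum(bitwShiftL(1L, match(v, prob$universe) - 1L)), integer(1))
  n_masks <- bitwShiftL(1L, m)
  un <- integer(n_masks)                      # kmer union per window subset
  for (j in seq_len(m)) {
    lo <- seq_len(bitwShiftL(1L, j - 1L))
    un[lo + bitwShiftL(1L, j - 1L)] <- bitwOr(un[lo], vm[j])
  }
  cost <- integer(n_masks)
  for (b in 0:(S - 1L))
    cost <- cost + bitwAnd(bitwShiftR(un, b), 1L)
  weight <- numeric(n_masks)
  for (j in seq_len(m))
    weight <- weight + prob$weights[j] * (bitwAnd(un, vm[j]) == vm[j])
  feasible <- cost <= prob$budget
  bestmask <- which(feasible)[which.max(weight[feasible])]
  xsel <- prob$universe %in%
    prob$universe[as.logical(bitwAnd(bitwShiftR(un[bestmask], 0:(S - 1L)),
                                     1L))]
  selection_result(prob, xsel, weight[bestmask], "optimal")
}

#' Random-then-prune selection baseline
#'
#' Samples `B` k-mers uniformly at random from the universe and keeps only
#' the windows whose constituent k-mers are all covered.  Because a single
#' methylated site needs all k of its overlapping k-mers, random selection
#' completes dramatically fewer windows than the coherent scheme at the same
#' budget.
#'
#' @param prob A `selection_problem`.
#' @param seed Integer seed for reproducibility.
#' @return A `selection_result` with status `"feasible"`.
#' @export
random_prune_baseline <- function(prob, seed = 1L) {
  stopifnot(inherits(prob, "selection_problem"))
  S <- length(prob$universe)
  xsel <- rep(FALSE, S)
  xsel[with_seed(seed, sample.int(S, min(prob$budget, S)))] <- TRUE
  selection_result(prob, xsel, NA_real_, "feasible")
}

## Evaluate a deterministic expression under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
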