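#' Scanpath comparison parameters
#'
#' Parameters controlling scanpath simplification and similarity
#' normalisation. Defaults follow the standard settings of vector-based
#' scanpath comparison: saccade pairs are merged when they continue
#' within 45 degrees of each other, or when both are shorter than 10% of
#' the screen diagonal and the fixation between them is shorter than
#' 150 ms. All values are recorded in pipeline output metadata so results
#' are never produced with silently baked-in settings.
#'
#' @param direction_threshold Angular merge threshold (radians).
#' @param amplitude_fraction Amplitude merge threshold, as a fraction of
#'   the screen diagonal.
#' @param duration_threshold Intervening-fixation duration threshold (ms)
#'   for amplitude-based merging.
#' @param screen Screen size `c(width, height)` in px; sets the diagonal
#'   used to normalise position, length and shape differences.
#' @param simplify Logical; set `FALSE` to compare raw saccade sequences.
#' @return A list of class `mm_params`.
#' @export
mm_params <- function(direction_threshold = 45 * pi / 180,
                      amplitude_fraction = 0.10,
                      duration_threshold = 150,
                      screen = c(1680, 1050),
                      simplify = TRUE) {
  stopifnot(direction_threshold >= 0, amplitude_fraction >= 0,
            duration_threshold >= 0, length(screen) == 2, all(screen > 0))
  structure(list(direction_threshold = direction_threshold,
                 amplitude_fraction = amplitude_fraction,
                 duration_threshold = duration_threshold,
                 screen = as.numeric(screen),
                 simplify = isTRUE(simplify)),
            class = "mm_params")
}

amplitude_threshold_px <- function(params) {
  params$amplitude_fraction * screen_diagonal(params$screen)
}

#' Simplify a scanpath into merged saccadic vectors
#'
#' Iteratively merges successive saccade pairs that (a) continue in a
#' similar direction (angular difference below the direction threshold),
#' or (b) are both small (amplitude below the amplitude threshold) with
#' an intervening fixation shorter than the duration threshold. A merged
#' vector is the vector sum of its parts, i.e. the intervening fixation
#' is removed (its duration is discarded). Merging repeats left-to-right
#' until a fixpoint, so the result is deterministic.
#'
#' @param sp A [scanpath()] with at least 2 fixations.
#' @param params An [mm_params()] object.
#' @return A `scanpath` whose fixations are the simplified sequence.
#' @export
simplify_scanpath <- function(sp, params = mm_params(screen = sp$screen)) {
  stopifnot(is_scanpath(sp))
  if (n_fixations(sp) < 2L)
    stop("degenerate scanpath: fewer than 2 fixations", call. = FALSE)
  m <- cpp_simplify(fixation_matrix(sp), params$direction_threshold,
                    amplitude_threshold_px(params), params$duration_threshold)
  out <- sp
  out$fixations <- data.frame(x = m[, 1], y = m[, 2],
                              onset = cumsum(c(0, m[-nrow(m), 3])),
                              duration = m[, 3])
  out
}

#' Saccade-shape cost matrix between two scanpaths
#'
#' Entry (i, j) is the Euclidean norm of the difference between the i-th
#' saccadic vector of `a` and the j-th of `b` — a shape cost combining
#' differences in length and direction, used to align the two sequences.
#'
#' @param a,b [scanpath()] objects (typically already simplified).
#' @return A numeric matrix of non-negative costs, with one row per
#'   saccade of `a` and one column per saccade of `b`.
#' @export
mm_cost_matrix <- function(a, b) {
  stopifnot(is_scanpath(a), is_scanpath(b))
  cpp_cost_matrix(fixation_matrix(a), fixation_matrix(b))
}

#' Temporal alignment by shortest path through the cost matrix
#'
#' Finds the minimal-total-cost monotone path from the top-left to the
#' bottom-right cell of a cost matrix, with steps right, down and
#' diagonal. The path cost is the sum of all entered cells, including the
#' start cell. Because the graph is a directed acyclic lattice, the
#' shortest path is computed by dynamic programming, which visits nodes
#' in the same order as Dijkstra's algorithm does on this graph and
#' returns the identical optimum. Ties are broken deterministically by
#' preferring diagonal, then right, then down steps.
#'
#' The alignment is relative: it does not require the two scanpaths to
#' have the same number of saccades.
#'
#' @param cost A numeric cost matrix with non-negative entries.
#' @return An integer matrix with columns `i`, `j`: the aligned saccade
#'   index pairs (1-based), starting at (1, 1) and ending at (n, m).
#'   The minimal path cost is attached as attribute `"cost"`.
#' @export
mm_align <- function(cost) {
  cost <- as.matrix(cost)
  if (any(cost < 0)) stop("cost matrix entries must be non-negative", call. = FALSE)
  path <- cpp_align(cost)
  colnames(path) <- c("i", "j")
  attr(path, "cost") <- sum(cost[path])
  path
}

#' Five-dimension similarity over an alignment
#'
#' For each aligned saccade pair a normalised difference is computed per
#' dimension, and the similarity is one minus the mean difference:
#' * `shape`: norm of the vector difference / (2 x screen diagonal);
#' * `direction`: absolute angular difference wrapped to \[0, pi\] / pi;
#' * `length`: absolute amplitude difference / screen diagonal;
#' * `position`: distance between the terminating fixation locations /
#'   screen diagonal;
#' * `duration`: absolute difference of the terminating fixation
#'   durations / the larger of the two (0 when both are 0).
#'
#' @param a,b Simplified [scanpath()] objects.
#' @param alignment An alignment from [mm_align()], valid for `a` and `b`.
#' @param screen Screen size `c(width, height)` px.
#' @return A named numeric vector of five similarities in \[0, 1\]:
#'   `position`, `duration`, `shape`, `direction`, `length`.
#' @export
mm_similarity <- function(a, b, alignment, screen = a$screen) {
  stopifnot(is_scanpath(a), is_scanpath(b))
  al <- as.matrix(alignment)
  if (max(al[, 1]) > n_fixations(a) - 1L || max(al[, 2]) > n_fixations(b) - 1L)
    stop("alignment indices exceed the available saccades", call. = FALSE)
  cpp_similarity(fixation_matrix(a), fixation_matrix(b),
                 matrix(as.integer(al), ncol = 2), screen_diagonal(screen))
}

#' Compare two scanpaths over five spatio-temporal dimensions
#'
#' The full vector-based comparison: both scanpaths are simplified, their
#' saccadic vectors aligned by the shortest path through the shape-cost
#' matrix, and similarity scored over fixation position, fixation
#' duration, saccade shape, saccade direction and saccade length. The
#' procedure is symmetric in its arguments up to floating-point ties in
#' the alignment.
#'
#' Scanpaths with exactly one saccade are compared without
#' simplification (there is nothing to merge).
#'
#' @param enc,rec [scanpath()] objects with at least 2 fixations each.
#' @param params An [mm_params()] object.
#' @return Named numeric vector of the five similarities in \[0, 1\],
#'   with attribute `n_vectors` giving the simplified vector counts.
#' @examples
#' sp <- scanpath(x = c(100, 400, 300, 900), y = c(500, 200, 600, 650),
#'                duration = c(250, 180, 300, 200))
#' compare_scanpaths(sp, sp)  # all dimensions 1
#' @export
compare_scanpaths <- function(enc, rec, params = mm_params(screen = enc$screen)) {
  stopifnot(is_scanpath(enc), is_scanpath(rec))
  if (n_fixations(enc) < 2L || n_fixations(rec) < 2L)
    stop("degenerate scanpath: fewer than 2 fixations", call. = FALSE)
  res <- cpp_compare(fixation_matrix(enc), fixation_matrix(rec),
                     params$direction_threshold, amplitude_threshold_px(params),
                     params$duration_threshold,
                     screen_diagonal(params$screen), params$simplify)
  out <- res$scores
  attr(out, "n_vectors") <- res$n_vectors
  out
}
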