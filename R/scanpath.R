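#' Construct a scanpath
#'
#' A scanpath is the ordered sequence of fixations a participant produced
#' while encoding or recalling one image. Coordinates follow the usual
#' eye-tracker convention: origin at the top-left corner of the screen,
#' `x` increasing rightward, `y` increasing *downward*, in pixels. All
#' angular quantities in the package are computed in this frame.
#'
#' @param x,y Numeric vectors of fixation centroid coordinates (px).
#' @param duration Fixation durations (ms); must be strictly positive.
#' @param onset Fixation onsets from trial start (ms); must be strictly
#'   increasing. Defaults to the cumulative sum of preceding durations.
#' @param participant,image Identifiers for the trial.
#' @param image_type `"scene"` or `"object_arrangement"`.
#' @param phase `"encoding"` or `"recall"`.
#' @param screen Screen size as `c(width, height)` in px. Defaults to the
#'   1680 x 1050 geometry of a typical widescreen eye-tracking monitor.
#' @param warn_offscreen Warn when fixations fall outside the screen
#'   bounds. Off-screen fixations are retained; dropping them is left to
#'   the caller.
#'
#' @return An object of class `scanpath`: a list with elements
#'   `participant`, `image`, `image_type`, `phase`, `fixations` (a
#'   data frame with columns `x`, `y`, `onset`, `duration`) and `screen`.
#' @examples
#' sp <- scanpath(x = c(100, 400, 300), y = c(500, 200, 600),
#'                duration = c(250, 180, 300))
#' saccade_vectors(sp)
#' @export
scanpath <- function(x, y, duration, onset = NULL,
                     participant = "p01", image = "img01",
                     image_type = c("scene", "object_arrangement"),
                     phase = c("encoding", "recall"),
                     screen = c(1680, 1050), warn_offscreen = TRUE) {
  image_type <- match.arg(image_type)
  phase <- match.arg(phase)
  n <- length(x)
  if (n < 1L) stop("a scanpath needs at least one fixation", call. = FALSE)
  if (length(y) != n || length(duration) != n)
    stop("x, y and duration must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("fixation coordinates must be finite", call. = FALSE)
  if (any(duration <= 0))
    stop("fixation durations must be strictly positive", call. = FALSE)
  if (is.null(onset)) onset <- cumsum(c(0, duration[-n]))
  if (length(onset) != n)
    stop("onset must have one value per fixation", call. = FALSE)
  if (n > 1L && any(diff(onset) <= 0))
    stop("fixation onsets must be strictly increasing", call. = FALSE)
  if (warn_offscreen &&
      (any(x < 0 | x > screen[1]) || any(y < 0 | y > screen[2])))
    warning("scanpath contains fixations outside the screen bounds; they are retained",
            call. = FALSE)
  structure(
    list(participant = participant, image = image, image_type = image_type,
         phase = phase,
         fixations = data.frame(x = as.numeric(x), y = as.numeric(y),
                                onset = as.numeric(onset),
                                duration = as.numeric(duration)),
         screen = as.numeric(screen)),
    class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> %s / %s (%s, %s): %d fixations, %.0f ms\n",
              x$participant, x$image, x$image_type, x$phase,
              nrow(x$fixations),
              sum(x$fixations$duration)))
  invisible(x)
}

#' @rdname scanpath
#' @param sp An object to test.
#' @export
is_scanpath <- function(sp) inherits(sp, "scanpath")

n_fixations <- function(sp) nrow(sp$fixations)

screen_diagonal <- function(screen) sqrt(screen[1]^2 + screen[2]^2)

# n x 3 matrix (x, y, duration) used by the compiled comparison core
fixation_matrix <- function(sp) {
  cbind(sp$fixations$x, sp$fixations$y, sp$fixations$duration)
}

#' Saccadic vectors of a scanpath
#'
#' Saccades are represented implicitly as the displacement between
#' consecutive fixation centroids; no saccade-event detection is
#' performed. The i-th vector points from fixation i to fixation i + 1.
#' Direction is `atan2(dy, dx)` in the screen frame (y downward), in
#' radians in (-pi, pi].
#'
#' @param sp A [scanpath()] with at least two fixations.
#' @return A tibble with one row per saccade and columns `dx`, `dy`,
#'   `amplitude` (px) and `direction` (radians).
#' @export
saccade_vectors <- function(sp) {
  stopifnot(is_scanpath(sp))
  n <- n_fixations(sp)
  if (n < 2L)
    stop("degenerate scanpath: fewer than 2 fixations", call. = FALSE)
  dx <- diff(sp$fixations$x)
  dy <- diff(sp$fixations$y)
  tibble::tibble(dx = dx, dy = dy,
                 amplitude = sqrt(dx^2 + dy^2),
                 direction = atan2(dy, dx))
}

#' Mnemonic content score
#'
#' Per-trial index of subjective memory quality: the arithmetic mean of
#' the three post-recall ratings (overall recollection strength,
#' vividness, spatial accuracy), each on a 0-100 scale.
#'
#' @param strength,vividness,spatial_accuracy Numeric ratings in
#'   \[0, 100\]; vectors are averaged elementwise.
#' @return The mean rating, same length as the inputs.
#' @examples
#' mnemonic_content(90, 75, 60)
#' @export
mnemonic_content <- function(strength, vividness, spatial_accuracy) {
  r <- cbind(strength, vividness, spatial_accuracy)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 100))
    stop("ratings must lie in [0, 100]", call. = FALSE)
  unname(rowMeans(r))
}

#' Cumulative number of study fixations
#'
#' The number of fixations a participant made while encoding an image; an
#' established index of how well the stimulus was encoded into memory,
#' used as the encoding-strength covariate in the memory-quality models.
#'
#' @param sp An encoding-phase [scanpath()].
#' @return Integer fixation count.
#' @export
cumulative_study_fixations <- function(sp) {
  stopifnot(is_scanpath(sp))
  if (!identical(sp$phase, "encoding"))
    stop("cumulative study fixations are defined for encoding scanpaths", call. = FALSE)
  n_fixations(sp)
}
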