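#' Sequential encoding-recollection similarity (SERS)
#'
#' Similarity between the scanpath a participant produced while encoding
#' an image and the scanpath produced while recalling the *same* image,
#' over the five spatio-temporal dimensions of [compare_scanpaths()].
#'
#' @param enc Encoding-phase [scanpath()].
#' @param rec Recall-phase [scanpath()] for the same participant and image.
#' @param params An [mm_params()] object.
#' @return Named numeric vector of five similarities in \[0, 1\].
#' @export
sers <- function(enc, rec, params = mm_params(screen = enc$screen)) {
  stopifnot(is_scanpath(enc), is_scanpath(rec))
  if (!identical(enc$participant, rec$participant) ||
      !identical(enc$image, rec$image))
    stop("SERS compares encoding and recall of the same participant and image",
         call. = FALSE)
  if (!identical(enc$phase, "encoding") || !identical(rec$phase, "recall"))
    stop("`enc` must be an encoding scanpath and `rec` a recall scanpath",
         call. = FALSE)
  compare_scanpaths(enc, rec, params)
}

#' Cross-image baseline similarity
#'
#' The similarity between an image's encoding scanpath and the same
#' participant's recall scanpaths for all *other* images of the same
#' type, averaged per dimension with equal weight per image. The baseline
#' captures idiosyncratic viewing tendencies that inflate raw SERS.
#'
#' @param enc Encoding-phase [scanpath()].
#' @param other_recalls List of recall [scanpath()]s from the same
#'   participant and image type, each for a different image than `enc`.
#' @param params An [mm_params()] object.
#' @return Named numeric vector of five mean similarities.
#' @export
baseline_similarity <- function(enc, other_recalls,
                                params = mm_params(screen = enc$screen)) {
  stopifnot(is_scanpath(enc), length(other_recalls) >= 1)
  for (r in other_recalls) {
    stopifnot(is_scanpath(r))
    if (!identical(r$participant, enc$participant) ||
        !identical(r$image_type, enc$image_type) ||
        identical(r$image, enc$image))
      stop("baseline recalls must share participant and image type, and differ in image",
           call. = FALSE)
  }
  scores <- vapply(other_recalls, function(r) compare_scanpaths(enc, r, params),
                   numeric(5))
  rowMeans(scores)
}

mm_dimensions <- c("position", "duration", "shape", "direction", "length")

# split a fixation table into per-trial (x, y, duration) matrices
trial_matrices <- function(fixations) {
  fixations <- dplyr::arrange(fixations, .data$participant, .data$image,
                              .data$phase, .data$onset_ms)
  key <- paste(fixations$participant, fixations$image, fixations$phase, sep = "\r")
  idx <- split(seq_len(nrow(fixations)), factor(key, levels = unique(key)))
  meta <- fixations[vapply(idx, `[`, integer(1), 1L),
                    c("participant", "image", "image_type", "phase")]
  mats <- lapply(idx, function(i)
    cbind(fixations$x[i], fixations$y[i], fixations$duration_ms[i]))
  list(meta = tibble::as_tibble(meta), mats = mats)
}

#' Per-trial replay scores against the cross-image baseline
#'
#' For every (participant, image) with a valid encoding and recall
#' scanpath, computes the SERS score, the cross-image baseline (mean
#' similarity of the encoding scanpath to the same participant's recalls
#' of all other same-type images), and the replay score — SERS minus
#' baseline — for each of the five dimensions. A replay score above zero
#' indicates sequential reinstatement beyond idiosyncratic viewing
#' tendencies.
#'
#' Trials with fewer than `min_fixations` fixations in either phase are
#' excluded from scoring (and from other images' baselines), as are
#' trials whose counterpart phase is missing or whose baseline comparison
#' set is empty. Exclusions are reported in the `"exclusions"` attribute
#' with machine-readable reason codes.
#'
#' @param fixations Fixation table with columns `participant`, `image`,
#'   `image_type`, `phase`, `x`, `y`, `onset_ms`, `duration_ms` (see
#'   [read_fixations()]).
#' @param params An [mm_params()] object.
#' @param min_fixations Minimum fixations per phase for a trial to be scored.
#' @return A tibble with one row per scored (participant, image) and
#'   columns `sers_*`, `baseline_*`, `replay_*` for the five dimensions.
#'   Attribute `"exclusions"` holds a tibble of dropped trials.
#' @export
replay_scores <- function(fixations, params = mm_params(), min_fixations = 2L) {
  tm <- trial_matrices(fixations)
  nfix <- vapply(tm$mats, nrow, integer(1))
  valid <- nfix >= min_fixations
  excl <- tm$meta[!valid, ]
  excl$reason <- if (nrow(excl)) "too_few_fixations" else character(0)

  meta <- tm$meta[valid, ]
  mats <- tm$mats[valid]
  diag_px <- screen_diagonal(params$screen)
  amp_px <- amplitude_threshold_px(params)

  rows <- list()
  for (p in unique(meta$participant)) {
    for (ty in unique(meta$image_type[meta$participant == p])) {
      sel <- meta$participant == p & meta$image_type == ty
      enc_i <- which(sel & meta$phase == "encoding")
      rec_i <- which(sel & meta$phase == "recall")
      enc_imgs <- meta$image[enc_i]
      rec_imgs <- meta$image[rec_i]

      scored <- enc_imgs[enc_imgs %in% rec_imgs]
      for (img in setdiff(union(enc_imgs, rec_imgs), scored)) {
        excl <- dplyr::bind_rows(excl, tibble::tibble(
          participant = p, image = img, image_type = ty,
          phase = if (img %in% enc_imgs) "recall" else "encoding",
          reason = "missing_counterpart"))
      }
      if (length(scored) == 0L || length(rec_i) == 0L) next

      S <- cpp_cross_compare(mats[enc_i[match(scored, enc_imgs)]], mats[rec_i],
                             params$direction_threshold, amp_px,
                             params$duration_threshold, diag_px)
      dim(S) <- c(length(scored), length(rec_i), 5L)
      for (k in seq_along(scored)) {
        img <- scored[k]
        own <- which(rec_imgs == img)
        others <- which(rec_imgs != img)
        if (length(others) == 0L) {
          excl <- dplyr::bind_rows(excl, tibble::tibble(
            participant = p, image = img, image_type = ty,
            phase = NA_character_, reason = "empty_baseline_set"))
          next
        }
        sers_k <- S[k, own, ]
        base_k <- apply(S[k, others, , drop = FALSE], 3, mean)
        rows[[length(rows) + 1L]] <- c(
          list(participant = p, image = img, image_type = ty),
          stats::setNames(as.list(sers_k), paste0("sers_", mm_dimensions)),
          stats::setNames(as.list(base_k), paste0("baseline_", mm_dimensions)),
          stats::setNames(as.list(sers_k - base_k), paste0("replay_", mm_dimensions)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- tibble::as_tibble(excl)
  attr(out, "params") <- params
  out
}

#' Shuffle recall image labels (permutation null)
#'
#' Randomly permutes the image labels of the recall trials within each
#' participant and image type, leaving encoding trials untouched. Under
#' this null the expected replay score is exactly zero on every
#' dimension, which makes it the reference distribution for calibration
#' checks of the replay pipeline.
#'
#' @param fixations Fixation table (see [replay_scores()]).
#' @return The fixation table with permuted recall image labels.
#' @export
shuffle_recall_images <- function(fixations) {
  out <- fixations
  rec <- out$phase == "recall"
  for (p in unique(out$participant)) {
    for (ty in unique(out$image_type)) {
      sel <- rec & out$participant == p & out$image_type == ty
      imgs <- unique(out$image[sel])
      if (length(imgs) < 2L) next
      new <- sample(imgs)
      out$image[sel] <- new[match(out$image[sel], imgs)]
    }
  }
  out
}

aoi_grid_dims <- function(grid) {
  if (length(grid) == 2L) return(as.integer(grid))
  switch(as.character(grid),
         "4" = c(2L, 2L), "8" = c(2L, 4L), "12" = c(3L, 4L), "16" = c(4L, 4L),
         stop("grid must be 4, 8, 12 or 16 cells, or an explicit c(rows, cols)",
              call. = FALSE))
}

#' Area-of-interest fixation profile
#'
#' Partitions the screen into a grid of equal rectangular areas of
#' interest (the main analysis uses the four screen quadrants) and
#' returns the proportion of fixations whose centroid falls in each
#' cell. Cells are half-open (`[x0, x1)`, `[y0, y1)`) with the last row
#' and column closed, so boundary fixations are assigned
#' deterministically; fixations outside the screen are clamped to the
#' nearest edge cell.
#'
#' @param sp A [scanpath()] with at least one fixation.
#' @param grid Total cell count (4, 8, 12 or 16) or explicit
#'   `c(rows, cols)`. 8 maps to 2 x 4, 12 to 3 x 4, 16 to 4 x 4.
#' @return An object of class `aoi_profile`: list with `grid`
#'   (rows, cols), `proportions` (row-major numeric vector summing to 1)
#'   and `n_fixations`.
#' @export
aoi_profile <- function(sp, grid = 4) {
  stopifnot(is_scanpath(sp), n_fixations(sp) >= 1L)
  dims <- aoi_grid_dims(grid)
  rows <- dims[1]; cols <- dims[2]
  w <- sp$screen[1]; h <- sp$screen[2]
  cx <- pmin(pmax(floor(sp$fixations$x / (w / cols)), 0), cols - 1)
  cy <- pmin(pmax(floor(sp$fixations$y / (h / rows)), 0), rows - 1)
  cell <- cy * cols + cx + 1
  counts <- tabulate(cell, nbins = rows * cols)
  structure(list(grid = c(rows = rows, cols = cols),
                 proportions = counts / sum(counts),
                 n_fixations = length(cell)),
            class = "aoi_profile")
}

#' Spatial overlap between two AOI profiles
#'
#' Default metric is total-variation similarity,
#' `1 - sum(|p_enc - p_rec|) / 2`, which is 1 for identical profiles and
#' 0 for profiles concentrated in disjoint cells. The alternative
#' `"rank"` metric is the Spearman rank correlation of the cell
#' proportions rescaled from \[-1, 1\] to \[0, 1\]. The metric used is
#' attached to the result so scores from different metrics are never
#' silently mixed.
#'
#' @param enc_profile,rec_profile [aoi_profile()] objects on the same grid.
#' @param metric `"tv"` (total variation, default) or `"rank"`.
#' @return A similarity in \[0, 1\] with attribute `"metric"`.
#' @export
spatial_overlap <- function(enc_profile, rec_profile, metric = c("tv", "rank")) {
  metric <- match.arg(metric)
  stopifnot(inherits(enc_profile, "aoi_profile"), inherits(rec_profile, "aoi_profile"))
  if (!identical(enc_profile$grid, rec_profile$grid))
    stop("AOI profiles were computed on different grids", call. = FALSE)
  p <- enc_profile$proportions; q <- rec_profile$proportions
  value <- if (metric == "tv") {
    1 - sum(abs(p - q)) / 2
  } else if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    # rank correlation is undefined for a flat profile: identical
    # profiles still count as perfect overlap, anything else as neutral
    if (max(abs(p - q)) == 0) 1 else 0.5
  } else {
    (stats::cor(p, q, method = "spearman") + 1) / 2
  }
  structure(value, metric = metric)
}

#' Gaze transitions between response options
#'
#' Number of consecutive changes in an ordered sequence of AOI labels,
#' e.g. gaze alternations between the four response options of a
#' forced-choice recognition screen — an established index of choice
#' uncertainty (more transitions, less certainty).
#'
#' @param fixation_aois Ordered vector of AOI labels.
#' @return Integer count of label changes.
#' @examples
#' gaze_transitions(c("A", "B", "A", "C"))  # 3
#' @export
gaze_transitions <- function(fixation_aois) {
  n <- length(fixation_aois)
  if (n < 2L) return(0L)
  sum(fixation_aois[-1] != fixation_aois[-n])
}

#' Spatial reinstatement table over AOI grids
#'
#' Computes, for every (participant, image) with fixations in both
#' phases, the encoding and recall AOI profiles and their spatial
#' overlap, for each requested grid.
#'
#' @param fixations Fixation table (see [replay_scores()]).
#' @param grids Vector of AOI cell counts; defaults to the 4-quadrant
#'   analysis plus the 8/12/16-cell sensitivity grids.
#' @param metric Overlap metric passed to [spatial_overlap()].
#' @param screen Screen size `c(width, height)` px.
#' @return Tibble with columns `participant`, `image`, `image_type`,
#'   `grid`, `metric`, `overlap`.
#' @export
aoi_overlap_table <- function(fixations, grids = c(4, 8, 12, 16),
                              metric = "tv", screen = c(1680, 1050)) {
  tm <- trial_matrices(fixations)
  meta <- tm$meta
  rows <- list()
  keys <- unique(meta[meta$phase == "encoding", c("participant", "image", "image_type")])
  for (r in seq_len(nrow(keys))) {
    p <- keys$participant[r]; img <- keys$image[r]
    ei <- which(meta$participant == p & meta$image == img & meta$phase == "encoding")
    ri <- which(meta$participant == p & meta$image == img & meta$phase == "recall")
    if (length(ei) != 1L || length(ri) != 1L) next
    enc_sp <- scanpath(tm$mats[[ei]][, 1], tm$mats[[ei]][, 2], tm$mats[[ei]][, 3],
                       participant = p, image = img, phase = "encoding",
                       screen = screen, warn_offscreen = FALSE)
    rec_sp <- scanpath(tm$mats[[ri]][, 1], tm$mats[[ri]][, 2], tm$mats[[ri]][, 3],
                       participant = p, image = img, phase = "recall",
                       screen = screen, warn_offscreen = FALSE)
    for (g in grids) {
      ov <- spatial_overlap(aoi_profile(enc_sp, g), aoi_profile(rec_sp, g),
                            metric = metric)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant = p, image = img, image_type = keys$image_type[r],
        grid = g, metric = metric, overlap = as.numeric(ov))
    }
  }
  dplyr::bind_rows(rows)
}
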