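fixation_columns <- c("participant", "image", "image_type", "phase",
                      "fix_index", "x", "y", "onset_ms", "duration_ms")

#' Read a fixation table from CSV
#'
#' The sole data interchange format of the pipeline: one row per
#' fixation with columns `participant`, `image`, `image_type`, `phase`,
#' `fix_index`, `x`, `y`, `onset_ms`, `duration_ms` (UTF-8, one header
#' row). Rows are grouped by (participant, image, phase) and ordered by
#' `fix_index`; the input row order is irrelevant. Converters for
#' proprietary eye-tracker exports (SMI, EyeLink) should target this
#' schema.
#'
#' @param path CSV file path.
#' @return A validated fixation tibble sorted by trial and fixation index.
#' @export
read_fixations <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_fixations(tab)
}

#' @rdname read_fixations
#' @param tab A fixation data frame to validate.
#' @export
validate_fixations <- function(tab) {
  missing_cols <- setdiff(fixation_columns, names(tab))
  if (length(missing_cols))
    stop("fixation table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- dplyr::arrange(tab, .data$participant, .data$image, .data$phase,
                        .data$fix_index)
  key <- paste(tab$participant, tab$image, tab$phase, tab$fix_index, sep = "\r")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("duplicate (participant, image, phase, fix_index) keys at rows: ",
         paste(utils::head(rows, 5), collapse = ", "), call. = FALSE)
  }
  trial <- paste(tab$participant, tab$image, tab$phase, sep = "\r")
  bad <- which(c(FALSE, diff(tab$onset_ms) <= 0) &
                 trial == dplyr::lag(trial, default = ""))
  if (length(bad))
    stop("fixation onsets are not strictly increasing within trial at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(tab$duration_ms <= 0))
    stop("fixation durations must be strictly positive", call. = FALSE)
  tibble::as_tibble(tab)
}

#' Write a fixation table to CSV
#'
#' Inverse of [read_fixations()]: writes the canonical fixation schema.
#'
#' @param fixations Fixation tibble (or list of [scanpath()] objects).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  if (is.list(fixations) && !is.data.frame(fixations) &&
      all(vapply(fixations, is_scanpath, logical(1)))) {
    fixations <- dplyr::bind_rows(lapply(fixations, function(sp) {
      tibble::tibble(participant = sp$participant, image = sp$image,
                     image_type = sp$image_type, phase = sp$phase,
                     fix_index = seq_len(nrow(sp$fixations)),
                     x = sp$fixations$x, y = sp$fixations$y,
                     onset_ms = sp$fixations$onset,
                     duration_ms = sp$fixations$duration)
    }))
  }
  readr::write_csv(fixations[, fixation_columns], path, progress = FALSE)
  invisible(path)
}

#' Convert a fixation table into scanpath objects
#'
#' @param fixations A validated fixation tibble.
#' @param screen Screen size `c(width, height)` px.
#' @return A list of [scanpath()] objects, one per (participant, image,
#'   phase).
#' @export
as_scanpaths <- function(fixations, screen = c(1680, 1050)) {
  fixations <- validate_fixations(fixations)
  key <- paste(fixations$participant, fixations$image, fixations$phase, sep = "\r")
  idx <- split(seq_len(nrow(fixations)), factor(key, levels = unique(key)))
  unname(lapply(idx, function(i) {
    scanpath(fixations$x[i], fixations$y[i], fixations$duration_ms[i],
             onset = fixations$onset_ms[i],
             participant = fixations$participant[i][1],
             image = fixations$image[i][1],
             image_type = fixations$image_type[i][1],
             phase = fixations$phase[i][1],
             screen = screen, warn_offscreen = FALSE)
  }))
}
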