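#' Configuration for the synthetic experiment generator
#'
#' Defines a full blank-screen recall experiment: participants encode a
#' set of scene and object-arrangement images (5 s each), then recall
#' each while viewing a blank screen (7 s), rate the recollection, and
#' complete a surprise recognition test. The generator emulates the
#' statistical structure this pipeline assumes — image-specific anchor
#' points stand in for visual content, recall scanpaths are distorted
#' copies of encoding scanpaths (spatial contraction, global offset,
#' positional jitter, inflated fixation durations, partial retention of
#' fixation order), and ratings are causally linked to the trial's true
#' replay fidelity with crossed participant/image random effects.
#'
#' Three latent per-trial fidelities drive the distortions and the
#' ratings: `phi` (sequential fidelity — the probability each encoding
#' fixation is retained in order), `shape_fidelity` (attenuates
#' per-saccade amplitude noise) and `direction_fidelity` (attenuates
#' per-saccade rotation noise). Each is drawn from a Beta distribution
#' with the stated mean and concentration `fidelity_concentration`.
#'
#' @param n_participants Number of participants.
#' @param n_images_per_type Images per type, named `scene` and
#'   `object_arrangement`.
#' @param screen Screen size `c(width, height)` px.
#' @param frame_fraction Fraction of the screen covered by the image frame.
#' @param encoding_duration,recall_duration Trial durations (ms).
#' @param n_fixations_mean Mean encoding fixation count (Poisson, min 3).
#' @param fixation_scatter SD (px) of fixation positions around anchors.
#' @param fix_duration_meanlog,fix_duration_sdlog Lognormal fixation
#'   duration parameters (ms scale).
#' @param saccade_gap Inter-fixation gap (ms) used when building onsets.
#' @param n_anchors_scene Anchor count for scenes (center-biased);
#'   object arrangements always use 4 well-separated anchors.
#' @param scene_anchor_spread Scene anchor spread as a fraction of the
#'   frame size.
#' @param contraction Recall spatial contraction factor (gamma, in
#'   (0, 1]) at shape fidelity 1.
#' @param contraction_gain Fraction by which contraction deepens as
#'   shape fidelity falls: the per-trial factor is
#'   `contraction * (1 - contraction_gain * (1 - shape fidelity))`, so
#'   poorly remembered saccade metrics come out more contracted.
#' @param offset_sd Recall global offset SD (px).
#' @param duration_inflation Recall fixation duration multiplier (kappa >= 1).
#' @param jitter_sd Recall per-fixation positional jitter SD (px),
#'   applied on every trial.
#' @param pos_noise_sd SD (px) of the low-frequency positional drift
#'   accumulated across the recall sequence at sequential fidelity 0
#'   (scales with `1 - phi` of the trial): poorly retained sequences
#'   wander away from the encoded locations while the local saccade
#'   geometry is left intact.
#' @param reanchor Re-anchoring weight in \[0, 1\]: each recall fixation
#'   is pulled back toward its remembered location with this weight, so
#'   saccade-level noise perturbs the local path geometry without
#'   accumulating into a global random walk (memory-guided gaze targets
#'   remembered locations; saccade errors do not compound).
#' @param phi,shape_fidelity,direction_fidelity Mean latent fidelities in
#'   \[0, 1\].
#' @param fidelity_concentration Beta concentration of the fidelity draws.
#' @param amp_noise_sd Per-saccade lognormal amplitude noise SD at
#'   fidelity 0 (scales with `1 - shape_fidelity`).
#' @param dir_noise_sd Per-saccade rotation noise SD (radians) at
#'   fidelity 0 (scales with `1 - direction_fidelity`).
#' @param intercept,b_type,b_pos,b_shape,b_dir Rating-model effects on
#'   the \[0, 1\] latent scale: intercept (object arrangements), scene
#'   advantage, position-fidelity effect (both types), shape-fidelity
#'   effect (scenes only), direction-fidelity effect (object
#'   arrangements only).
#' @param sd_participant,sd_image,sd_slope,sd_resid Random-effect and
#'   residual SDs of the latent rating.
#' @param rating_noise_sd Per-rating measurement noise SD (keeps the
#'   three ratings correlated around r = 0.9).
#' @param seed Integer seed; together with the config it fully
#'   determines the generated experiment. Random streams are split per
#'   (participant, image, phase), so adding participants does not
#'   perturb existing trials.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_participants = 60,
                              n_images_per_type = c(scene = 18, object_arrangement = 18),
                              screen = c(1680, 1050),
                              frame_fraction = 0.8,
                              encoding_duration = 5000,
                              recall_duration = 7000,
                              n_fixations_mean = 15,
                              fixation_scatter = 40,
                              fix_duration_meanlog = log(230),
                              fix_duration_sdlog = 0.45,
                              saccade_gap = 30,
                              n_anchors_scene = 6,
                              scene_anchor_spread = 0.22,
                              contraction = 0.8,
                              contraction_gain = 0.5,
                              offset_sd = 60,
                              duration_inflation = 1.6,
                              jitter_sd = 15,
                              pos_noise_sd = 300,
                              reanchor = 0.6,
                              phi = 0.6,
                              shape_fidelity = 0.5,
                              direction_fidelity = 0.5,
                              fidelity_concentration = 1.5,
                              amp_noise_sd = 1.0,
                              dir_noise_sd = 2.0,
                              intercept = 0.49,
                              b_type = 0.17,
                              b_pos = 0.5,
                              b_shape = 1.0,
                              b_dir = 0.5,
                              sd_participant = 0.08,
                              sd_image = 0.05,
                              sd_slope = 0.04,
                              sd_resid = 0.10,
                              rating_noise_sd = 0.06,
                              seed = 1L) {
  cfg <- as.list(environment())
  bad <- character(0)
  if (cfg$n_participants < 1) bad <- c(bad, "n_participants")
  if (any(cfg$n_images_per_type < 1) ||
      !setequal(names(cfg$n_images_per_type), c("scene", "object_arrangement")))
    bad <- c(bad, "n_images_per_type")
  if (cfg$contraction <= 0 || cfg$contraction > 1) bad <- c(bad, "contraction")
  if (cfg$contraction_gain < 0 || cfg$contraction_gain > 1) bad <- c(bad, "contraction_gain")
  if (cfg$reanchor < 0 || cfg$reanchor > 1) bad <- c(bad, "reanchor")
  if (cfg$duration_inflation < 1) bad <- c(bad, "duration_inflation")
  for (f in c("phi", "shape_fidelity", "direction_fidelity"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad <- c(bad, f)
  for (f in c("offset_sd", "jitter_sd", "pos_noise_sd", "amp_noise_sd", "dir_noise_sd",
              "sd_participant", "sd_image", "sd_slope", "sd_resid",
              "rating_noise_sd"))
    if (cfg[[f]] < 0) bad <- c(bad, f)
  if (length(bad))
    stop("invalid simulation_config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# deterministic per-(participant, image, stream) seed so streams are split
trial_seed <- function(seed, p, i, stream) {
  as.integer(((as.numeric(seed) %% 1e6) * 1021 + p * 131071 +
                i * 7919 + stream * 524287) %% 2147483629)
}

image_table <- function(cfg) {
  n_sc <- cfg$n_images_per_type[["scene"]]
  n_ob <- cfg$n_images_per_type[["object_arrangement"]]
  tibble::tibble(
    i_index = seq_len(n_sc + n_ob),
    image = c(sprintf("scene_%02d", seq_len(n_sc)),
              sprintf("object_%02d", seq_len(n_ob))),
    image_type = rep(c("scene", "object_arrangement"), c(n_sc, n_ob)))
}

draw_fidelity <- function(mean, conc) {
  if (mean <= 0 || mean >= 1) return(mean)
  stats::rbeta(1, mean * conc, (1 - mean) * conc)
}

# latent anchor points standing in for image content; shared across
# participants for the same image
image_anchors <- function(cfg, i_index, image_type) {
  set.seed(trial_seed(cfg$seed, 0, i_index, 1L))
  w <- cfg$screen[1]; h <- cfg$screen[2]
  fx <- (1 - cfg$frame_fraction) / 2
  x0 <- fx * w; x1 <- (1 - fx) * w
  y0 <- fx * h; y1 <- (1 - fx) * h
  if (image_type == "scene") {
    k <- cfg$n_anchors_scene
    ax <- pmin(pmax(rnorm(k, (x0 + x1) / 2, cfg$scene_anchor_spread * (x1 - x0)), x0), x1)
    ay <- pmin(pmax(rnorm(k, (y0 + y1) / 2, cfg$scene_anchor_spread * (y1 - y0)), y0), y1)
  } else {
    # four well-separated objects, one per frame quadrant, jittered
    qx <- x0 + c(0.25, 0.75, 0.25, 0.75) * (x1 - x0)
    qy <- y0 + c(0.25, 0.25, 0.75, 0.75) * (y1 - y0)
    ax <- pmin(pmax(qx + rnorm(4, 0, 0.08 * (x1 - x0)), x0), x1)
    ay <- pmin(pmax(qy + rnorm(4, 0, 0.08 * (y1 - y0)), y0), y1)
  }
  cbind(ax, ay)
}

# encoding core on plain vectors; anchors passed in so callers can cache them
gen_enc_core <- function(cfg, participant, image, anchors) {
  set.seed(trial_seed(cfg$seed, participant, image, 2L))
  n <- max(3L, stats::rpois(1, cfg$n_fixations_mean))
  k <- nrow(anchors)
  visit <- integer(n)
  visit[1] <- sample.int(k, 1)
  if (k > 1L && n > 1L) {
    offs <- sample.int(k - 1L, n - 1L, replace = TRUE)  # no immediate revisits
    for (t in 2:n) visit[t] <- ((visit[t - 1L] - 1L + offs[t - 1L]) %% k) + 1L
  }
  x <- pmin(pmax(anchors[visit, 1] + rnorm(n, 0, cfg$fixation_scatter), 0), cfg$screen[1])
  y <- pmin(pmax(anchors[visit, 2] + rnorm(n, 0, cfg$fixation_scatter), 0), cfg$screen[2])
  dur <- stats::rlnorm(n, cfg$fix_duration_meanlog, cfg$fix_duration_sdlog)
  onset <- cumsum(c(0, dur[-n] + cfg$saccade_gap))
  keep <- onset < cfg$encoding_duration
  keep[1:2] <- TRUE
  x <- x[keep]; y <- y[keep]; dur <- dur[keep]; onset <- onset[keep]
  m <- length(x)
  dur[m] <- max(min(dur[m], cfg$encoding_duration - onset[m]), 1)
  list(x = x, y = y, dur = dur, onset = onset)
}

#' Generate an encoding scanpath
#'
#' Fixations are noisy visits to the image's latent anchors (no
#' immediate revisits); durations are lognormal around ~230 ms and the
#' sequence is truncated so it fits within the encoding duration.
#'
#' @param cfg A [simulation_config()].
#' @param participant Participant index (1-based).
#' @param image Image index (1-based, across both types; scenes first).
#' @return An encoding [scanpath()].
#' @export
generate_encoding <- function(cfg, participant = 1L, image = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  imgs <- image_table(cfg)
  stopifnot(image >= 1, image <= nrow(imgs))
  ity <- imgs$image_type[image]
  core <- gen_enc_core(cfg, participant, image,
                       image_anchors(cfg, image, ity))
  sp <- scanpath(core$x, core$y, core$dur, onset = core$onset,
                 participant = sprintf("p%02d", participant),
                 image = imgs$image[image], image_type = ity,
                 phase = "encoding", screen = cfg$screen,
                 warn_offscreen = FALSE)
  sp$p_index <- as.integer(participant)
  sp$i_index <- as.integer(image)
  sp
}

#' Generate a recall scanpath from an encoding scanpath
#'
#' Applies the distortions characteristic of looking-at-nothing recall:
#' each encoding fixation is retained in order with probability equal to
#' the trial's sequential fidelity (non-retained fixations are
#' re-inserted at a random serial position); saccadic vectors receive
#' amplitude and rotation noise attenuated by the shape and direction
#' fidelities; the path is contracted about its centroid, globally
#' offset, jittered per fixation; and fixation durations are inflated
#' and the sequence truncated to the recall duration.
#'
#' @param cfg A [simulation_config()].
#' @param encoding An encoding scanpath produced by [generate_encoding()].
#' @param fidelity Optional list overriding the latent fidelity draws,
#'   with elements `position`, `shape`, `direction` in \[0, 1\].
#' @return A recall [scanpath()] with the trial's true fidelities
#'   attached as the `fidelity` element.
#' @export
generate_recall <- function(cfg, encoding, fidelity = NULL) {
  stopifnot(inherits(cfg, "sim_config"), is_scanpath(encoding))
  p <- encoding$p_index %||% 1L
  i <- encoding$i_index %||% 1L
  fx <- encoding$fixations
  core <- gen_rec_core(cfg, list(x = fx$x, y = fx$y, dur = fx$duration),
                       p, i, fidelity)
  sp <- scanpath(core$x, core$y, core$dur, onset = core$onset,
                 participant = encoding$participant, image = encoding$image,
                 image_type = encoding$image_type, phase = "recall",
                 screen = cfg$screen, warn_offscreen = FALSE)
  sp$p_index <- p
  sp$i_index <- i
  sp$fidelity <- core$fidelity
  sp
}

gen_rec_core <- function(cfg, enc, p, i, fidelity = NULL) {
  set.seed(trial_seed(cfg$seed, p, i, 3L))
  f_pos <- fidelity$position %||% draw_fidelity(cfg$phi, cfg$fidelity_concentration)
  f_shape <- fidelity$shape %||% draw_fidelity(cfg$shape_fidelity, cfg$fidelity_concentration)
  f_dir <- fidelity$direction %||% draw_fidelity(cfg$direction_fidelity, cfg$fidelity_concentration)

  n <- length(enc$x)
  keep <- runif(n) < f_pos
  nk <- sum(keep)
  key <- numeric(n)
  key[keep] <- seq_len(nk)
  if (nk < n) key[!keep] <- runif(n - nk, 0, nk + 1)  # uniform over the nk + 1 gaps
  ord <- order(key)
  x <- enc$x[ord]; y <- enc$y[ord]; dur <- enc$dur[ord]

  if (n >= 2) {
    x0 <- x; y0 <- y
    dx <- diff(x0); dy <- diff(y0)
    ssd <- cfg$amp_noise_sd * (1 - f_shape)
    sc <- exp(rnorm(n - 1, 0, ssd) - ssd^2 / 2)  # mean-one amplitude noise
    th <- rnorm(n - 1, 0, cfg$dir_noise_sd * (1 - f_dir))
    ndx <- sc * (cos(th) * dx - sin(th) * dy)
    ndy <- sc * (sin(th) * dx + cos(th) * dy)
    b <- cfg$reanchor
    for (t in 2:n) {
      x[t] <- b * x0[t] + (1 - b) * (x[t - 1] + ndx[t - 1])
      y[t] <- b * y0[t] + (1 - b) * (y[t - 1] + ndy[t - 1])
    }
  }
  gam <- cfg$contraction * (1 - cfg$contraction_gain * (1 - f_shape))
  cx <- mean(x); cy <- mean(y)
  x <- cx + gam * (x - cx)
  y <- cy + gam * (y - cy)
  w <- if (n > 1) seq(0, 1, length.out = n) else 0
  x <- x + rnorm(1, 0, cfg$offset_sd) + w * rnorm(1, 0, cfg$pos_noise_sd * (1 - f_pos)) +
    rnorm(n, 0, cfg$jitter_sd)
  y <- y + rnorm(1, 0, cfg$offset_sd) + w * rnorm(1, 0, cfg$pos_noise_sd * (1 - f_pos)) +
    rnorm(n, 0, cfg$jitter_sd)
  x <- pmin(pmax(x, 0), cfg$screen[1])
  y <- pmin(pmax(y, 0), cfg$screen[2])

  dur <- dur * cfg$duration_inflation
  onset <- cumsum(c(0, dur[-n] + cfg$saccade_gap))
  sel <- onset < cfg$recall_duration
  sel[1:min(2, n)] <- TRUE
  x <- x[sel]; y <- y[sel]; dur <- dur[sel]; onset <- onset[sel]
  m <- length(x)
  dur[m] <- max(min(dur[m], cfg$recall_duration - onset[m]), 1)

  list(x = x, y = y, dur = dur, onset = onset,
       fidelity = c(position = f_pos, shape = f_shape, direction = f_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate ratings and surprise-test outcomes from ground truth
#'
#' The latent memory quality of a trial is a linear function of the
#' trial's true fidelities: an intercept, a scene advantage, a
#' position-fidelity effect for both image types, a shape-fidelity
#' effect for scenes only and a direction-fidelity effect for object
#' arrangements only, plus crossed participant/image random intercepts,
#' a participant-level random slope for image type, and trial noise. The
#' three subjective ratings are the latent value plus independent
#' measurement noise (so they are highly correlated), the mnemonic
#' content score is their mean, and the surprise-test outcomes (4AFC
#' accuracy, confidence, response time, gaze transitions between
#' options) are drawn from monotone links on the same latent value.
#'
#' @param cfg A [simulation_config()].
#' @param truth Tibble of per-trial ground truth with columns `p_index`,
#'   `i_index`, `participant`, `image`, `image_type`, `f_position`,
#'   `f_shape`, `f_direction` (as produced by [generate_experiment()]).
#' @return The trial table: one row per (participant, image) with the
#'   three ratings, the mnemonic content score, surprise-test outcomes
#'   and the latent memory quality is returned in the `latent` column of
#'   the attached `"truth"` attribute.
#' @export
generate_ratings <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  np <- max(truth$p_index)
  u_p <- s_p <- numeric(np)
  for (p in seq_len(np)) {
    set.seed(trial_seed(cfg$seed, p, 0L, 4L))
    u_p[p] <- rnorm(1, 0, cfg$sd_participant)
    s_p[p] <- rnorm(1, 0, cfg$sd_slope)
  }
  ni <- max(truth$i_index)
  u_i <- numeric(ni)
  for (i in seq_len(ni)) {
    set.seed(trial_seed(cfg$seed, 0L, i, 5L))
    u_i[i] <- rnorm(1, 0, cfg$sd_image)
  }
  n <- nrow(truth)
  scene <- as.numeric(truth$image_type == "scene")
  lat <- r1 <- r2 <- r3 <- conf <- rt <- numeric(n)
  acc <- trans <- integer(n)
  for (t in seq_len(n)) {
    set.seed(trial_seed(cfg$seed, truth$p_index[t], truth$i_index[t], 6L))
    l <- cfg$intercept + (cfg$b_type + s_p[truth$p_index[t]]) * scene[t] +
      cfg$b_pos * (truth$f_position[t] - 0.5) +
      scene[t] * cfg$b_shape * (truth$f_shape[t] - 0.5) +
      (1 - scene[t]) * cfg$b_dir * (truth$f_direction[t] - 0.5) +
      u_p[truth$p_index[t]] + u_i[truth$i_index[t]] +
      rnorm(1, 0, cfg$sd_resid)
    lat[t] <- l
    r <- pmin(pmax(l + rnorm(3, 0, cfg$rating_noise_sd), 0), 1) * 100
    r1[t] <- r[1]; r2[t] <- r[2]; r3[t] <- r[3]
    acc[t] <- stats::rbinom(1, 1, stats::plogis(2.0 + 11 * (l - 0.575)))
    conf[t] <- 100 * pmin(pmax(stats::plogis(1.43 + 9 * (l - 0.575)) +
                                 rnorm(1, 0, 0.08), 0), 1)
    rt[t] <- stats::rlnorm(1, 9.2 - 3.5 * (l - 0.49), 0.6)
    trans[t] <- stats::rpois(1, exp(2.36 - 2.6 * (l - 0.575)))
  }
  trials <- tibble::tibble(
    participant = truth$participant, image = truth$image,
    image_type = truth$image_type,
    recollection_strength = r1, vividness = r2, spatial_accuracy = r3,
    mnemonic_content = mnemonic_content(r1, r2, r3),
    surprise_accuracy = acc, confidence = conf, response_time = rt,
    gaze_transitions = trans,
    n_study_fixations = truth$n_study_fixations)
  attr(trials, "truth") <- dplyr::mutate(truth, latent = lat)
  trials
}

#' Generate a complete synthetic experiment
#'
#' Runs the full generative model: encoding scanpaths for every
#' participant x image, distorted recall scanpaths, and the trial table
#' of ratings and surprise-test outcomes. Identical configurations
#' (including the seed) yield identical output.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `fixations` (long fixation table in the CSV
#'   schema read by [read_fixations()]), `trials` (the trial table),
#'   `truth` (per-trial latent fidelities and effects; for validation
#'   only — never consumed by the analysis pipeline) and `config`.
#' @export
generate_experiment <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  imgs <- image_table(cfg)
  ni <- nrow(imgs)
  anchors <- lapply(seq_len(ni), function(i)
    image_anchors(cfg, i, imgs$image_type[i]))
  pid <- sprintf("p%02d", seq_len(cfg$n_participants))

  nt <- cfg$n_participants * ni
  chunks <- vector("list", nt * 2L)
  ci <- 0L
  t_p <- t_i <- t_nenc <- t_nrec <- integer(nt)
  t_fpos <- t_fshape <- t_fdir <- numeric(nt)
  ti <- 0L
  for (p in seq_len(cfg$n_participants)) {
    for (i in seq_len(ni)) {
      enc <- gen_enc_core(cfg, p, i, anchors[[i]])
      rec <- gen_rec_core(cfg, enc, p, i)
      for (ph in c("encoding", "recall")) {
        sp <- if (ph == "encoding") enc else rec
        ci <- ci + 1L
        m <- length(sp$x)
        chunks[[ci]] <- list(participant = rep(pid[p], m),
                             image = rep(imgs$image[i], m),
                             image_type = rep(imgs$image_type[i], m),
                             phase = rep(ph, m),
                             fix_index = seq_len(m),
                             x = sp$x, y = sp$y,
                             onset_ms = sp$onset, duration_ms = sp$dur)
      }
      ti <- ti + 1L
      t_p[ti] <- p; t_i[ti] <- i
      t_nenc[ti] <- length(enc$x); t_nrec[ti] <- length(rec$x)
      t_fpos[ti] <- rec$fidelity[["position"]]
      t_fshape[ti] <- rec$fidelity[["shape"]]
      t_fdir[ti] <- rec$fidelity[["direction"]]
    }
  }
  fixations <- tibble::as_tibble(
    lapply(stats::setNames(names(chunks[[1]]), names(chunks[[1]])),
           function(col) unlist(lapply(chunks, `[[`, col), use.names = FALSE)))
  truth <- tibble::tibble(
    p_index = t_p, i_index = t_i,
    participant = pid[t_p], image = imgs$image[t_i],
    image_type = imgs$image_type[t_i],
    f_position = t_fpos, f_shape = t_fshape, f_direction = t_fdir,
    n_study_fixations = t_nenc, n_recall_fixations = t_nrec)
  trials <- generate_ratings(cfg, truth)
  list(fixations = fixations, trials = trials,
       truth = attr(trials, "truth"), config = cfg)
}

#' Mean SERS as a function of sequential fidelity
#'
#' Simulates encoding/recall scanpath pairs at fixed sequential-fidelity
#' values (shape and direction fidelities held at their configured
#' means) and returns the mean SERS per grid point for one dimension.
#' Used to verify that degrading the retention of fixation order
#' degrades measured sequential similarity monotonically.
#'
#' @param cfg A [simulation_config()].
#' @param phi_values Sequential-fidelity grid.
#' @param n_trials Trials simulated per grid point.
#' @param dimension Similarity dimension to summarise.
#' @return Tibble with columns `phi` and `mean_sers`.
#' @export
sers_fidelity_curve <- function(cfg = simulation_config(),
                                phi_values = c(1, 0.75, 0.5, 0.25, 0),
                                n_trials = 200, dimension = "position") {
  dimension <- match.arg(dimension, mm_dimensions)
  params <- mm_params(screen = cfg$screen)
  imgs <- image_table(cfg)
  out <- lapply(phi_values, function(phi) {
    s <- vapply(seq_len(n_trials), function(t) {
      enc <- generate_encoding(cfg, t, ((t - 1L) %% nrow(imgs)) + 1L)
      rec <- generate_recall(cfg, enc,
                             fidelity = list(position = phi,
                                             shape = cfg$shape_fidelity,
                                             direction = cfg$direction_fidelity))
      compare_scanpaths(enc, rec, params)[[dimension]]
    }, numeric(1))
    tibble::tibble(phi = phi, mean_sers = mean(s))
  })
  dplyr::bind_rows(out)
}
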