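#' Encoding-strength control analysis
#'
#' Tests whether replay effects on memory quality reduce to how well the
#' images were initially encoded. Starting from a fitted memory-quality
#' structure, the cumulative number of study fixations is added to the
#' model (likelihood-ratio test reported), and then its interactions
#' with every variable of the base structure are added — each on its own
#' against the main-effect model, and jointly as a block. If replay
#' genuinely predicts memory quality beyond encoding strength, none of
#' the interactions should improve the fit.
#'
#' @param response Response column name.
#' @param terms Fixed-effect terms of the base memory-quality model.
#' @param data Joined trial/replay data containing `n_study_fixations`.
#' @param random,alpha As in [fit_mixed()] / [backward_select()].
#' @return A list with `lr_n_study` (LR test of adding the main
#'   effect), `interactions` (tibble of per-interaction LR tests, each
#'   added alone), `joint` (LR test of all interactions as a block),
#'   `joint_f` and `joint_f_replay` (Satterthwaite joint F tests of the
#'   full interaction block and of the replay-term interactions only —
#'   better calibrated than the ML likelihood ratio when groups are
#'   few) and `final` (REML fit of the model with the main effect).
#' @export
encoding_strength_control <- function(response, terms, data,
                                      random = default_random(), alpha = 0.05) {
  terms <- normalize_term(terms)
  base <- fit_mixed(response, terms, data, reml = FALSE, random = random)
  random <- base$random  # hold the structure fixed across all comparisons
  with_n <- fit_mixed(response, c(terms, "n_study_fixations"), data,
                      reml = FALSE, random = random, singular_fallback = FALSE)
  lr_n <- lr_test(with_n, base)
  vars <- setdiff(unique(unlist(strsplit(terms, ":", fixed = TRUE))),
                  "n_study_fixations")
  cands <- normalize_term(paste0("n_study_fixations:", vars))
  inter <- dplyr::bind_rows(lapply(cands, function(tm) {
    fit <- fit_mixed(response, c(terms, "n_study_fixations", tm), data,
                     reml = FALSE, random = random, singular_fallback = FALSE)
    lt <- lr_test(fit, with_n)
    tibble::tibble(term = tm, chisq = lt$chisq, df = lt$df, p_value = lt$p_value)
  }))
  all_fit <- fit_mixed(response, c(terms, "n_study_fixations", cands), data,
                       reml = FALSE, random = random, singular_fallback = FALSE)
  joint <- lr_test(all_fit, with_n)
  # Satterthwaite joint F test of the interaction block on the REML fit:
  # better calibrated than the ML likelihood ratio when groups are few
  all_reml <- fit_mixed(response, c(terms, "n_study_fixations", cands), data,
                        reml = TRUE, random = random, singular_fallback = FALSE)
  cn <- names(lme4::fixef(all_reml$model))
  satt_block <- function(idx) {
    L <- matrix(0, length(idx), length(cn))
    L[cbind(seq_along(idx), idx)] <- 1
    ct <- as.data.frame(lmerTest::contest(all_reml$model, L, joint = TRUE))
    list(f = ct[["F value"]], df1 = ct[["NumDF"]], df2 = ct[["DenDF"]],
         p_value = ct[["Pr(>F)"]])
  }
  is_inter <- grepl("n_study_fixations.*:|:.*n_study_fixations", cn)
  joint_f <- satt_block(which(is_inter))
  joint_f_replay <- satt_block(which(is_inter & grepl("replay_", cn)))
  final <- fit_mixed(response, c(terms, "n_study_fixations"), data,
                     reml = TRUE, random = random, singular_fallback = FALSE)
  list(lr_n_study = lr_n, interactions = inter, joint = joint,
       joint_f = joint_f, joint_f_replay = joint_f_replay,
       final = final, alpha = alpha)
}

#' Run the full set of study models
#'
#' Reproduces the analysis families of the scanpath-replay design on a
#' joined trial/replay table:
#'
#' 1. *Behavioural*: image-type effects on the recall-phase mnemonic
#'    content score and on the surprise-test measures (4AFC accuracy by
#'    logistic mixed model; confidence, response time and gaze
#'    transitions on correct trials only).
#' 2. *Sequential reinstatement*: per-dimension, per-type
#'    SERS-versus-baseline contrasts ([sers_baseline_table()]).
#' 3. *Memory quality*: backward selection from the maximal model of
#'    mnemonic content on image type, position/shape/direction replay
#'    and their type interactions.
#' 4. *Encoding strength*: the [encoding_strength_control()] applied to
#'    the selected memory-quality structure.
#'
#' Ratings (0-100) are modelled on a \[0, 1\] scale. No correction for
#' multiple comparisons is applied across the five similarity
#' dimensions; the report notes this.
#'
#' @param trials Trial table (see [generate_experiment()] or
#'   [read_fixations()] companions) with ratings and surprise outcomes.
#' @param replay Replay table from [replay_scores()].
#' @param alpha Selection threshold.
#' @return A list of class `study_report`.
#' @export
run_study_models <- function(trials, replay, alpha = 0.05) {
  required <- c("participant", "image", "image_type", "mnemonic_content",
                "surprise_accuracy", "confidence", "response_time",
                "gaze_transitions", "n_study_fixations")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols))
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  d <- dplyr::inner_join(replay, trials,
                         by = c("participant", "image", "image_type"))
  d$mnemonic01 <- d$mnemonic_content / 100
  d$confidence01 <- d$confidence / 100
  d$image_type <- factor(d$image_type,
                         levels = c("object_arrangement", "scene"))

  type_effect <- function(response, family, data) {
    full <- fit_mixed(response, "image_type", data, family = family, reml = FALSE)
    null <- fit_mixed(response, character(0), data, family = family,
                      reml = FALSE, random = full$random,
                      singular_fallback = FALSE)
    lt <- lr_test(full, null)
    rep_fit <- fit_mixed(response, "image_type", data, family = family,
                         reml = (family == "gaussian"), random = full$random,
                         singular_fallback = FALSE)
    cf <- rep_fit$coefficients[rep_fit$coefficients$term != "(Intercept)", ]
    tibble::tibble(response = response, family = family,
                   chisq = lt$chisq, df = lt$df, p_lr = lt$p_value,
                   estimate = cf$estimate[1], std_error = cf$std_error[1],
                   statistic = cf$statistic[1], p_value = cf$p_value[1],
                   n = rep_fit$n_obs)
  }
  correct <- d[d$surprise_accuracy == 1, ]
  behavioural <- dplyr::bind_rows(
    type_effect("mnemonic01", "gaussian", d),
    type_effect("surprise_accuracy", "binomial", d),
    type_effect("confidence01", "gaussian", correct),
    type_effect("response_time", "gaussian", correct),
    type_effect("gaze_transitions", "gaussian", correct))

  reinstatement <- sers_baseline_table(d)

  maximal <- c("image_type", "replay_position", "replay_shape",
               "replay_direction", "image_type:replay_position",
               "image_type:replay_shape", "image_type:replay_direction")
  memory_quality <- backward_select("mnemonic01", maximal, d, alpha = alpha)

  encoding_strength <- encoding_strength_control(
    "mnemonic01", memory_quality$terms, d,
    random = memory_quality$random, alpha = alpha)

  structure(list(behavioural = behavioural,
                 sers_baseline = reinstatement,
                 memory_quality = memory_quality,
                 encoding_strength = encoding_strength,
                 alpha = alpha,
                 p_method = memory_quality$final$p_method,
                 notes = paste("No multiple-testing correction is applied across",
                               "the five similarity dimensions."),
                 n_trials = nrow(d)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Scanpath replay study report ==\n\n")
  cat(sprintf("%d scored trials; alpha = %g; coefficient tests: %s\n\n",
              x$n_trials, x$alpha, x$p_method))
  cat("-- Image-type effects (recall phase and surprise test) --\n")
  print(x$behavioural)
  cat("\n-- SERS vs baseline (per dimension and image type) --\n")
  print(x$sers_baseline)
  cat("\n-- Memory-quality model (backward selection) --\n")
  print(x$memory_quality)
  print(x$memory_quality$final$coefficients)
  cat("\n-- Encoding-strength control --\n")
  cat(sprintf("adding n_study_fixations: chisq = %.2f, df = %d, p = %.3g\n",
              x$encoding_strength$lr_n_study$chisq,
              x$encoding_strength$lr_n_study$df,
              x$encoding_strength$lr_n_study$p_value))
  print(x$encoding_strength$interactions)
  cat(sprintf("joint interaction block: chisq = %.2f, df = %d, p = %.3g (LR); F = %.2f, p = %.3g (Satterthwaite)\n",
              x$encoding_strength$joint$chisq, x$encoding_strength$joint$df,
              x$encoding_strength$joint$p_value,
              x$encoding_strength$joint_f$f,
              x$encoding_strength$joint_f$p_value))
  cat("\nNote:", x$notes, "\n")
  invisible(x)
}

#' Convert a study report to a plain list for JSON serialisation
#'
#' @param report A `study_report` from [run_study_models()].
#' @return A nested list of data frames and scalars.
#' @export
report_as_list <- function(report) {
  list(
    alpha = report$alpha,
    p_method = report$p_method,
    n_trials = report$n_trials,
    behavioural = report$behavioural,
    sers_baseline = report$sers_baseline,
    memory_quality = list(
      retained_terms = report$memory_quality$terms,
      selection_trace = report$memory_quality$trace,
      coefficients = report$memory_quality$final$coefficients,
      singular = report$memory_quality$final$singular,
      random = report$memory_quality$final$random),
    encoding_strength = list(
      lr_n_study = report$encoding_strength$lr_n_study,
      interactions = report$encoding_strength$interactions,
      joint = report$encoding_strength$joint,
      joint_f = report$encoding_strength$joint_f,
      joint_f_replay = report$encoding_strength$joint_f_replay),
    notes = report$notes)
}
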