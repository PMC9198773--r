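#' Default random-effects structure
#'
#' Participants and images enter every model as crossed random
#' intercepts; participants additionally receive a random slope for
#' image type. When that slope renders a fit singular, [fit_mixed()] can
#' fall back to the intercepts-only structure.
#'
#' @param slope Include the participant-level random slope for image type?
#' @return A one-sided random-effects formula fragment as a string.
#' @export
default_random <- function(slope = TRUE) {
  if (slope) "(1 + image_type | participant) + (1 | image)"
  else "(1 | participant) + (1 | image)"
}

normalize_term <- function(t) {
  vapply(strsplit(t, ":", fixed = TRUE),
         function(v) paste(sort(v), collapse = ":"), character(1))
}

#' Fit a mixed-effects model with a fixed reporting contract
#'
#' Thin, contract-stable wrapper around `lmerTest::lmer()` (Gaussian
#' responses; Satterthwaite degrees of freedom for coefficient tests)
#' and `lme4::glmer()` (binomial responses; Wald z tests). Gaussian
#' models intended for final reporting are fitted by REML; models
#' entering likelihood-ratio comparisons must be fitted with
#' `reml = FALSE`.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (e.g.
#'   `c("image_type", "replay_position", "image_type:replay_shape")`);
#'   empty for an intercept-only (unconditional) model.
#' @param data Data frame containing response, predictors, `participant`
#'   and `image`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param reml Fit Gaussian models by REML? Ignored for binomial.
#' @param random Random-effects specification string; see
#'   [default_random()].
#' @param singular_fallback On a singular fit with a random slope,
#'   automatically refit with random intercepts only (recorded in the
#'   result).
#' @return A `replay_fit` object: list with the fitted `model`, a
#'   `coefficients` tibble (term, estimate, std_error, statistic, df,
#'   p_value), `deviance` (-2 log-likelihood), `logLik`, `n_obs`,
#'   `converged`, `singular`, `fallback_used`, `p_method` and the spec
#'   fields.
#' @export
fit_mixed <- function(response, fixed, data,
                      family = c("gaussian", "binomial"),
                      reml = TRUE, random = default_random(),
                      singular_fallback = TRUE) {
  family <- match.arg(family)
  if (!response %in% names(data))
    stop("response column `", response, "` not found", call. = FALSE)
  missing_cols <- setdiff(unique(unlist(strsplit(fixed, ":", fixed = TRUE))),
                          names(data))
  if (length(missing_cols))
    stop("missing predictor columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (length(unique(data$participant)) < 2L || length(unique(data$image)) < 2L)
    stop("need at least 2 participants and 2 images", call. = FALSE)

  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  form <- stats::as.formula(paste(response, "~", rhs, "+", random))
  fit_one <- function(form) {
    if (family == "gaussian") {
      suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = data, REML = reml)))
    } else {
      suppressMessages(suppressWarnings(
        lme4::glmer(form, data = data, family = stats::binomial())))
    }
  }
  fit <- fit_one(form)
  fallback_used <- FALSE
  if (lme4::isSingular(fit) && singular_fallback && grepl("image_type \\|", random)) {
    random <- default_random(slope = FALSE)
    form <- stats::as.formula(paste(response, "~", rhs, "+", random))
    fit <- fit_one(form)
    fallback_used <- TRUE
  }

  cf <- as.data.frame(stats::coef(summary(fit)))
  if (family == "gaussian") {
    coefs <- tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                            std_error = cf[, "Std. Error"], df = cf[, "df"],
                            statistic = cf[, "t value"],
                            p_value = cf[, "Pr(>|t|)"])
    p_method <- "satterthwaite"
  } else {
    coefs <- tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                            std_error = cf[, "Std. Error"], df = NA_real_,
                            statistic = cf[, "z value"],
                            p_value = cf[, "Pr(>|z|)"])
    p_method <- "wald_z"
  }
  ll <- as.numeric(stats::logLik(fit))
  structure(list(model = fit, response = response,
                 fixed = normalize_term(fixed), random = random,
                 family = family, reml = if (family == "gaussian") reml else FALSE,
                 coefficients = coefs, logLik = ll, deviance = -2 * ll,
                 df = attr(stats::logLik(fit), "df"),
                 n_obs = stats::nobs(fit),
                 converged = length(fit@optinfo$conv$lme4$messages) == 0L,
                 singular = lme4::isSingular(fit),
                 fallback_used = fallback_used, p_method = p_method),
            class = "replay_fit")
}

#' @export
print.replay_fit <- function(x, ...) {
  cat(sprintf("<replay_fit> %s ~ %s + %s  [%s, %s]\n", x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$random, x$family, if (x$reml) "REML" else "ML"))
  print(x$coefficients)
  if (x$fallback_used) cat("note: singular fit; refitted with random intercepts only\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' Chi-squared test comparing two maximum-likelihood fits of nested
#' fixed-effect structures on the same rows: the statistic is the
#' deviance of the reduced model minus the deviance of the full model,
#' with degrees of freedom equal to the parameter-count difference.
#'
#' @param full,reduced `replay_fit` objects fitted with `reml = FALSE`,
#'   `reduced` nested in `full`.
#' @return A list with `chisq`, `df` and `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "replay_fit"), inherits(reduced, "replay_fit"))
  if (full$reml || reduced$reml)
    stop("likelihood-ratio tests require maximum-likelihood fits (reml = FALSE)",
         call. = FALSE)
  if (!identical(full$family, reduced$family) ||
      !identical(full$response, reduced$response))
    stop("models must share response and family", call. = FALSE)
  if (!all(reduced$fixed %in% full$fixed))
    stop("`reduced` is not nested in `full`", call. = FALSE)
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted on different numbers of rows", call. = FALSE)
  chisq <- max(0, reduced$deviance - full$deviance)
  df <- full$df - reduced$df
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p_value = p)
}

# a term is removable when no other term's variable set strictly contains it
removable_terms <- function(terms) {
  if (!length(terms)) return(character(0))
  vars <- strsplit(terms, ":", fixed = TRUE)
  keep <- vapply(seq_along(terms), function(i) {
    !any(vapply(seq_along(terms), function(j) {
      j != i && all(vars[[i]] %in% vars[[j]])
    }, logical(1)))
  }, logical(1))
  terms[keep]
}

#' Backward selection by likelihood-ratio tests
#'
#' Starting from a maximal fixed-effects structure, repeatedly removes
#' the least significant removable term: at each step every term not
#' contained in a remaining higher-order interaction (marginality is
#' respected) is tested by a likelihood-ratio test against the current
#' model, and the term with the largest p-value is dropped if that
#' p-value is at or above `alpha`. Selection stops when every removable
#' term tests significant, or none remain. All comparisons use
#' maximum-likelihood fits; the final Gaussian model is refitted by REML
#' for reporting.
#'
#' @param response Response column name.
#' @param fixed Character vector of candidate fixed-effect terms (the
#'   maximal model).
#' @param data Model data frame.
#' @param family,random As in [fit_mixed()].
#' @param alpha Retention threshold for the likelihood-ratio p-value.
#' @return A `selection_trace` object: list with `trace` (tibble of
#'   step, dropped, chisq, df, p_value), `final` (`replay_fit` refitted
#'   by REML where applicable), `terms` retained, and `alpha`.
#' @export
backward_select <- function(response, fixed, data,
                            family = c("gaussian", "binomial"),
                            random = default_random(), alpha = 0.05) {
  family <- match.arg(family)
  current <- normalize_term(fixed)
  trace <- list()
  # settle the random structure on the maximal model, then hold it fixed so
  # every likelihood-ratio comparison is between commensurable fits
  full_fit <- if (length(current))
    fit_mixed(response, current, data, family = family,
              reml = FALSE, random = random) else NULL
  if (!is.null(full_fit)) random <- full_fit$random
  step <- 0L
  while (length(current)) {
    if (is.null(full_fit))
      full_fit <- fit_mixed(response, current, data, family = family,
                            reml = FALSE, random = random,
                            singular_fallback = FALSE)
    cand <- removable_terms(current)
    if (!length(cand)) break
    tests <- lapply(cand, function(t) {
      red <- fit_mixed(response, setdiff(current, t), data, family = family,
                       reml = FALSE, random = random,
                       singular_fallback = FALSE)
      c(list(fit = red), lr_test(full_fit, red))
    })
    ps <- vapply(tests, function(z) z$p_value, numeric(1))
    worst <- which.max(ps)
    if (ps[worst] < alpha) break
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, dropped = cand[worst],
                                    chisq = tests[[worst]]$chisq,
                                    df = tests[[worst]]$df,
                                    p_value = ps[worst])
    current <- setdiff(current, cand[worst])
    full_fit <- tests[[worst]]$fit
  }
  final <- fit_mixed(response, current, data, family = family,
                     reml = (family == "gaussian"), random = random,
                     singular_fallback = FALSE)
  structure(list(trace = dplyr::bind_rows(trace), final = final,
                 terms = current, alpha = alpha, random = random),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> retained:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
      sprintf(" [alpha = %g]\n", x$alpha))
  if (nrow(x$trace)) print(x$trace) else cat("no terms dropped\n")
  invisible(x)
}

#' SERS-versus-baseline replay contrast
#'
#' Tests whether the mean replay score (SERS minus baseline) on one
#' dimension differs from zero, using a linear mixed model of the paired
#' differences with crossed random intercepts for participant and image:
#' `replay ~ 1 + (1 | participant) + (1 | image)`. This is the paired
#' formulation of the SERS-versus-baseline contrast. Reported are the
#' REML/Satterthwaite test of the intercept and the likelihood-ratio
#' chi-squared against the zero-intercept model.
#'
#' @param records Replay table from [replay_scores()].
#' @param dimension One of `"position"`, `"duration"`, `"shape"`,
#'   `"direction"`, `"length"`.
#' @param image_type Optional: restrict to `"scene"` or
#'   `"object_arrangement"`.
#' @param method `"lmm"` (default) fits the mixed model of the paired
#'   differences and reports the Satterthwaite test plus the
#'   likelihood-ratio chi-squared. `"participant"` performs a one-sample
#'   t test on the per-participant mean replay. The participant-level
#'   test remains exactly calibrated when records within a participant
#'   are mutually dependent — as they are by construction, since every
#'   record's baseline shares comparisons with the other records — and
#'   is therefore the method used for calibration checks; the mixed
#'   model, which conditions on independent record-level residuals, is
#'   conservative under such dependence.
#' @return One-row tibble with the estimate and tests.
#' @export
replay_contrast <- function(records, dimension, image_type = NULL,
                            method = c("lmm", "participant")) {
  dimension <- match.arg(dimension, mm_dimensions)
  method <- match.arg(method)
  d <- records
  if (!is.null(image_type)) d <- d[d$image_type == image_type, ]
  d$.y <- d[[paste0("replay_", dimension)]]
  if (method == "participant") {
    pm <- tapply(d$.y, d$participant, mean)
    tt <- stats::t.test(pm)
    return(tibble::tibble(dimension = dimension,
                          image_type = if (is.null(image_type)) "all" else image_type,
                          estimate = unname(tt$estimate),
                          std_error = unname(tt$stderr),
                          df = unname(tt$parameter),
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value,
                          chisq = NA_real_, df_lr = NA_real_, p_lr = NA_real_,
                          n = nrow(d)))
  }
  reml <- suppressMessages(suppressWarnings(
    lmerTest::lmer(.y ~ 1 + (1 | participant) + (1 | image), data = d)))
  cf <- stats::coef(summary(reml))
  ml1 <- suppressMessages(suppressWarnings(
    lme4::lmer(.y ~ 1 + (1 | participant) + (1 | image), data = d, REML = FALSE)))
  ml0 <- suppressMessages(suppressWarnings(
    lme4::lmer(.y ~ 0 + (1 | participant) + (1 | image), data = d, REML = FALSE)))
  chisq <- max(0, 2 * (as.numeric(stats::logLik(ml1)) - as.numeric(stats::logLik(ml0))))
  tibble::tibble(dimension = dimension,
                 image_type = if (is.null(image_type)) "all" else image_type,
                 estimate = cf[1, "Estimate"], std_error = cf[1, "Std. Error"],
                 df = cf[1, "df"], statistic = cf[1, "t value"],
                 p_value = cf[1, "Pr(>|t|)"],
                 chisq = chisq, df_lr = 1, p_lr = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 n = nrow(d))
}

#' Per-dimension, per-type SERS-versus-baseline table
#'
#' Runs [replay_contrast()] for every similarity dimension within each
#' image type. No correction for multiple comparisons is applied across
#' the five dimensions; interpret the five tests jointly with that in
#' mind.
#'
#' @param records Replay table from [replay_scores()].
#' @return Tibble of contrasts, one row per dimension x image type.
#' @export
sers_baseline_table <- function(records) {
  dplyr::bind_rows(lapply(unique(records$image_type), function(ty)
    dplyr::bind_rows(lapply(mm_dimensions, function(d)
      replay_contrast(records, d, image_type = ty)))))
}

#' Analytic power for detecting a correlation
#'
#' Power of the two-sided test of a product-moment correlation via the
#' Fisher z approximation: `atanh(r) * sqrt(n - 3)` is compared against
#' the standard-normal alpha quantiles.
#'
#' @param r True correlation under the alternative.
#' @param n Sample size.
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @examples
#' power_correlation(0.5, 60)  # > 0.9
#' @export
power_correlation <- function(r, n, alpha = 0.05) {
  stopifnot(abs(r) < 1, n > 3)
  z <- atanh(r) * sqrt(n - 3)
  za <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(z - za) + stats::pnorm(-z - za)
}

#' Analytic power for a standardized mean difference
#'
#' Power of the two-sided paired/one-sample t test of effect size `d`
#' via the noncentral t distribution.
#'
#' @param d Standardized effect size.
#' @param n Sample size (pairs).
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_mean_difference <- function(d, n, alpha = 0.05) {
  ncp <- d * sqrt(n)
  tc <- stats::qt(1 - alpha / 2, df = n - 1)
  stats::pt(-tc, df = n - 1, ncp = ncp) + 1 - stats::pt(tc, df = n - 1, ncp = ncp)
}
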