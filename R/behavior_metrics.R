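# Behavioral outcome measures: estimation error, extreme-jar bias,
# winsorization, and the trial-wise bias test with a subject covariate.

#' Experienced proportion and estimation error per trial
#'
#' The experienced proportion theta_t is the best unbiased estimate of the
#' jar's blue-marble proportion given the samples actually shown on trial t:
#' pooled total blue / total marbles by default, or the mean of per-sample
#' proportions. Estimation error is `abs(theta_t - reported_estimate)`.
#'
#' @param data Long behavior tibble (one row per trial and sample) with
#'   `trial_id`, `n_blue`, `n_red`, `reported_estimate`, and optionally
#'   `subject_id`, `p_blue`, `valid`.
#' @param method `"pooled"` (default) or `"mean_of_samples"`.
#' @return One row per valid trial: grouping ids, `p_blue` (if present),
#'   `experienced`, `reported_estimate`, `error`.
#' @export
estimation_errors <- function(data, method = c("pooled", "mean_of_samples")) {
  method <- match.arg(method)
  if ("valid" %in% names(data)) data <- dplyr::filter(data, .data$valid)
  data <- dplyr::filter(data, !is.na(.data$reported_estimate))
  keys <- intersect(c("subject_id", "trial_id"), names(data))
  extra <- intersect(c("block_id", "jar_id", "p_blue"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(extra), dplyr::first),
      experienced = if (method == "pooled") {
        sum(.data$n_blue) / sum(.data$n_blue + .data$n_red)
      } else {
        mean(.data$n_blue / (.data$n_blue + .data$n_red))
      },
      reported_estimate = dplyr::first(.data$reported_estimate),
      .groups = "drop"
    ) |>
    dplyr::mutate(error = abs(.data$experienced - .data$reported_estimate))
}

#' Median estimation error of one subject
#'
#' @param errors Per-trial error tibble from [estimation_errors()] (or a
#'   numeric vector of errors).
#' @return The median per-trial estimation error.
#' @export
subject_median_error <- function(errors) {
  x <- if (is.data.frame(errors)) errors$error else errors
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("No valid trials.")
  median(x)
}

#' Extreme-jar bias slope
#'
#' Unstandardized least-squares slope of trial-wise estimation error on the
#' jar's marble-ratio distance from 50:50 (`abs(p_blue - 0.5)`). A positive
#' slope means larger errors for more extreme jars (under-extremity).
#'
#' @param errors Per-trial tibble with `error` and `p_blue` columns.
#' @return The fitted slope.
#' @export
extreme_jar_bias <- function(errors) {
  distance <- abs(errors$p_blue - 0.5)
  if (length(unique(distance)) < 3) {
    abort("Need at least 3 distinct jar distances.")
  }
  unname(coef(lm(errors$error ~ distance))[2L])
}

#' Group-level trial-wise bias test
#'
#' Least-squares model predicting trial-wise estimation error from the jar's
#' distance from 50:50 with subject identity as fixed indicator covariates.
#' Reports the distance term's F statistic (entered last), p value and
#' semi-partial eta squared (its sequential sum of squares over the total
#' sum of squares).
#'
#' @param errors Per-trial tibble with `error`, `p_blue`, `subject_id`.
#' @return A one-row tibble: `estimate` (distance slope), `F`, `df1`, `df2`,
#'   `p_value`, `eta_sq_partial`.
#' @export
trialwise_bias_test <- function(errors) {
  d <- tibble::tibble(
    error = errors$error,
    distance = abs(errors$p_blue - 0.5),
    subject = factor(errors$subject_id %||% 1)
  )
  multi <- nlevels(d$subject) > 1
  full <- if (multi) lm(error ~ subject + distance, data = d)
          else lm(error ~ distance, data = d)
  if (any(is.na(coef(full)))) abort("Rank-deficient design.")
  reduced <- if (multi) lm(error ~ subject, data = d)
             else lm(error ~ 1, data = d)
  a <- anova(reduced, full)
  ss_total <- sum((d$error - mean(d$error))^2)
  tibble::tibble(
    estimate = unname(coef(full)["distance"]),
    F = a$F[2L],
    df1 = a$Df[2L],
    df2 = a$Res.Df[2L],
    p_value = a$`Pr(>F)`[2L],
    eta_sq_partial = a$`Sum of Sq`[2L] / ss_total
  )
}

#' Winsorize univariate outliers
#'
#' Tukey-fence winsorization: values beyond 1.5 interquartile ranges from
#' the 25th / 75th percentile are replaced by the most extreme value inside
#' the fences. Quartiles use the default linear-interpolation definition.
#' Idempotent.
#'
#' @param x Numeric vector (length >= 4).
#' @return `x` with outlying values imputed.
#' @export
winsorize <- function(x) {
  if (length(x) < 4) abort("Need at least 4 values to winsorize.")
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  inside <- x >= fence[1] & x <= fence[2]
  if (!any(inside, na.rm = TRUE)) return(x)
  x[which(x < fence[1])] <- min(x[inside], na.rm = TRUE)
  x[which(x > fence[2])] <- max(x[inside], na.rm = TRUE)
  x
}

#' Per-subject behavioral summary
#'
#' @param data Long multi-subject behavior tibble.
#' @param winsorize_group Winsorize the summary measures across subjects
#'   (recommended for group analyses; default TRUE).
#' @param method Experienced-proportion definition, see [estimation_errors()].
#' @return A tibble with one row per subject: `subject_id`, `median_error`,
#'   `extreme_jar_bias`, plus `*_winsorized` flags when group winsorization
#'   changed a value.
#' @export
behavior_summary <- function(data, winsorize_group = TRUE,
                             method = c("pooled", "mean_of_samples")) {
  errs <- estimation_errors(data, method = method)
  out <- errs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ tibble::tibble(
      median_error = subject_median_error(.x),
      extreme_jar_bias = extreme_jar_bias(.x)
    )) |>
    dplyr::ungroup()
  if (winsorize_group && nrow(out) >= 4) {
    me <- winsorize(out$median_error)
    bias <- winsorize(out$extreme_jar_bias)
    out$median_error_winsorized <- me != out$median_error
    out$extreme_jar_bias_winsorized <- bias != out$extreme_jar_bias
    out$median_error <- me
    out$extreme_jar_bias <- bias
  }
  out
}
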