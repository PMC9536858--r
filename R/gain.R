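# Threshold-linear decomposition of inhibition. Ordering responses from
# largest to smallest under control conditions, normalizing both conditions
# to the largest control response, and regressing the inhibited responses
# on the control responses yields a line whose slope captures the
# proportional (divisive) component of suppression and whose intercept the
# subtractive component; slope 1 / intercept 0 means no effect.

#' Assemble matched tuning curves for the threshold-linear fit
#'
#' Orders the control responses from largest to smallest (ties broken by
#' the incoming — panel — order, recorded in the output), permutes the
#' light-condition responses by the *control* ordering (never independently
#' sorted), and normalizes both vectors by the maximum control response.
#'
#' @param control,light Matched numeric response vectors (same stimuli or
#'   mouth-light frequencies, same order).
#' @param labels Optional labels for the entries (stimuli / frequencies).
#' @return List of class `tuning_curve`: `control` (nonincreasing, max 1),
#'   `light`, `order` (permutation applied), `labels` (reordered), `ties`
#'   (were there control ties broken by input order?), `norm` (the
#'   normalizer, original units).
#' @export
tuning_curve_assembly <- function(control, light, labels = NULL) {
  if (length(control) != length(light)) {
    stop("control and light response sets do not match", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(control)) {
    stop("labels length mismatch", call. = FALSE)
  }
  m <- max(control)
  if (m <= 0) stop("maximum control response must be > 0", call. = FALSE)
  ord <- order(-control) # stable: ties keep input (panel) order
  structure(
    list(control = unname(control[ord]) / m, light = unname(light[ord]) / m,
         order = ord, labels = if (is.null(labels)) NULL else labels[ord],
         ties = anyDuplicated(control) > 0, norm = m),
    class = "tuning_curve"
  )
}

#' Threshold-linear divisive/subtractive fit
#'
#' Fits ordinary least squares of normalized inhibited responses on
#' normalized control responses after [tuning_curve_assembly()]. With
#' `scope = "per_neuron"`, `control` and `light` are one neuron's matched
#' response vectors. With `scope = "population_mean"`, they are matrices
#' (neurons x responses): each neuron's curves are assembled individually,
#' then the normalized ordered responses are averaged across neurons at
#' each rank before the single population fit — the headline population
#' decomposition. Inference on slope != 1 and intercept != 0 uses standard
#' linear-model t statistics; because ordered (and, for the population
#' scope, averaged) points are not independent observations, these p-values
#' are descriptive and labeled as such.
#'
#' @param control,light Numeric vectors (per-neuron scope) or matrices with
#'   one row per neuron (population scope). At least 3 matched pairs.
#' @param scope `"per_neuron"` or `"population_mean"`.
#' @param labels Optional response labels (per-neuron scope only).
#' @return List of class `gain_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_slope_ne_1`, `p_intercept_ne_0`, `n`, `scope`, `control`, `light`
#'   (the points actually fitted), `inference` (a note on the descriptive
#'   status of the p-values).
#' @examples
#' ctrl <- c(1, 0.7, 0.4, 0.2, 0.05)
#' fit <- threshold_linear_fit(ctrl, 0.5 * ctrl)
#' fit$slope # 0.5: purely divisive suppression
#' @export
threshold_linear_fit <- function(control, light,
                                 scope = c("per_neuron", "population_mean"),
                                 labels = NULL) {
  scope <- match.arg(scope)
  if (scope == "population_mean") {
    control <- as.matrix(control)
    light <- as.matrix(light)
    if (!all(dim(control) == dim(light))) {
      stop("control and light matrices do not match", call. = FALSE)
    }
    curves <- lapply(seq_len(nrow(control)), function(i) {
      tuning_curve_assembly(control[i, ], light[i, ])
    })
    x <- colMeans(do.call(rbind, lapply(curves, `[[`, "control")))
    y <- colMeans(do.call(rbind, lapply(curves, `[[`, "light")))
  } else {
    tc <- tuning_curve_assembly(control, light, labels)
    x <- tc$control
    y <- tc$light
  }
  if (length(x) < 3) stop("need >= 3 matched response pairs", call. = FALSE)

  fit <- stats::lm(y ~ x)
  # collinear inputs (e.g. the no-inhibition identity) fit exactly;
  # suppress the resulting "essentially perfect fit" warning
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["x", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  df <- fit$df.residual
  p_slope <- 2 * stats::pt(-abs((slope - 1) / cf["x", "Std. Error"]), df)
  p_int <- 2 * stats::pt(-abs(intercept / cf["(Intercept)", "Std. Error"]), df)

  structure(
    list(slope = slope, intercept = intercept,
         r_squared = suppressWarnings(summary(fit))$r.squared,
         p_slope_ne_1 = p_slope, p_intercept_ne_0 = p_int,
         n = length(x), scope = scope, control = x, light = y,
         inference = paste("p-values are descriptive: ordered, normalized",
                           "(and population-averaged) points are not",
                           "independent observations")),
    class = "gain_fit"
  )
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf(
    "<gain_fit> (%s, n = %d): slope %.3f, intercept %.3f, r^2 %.3f\n",
    x$scope, x$n, x$slope, x$intercept, x$r_squared
  ))
  invisible(x)
}

#' Threshold-linear fit from response profiles
#'
#' Convenience wrapper: extracts matched control / brain-light net-response
#' vectors from a list of [response_profile] objects and runs the
#' population-mean threshold-linear decomposition.
#'
#' @param profiles List of [response_profile] objects with both conditions.
#' @param stimuli Stimulus order; default taken from the first profile.
#' @return A `gain_fit` (population-mean scope).
#' @export
gain_from_profiles <- function(profiles, stimuli = NULL) {
  ctrl <- profile_matrix(profiles, "control", stimuli)
  lt <- profile_matrix(profiles, "light_br", colnames(ctrl))
  threshold_linear_fit(ctrl, lt, scope = "population_mean")
}
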