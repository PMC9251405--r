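#' Precision configuration for the Bayesian fusion
#'
#' `h_prior` and `h_sensor` rescale the variance (inverse precision) of the
#' network prediction and of the sensory sample respectively: values above
#' 1 make a signal less precise (less attended), values below 1 make it
#' more precise.  `sigma_sensor2` is the base sensory variance; its default
#' 0.05 matches the constant used with the hand-drawn stimuli, and
#' [estimate_sensor_variance()] recomputes it from a dataset when
#' `estimate_from_data` is set.
#'
#' @param h_prior Positive multiplier on the prediction variance.
#' @param h_sensor Positive multiplier on the sensory variance.
#' @param sigma_sensor2 Base sensory variance, a positive scalar or a
#'   D-vector.
#' @param estimate_from_data If TRUE, callers that hold a dataset should
#'   replace `sigma_sensor2` by [estimate_sensor_variance()].
#' @return A list of class `precision_config`.
#' @export
precision_config <- function(h_prior = 1, h_sensor = 1, sigma_sensor2 = 0.05,
                             estimate_from_data = FALSE) {
  vals <- c(h_prior = h_prior, h_sensor = h_sensor, sigma_sensor2)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("h_prior, h_sensor and sigma_sensor2 must be strictly positive and finite")
  structure(list(h_prior = h_prior, h_sensor = h_sensor,
                 sigma_sensor2 = sigma_sensor2,
                 estimate_from_data = isTRUE(estimate_from_data)),
            class = "precision_config")
}

#' @export
print.precision_config <- function(x, ...) {
  cat(sprintf("<precision_config> H_prior = %g, H_sensor = %g, sigma_sensor2 = %s\n",
              x$h_prior, x$h_sensor, paste(signif(x$sigma_sensor2, 4), collapse = ", ")))
  invisible(x)
}

#' Precision-weighted fusion of prediction and sensory input
#'
#' Componentwise product of the two Gaussians after variance scaling:
#' `sigma_post^2 = (Hs ss2 * Hp sn2) / (Hs ss2 + Hp sn2)` and
#' `mu_post = sigma_post^2 * (mu_net / (Hp sn2) + x / (Hs ss2))`.
#' The posterior mean is a convex combination of the two means; scaling
#' both H factors jointly leaves the mean unchanged while rescaling the
#' posterior variance — relative precision sets where the posterior sits,
#' absolute precision how sharp it is.
#'
#' @param mu_net D-vector, predicted mean (top-down prior).
#' @param sigma2_net D-vector of strictly positive prediction variances.
#' @param x D-vector, sensory sample (bottom-up input).
#' @param cfg A [precision_config()].
#' @return List with `mean` and `variance` (both D-vectors).
#' @export
integrate_signals <- function(mu_net, sigma2_net, x, cfg = precision_config()) {
  if (any(!is.finite(sigma2_net)) || any(sigma2_net <= 0))
    stop("prediction variances must be strictly positive")
  ss2 <- rep(cfg$sigma_sensor2, length.out = length(mu_net))
  vp <- cfg$h_prior * sigma2_net
  vs <- cfg$h_sensor * ss2
  vpost <- (vs * vp) / (vs + vp)
  list(mean = vpost * (mu_net / vp + x / vs), variance = vpost)
}

#' Estimate the base sensory variance from a dataset
#'
#' The per-dimension variance of the one-step increments of the training
#' trajectories, averaged across dimensions — the "actual variance present
#' in the input signal".  The result is floored at `1e-6`.
#'
#' @param dataset A [build_dataset()] result.
#' @param floor Lower clamp for degenerate (constant) input.
#' @return A positive scalar.
#' @export
estimate_sensor_variance <- function(dataset, floor = 1e-6) {
  train <- training_trajectories(dataset)
  if (length(train) < 1L) stop("dataset has no training trajectories")
  incs <- do.call(rbind, lapply(train, function(tr) diff(tr$points)))
  if (is.null(incs) || nrow(incs) < 2L)
    stop("cannot estimate sensor variance from fewer than two increments")
  max(mean(apply(incs, 2, var)), floor)
}
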