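#' Specification of the simulated ordinal observers
#'
#' Latent-variable stand-in for human raters scoring image quality from 4 (no
#' visible motion artifacts) down to 1 (severe motion artifacts). All
#' observers share the same three latent cutpoints on the quality-metric axis
#' but draw independent logistic noise.
#'
#' @param n_observers integer >= 2.
#' @param thresholds strictly increasing reals of length 3: cutpoints between
#'   categories 4|3, 3|2 and 2|1 on the metric axis.
#' @param noise_scale positive scale of the logistic latent noise.
#' @param seed integer seed.
#' @return object of class `observer_spec`.
#' @export
observer_spec <- function(n_observers = 2, thresholds, noise_scale = 0.5, seed = 1L) {
  stopifnot(n_observers >= 2, length(thresholds) == 3,
            all(diff(thresholds) > 0), noise_scale > 0)
  structure(list(n_observers = as.integer(n_observers),
                 thresholds = as.numeric(thresholds),
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "observer_spec")
}

#' Calibrate observer cutpoints from a metric distribution
#'
#' Places the three cutpoints at the quartiles of the observed quality-metric
#' values so that, under low noise, the four categories are roughly balanced.
#'
#' @param metric_values numeric vector of metric values (e.g. gradient entropy).
#' @inheritParams observer_spec
#' @return an [observer_spec()].
#' @export
calibrate_observer_spec <- function(metric_values, n_observers = 2,
                                    noise_scale = 0.5, seed = 1L) {
  th <- as.numeric(stats::quantile(metric_values, c(0.25, 0.5, 0.75)))
  if (any(diff(th) <= 0)) {  # degenerate metric distribution
    eps <- max(1e-6, 1e-6 * abs(th[2]))
    th <- th[2] + c(-eps, 0, eps)
  }
  observer_spec(n_observers = n_observers, thresholds = th,
                noise_scale = noise_scale, seed = seed)
}

#' Simulate ordinal observer scores
#'
#' Each observer's score for an image is `4 - #(thresholds below metric +
#' noise)`, clipped to 1..4, with independent logistic noise per observer and
#' image. In the noiseless limit the score is a deterministic step function of
#' the metric.
#'
#' @param metric_values finite numeric vector, one metric value per image.
#' @param spec an [observer_spec()].
#' @return integer matrix (image x observer) with values in 1..4.
#' @export
simulate_observer_scores <- function(metric_values, spec) {
  stopifnot(all(is.finite(metric_values)))
  n <- length(metric_values)
  set.seed(spec$seed)
  scores <- matrix(0L, n, spec$n_observers)
  for (ob in seq_len(spec$n_observers)) {
    latent <- metric_values + rlogis(n, location = 0, scale = spec$noise_scale)
    sc <- 4L - vapply(latent, function(v) sum(spec$thresholds < v), integer(1))
    scores[, ob] <- pmin(4L, pmax(1L, sc))
  }
  scores
}

#' Exact category probabilities of the latent observer model
#'
#' Closed-form P(score = s | metric) under the shared-threshold logistic
#' model; used as the independent reference for Monte-Carlo checks.
#'
#' @param metric scalar metric value.
#' @param spec an [observer_spec()].
#' @return numeric vector of probabilities for scores 1..4 (sums to 1).
#' @export
observer_score_probs <- function(metric, spec) {
  # P(score <= s) = P(metric + eps > threshold_{4-s}) for s = 1..3
  th <- spec$thresholds
  p_gt <- stats::plogis((metric - th) / spec$noise_scale)  # P(latent > th_j)
  # latent > th3 -> score 1; th2<latent<=th3 -> 2; th1<latent<=th2 -> 3; else 4
  c(p_gt[3], p_gt[2] - p_gt[3], p_gt[1] - p_gt[2], 1 - p_gt[1])
}
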