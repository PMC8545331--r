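# Pointwise negative log-likelihood contributions shared by the objective
# and both gradient methods.
#
# Normal noise:      g = 0.5 ((y - ybar)/sigma)^2 + 0.5 log(2 pi sigma^2)
# Log-normal noise:  the same on log-transformed values plus log(ybar).

nll_point <- function(y, ybar, sigma, distribution = "normal") {
  if (sigma <= 0) stop("noise scale sigma must be positive", call. = FALSE)
  if (distribution == "normal") {
    r <- y - ybar
    list(g = 0.5 * (r / sigma)^2 + 0.5 * log(2 * pi * sigma^2),
         dgdy = r / sigma^2,
         dgdsigma = -r^2 / sigma^3 + 1 / sigma)
  } else if (distribution %in% c("log-normal", "lognormal", "logNormal")) {
    if (y <= 0 || ybar <= 0)
      stop("log-normal noise requires positive simulated and measured values",
           call. = FALSE)
    r <- log(y) - log(ybar)
    list(g = 0.5 * (r / sigma)^2 + 0.5 * log(2 * pi * sigma^2) + log(ybar),
         dgdy = r / (sigma^2 * y),
         dgdsigma = -r^2 / sigma^3 + 1 / sigma)
  } else {
    stop("unsupported noise distribution '", distribution,
         "' (supported: normal, log-normal)", call. = FALSE)
  }
}

#' Negative log-likelihood of simulated outputs against measurements
#'
#' @param y_sim numeric vector of simulated observable values, one per
#'   measurement row.
#' @param measurements data.frame with a `measurement` column (and
#'   optionally `noiseDistribution`).
#' @param noise numeric vector of noise scales sigma, one per row (recycled
#'   if length 1).
#' @return scalar total negative log-likelihood.
#' @export
negloglik <- function(y_sim, measurements, noise) {
  n <- nrow(measurements)
  if (length(y_sim) != n)
    stop("y_sim must contain one simulated value per measurement row",
         call. = FALSE)
  if (anyNA(y_sim)) stop("missing simulated value", call. = FALSE)
  noise <- rep_len(noise, n)
  dist <- if ("noiseDistribution" %in% names(measurements))
    measurements$noiseDistribution else rep("normal", n)
  total <- 0
  for (i in seq_len(n))
    total <- total + nll_point(y_sim[i], measurements$measurement[i],
                               noise[i], dist[i])$g
  total
}
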