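# Loss family for waveform regression: point-by-point losses (MAE, RMSE,
# Huber, epsilon-insensitive Huber) and the waveform-similarity loss
# (negative Pearson), plus their combination and the multi-task sum.
# Each loss also has an analytic gradient wrt the prediction, used by the
# manual backprop in train().

#' Loss configuration
#'
#' @param name one of `"mae"`, `"rmse"`, `"huber"`, `"neg_pearson"`,
#'   `"huber_pearson"`, `"eps_huber"`.
#' @param delta Huber threshold (> 0, default 1).
#' @param epsilon insensitive zone half-width (>= 0, default 0.1).
#' @param alpha,beta multi-task weights for the pulse and respiration terms
#'   (default 1, 1; not both zero). The single-task heart-rate mode is
#'   `alpha = 1, beta = 0`.
#' @return validated list.
#' @export
lossConfig <- function(name = c("huber", "mae", "rmse", "neg_pearson",
                                "huber_pearson", "eps_huber"),
                       delta = 1, epsilon = 0.1, alpha = 1, beta = 1) {
  name <- match.arg(name)
  stopifnot(delta > 0, epsilon >= 0, alpha >= 0, beta >= 0)
  if (alpha == 0 && beta == 0) stop("alpha and beta cannot both be zero")
  list(name = name, delta = delta, epsilon = epsilon,
       alpha = alpha, beta = beta)
}

checkLengths <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 1) stop("empty input")
}

#' Huber loss
#'
#' Mean over samples of \eqn{e^2/2} when \eqn{|e| \le \delta} and
#' \eqn{\delta(|e| - \delta/2)} otherwise, \eqn{e = y - \hat y}: quadratic
#' near zero (RMSE-like), linear in the tails (MAE-like), continuous and
#' once-differentiable at \eqn{|e| = \delta}, with gradient magnitude
#' bounded by \eqn{\delta} (outlier robustness).
#'
#' @param y,yhat equal-length numeric vectors.
#' @param delta threshold (default 1).
#' @return scalar loss.
#' @export
huberLoss <- function(y, yhat, delta = 1) {
  checkLengths(y, yhat)
  e <- abs(y - yhat)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta)))
}

huberGrad <- function(y, yhat, delta = 1) {
  e <- yhat - y
  ifelse(abs(e) <= delta, e, delta * sign(e)) / length(y)
}

#' Epsilon-insensitive Huber loss
#'
#' Zero for \eqn{|e| \le \epsilon}, \eqn{(|e|-\epsilon)^2/2} for
#' \eqn{\epsilon < |e| \le \delta+\epsilon}, and
#' \eqn{\delta(|e|-\epsilon) - \delta^2/2} beyond; continuous at both
#' breakpoints, and identical to [huberLoss()] when `epsilon = 0`.
#'
#' @param y,yhat equal-length numeric vectors.
#' @param delta Huber threshold (default 1).
#' @param epsilon insensitive half-width (default 0.1).
#' @return scalar loss.
#' @export
epsHuberLoss <- function(y, yhat, delta = 1, epsilon = 0.1) {
  checkLengths(y, yhat)
  e <- abs(y - yhat)
  mean(ifelse(e <= epsilon, 0,
              ifelse(e <= delta + epsilon, 0.5 * (e - epsilon)^2,
                     delta * (e - epsilon) - 0.5 * delta^2)))
}

epsHuberGrad <- function(y, yhat, delta = 1, epsilon = 0.1) {
  e <- yhat - y
  a <- abs(e)
  g <- ifelse(a <= epsilon, 0,
              ifelse(a <= delta + epsilon, (a - epsilon), delta)) * sign(e)
  g / length(y)
}

#' Mean absolute error
#' @param y,yhat equal-length numeric vectors.
#' @return scalar loss.
#' @export
maeLoss <- function(y, yhat) {
  checkLengths(y, yhat)
  mean(abs(y - yhat))
}

maeGrad <- function(y, yhat) sign(yhat - y) / length(y)

#' Root mean squared error (as a training loss)
#'
#' The square root is applied after the batch mean, matching the printed
#' name; note its gradient `e / (N * rmse)` therefore differs from the MSE
#' gradient by the `1 / rmse` factor.
#'
#' @param y,yhat equal-length numeric vectors.
#' @return scalar loss.
#' @export
rmseLoss <- function(y, yhat) {
  checkLengths(y, yhat)
  sqrt(mean((y - yhat)^2))
}

rmseGrad <- function(y, yhat) {
  e <- yhat - y
  r <- sqrt(mean(e^2))
  if (r == 0) return(rep(0, length(y)))
  e / (length(y) * r)
}

#' Negative Pearson loss
#'
#' `1 - r(y, yhat)`: zero for any positive-affine match, 2 for a perfect
#' anti-correlation; invariant to positive affine transforms of either
#' argument. Constrains waveform shape rather than amplitude.
#'
#' @param y,yhat equal-length, non-constant numeric vectors.
#' @return scalar in `[0, 2]`.
#' @export
negPearsonLoss <- function(y, yhat) {
  checkLengths(y, yhat)
  if (sd(y) == 0 || sd(yhat) == 0)
    stop("degenerate input: correlation undefined for a constant series")
  1 - cor(y, yhat)
}

negPearsonGrad <- function(y, yhat) {
  yc <- y - mean(y)
  xc <- yhat - mean(yhat)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  if (sxx == 0 || syy == 0)
    stop("degenerate input: correlation undefined for a constant series")
  r <- sum(xc * yc) / sqrt(sxx * syy)
  -(yc / sqrt(sxx * syy) - r * xc / sxx)
}

#' Multi-task combination
#'
#' `alpha * loss_pulse + beta * loss_resp`; with `alpha = 1, beta = 0` this
#' is the single-task heart-rate objective.
#'
#' @param loss_pulse,loss_resp finite scalar losses.
#' @param alpha,beta nonnegative weights, not both zero.
#' @return scalar.
#' @export
multitaskLoss <- function(loss_pulse, loss_resp, alpha = 1, beta = 1) {
  if (alpha == 0 && beta == 0) stop("alpha and beta cannot both be zero")
  if (!is.finite(loss_pulse) || !is.finite(loss_resp))
    stop("component losses must be finite")
  alpha * loss_pulse + beta * loss_resp
}

# value + gradient dispatcher used by training
lossValueGrad <- function(y, yhat, cfg) {
  switch(cfg$name,
    huber = list(value = huberLoss(y, yhat, cfg$delta),
                 grad = huberGrad(y, yhat, cfg$delta)),
    eps_huber = list(value = epsHuberLoss(y, yhat, cfg$delta, cfg$epsilon),
                     grad = epsHuberGrad(y, yhat, cfg$delta, cfg$epsilon)),
    mae = list(value = maeLoss(y, yhat), grad = maeGrad(y, yhat)),
    rmse = list(value = rmseLoss(y, yhat), grad = rmseGrad(y, yhat)),
    neg_pearson = list(value = negPearsonLoss(y, yhat),
                       grad = negPearsonGrad(y, yhat)),
    huber_pearson = list(
      value = huberLoss(y, yhat, cfg$delta) + negPearsonLoss(y, yhat),
      grad = huberGrad(y, yhat, cfg$delta) + negPearsonGrad(y, yhat)),
    stop("unknown loss: ", cfg$name))
}
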