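# 3D central difference convolution (3D-CDC).
#
# For output location l0 the operator computes
#   sum_{ln in C} w(ln) x(l0 + ln)  +  theta * ( -x(l0) * sum_{ln in R} w(ln) )
# where C is the full receptive cube and R the set of offsets contributing
# the central-difference term. theta in [0, 1] trades off intensity
# information (vanilla convolution, theta = 0) against temporal-gradient
# information; R excludes the current-time spatial plane in the "temporal"
# variant and equals C in the "spatiotemporal" variant. The operator adds
# no parameters over a vanilla 3D convolution.
#
# Efficient form used here (mathematically identical): the difference term
# is a pointwise channel mix of x with the per-(in,out) sums of w over R,
# so cdc(x) = conv3d(x, w) - theta * x %*% sumR(w).

#' Receptive-cube and difference-offset sets for a CDC kernel
#'
#' @param kt,kh,kw odd kernel dimensions (time, height, width).
#' @param variant `"spatiotemporal"` (R = full cube C), `"temporal"`
#'   (R = offsets with nonzero temporal component) or `"vanilla"` (R empty,
#'   the difference term is disabled).
#' @return `list(C, R)`: integer matrices of `(dt, dh, dw)` offsets
#'   centered at 0, one row per tap.
#' @export
receptiveSets <- function(kt, kh, kw,
                          variant = c("temporal", "spatiotemporal", "vanilla")) {
  variant <- match.arg(variant)
  if (kt %% 2 == 0 || kh %% 2 == 0 || kw %% 2 == 0)
    stop("kernel dimensions must be odd so the cube has a center")
  off <- expand.grid(dt = seq_len(kt) - (kt + 1) / 2,
                     dh = seq_len(kh) - (kh + 1) / 2,
                     dw = seq_len(kw) - (kw + 1) / 2)
  C <- as.matrix(off)
  R <- switch(variant,
              spatiotemporal = C,
              temporal = C[C[, "dt"] != 0, , drop = FALSE],
              vanilla = C[0, , drop = FALSE])
  list(C = C, R = R)
}

# logical tap-inclusion vector over the kernel's (kt, kh, kw) flattening
# (dt fastest), matching the weight array layout
tapMaskR <- function(kt, kh, kw, variant) {
  if (variant == "vanilla") return(rep(FALSE, kt * kh * kw))
  dt <- rep(seq_len(kt) - (kt + 1) / 2, times = kh * kw)
  if (variant == "spatiotemporal") rep(TRUE, kt * kh * kw) else dt != 0
}

# per-(in, out) channel sums of the weights over the difference set R:
# a Cin x Cout matrix
sumWeightsR <- function(w, variant) {
  kd <- dim(w)
  m <- tapMaskR(kd[1], kd[2], kd[3], variant)
  wm <- matrix(w, nrow = kd[1] * kd[2] * kd[3])   # taps x (Cin*Cout)
  sums <- colSums(wm[m, , drop = FALSE])
  matrix(sums, kd[4], kd[5])
}

#' CDC kernel specification
#'
#' @param weights `(kt, kh, kw, Cin, Cout)` array of learnable weights.
#' @param theta trade-off between intensity and gradient terms, in `[0, 1]`
#'   (default 0.6).
#' @param variant see [receptiveSets()]; default `"temporal"`.
#' @return validated spec list.
#' @export
cdcKernelSpec <- function(weights, theta = 0.6,
                          variant = c("temporal", "spatiotemporal", "vanilla")) {
  variant <- match.arg(variant)
  kd <- dim(weights)
  if (length(kd) != 5) stop("weights must be a 5-d array")
  if (any(kd[1:3] %% 2 == 0)) stop("kernel dimensions must be odd")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  list(weights = weights, theta = theta, variant = variant)
}

#' 3D central difference convolution
#'
#' Zero-padded, stride-1, same-size output. With `theta = 0` (or variant
#' `"vanilla"`) the result equals a vanilla 3D convolution; with the
#' spatiotemporal variant and `theta = 1` a constant input yields exactly
#' the bias at interior positions.
#'
#' @param x `(T, H, W, Cin)` input array.
#' @param spec a [cdcKernelSpec()] (or a plain list with `weights`, `theta`,
#'   `variant`).
#' @param bias length-`Cout` bias (default zeros).
#' @return `(T, H, W, Cout)` output array.
#' @export
cdc3d <- function(x, spec, bias = NULL) {
  kd <- dim(spec$weights)
  if (dim(x)[4] != kd[4]) stop("input channels do not match the kernel")
  if (is.null(bias)) bias <- rep(0, kd[5])
  out <- .cppConv3dForward(x, spec$weights, bias)
  if (spec$theta > 0 && spec$variant != "vanilla") {
    sR <- sumWeightsR(spec$weights, spec$variant)
    P <- prod(dim(x)[1:3])
    diff_term <- matrix(x, P, kd[4]) %*% sR
    out <- out - spec$theta * array(diff_term, dim = dim(out))
  }
  out
}

# backward pass: gradients wrt input, weights, bias; need_dx = FALSE skips
# the input gradient (first layers, where it is never used)
cdc3dBackward <- function(x, spec, dout, need_dx = TRUE) {
  g <- .cppConv3dBackward(x, spec$weights, dout, need_dx)
  if (spec$theta > 0 && spec$variant != "vanilla") {
    kd <- dim(spec$weights)
    P <- prod(dim(x)[1:3])
    sR <- sumWeightsR(spec$weights, spec$variant)
    dmat <- matrix(dout, P, kd[5])
    if (need_dx)
      g$dx <- g$dx - spec$theta * array(dmat %*% t(sR), dim = dim(x))
    # d/dw for taps in R gains -theta * (x' dout) per (in, out) channel
    G <- crossprod(matrix(x, P, kd[4]), dmat)          # Cin x Cout
    m <- tapMaskR(kd[1], kd[2], kd[3], spec$variant)
    dwm <- matrix(g$dw, nrow = kd[1] * kd[2] * kd[3])
    dwm[m, ] <- dwm[m, ] - spec$theta * rep(as.vector(G), each = sum(m))
    g$dw <- array(dwm, dim = kd)
  }
  g
}

#' Vanilla 3D convolution
#'
#' Standard zero-padded stride-1 3D convolution; the `theta = 0` reference
#' for [cdc3d()] and the plain-3D ablation backbone.
#'
#' @param x `(T, H, W, Cin)` input array.
#' @param weights `(kt, kh, kw, Cin, Cout)` array.
#' @param bias length-`Cout` bias (default zeros).
#' @return `(T, H, W, Cout)` array.
#' @export
vanillaConv3d <- function(x, weights, bias = NULL) {
  if (is.null(bias)) bias <- rep(0, dim(weights)[5])
  .cppConv3dForward(x, weights, bias)
}
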