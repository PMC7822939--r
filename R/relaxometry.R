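#' Voxel-wise T1 mapping by the linearized variable-flip-angle method
#'
#' For each voxel the spoiled-GRE signal equation is linearized as
#' \deqn{S/\sin\alpha = E \cdot S/\tan\alpha + M_0 (1 - E), \quad
#'       E = e^{-TR/T_1},}
#' and an ordinary least-squares line is fitted to the points
#' \eqn{(X_i, Y_i) = (S_i/\tan\alpha_i,\ S_i/\sin\alpha_i)} over the flip
#' angles. T1 is recovered from the slope, `T1 = -TR / ln(slope)`, and
#' `M0 = intercept / (1 - slope)`. Any constant transverse-decay factor A
#' cancels in the slope, so T1 is unbiased by ignoring A.
#'
#' A voxel is marked invalid (`NaN` in the maps, `FALSE` in `valid_mask`)
#' when its slope falls outside `(0, 1)`, any of its signals is at or below
#' `signal_floor`, or the regressor variance is degenerate. Invalid voxels
#' never raise errors.
#'
#' @param stack A VFA-mode [simulate_acquisition()] result (or any
#'   `signal_stack` with `mode == "vfa"`).
#' @param signal_floor Signals at or below this level (a.u.) invalidate the
#'   voxel; default 0 (only non-positive signals excluded).
#' @return Object of class `t1_fit`: `t1_map`, `m0_map`, `slope_map`
#'   (3D arrays) and `valid_mask` (3D logical).
#' @export
fit_t1_vfa <- function(stack, signal_floor = 0) {
  stopifnot(inherits(stack, "signal_stack"))
  if (stack$protocol$mode != "vfa")
    stop("fit_t1_vfa requires a vfa-mode stack", call. = FALSE)
  fa <- stack$protocol$flip_angles
  if (length(unique(fa)) < 2L)
    stop("need >= 2 distinct flip angles", call. = FALSE)
  tr <- stack$protocol$tr
  dims <- dim(stack$frames)[-1]
  nf <- length(fa)
  s <- matrix(stack$frames, nrow = nf)       # frames x voxels
  a <- fa * pi / 180
  x <- s / tan(a)                            # recycles a down columns
  y <- s / sin(a)
  n <- nf
  sx <- colSums(x); sy <- colSums(y)
  sxx <- colSums(x * x); sxy <- colSums(x * y)
  varx <- sxx - sx^2 / n
  slope <- (sxy - sx * sy / n) / varx
  intercept <- (sy - slope * sx) / n
  ok <- is.finite(slope) & slope > 0 & slope < 1 &
        varx > 1e-12 * pmax(sxx, 1e-300) &
        colSums(s > signal_floor) == n
  t1 <- m0 <- rep(NaN, length(slope))
  t1[ok] <- -tr / log(slope[ok])
  m0[ok] <- intercept[ok] / (1 - slope[ok])
  slope[!ok] <- NaN
  structure(list(t1_map = array(t1, dims),
                 m0_map = array(m0, dims),
                 slope_map = array(slope, dims),
                 valid_mask = array(ok, dims),
                 tr = tr),
            class = "t1_fit")
}

#' Voxel-wise T2* mapping by log-linear mono-exponential fitting
#'
#' Fits `ln S = ln S0 - TE / T2*` by ordinary least squares over the echo
#' times of a multi-echo stack; `T2* = -1/slope`, `S0 = exp(intercept)`.
#' An optional weighted fit (weights `S^2`, the first-order variance
#' correction for log-transformed data) is available but not the default.
#'
#' A voxel is invalid when any of its signals is at or below `signal_floor`
#' (the log is undefined or unstable), the fitted slope is >= 0
#' (non-decaying), or the fitted T2* exceeds `t2s_cap`.
#'
#' @param stack A multiecho-mode `signal_stack`.
#' @param signal_floor Signals at or below this level invalidate the voxel;
#'   default 0.
#' @param t2s_cap Upper bound (ms) on credible T2*; default 200 ms, beyond
#'   any plaque-tissue value.
#' @param weighted Use `S^2`-weighted least squares instead of unweighted.
#' @return Object of class `t2s_fit`: `t2s_map`, `s0_map`, `valid_mask`.
#' @export
fit_t2star <- function(stack, signal_floor = 0, t2s_cap = 200,
                       weighted = FALSE) {
  stopifnot(inherits(stack, "signal_stack"))
  if (stack$protocol$mode != "multiecho")
    stop("fit_t2star requires a multiecho-mode stack", call. = FALSE)
  te <- stack$protocol$echo_times
  if (length(unique(te)) < 2L)
    stop("need >= 2 distinct echo times", call. = FALSE)
  dims <- dim(stack$frames)[-1]
  nf <- length(te)
  s <- matrix(stack$frames, nrow = nf)
  pos <- colSums(s > signal_floor & s > 0) == nf
  logs <- log(pmax(s, .Machine$double.xmin))
  if (weighted) {
    w <- s * s
    sw <- colSums(w)
    swx <- colSums(w * te); swy <- colSums(w * logs)
    swxx <- colSums(w * te * te); swxy <- colSums(w * te * logs)
    varx <- swxx - swx^2 / sw
    slope <- (swxy - swx * swy / sw) / varx
    intercept <- (swy - slope * swx) / sw
  } else {
    n <- nf
    sx <- sum(te); sxx <- sum(te * te)
    sy <- colSums(logs); sxy <- colSums(te * logs)
    varx <- sxx - sx^2 / n
    slope <- (sxy - sx * sy / n) / varx
    intercept <- (sy - slope * sx) / n
  }
  t2s <- -1 / slope
  ok <- pos & is.finite(slope) & slope < 0 & t2s <= t2s_cap
  t2s[!ok] <- NaN
  s0 <- ifelse(ok, exp(intercept), NaN)
  structure(list(t2s_map = array(t2s, dims),
                 s0_map = array(s0, dims),
                 valid_mask = array(ok, dims)),
            class = "t2s_fit")
}

#' Bundle registered T1 and T2* maps
#'
#' The two map acquisitions are assumed to image the specimen in the same
#' position, so registered maps share one voxel grid.
#'
#' @param t1_fit A [fit_t1_vfa()] result.
#' @param t2s_fit A [fit_t2star()] result.
#' @param registered Logical; when `TRUE` (default) the grids must agree.
#' @return Object of class `relaxation_maps`.
#' @export
relaxation_maps <- function(t1_fit, t2s_fit, registered = TRUE) {
  stopifnot(inherits(t1_fit, "t1_fit"), inherits(t2s_fit, "t2s_fit"))
  if (registered && !identical(dim(t1_fit$t1_map), dim(t2s_fit$t2s_map)))
    stop("registered maps must share one grid", call. = FALSE)
  structure(list(t1 = t1_fit, t2s = t2s_fit, registered = registered),
            class = "relaxation_maps")
}
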