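#' Spoiled gradient-echo steady-state signal
#'
#' Closed-form magnitude signal of a spoiled 3D gradient-echo sequence,
#' \deqn{S = M_0 \frac{1 - e^{-TR/T_1}}{1 - e^{-TR/T_1}\cos\alpha}
#'       \sin(\alpha)\, A,}
#' where the factor \eqn{A = e^{-TE/T_2^*}} accounts for transverse decay at
#' the (fixed) echo time and can be set to 1 to model the regime where
#' \eqn{TE \ll T_2^*} and A is ignored.
#'
#' All arguments are vectorized and recycled.
#'
#' @param m0 Equilibrium longitudinal magnetization (a.u.).
#' @param t1 Longitudinal relaxation time (ms), > 0.
#' @param tr Repetition time (ms), > 0.
#' @param alpha Flip angle (degrees), in `[0, 180)`.
#' @param a_factor Multiplicative transverse-decay factor A (default 1).
#' @return Signal amplitude (a.u.), same length as the recycled inputs.
#' @export
#' @examples
#' vfa_signal(1, 1000, 10, 20)  # ~0.0489
vfa_signal <- function(m0, t1, tr, alpha, a_factor = 1) {
  if (any(t1 <= 0)) stop("t1 must be > 0", call. = FALSE)
  if (any(tr <= 0)) stop("tr must be > 0", call. = FALSE)
  if (any(alpha < 0 | alpha >= 180))
    stop("alpha must be in [0, 180) degrees", call. = FALSE)
  a <- alpha * pi / 180
  e1 <- exp(-tr / t1)
  m0 * (1 - e1) / (1 - e1 * cos(a)) * sin(a) * a_factor
}

#' Mono-exponential T2* decay signal
#'
#' \deqn{S = S_0 e^{-TE/T_2^*}.}
#'
#' @param s0 Signal amplitude at TE = 0 (a.u.).
#' @param t2s Effective transverse relaxation time T2* (ms), > 0.
#' @param te Echo time (ms), >= 0.
#' @return Signal amplitude (a.u.).
#' @export
#' @examples
#' t2star_signal(1, 10, 10)  # exp(-1)
t2star_signal <- function(s0, t2s, te) {
  if (any(t2s <= 0)) stop("t2s must be > 0", call. = FALSE)
  if (any(te < 0)) stop("te must be >= 0", call. = FALSE)
  s0 * exp(-te / t2s)
}

#' Simulate a spoiled gradient-echo acquisition of a phantom
#'
#' Evaluates the forward model voxel-wise for every frame of the protocol.
#' In VFA mode each frame is [vfa_signal()] at one flip angle, with
#' `A = exp(-te_fixed / t2s_true)` computed from the ground truth (set
#' `use_a_factor = FALSE` to force A = 1). In multiecho mode the zero-echo
#' amplitude `S0` is the spoiled-GRE steady-state signal at the protocol's
#' flip angle and TR, and each frame is [t2star_signal()] at one echo time.
#'
#' Gaussian noise adds `N(0, sigma * Smax)` to each voxel; Rician noise
#' replaces S with `|S + n1 + i n2|`, `n1, n2 ~ N(0, sigma * Smax)`, where
#' `Smax` is the maximum noiseless signal over the stack. The noise draw is
#' deterministic given `protocol$seed`.
#'
#' @param phantom A [generate_phantom()] result.
#' @param protocol An [acquisition_protocol()].
#' @param use_a_factor Logical; include the transverse-decay factor A in the
#'   VFA forward model (default `TRUE`).
#' @return An object of class `signal_stack`: `frames` is a 4D array with
#'   axis 1 indexing the acquisition (flip angle or echo time) and axes 2-4
#'   the spatial grid; plus `protocol` and `phantom_id`.
#' @export
simulate_acquisition <- function(phantom, protocol, use_a_factor = TRUE) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(protocol, "acquisition_protocol"))
  dims <- dim(phantom$labels)
  nf <- n_frames(protocol)
  frames <- array(0, dim = c(nf, dims))
  if (protocol$mode == "vfa") {
    a_fac <- if (use_a_factor) exp(-protocol$te_fixed / phantom$t2s_true) else 1
    for (i in seq_len(nf))
      frames[i, , , ] <- vfa_signal(phantom$m0_true, phantom$t1_true,
                                    protocol$tr, protocol$flip_angles[i],
                                    a_fac)
  } else {
    s0 <- vfa_signal(phantom$m0_true, phantom$t1_true, protocol$tr,
                     protocol$flip_angle)
    for (i in seq_len(nf))
      frames[i, , , ] <- t2star_signal(s0, phantom$t2s_true,
                                       protocol$echo_times[i])
  }
  if (protocol$noise_model != "none" && protocol$noise_sigma > 0) {
    smax <- max(frames)
    sd_n <- protocol$noise_sigma * smax
    withr::with_seed(protocol$seed, {
      if (protocol$noise_model == "gaussian") {
        frames <- frames + array(stats::rnorm(length(frames), 0, sd_n),
                                 dim = dim(frames))
      } else {
        n1 <- array(stats::rnorm(length(frames), 0, sd_n), dim = dim(frames))
        n2 <- array(stats::rnorm(length(frames), 0, sd_n), dim = dim(frames))
        frames <- sqrt((frames + n1)^2 + n2^2)
      }
    })
  }
  structure(list(frames = frames, protocol = protocol,
                 phantom_id = phantom$plaque_id),
            class = "signal_stack")
}

#' @export
print.signal_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<signal_stack> %s  %s mode, %d frames, grid %s, noise %s (sigma %g)\n",
              x$phantom_id, x$protocol$mode, d[1],
              paste(d[-1], collapse = "x"),
              x$protocol$noise_model, x$protocol$noise_sigma))
  invisible(x)
}
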