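#' Parameters of the local-intensity-clustering level-set model
#'
#' The segmentation minimizes, by alternating updates, the energy
#' \deqn{E = \sum_y \sum_{i=1,2} \int K_\sigma(y-x) |I(x) - b(y) c_i|^2 M_i(\phi(x)) dx
#'       + \nu \, Length(\phi) + \mu \, DistReg(\phi)}
#' where the image is modelled as `I = b J + n` with a slowly varying
#' multiplicative bias `b`, a piecewise-constant true image `J` taking values
#' `c1` (liver) and `c2` (background), and zero-mean Gaussian noise `n`.
#' `K_sigma` is a truncated Gaussian window, `M1 = H_eps(phi)`,
#' `M2 = 1 - H_eps(phi)` with the smoothed Heaviside
#' `H_eps(phi) = (1 + (2/pi) atan(phi/eps)) / 2`, `Length` is the smoothed
#' contour length and `DistReg` the double-well distance regularizer keeping
#' `|grad phi|` near 1.
#'
#' @param kernel_scale Gaussian window sigma in pixels.
#' @param length_weight nu, weight of the contour-length penalty (intensity^2
#'   units; the default assumes a 0-255 intensity scale).
#' @param regularization_weight mu, weight of the distance regularizer.
#' @param heaviside_width eps of the smoothed Heaviside, pixels.
#' @param time_step explicit Euler step; stability requires
#'   `time_step * regularization_weight < 0.25`.
#' @param max_iters maximum alternating sweeps.
#' @param energy_tol relative energy-change convergence threshold.
#' @param bias_floor minimum allowed bias value when dividing `I / b`.
#' @return object of class `lic_params`.
#' @export
lic_params <- function(kernel_scale = 4,
                       length_weight = 0.002 * 255^2,
                       regularization_weight = 1,
                       heaviside_width = 1,
                       time_step = 0.1,
                       max_iters = 500L,
                       energy_tol = 1e-5,
                       bias_floor = 0.1) {
  if (kernel_scale <= 0) stop_param("kernel_scale must be > 0")
  if (heaviside_width <= 0) stop_param("heaviside_width must be > 0")
  if (time_step * regularization_weight >= 0.25) {
    stop_param("time_step * regularization_weight must be < 0.25 for stability")
  }
  if (max_iters < 1) stop_param("max_iters must be >= 1")
  structure(list(kernel_scale = kernel_scale, length_weight = length_weight,
                 regularization_weight = regularization_weight,
                 heaviside_width = heaviside_width, time_step = time_step,
                 max_iters = as.integer(max_iters), energy_tol = energy_tol,
                 bias_floor = bias_floor), class = "lic_params")
}

#' Wrap a 2-D intensity grid as a slice
#'
#' @param intensities numeric matrix (height x width), finite values.
#' @param pixel_spacing mm per pixel.
#' @param metadata optional named list of source identifiers.
#' @return object of class `lsn_slice`.
#' @export
lsn_slice <- function(intensities, pixel_spacing = 1, metadata = list()) {
  intensities <- as.matrix(intensities)
  if (!all(is.finite(intensities))) stop_domain("slice intensities must be finite")
  if (nrow(intensities) < 32 || ncol(intensities) < 32) {
    stop_domain("slice must be at least 32 x 32 pixels")
  }
  structure(list(intensities = intensities, pixel_spacing = pixel_spacing,
                 metadata = metadata), class = "lsn_slice")
}

smooth_heaviside <- function(phi, eps) 0.5 * (1 + (2 / pi) * atan(phi / eps))
smooth_delta <- function(phi, eps) (eps / pi) / (eps^2 + phi^2)

# Initial level-set state: binary-step phi, flat bias, region-mean clusters.
lic_init_state <- function(I, init_mask, c0 = 2) {
  if (!any(init_mask)) stop_param("init_mask must contain at least one foreground pixel")
  if (all(init_mask)) stop_param("init_mask must not cover the whole image")
  phi <- matrix(-c0, nrow(I), ncol(I))
  phi[init_mask] <- c0
  list(phi = phi, bias = matrix(1, nrow(I), ncol(I)),
       cluster_means = c(mean(I[init_mask]), mean(I[!init_mask])))
}

# e_i(x) = I(x)^2 (K*1)(x) - 2 I(x) c_i (K*b)(x) + c_i^2 (K*b^2)(x)
lic_e_fields <- function(I, state, params, op = NULL) {
  if (is.null(op)) op <- blur_operator(nrow(I), ncol(I), params$kernel_scale)
  Kone <- gaussian_blur(matrix(1, nrow(I), ncol(I)), params$kernel_scale, op)
  Kb <- gaussian_blur(state$bias, params$kernel_scale, op)
  Kb2 <- gaussian_blur(state$bias^2, params$kernel_scale, op)
  c1 <- state$cluster_means[1]; c2 <- state$cluster_means[2]
  list(e1 = I^2 * Kone - 2 * I * c1 * Kb + c1^2 * Kb2,
       e2 = I^2 * Kone - 2 * I * c2 * Kb + c2^2 * Kb2,
       Kb = Kb, Kb2 = Kb2, Kone = Kone)
}

# Double-well potential p(s) and p'(s)/s of the distance regularizer.
dw_potential <- function(s) {
  ifelse(s <= 1, (1 - cos(2 * pi * s)) / (2 * pi)^2, 0.5 * (s - 1)^2)
}

dw_dp_over_s <- function(s) {
  out <- ifelse(s <= 1,
                ifelse(s < 1e-10, 1, sin(2 * pi * s) / (2 * pi * pmax(s, 1e-10))),
                (s - 1) / s)
  out
}

#' Local-intensity-clustering energy
#'
#' Evaluates the full LIC energy (data term via convolutions, plus the
#' length and distance-regularization penalties) for a given state.
#'
#' @param slice an [lsn_slice()].
#' @param state list with `phi`, `bias`, `cluster_means` (as returned by the
#'   update operations).
#' @param params an [lic_params()].
#' @return scalar energy.
#' @export
lic_energy <- function(slice, state, params) {
  I <- slice$intensities
  if (!all(is.finite(state$phi)) || !all(is.finite(state$bias)) ||
      !all(is.finite(state$cluster_means))) {
    stop_num("non-finite segmentation state")
  }
  ef <- lic_e_fields(I, state, params)
  M1 <- smooth_heaviside(state$phi, params$heaviside_width)
  data_term <- sum(ef$e1 * M1 + ef$e2 * (1 - M1))
  gr <- grad_row(state$phi); gc <- grad_col(state$phi)
  gmag <- sqrt(gr^2 + gc^2)
  length_term <- sum(smooth_delta(state$phi, params$heaviside_width) * gmag)
  reg_term <- sum(dw_potential(gmag))
  data_term + params$length_weight * length_term +
    params$regularization_weight * reg_term
}

#' Closed-form cluster-mean update
#'
#' Minimizes the LIC energy in `(c1, c2)` with `phi` and `b` fixed:
#' `c_i = sum((K*b) I M_i) / sum((K*b^2) M_i)`.
#'
#' @inheritParams lic_energy
#' @return numeric `c(c1, c2)`.
#' @export
update_cluster_means <- function(slice, state, params) {
  I <- slice$intensities
  op <- blur_operator(nrow(I), ncol(I), params$kernel_scale)
  Kb <- gaussian_blur(state$bias, params$kernel_scale, op)
  Kb2 <- gaussian_blur(state$bias^2, params$kernel_scale, op)
  M1 <- smooth_heaviside(state$phi, params$heaviside_width)
  num <- c(sum(Kb * I * M1), sum(Kb * I * (1 - M1)))
  den <- c(sum(Kb2 * M1), sum(Kb2 * (1 - M1)))
  if (any(den < .Machine$double.eps)) {
    stop_num("degenerate phase: a membership function has (near-)zero mass")
  }
  num / den
}

#' Closed-form bias-field update
#'
#' Minimizes the LIC energy in `b` with `phi` and `c` fixed:
#' `b = K*(I J1) / K*(J2)` with `J1 = sum_i c_i M_i`, `J2 = sum_i c_i^2 M_i`.
#' The result is floored at `params$bias_floor`; smoothness is inherited from
#' the Gaussian window.
#'
#' @inheritParams lic_energy
#' @return bias-field matrix.
#' @export
update_bias <- function(slice, state, params) {
  I <- slice$intensities
  op <- blur_operator(nrow(I), ncol(I), params$kernel_scale)
  M1 <- smooth_heaviside(state$phi, params$heaviside_width)
  c1 <- state$cluster_means[1]; c2 <- state$cluster_means[2]
  J1 <- c1 * M1 + c2 * (1 - M1)
  J2 <- c1^2 * M1 + c2^2 * (1 - M1)
  num <- gaussian_blur(I * J1, params$kernel_scale, op)
  den <- gaussian_blur(J2, params$kernel_scale, op)
  if (any(den < .Machine$double.eps)) {
    stop_num("degenerate phase: bias denominator vanished")
  }
  pmax(num / den, params$bias_floor)
}

#' One explicit level-set evolution step
#'
#' Gradient flow of the LIC energy in `phi`:
#' `phi <- phi + dt * (-delta(phi) (e1 - e2) + nu delta(phi) curvature(phi)
#'  + mu distreg(phi))`.
#'
#' @inheritParams lic_energy
#' @return updated `phi` matrix.
#' @export
evolve_level_set <- function(slice, state, params) {
  I <- slice$intensities
  ef <- lic_e_fields(I, state, params)
  phi <- state$phi
  d <- smooth_delta(phi, params$heaviside_width)
  gr <- grad_row(phi); gc <- grad_col(phi)
  gmag <- sqrt(gr^2 + gc^2)
  safe <- pmax(gmag, 1e-10)
  curv <- divergence(gr / safe, gc / safe)
  dps <- dw_dp_over_s(gmag)
  reg_force <- divergence(dps * gr, dps * gc)
  phi_new <- phi + params$time_step *
    (-d * (ef$e1 - ef$e2) + params$length_weight * d * curv +
       params$regularization_weight * reg_force)
  if (!all(is.finite(phi_new))) {
    stop_num("level-set evolution diverged (non-finite phi)")
  }
  phi_new
}

#' Segment a slice with simultaneous bias-field estimation
#'
#' Alternates the level-set evolution with the closed-form cluster-mean and
#' bias updates until the relative energy change drops below
#' `params$energy_tol` or `params$max_iters` sweeps are exhausted. The final
#' mask is `phi > 0` restricted to its largest 4-connected component; the
#' bias-corrected image is `J = I / max(b, bias_floor)`.
#'
#' @param slice an [lsn_slice()].
#' @param init_mask logical matrix initializing the liver phase (non-empty,
#'   not full-image); see [initial_liver_mask()] for an automatic choice.
#' @param params an [lic_params()].
#' @return a `segmentation_result` list: `mask`, `phi`, `bias`, `corrected`,
#'   `cluster_means`, `energy_trace`, `converged`, `iterations_used`.
#' @export
segment_with_bias <- function(slice, init_mask, params = lic_params()) {
  stopifnot(inherits(slice, "lsn_slice"))
  I <- slice$intensities
  init_mask <- as.matrix(init_mask)
  if (!identical(dim(init_mask), dim(I))) stop_param("init_mask shape must match the slice")
  init_mask <- init_mask > 0
  state <- lic_init_state(I, init_mask)
  energy_trace <- lic_energy(slice, state, params)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iters)) {
    iters <- it
    state$phi <- evolve_level_set(slice, state, params)
    state$cluster_means <- update_cluster_means(slice, state, params)
    state$bias <- update_bias(slice, state, params)
    e <- lic_energy(slice, state, params)
    energy_trace <- c(energy_trace, e)
    prev <- energy_trace[length(energy_trace) - 1L]
    if (abs(e - prev) < params$energy_tol * abs(prev)) {
      converged <- TRUE
      break
    }
  }
  mask <- state$phi > 0
  if (!any(mask)) {
    stop(errorCondition("segmentation collapsed to an empty mask",
                        class = c("lsn_numeric_error", "lsn_error"),
                        energy_trace = energy_trace))
  }
  mask <- largest_component(mask)
  b <- pmax(state$bias, params$bias_floor)
  structure(list(mask = mask, phi = state$phi, bias = state$bias,
                 corrected = I / b, cluster_means = state$cluster_means,
                 energy_trace = energy_trace, converged = converged,
                 iterations_used = iters), class = "segmentation_result")
}

#' Automatic liver-phase initialization
#'
#' Otsu threshold of the slice followed by largest-connected-component
#' selection; the bright phase is taken as the liver candidate.
#'
#' @param slice an [lsn_slice()].
#' @return logical matrix.
#' @export
initial_liver_mask <- function(slice) {
  stopifnot(inherits(slice, "lsn_slice"))
  I <- slice$intensities
  thr <- otsu_threshold(I)
  largest_component(I > thr)
}
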