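#' Specification of a synthetic liver phantom
#'
#' Describes a single 2-D slice phantom: a bright, star-convex "liver" region
#' on a darker background, modulated by a smooth multiplicative bias field and
#' corrupted by additive zero-mean Gaussian noise. The liver boundary radius is
#' a low-order Fourier base shape plus `nodule_count` compact Gaussian bumps of
#' amplitude `nodularity_amplitude` pixels, which is the ground-truth
#' nodularity knob every downstream stage is validated against.
#'
#' All generator outputs are pure functions of the spec: the same spec yields
#' bit-identical phantoms.
#'
#' @param image_height,image_width image size in pixels.
#' @param pixel_spacing pixel size in mm/pixel.
#' @param center liver center `c(row, col)` in pixels; default image center.
#' @param base_radius mean liver radius in pixels (>= 5).
#' @param fourier_coeffs numeric vector `c(a1, b1, a2, b2, ...)` of radial
#'   Fourier coefficients (order <= 4, dimensionless fractions of
#'   `base_radius`): `r0(theta) = base_radius * (1 + sum_k a_k cos(k theta) +
#'   b_k sin(k theta))`.
#' @param nodularity_amplitude bump amplitude A in pixels (>= 0).
#' @param nodule_count number of random bumps along the boundary.
#' @param nodule_width angular bump width (Gaussian sigma, radians).
#' @param liver_intensity,background_intensity region intensities (a.u.).
#' @param bias_contrast bias-field contrast beta (dimensionless, >= 0).
#' @param bias_kind one of `"planar_ramp"`, `"gaussian_bump"`, `"none"`.
#' @param noise_sd additive Gaussian noise SD (a.u., >= 0).
#' @param seed integer seed driving bump placement and noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 128L, image_width = 128L,
                         pixel_spacing = 0.74,
                         center = NULL,
                         base_radius = 36,
                         fourier_coeffs = c(0.06, 0.03, -0.04, 0.02),
                         nodularity_amplitude = 0,
                         nodule_count = 16L,
                         nodule_width = 0.12,
                         liver_intensity = 180,
                         background_intensity = 70,
                         bias_contrast = 0,
                         bias_kind = c("none", "planar_ramp", "gaussian_bump"),
                         noise_sd = 0,
                         seed = 1L) {
  bias_kind <- match.arg(bias_kind)
  if (is.null(center)) center <- c((image_height + 1) / 2, (image_width + 1) / 2)
  if (base_radius < 5) stop_domain("base_radius must be >= 5 pixels")
  if (nodularity_amplitude < 0) stop_domain("nodularity_amplitude must be >= 0")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (bias_contrast < 0) stop_domain("bias_contrast must be >= 0")
  if (liver_intensity == background_intensity) {
    stop_domain("liver_intensity must differ from background_intensity")
  }
  if (length(fourier_coeffs) > 8) stop_domain("fourier_coeffs order must be <= 4")
  structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    pixel_spacing = pixel_spacing, center = center, base_radius = base_radius,
    fourier_coeffs = fourier_coeffs, nodularity_amplitude = nodularity_amplitude,
    nodule_count = as.integer(nodule_count), nodule_width = nodule_width,
    liver_intensity = liver_intensity, background_intensity = background_intensity,
    bias_contrast = bias_contrast, bias_kind = bias_kind,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Radial base shape r0(theta), vectorized over theta.
phantom_base_radius <- function(spec, theta) {
  r <- rep(1, length(theta))
  fc <- spec$fourier_coeffs
  if (length(fc)) {
    for (k in seq_len(ceiling(length(fc) / 2))) {
      a <- fc[2 * k - 1]
      b <- if (2 * k <= length(fc)) fc[2 * k] else 0
      r <- r + a * cos(k * theta) + b * sin(k * theta)
    }
  }
  spec$base_radius * r
}

# Seeded bump centers; pure function of the spec.
phantom_bump_centers <- function(spec) {
  if (spec$nodule_count <= 0L) return(numeric(0))
  with_local_seed(spec$seed, stats::runif(spec$nodule_count, 0, 2 * pi))
}

# Wrapped-Gaussian angular bump profile summed over all nodules.
phantom_bump_sum <- function(theta, centers, width) {
  if (!length(centers)) return(rep(0, length(theta)))
  s <- rep(0, length(theta))
  for (th0 in centers) {
    d <- atan2(sin(theta - th0), cos(theta - th0)) # wrapped difference
    s <- s + exp(-0.5 * (d / width)^2)
  }
  s
}

phantom_radius <- function(spec, theta) {
  phantom_base_radius(spec, theta) +
    spec$nodularity_amplitude *
      phantom_bump_sum(theta, phantom_bump_centers(spec), spec$nodule_width)
}

#' Ground-truth phantom boundary
#'
#' Samples the star-convex boundary `r(theta) = r0(theta) + A * sum of bumps`
#' at `n_theta` angles and returns a closed, counter-clockwise ordered point
#' list in (row, col) pixel coordinates (counter-clockwise with the row axis
#' pointing down means decreasing visual angle is traversed so that the
#' enclosed region lies to the left in the (col, -row) frame).
#'
#' @param spec a [phantom_spec()].
#' @param n_theta number of boundary samples (>= 720).
#' @return matrix with columns `row`, `col`; the first point is not repeated.
#' @export
generate_boundary <- function(spec, n_theta = 720L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_theta <- max(as.integer(n_theta), 720L)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  r <- phantom_radius(spec, theta)
  if (any(r <= 0)) stop_domain("boundary radius collapsed to <= 0")
  row <- spec$center[1] - r * sin(theta)
  col <- spec$center[2] + r * cos(theta)
  margin <- 2
  if (min(row) < 1 + margin || min(col) < 1 + margin ||
      max(row) > spec$image_height - margin || max(col) > spec$image_width - margin) {
    stop_domain("phantom boundary exceeds the image bounds: a >= ", margin,
                "-pixel margin to every border is required")
  }
  cbind(row = row, col = col)
}

#' Smooth multiplicative bias field
#'
#' Builds the phantom's ground-truth bias field, rescaled to mean 1 over the
#' image domain. For `planar_ramp` the raw field is linear in the column
#' index, running from `1 - beta` at the left edge to `1 + beta` at the right
#' edge (so the max/min ratio is `(1 + beta) / (1 - beta)`, i.e. the
#' documented constant c = 1). For `gaussian_bump` the raw field is
#' `1 + beta * exp(-d^2 / (2 s^2))` centered on `spec$center` with
#' `s = min(height, width) / 4`.
#'
#' @param spec a [phantom_spec()].
#' @return matrix of positive values with mean 1 (to 1e-6).
#' @export
make_bias_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_height; w <- spec$image_width
  beta <- spec$bias_contrast
  raw <- switch(spec$bias_kind,
    none = matrix(1, h, w),
    planar_ramp = {
      if (beta >= 1) stop_domain("planar_ramp bias needs bias_contrast < 1 to stay positive")
      ramp <- 1 + beta * (2 * (seq_len(w) - 1) / (w - 1) - 1)
      matrix(ramp, h, w, byrow = TRUE)
    },
    gaussian_bump = {
      s <- min(h, w) / 4
      d2 <- outer((seq_len(h) - spec$center[1])^2, (seq_len(w) - spec$center[2])^2, `+`)
      1 + beta * exp(-d2 / (2 * s^2))
    }
  )
  if (any(raw <= 0)) stop_domain("bias field is not positive everywhere")
  raw / mean(raw)
}

#' Generate a synthetic liver phantom
#'
#' Rasterizes the ground-truth boundary to a binary mask (a pixel belongs to
#' the liver iff its center lies inside the star-convex boundary), applies the
#' bias field to the piecewise-constant truth and adds seeded Gaussian noise:
#' `image = bias * (liver * mask + background * (1 - mask)) + noise`.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_data` list: `image`, `true_mask`, `true_boundary`,
#'   `true_bias`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  boundary <- generate_boundary(spec)
  h <- spec$image_height; w <- spec$image_width
  # star-convex: pixel center inside iff distance-to-center < r(theta(pixel))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rows - spec$center[1]
  dc <- cols - spec$center[2]
  theta <- atan2(-dr, dc) # visual angle, consistent with generate_boundary
  dist <- sqrt(dr^2 + dc^2)
  mask <- dist < phantom_radius(spec, as.numeric(theta))
  dim(mask) <- c(h, w)
  bias <- make_bias_field(spec)
  truth <- spec$liver_intensity * mask + spec$background_intensity * (!mask)
  noise <- if (spec$noise_sd > 0) {
    with_local_seed(spec$seed + 1L,
                    matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
  } else matrix(0, h, w)
  structure(list(
    image = bias * truth + noise,
    true_mask = mask,
    true_boundary = boundary,
    true_bias = bias,
    spec = spec
  ), class = "phantom_data")
}

#' Write a phantom and its ground truth to disk
#'
#' The image is written both as 16-bit PNG (intensities rescaled to the full
#' 16-bit range) and as NIfTI-1 with pixel spacing in the header; the mask as
#' PNG, the boundary as CSV (`index,row,col`), the bias field as NIfTI.
#'
#' @param phantom a `phantom_data` object.
#' @param dir output directory (created if needed).
#' @param stem filename stem.
#' @return invisibly, the named list of written paths.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  stopifnot(inherits(phantom, "phantom_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(stem, ext))
  write_png16(phantom$image, p(".png"))
  write_nifti(phantom$image, p(".nii"), spacing = phantom$spec$pixel_spacing)
  write_png16(phantom$true_mask * 1, p("_mask.png"))
  write_nifti(phantom$true_bias, p("_bias.nii"), spacing = phantom$spec$pixel_spacing)
  bnd <- data.frame(index = seq_len(nrow(phantom$true_boundary)) - 1L,
                    row = phantom$true_boundary[, "row"],
                    col = phantom$true_boundary[, "col"])
  utils::write.csv(bnd, p("_boundary.csv"), row.names = FALSE)
  invisible(list(image_png = p(".png"), image_nii = p(".nii"),
                 mask_png = p("_mask.png"), bias_nii = p("_bias.nii"),
                 boundary_csv = p("_boundary.csv")))
}

#' Read a phantom spec from a YAML or JSON config file
#'
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  cfg <- read_config_file(path)
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop_param("unknown phantom config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$center)) cfg$center <- as.numeric(unlist(cfg$center))
  if (!is.null(cfg$fourier_coeffs)) cfg$fourier_coeffs <- as.numeric(unlist(cfg$fourier_coeffs))
  do.call(phantom_spec, cfg)
}
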