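# Independent oracles: direct-summation convolutions for the level-set
# energy terms, exact-test enumerations, and small geometry helpers. These
# deliberately re-derive every quantity from first principles (loops, combn)
# rather than calling the package's vectorized code paths.

# Truncated normalized Gaussian, same truncation rule as the implementation
# (radius = ceiling(2.5 sigma)) so direct summation is comparable.
oracle_kernel_1d <- function(sigma) {
  r <- ceiling(2.5 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# 2-D convolution with a separable Gaussian and reflective borders, by
# explicit quadruple loop.
oracle_conv <- function(img, sigma) {
  k <- oracle_kernel_1d(sigma)
  r <- (length(k) - 1) / 2
  K2 <- outer(k, k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in seq(-r, r)) {
        for (dj in seq(-r, r)) {
          acc <- acc + K2[di + r + 1, dj + r + 1] *
            img[oracle_reflect(i + di, h), oracle_reflect(j + dj, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Data term of the clustering energy by literal four-nested-loop summation:
# sum over pixels x and window offsets of K(off) |I(x) - b(refl(x+off)) c_i|^2 M_i(x).
oracle_lic_data_energy <- function(I, phi, b, cmeans, sigma, eps) {
  k <- oracle_kernel_1d(sigma)
  r <- (length(k) - 1) / 2
  K2 <- outer(k, k)
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  h <- nrow(I); w <- ncol(I)
  acc <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      M <- c(H[i, j], 1 - H[i, j])
      for (di in seq(-r, r)) {
        for (dj in seq(-r, r)) {
          bv <- b[oracle_reflect(i + di, h), oracle_reflect(j + dj, w)]
          kw <- K2[di + r + 1, dj + r + 1]
          for (ph in 1:2) {
            acc <- acc + kw * (I[i, j] - bv * cmeans[ph])^2 * M[ph]
          }
        }
      }
    }
  }
  acc
}

oracle_e_fields <- function(I, b, cmeans, sigma) {
  Kone <- oracle_conv(matrix(1, nrow(I), ncol(I)), sigma)
  Kb <- oracle_conv(b, sigma)
  Kb2 <- oracle_conv(b^2, sigma)
  lapply(cmeans, function(ci) I^2 * Kone - 2 * I * ci * Kb + ci^2 * Kb2)
}

oracle_bias_update <- function(I, phi, cmeans, sigma, eps) {
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  J1 <- cmeans[1] * H + cmeans[2] * (1 - H)
  J2 <- cmeans[1]^2 * H + cmeans[2]^2 * (1 - H)
  oracle_conv(I * J1, sigma) / oracle_conv(J2, sigma)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  Us <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  # two-sided: as extreme or more, by distance from the mean
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns.
oracle_wsr_exact <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) min(sum(r[s]), sum(r[!s])))
  mean(Ws <= W_obs + 1e-12)
}

# Symmetric Hausdorff distance between two point sets (rows = points).
hausdorff_distance <- function(A, B) {
  one_way <- function(P, Q) {
    max(vapply(seq_len(nrow(P)), function(i) {
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2))
    }, numeric(1)))
  }
  max(one_way(A, B), one_way(B, A))
}

# Distance from point p to segment (a, b).
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

min_distance_to_polygon <- function(p, verts, closed = TRUE) {
  n <- nrow(verts)
  segs <- if (closed) cbind(seq_len(n), c(seq_len(n)[-1], 1)) else
    cbind(seq_len(n - 1), seq_len(n)[-1])
  min(apply(segs, 1, function(s) {
    point_segment_distance(p, verts[s[1], ], verts[s[2], ])
  }))
}

# Binary erosion by a disk of radius r (pixel-center metric).
erode_disk <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  out <- matrix(TRUE, h, w)
  for (k in seq_len(nrow(offs))) {
    ii <- pmin(pmax(seq_len(h) + offs$di[k], 1), h)
    jj <- pmin(pmax(seq_len(w) + offs$dj[k], 1), w)
    out <- out & mask[ii, jj]
  }
  out & mask
}

# Small phantom slice used across tests (fast to segment).
test_phantom <- function(A = 0, seed = 1, noise_sd = 0, bias_contrast = 0,
                         bias_kind = "none", size = 96L, radius = 30) {
  sp <- phantom_spec(image_height = size, image_width = size,
                     base_radius = radius, nodularity_amplitude = A,
                     noise_sd = noise_sd, bias_contrast = bias_contrast,
                     bias_kind = bias_kind, seed = seed)
  generate_phantom(sp)
}

phantom_slice <- function(ph) lsn_slice(ph$image, ph$spec$pixel_spacing)

# Build a surface_segment directly from a point matrix (test fixture).
make_segment <- function(points, spacing = 1) {
  structure(list(points = points, pixel_spacing = spacing,
                 arc_length_mm = sum(sqrt(diff(points[, 1])^2 +
                                            diff(points[, 2])^2)) * spacing,
                 start_index = 1L, end_index = nrow(points)),
            class = "surface_segment")
}

# Minimal explicit-VR little-endian DICOM built byte by byte, independent of
# the package reader. 4x4 uint16 image, PixelSpacing "0.74\0.74".
build_test_dicom <- function(path, rows = 4L, cols = 4L,
                             spacing = "0.74\\0.74 ", values = NULL) {
  if (is.null(values)) values <- seq_len(rows * cols) * 10L
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  short_elem <- function(grp, el, vr, payload) {
    c(u16(grp), u16(el), charToRaw(vr), u16(length(payload)), payload)
  }
  long_elem <- function(grp, el, vr, payload) {
    c(u16(grp), u16(el), charToRaw(vr), as.raw(c(0, 0)), u32(length(payload)),
      payload)
  }
  pad_even <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  pix <- unlist(lapply(values, u16))
  out <- c(
    raw(128), charToRaw("DICM"),
    short_elem(0x0028, 0x0010, "US", u16(rows)),
    short_elem(0x0028, 0x0011, "US", u16(cols)),
    short_elem(0x0028, 0x0030, "DS", charToRaw(pad_even(spacing))),
    short_elem(0x0028, 0x0100, "US", u16(16)),
    short_elem(0x0028, 0x0103, "US", u16(0)),
    long_elem(0x7fe0, 0x0010, "OW", pix)
  )
  writeBin(out, path)
  path
}
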