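#' @title Liver surface line extraction and ROI selection
#' @name surface
#' @description Sub-pixel boundary tracing of a segmentation mask
#'   (marching squares at iso-level 0.5), arc-length resampling so residual
#'   statistics are computed on a pixel-by-pixel basis, and selection of
#'   regions of interest (arcs) along the surface line.
NULL

# Segment lookup for a marching-squares cell: which pairs of crossed edges
# (T top, R right, B bottom, L left) are joined, by corner-inside case
# (tl*8 + tr*4 + br*2 + bl). Saddle cases (5, 10) are resolved by the cell
# center average (> level connects the inside diagonal).
ms_cell_segments <- function(case, center_high) {
  switch(case + 1L,
    NULL,                       # 0
    list(c("L", "B")),          # 1: bl
    list(c("B", "R")),          # 2: br
    list(c("L", "R")),          # 3: bl+br
    list(c("T", "R")),          # 4: tr
    if (center_high) list(c("L", "T"), c("B", "R"))
    else list(c("T", "R"), c("L", "B")),          # 5: tr+bl saddle
    list(c("T", "B")),          # 6: tr+br
    list(c("L", "T")),          # 7: tr+br+bl
    list(c("L", "T")),          # 8: tl
    list(c("T", "B")),          # 9: tl+bl
    if (center_high) list(c("T", "R"), c("L", "B"))
    else list(c("L", "T"), c("B", "R")),          # 10: tl+br saddle
    list(c("T", "R")),          # 11: tl+br+bl
    list(c("L", "R")),          # 12: tl+tr
    list(c("B", "R")),          # 13: tl+tr+bl
    list(c("L", "B")),          # 14: tl+tr+br
    NULL                        # 15
  )
}

# All closed iso-`level` loops of a scalar field, as (row, col) polylines
# with linearly interpolated edge crossings. Coordinates refer to pixel
# centers of `field`; the field is zero-padded by one pixel so loops close.
marching_squares_loops <- function(field, level = 0.5) {
  m <- matrix(0, nrow(field) + 2L, ncol(field) + 2L)
  m[2:(nrow(field) + 1L), 2:(ncol(field) + 1L)] <- field
  h <- nrow(m); w <- ncol(m)
  # edge identity keys ("H i j": (i,j)-(i,j+1); "V i j": (i,j)-(i+1,j)) and
  # interpolated crossing coordinates
  edge_key <- function(i, j, e) {
    switch(e,
      T = paste("H", i, j),
      B = paste("H", i + 1L, j),
      L = paste("V", i, j),
      R = paste("V", i, j + 1L))
  }
  cross_pt <- function(i, j, e) {
    interp <- function(v0, v1) (level - v0) / (v1 - v0)
    switch(e,
      T = c(i, j + interp(m[i, j], m[i, j + 1L])),
      B = c(i + 1L, j + interp(m[i + 1L, j], m[i + 1L, j + 1L])),
      L = c(i + interp(m[i, j], m[i + 1L, j]), j),
      R = c(i + interp(m[i, j + 1L], m[i + 1L, j + 1L]), j + 1L))
  }
  inside <- m > level
  seg_keys_a <- character(0); seg_keys_b <- character(0)
  seg_pts_a <- list(); seg_pts_b <- list()
  n_seg <- 0L
  for (i in seq_len(h - 1L)) {
    ins_i <- inside[i, ]; ins_i1 <- inside[i + 1L, ]
    any_row <- which(ins_i[-w] | ins_i[-1L] | ins_i1[-w] | ins_i1[-1L])
    for (j in any_row) {
      case <- ins_i[j] * 8L + ins_i[j + 1L] * 4L + ins_i1[j + 1L] * 2L + ins_i1[j]
      if (case == 0L || case == 15L) next
      center_high <- (m[i, j] + m[i, j + 1L] + m[i + 1L, j] + m[i + 1L, j + 1L]) / 4 > level
      for (sg in ms_cell_segments(case, center_high)) {
        n_seg <- n_seg + 1L
        seg_keys_a[n_seg] <- edge_key(i, j, sg[1])
        seg_keys_b[n_seg] <- edge_key(i, j, sg[2])
        seg_pts_a[[n_seg]] <- cross_pt(i, j, sg[1])
        seg_pts_b[[n_seg]] <- cross_pt(i, j, sg[2])
      }
    }
  }
  if (!n_seg) return(list())
  adj <- new.env(parent = emptyenv())
  for (s in seq_len(n_seg)) {
    for (k in c(seg_keys_a[s], seg_keys_b[s])) {
      adj[[k]] <- c(if (!is.null(adj[[k]])) adj[[k]], s)
    }
  }
  used <- logical(n_seg)
  loops <- list()
  for (s0 in seq_len(n_seg)) {
    if (used[s0]) next
    pts <- list(seg_pts_a[[s0]])
    cur_key <- seg_keys_b[s0]
    cur_pt <- seg_pts_b[[s0]]
    used[s0] <- TRUE
    repeat {
      cand <- adj[[cur_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      s <- cand[1L]
      used[s] <- TRUE
      pts[[length(pts) + 1L]] <- cur_pt
      if (identical(seg_keys_a[s], cur_key)) {
        cur_key <- seg_keys_b[s]; cur_pt <- seg_pts_b[[s]]
      } else {
        cur_key <- seg_keys_a[s]; cur_pt <- seg_pts_a[[s]]
      }
    }
    loop <- do.call(rbind, pts)
    loops[[length(loops) + 1L]] <- loop - 1 # back to unpadded pixel coords
  }
  loops
}

# Signed area in the (x = col, y = -row) frame; > 0 for counter-clockwise.
contour_signed_area <- function(pts) {
  x <- pts[, 2]; y <- -pts[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

new_contour <- function(points, closed, pixel_spacing) {
  colnames(points) <- c("row", "col")
  structure(list(points = points, closed = closed,
                 pixel_spacing = pixel_spacing), class = "lsn_contour")
}

#' Extract the liver surface line from a binary mask
#'
#' Traces the boundary of the largest 4-connected component at sub-pixel
#' resolution (marching squares with linear interpolation at iso-level 0.5 of
#' the mask, lightly Gaussian-smoothed so crossings are genuinely sub-pixel
#' rather than staircase midpoints) into one closed chain, ordered
#' counter-clockwise (in the standard orientation with the row axis pointing
#' down, i.e. positive signed area in the (col, -row) frame).
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_spacing mm per pixel.
#' @param smooth_sigma Gaussian pre-smoothing of the mask indicator, pixels
#'   (0 disables; crossings then fall on staircase midpoints).
#' @return an `lsn_contour` (closed).
#' @export
extract_surface_line <- function(mask, pixel_spacing = 1, smooth_sigma = 1) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop_domain("mask is empty")
  comp <- largest_component(mask)
  field <- if (smooth_sigma > 0) gaussian_blur(comp * 1, smooth_sigma) else comp * 1
  loops <- marching_squares_loops(field)
  if (!length(loops)) stop_domain("degenerate mask: no traceable boundary")
  areas <- vapply(loops, function(p) abs(contour_signed_area(p)), numeric(1))
  pts <- loops[[which.max(areas)]]
  if (nrow(pts) < 8) stop_domain("degenerate mask: boundary has fewer than 8 points")
  if (contour_signed_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  new_contour(pts, closed = TRUE, pixel_spacing = pixel_spacing)
}

contour_cumlen <- function(contour) {
  p <- contour$points
  q <- if (contour$closed) rbind(p, p[1, ]) else p
  d <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  c(0, cumsum(d))
}

#' Total contour length in pixels
#' @param contour an `lsn_contour`.
#' @return scalar length (pixels).
#' @export
contour_length <- function(contour) {
  cl <- contour_cumlen(contour)
  cl[length(cl)]
}

#' Resample a contour at equal arc-length spacing
#'
#' Points are placed every `step` pixels along the polygonal chain; the first
#' point is preserved. For a closed contour the last resampled point does not
#' duplicate the first.
#'
#' @param contour an `lsn_contour`.
#' @param step arc-length step, pixels (> 0 and < total length / 8).
#' @return an `lsn_contour` with equally spaced points.
#' @export
resample_arclength <- function(contour, step = 1) {
  stopifnot(inherits(contour, "lsn_contour"))
  cl <- contour_cumlen(contour)
  L <- cl[length(cl)]
  if (step <= 0) stop_param("step must be > 0")
  if (step >= L / 8) stop_param("step too large: must be < total length / 8 = ", L / 8)
  p <- contour$points
  q <- if (contour$closed) rbind(p, p[1, ]) else p
  if (contour$closed) {
    n <- floor(L / step + 1e-9)
    s <- (seq_len(n) - 1) * step
  } else {
    s <- seq(0, L, by = step)
    if (L - s[length(s)] > 1e-9) s <- c(s, L)
  }
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(q) - 1L)
  seglen <- cl[seg + 1L] - cl[seg]
  t <- ifelse(seglen > 0, (s - cl[seg]) / seglen, 0)
  out <- q[seg, , drop = FALSE] * (1 - t) + q[seg + 1L, , drop = FALSE] * t
  new_contour(out, closed = contour$closed, pixel_spacing = contour$pixel_spacing)
}

#' Select a surface segment (ROI) from a contour
#'
#' Extracts the ordered sub-chain from `start_index` to `end_index`
#' (1-based, inclusive). On a closed contour `end_index < start_index` wraps
#' through the first point.
#'
#' @param contour an `lsn_contour`.
#' @param start_index,end_index 1-based point indices.
#' @param min_points minimum admissible segment size (a downstream polynomial
#'   fit of order p needs at least p + 2 points).
#' @return a `surface_segment`: `points`, `pixel_spacing`, `arc_length_mm`,
#'   `start_index`, `end_index`.
#' @export
select_segment <- function(contour, start_index, end_index, min_points = 4L) {
  stopifnot(inherits(contour, "lsn_contour"))
  n <- nrow(contour$points)
  if (start_index < 1 || start_index > n || end_index < 1 || end_index > n) {
    stop_param("segment indices must lie in 1..", n)
  }
  idx <- if (end_index >= start_index) {
    seq(start_index, end_index)
  } else {
    if (!contour$closed) stop_param("end_index < start_index on an open contour")
    c(seq(start_index, n), seq_len(end_index))
  }
  if (length(idx) < min_points) {
    stop_param("segment too short: ", length(idx), " points; at least ",
               min_points, " required")
  }
  pts <- contour$points[idx, , drop = FALSE]
  arc_px <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
  structure(list(points = pts, pixel_spacing = contour$pixel_spacing,
                 arc_length_mm = arc_px * contour$pixel_spacing,
                 start_index = start_index, end_index = end_index),
            class = "surface_segment")
}

#' Automatically place ROIs along a closed contour
#'
#' Places `n_rois` non-overlapping equal-arc-length windows at equal spacing,
#' deterministically anchored at the contour's first point (window k starts
#' at arc position (k-1) * L / n_rois).
#'
#' @param contour a closed `lsn_contour` (resample first for uniform index
#'   spacing).
#' @param n_rois number of ROIs (>= 3, matching the at-least-three rule for
#'   subject-level scores).
#' @param roi_arclength window length in mm; default 20% of the contour.
#' @return list of `surface_segment`s.
#' @export
auto_place_rois <- function(contour, n_rois = 4L, roi_arclength = NULL) {
  stopifnot(inherits(contour, "lsn_contour"))
  if (!contour$closed) stop_param("auto ROI placement requires a closed contour")
  if (n_rois < 3) stop_param("n_rois must be >= 3 (at least three ROI measurements)")
  cl_mm <- contour_cumlen(contour) * contour$pixel_spacing
  L <- cl_mm[length(cl_mm)]
  if (is.null(roi_arclength)) roi_arclength <- 0.2 * L
  if (n_rois * roi_arclength > L + 1e-9) {
    stop_param("infeasible packing: ", n_rois, " ROIs of ", roi_arclength,
               " mm exceed the contour length ", L, " mm")
  }
  npts <- nrow(contour$points)
  starts <- (seq_len(n_rois) - 1) * L / n_rois
  lapply(starts, function(s0) {
    s1 <- s0 + roi_arclength
    i0 <- which(cl_mm >= s0 - 1e-9)[1]
    i1 <- max(which(cl_mm[seq_len(npts)] < s1 - 1e-9))
    select_segment(contour, i0, min(i1, npts))
  })
}
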