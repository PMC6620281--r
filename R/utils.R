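# Internal numeric / image helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps generators pure functions of
# their spec without clobbering user RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) stop(errorCondition(paste0(...), class = c("lsn_domain_error", "lsn_error")))
stop_param  <- function(...) stop(errorCondition(paste0(...), class = c("lsn_parameter_error", "lsn_error")))
stop_geom   <- function(...) stop(errorCondition(paste0(...), class = c("lsn_geometry_error", "lsn_error")))
stop_num    <- function(...) stop(errorCondition(paste0(...), class = c("lsn_numeric_error", "lsn_error")))
stop_io     <- function(...) stop(errorCondition(paste0(...), class = c("lsn_io_error", "lsn_error")))

# Truncated, normalized 1-D Gaussian kernel (radius = ceiling(2.5*sigma)).
gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(2.5 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Reflect an out-of-range index into 1..n (whole-sample symmetric border).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  while (any(bad <- idx < 1L | idx > n)) {
    idx[bad & idx < 1L] <- 2L - idx[bad & idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
  }
  idx
}

# Dense n x n matrix applying a 1-D convolution with reflective borders.
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    j <- reflect_index(seq_len(n) + off, n)
    w <- kernel[off + r + 1L]
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + w
  }
  M
}

# Separable Gaussian blur with reflective borders. An optional precomputed
# operator (from blur_operator) avoids rebuilding the matrices in loops.
blur_operator <- function(nrow, ncol, sigma) {
  k <- gaussian_kernel_1d(sigma)
  list(Mr = conv_matrix_1d(nrow, k), Mc = conv_matrix_1d(ncol, k), kernel = k)
}

gaussian_blur <- function(img, sigma, op = NULL) {
  if (is.null(op)) op <- blur_operator(nrow(img), ncol(img), sigma)
  op$Mr %*% img %*% t(op$Mc)
}

# Central finite differences with replicated edges (unit pixel spacing).
grad_row <- function(f) {
  n <- nrow(f)
  up <- f[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- f[c(seq_len(n)[-1L], n), , drop = FALSE]
  (dn - up) / 2
}

grad_col <- function(f) {
  n <- ncol(f)
  lf <- f[, c(1L, seq_len(n - 1L)), drop = FALSE]
  rt <- f[, c(seq_len(n)[-1L], n), drop = FALSE]
  (rt - lf) / 2
}

divergence <- function(fr, fc) grad_row(fr) + grad_col(fc)

laplacian <- function(f) {
  n <- nrow(f); m <- ncol(f)
  up <- f[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- f[c(seq_len(n)[-1L], n), , drop = FALSE]
  lf <- f[, c(1L, seq_len(m - 1L)), drop = FALSE]
  rt <- f[, c(seq_len(m)[-1L], m), drop = FALSE]
  up + dn + lf + rt - 4 * f
}

# Otsu threshold on a numeric matrix (256-bin histogram).
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) <= 0) stop_domain("cannot threshold a constant image")
  nb <- 256L
  brk <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  (brk[k] + brk[k + 1L]) / 2
}

# Label 4-connected components of a logical matrix; returns integer matrix
# (0 = background) and sizes. Iterative BFS, no recursion.
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  sizes <- integer(0)
  idx_all <- which(mask)
  for (s in idx_all) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    count <- 0L
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      count <- count + length(q)
      r <- ((q - 1L) %% n) + 1L
      cc <- ((q - 1L) %/% n) + 1L
      for (d in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[d]
        cc2 <- cc + c(0L, 0L, -1L, 1L)[d]
        ok <- rr >= 1L & rr <= n & cc2 >= 1L & cc2 <= m
        if (!any(ok)) next
        nb <- (cc2[ok] - 1L) * n + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
    sizes[cur] <- count
  }
  list(labels = lab, sizes = sizes)
}

largest_component <- function(mask) {
  lc <- label_components(mask)
  if (!length(lc$sizes)) return(mask & FALSE)
  lc$labels == which.max(lc$sizes)
}

dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
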