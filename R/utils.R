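# Internal numeric helpers shared across the TPAF and SHG branches.

# Replicate-padded 3x3 Sobel gradient magnitude. Implemented with matrix
# shifts so values are exact (no FFT round-off), which matters for the
# hand-computed gradient oracles and for the RATS noise floor.
sobel_magnitude <- function(x) {
  stopifnot(is.matrix(x))
  nr <- nrow(x)
  nc <- ncol(x)
  if (nr < 2L || nc < 2L) {
    return(matrix(0, nr, nc))
  }
  pad <- rbind(x[1L, , drop = FALSE], x, x[nr, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
  # gx responds to horizontal (column-wise) change, gy to vertical
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

# Otsu's criterion on a plain numeric vector: the split maximizing
# between-class variance over the observed values. Returns the threshold
# (midpoint between the two classes' adjacent values), or NA_real_ when all
# values are equal so no split exists.
otsu_split <- function(values) {
  v <- sort(unique(values))
  if (length(v) < 2L) {
    return(NA_real_)
  }
  x <- sort(values)
  n <- length(x)
  best <- -Inf
  best_t <- NA_real_
  csum <- cumsum(x)
  total <- csum[n]
  for (i in seq_len(n - 1L)) {
    if (x[i] == x[i + 1L]) next
    w0 <- i / n
    m0 <- csum[i] / i
    m1 <- (total - csum[i]) / (n - i)
    bc <- w0 * (1 - w0) * (m0 - m1)^2
    if (bc > best) {
      best <- bc
      best_t <- (x[i] + x[i + 1L]) / 2
    }
  }
  best_t
}

# Bilinear interpolation of a value grid given node coordinates, evaluated at
# all pixels of an nr x nc image; queries outside the node hull are clamped
# (constant extrapolation beyond the outer node centres).
bilinear_expand <- function(node_rows, node_cols, values, nr, nc) {
  stopifnot(
    is.matrix(values),
    nrow(values) == length(node_rows),
    ncol(values) == length(node_cols)
  )
  interp1 <- function(nodes, q) {
    if (length(nodes) == 1L) {
      return(list(i0 = rep(1L, length(q)), i1 = rep(1L, length(q)), w = rep(0, length(q))))
    }
    q <- pmin(pmax(q, nodes[1L]), nodes[length(nodes)])
    i0 <- findInterval(q, nodes, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), length(nodes) - 1L)
    i1 <- i0 + 1L
    w <- (q - nodes[i0]) / (nodes[i1] - nodes[i0])
    list(i0 = i0, i1 = i1, w = w)
  }
  ri <- interp1(node_rows, seq_len(nr))
  ci <- interp1(node_cols, seq_len(nc))
  v00 <- values[ri$i0, ci$i0, drop = FALSE]
  v10 <- values[ri$i1, ci$i0, drop = FALSE]
  v01 <- values[ri$i0, ci$i1, drop = FALSE]
  v11 <- values[ri$i1, ci$i1, drop = FALSE]
  wr <- matrix(ri$w, nr, nc)
  wc <- matrix(ci$w, nr, nc, byrow = TRUE)
  (1 - wr) * (1 - wc) * v00 + wr * (1 - wc) * v10 +
    (1 - wr) * wc * v01 + wr * wc * v11
}

# Deterministic child-seed derivation: master seed mixed with a sample index
# by a fixed affine rule modulo a Mersenne prime, kept in 32-bit range.
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m + 1000003 * as.numeric(index)) %% m)
}

# Rejection sampler for a truncated normal; errors out rather than silently
# clamping if the acceptance region is pathologically small.
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf, max_tries = 10000L) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal: mean outside truncation bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    tries <- tries + 1L
  }
  if (length(out) < n) {
    stop("truncated normal rejection sampling failed to accept enough draws", call. = FALSE)
  }
  out[seq_len(n)]
}

clip_to_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)
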