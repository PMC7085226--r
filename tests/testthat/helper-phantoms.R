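# Shared fixtures, all generated in code.

# vertical step image: left half `lo`, right half `hi`
step_image <- function(n = 64L, lo = 10, hi = 200) {
  m <- matrix(lo, n, n)
  m[, (n %/% 2 + 1L):n] <- hi
  m
}

# structured two-level phantom: bright ellipses on dark background plus
# additive Gaussian noise; returns the image and the ground-truth mask
two_level_phantom <- function(n = 64L, fg = 200, bg = 40, noise_sd = 32,
                              n_blobs = 4L) {
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(n_blobs)) {
    cr <- runif(1, 10, n - 10)
    cc <- runif(1, 10, n - 10)
    a <- runif(1, 6, 14)
    b <- runif(1, 4, 10)
    gt <- gt | (outer((seq_len(n) - cr)^2 / a^2, rep(1, n)) +
      outer(rep(1, n), (seq_len(n) - cc)^2 / b^2)) <= 1
  }
  im <- ifelse(gt, fg, bg) + rnorm(n * n, 0, noise_sd)
  list(image = mpm_image(matrix(round(pmin(pmax(im, 0), 255)), n, n), "SHG"),
    truth = gt
  )
}

# exhaustive-search global threshold maximizing agreement with ground truth
best_global_threshold <- function(pixels, truth) {
  cand <- 0:255
  agree <- vapply(cand, function(t) sum((pixels > t) == truth), numeric(1))
  cand[which.max(agree)]
}

# published group summaries used across statistical tests
table1_summaries <- function() {
  list(
    nuclear = list(
      pre = list(n = 30L, mean = 596.56, sd = 208.69),
      post = list(n = 30L, mean = 856.22, sd = 255.74)
    ),
    collagen = list(
      pre = list(n = 30L, mean = 22.81, sd = 10.23),
      post = list(n = 30L, mean = 36.10, sd = 12.42)
    )
  )
}

summary_row <- function(g, group = "pre", metric = "m") {
  tibble::tibble(group = group, metric = metric, n = g$n, mean = g$mean, sd = g$sd)
}

# greedy nearest-centroid matching of measured nuclei to ground truth
match_nuclei <- function(measured, truth) {
  stopifnot(nrow(measured) == nrow(truth))
  d <- outer(measured$centroid_row, truth$centroid_row, `-`)^2 +
    outer(measured$centroid_col, truth$centroid_col, `-`)^2
  assign <- apply(d, 1L, which.min)
  stopifnot(!anyDuplicated(assign))
  truth[assign, ]
}
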