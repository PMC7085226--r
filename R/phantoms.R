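#' Generate a TPAF phantom with ground-truth nucleus labels
#'
#' Emulates a two-photon autofluorescence field: bright cytoplasm/stroma with
#' dark, signal-void nuclei (rendered as rotated ellipses), optional very
#' bright blobs mimicking necrosis or lipid-laden foam cells, and additive
#' Gaussian noise clipped to the bit range. Nuclei are placed without overlap
#' so the returned integer label mask is exact ground truth; identical
#' parameters and seed give bit-identical output.
#'
#' @param image_shape Integer `(rows, cols)`.
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param nucleus_area_mean_px2,nucleus_area_sd_px2 Mean and SD of per-nucleus
#'   target areas in px^2 (truncated below at 25 px^2).
#' @param nucleus_eccentricity_range Interval in `[0, 1)` from which each
#'   nucleus' eccentricity is drawn uniformly.
#' @param cytoplasm_level,nucleus_level Background and nucleus intensities;
#'   `nucleus_level < cytoplasm_level` (nuclei are signal voids).
#' @param n_bright_blobs Number of bright necrosis/foam-cell mimics.
#' @param blob_level Intensity of bright blobs (default near saturation).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; the generator is a pure function of its inputs.
#'
#' @return A list with elements `image` ([mpm_image()], TPAF role), `labels`
#'   (integer matrix; label `k > 0` marks nucleus `k`), and `nuclei` (tibble
#'   of ground truth: `nucleus_id`, `centroid_row`, `centroid_col`,
#'   `area_px2`, semi-axes and orientation).
#' @export
generate_tpaf <- function(image_shape = c(256L, 256L),
                          n_nuclei = 10L,
                          nucleus_area_mean_px2 = 596.56,
                          nucleus_area_sd_px2 = 90,
                          nucleus_eccentricity_range = c(0, 0.7),
                          cytoplasm_level = 180,
                          nucleus_level = 20,
                          n_bright_blobs = 0L,
                          blob_level = NULL,
                          noise_sd = 6,
                          bit_depth = 8L,
                          seed = 1L) {
  stopifnot(
    length(image_shape) == 2L, all(image_shape >= 16L),
    n_nuclei >= 0L, nucleus_area_mean_px2 > 0, nucleus_area_sd_px2 >= 0,
    length(nucleus_eccentricity_range) == 2L,
    nucleus_eccentricity_range[1L] >= 0, nucleus_eccentricity_range[2L] < 1,
    noise_sd >= 0, n_bright_blobs >= 0L
  )
  if (nucleus_level >= cytoplasm_level) {
    stop("`nucleus_level` must be below `cytoplasm_level`: nuclei are signal voids",
      call. = FALSE
    )
  }
  maxval <- 2^bit_depth - 1
  if (is.null(blob_level)) blob_level <- round(0.98 * maxval)
  nr <- as.integer(image_shape[1L])
  nc <- as.integer(image_shape[2L])

  withr::with_seed(as.integer(seed), {
    img <- matrix(cytoplasm_level, nr, nc)
    labels <- matrix(0L, nr, nc)
    truth <- list()
    placed <- matrix(numeric(0), ncol = 3) # centre_row, centre_col, radius

    if (n_nuclei > 0L) {
      areas <- rtruncnorm1(n_nuclei, nucleus_area_mean_px2, nucleus_area_sd_px2,
        lower = 25
      )
      eccs <- runif(n_nuclei, nucleus_eccentricity_range[1L], nucleus_eccentricity_range[2L])
      thetas <- runif(n_nuclei, 0, pi)
      for (k in seq_len(n_nuclei)) {
        ratio <- sqrt(1 - eccs[k]^2) # b/a
        a <- sqrt(areas[k] / (pi * ratio))
        b <- areas[k] / (pi * a)
        pos <- place_disjoint(placed, nr, nc, radius = a, margin = 4)
        if (is.null(pos)) {
          stop(sprintf(
            "could not place nucleus %d of %d without overlap; reduce n_nuclei or nucleus area",
            k, n_nuclei
          ), call. = FALSE)
        }
        placed <- rbind(placed, c(pos, a))
        px <- rasterize_ellipse(pos[1L], pos[2L], a, b, thetas[k], nr, nc)
        img[px] <- nucleus_level
        labels[px] <- k
        idx <- arrayInd(px, c(nr, nc))
        truth[[k]] <- tibble::tibble(
          nucleus_id = k,
          centroid_row = mean(idx[, 1L]),
          centroid_col = mean(idx[, 2L]),
          area_px2 = length(px),
          semi_major_px = a, semi_minor_px = b, theta = thetas[k]
        )
      }
    }

    if (n_bright_blobs > 0L) {
      for (k in seq_len(n_bright_blobs)) {
        r <- runif(1, 5, 12)
        pos <- place_disjoint(placed, nr, nc, radius = r, margin = 4)
        if (is.null(pos)) {
          stop(sprintf("could not place bright blob %d without overlapping a nucleus", k),
            call. = FALSE
          )
        }
        placed <- rbind(placed, c(pos, r))
        px <- rasterize_ellipse(pos[1L], pos[2L], r, r, 0, nr, nc)
        img[px] <- blob_level
      }
    }

    if (noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
    img <- round(clip_to_range(img, 0, maxval))

    list(
      image = mpm_image(img, channel = "TPAF", bit_depth = bit_depth,
        provenance = sprintf("tpaf phantom seed %d", as.integer(seed))
      ),
      labels = labels,
      nuclei = if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
        nucleus_id = integer(), centroid_row = numeric(), centroid_col = numeric(),
        area_px2 = integer(), semi_major_px = numeric(), semi_minor_px = numeric(),
        theta = numeric()
      )
    )
  })
}

# Uniform rejection placement of a disk of given bounding radius that keeps
# `margin` px clearance from every previously placed disk and the border.
place_disjoint <- function(placed, nr, nc, radius, margin, max_tries = 500L) {
  lo_r <- ceiling(radius) + 2
  hi_r <- nr - ceiling(radius) - 1
  lo_c <- ceiling(radius) + 2
  hi_c <- nc - ceiling(radius) - 1
  if (hi_r <= lo_r || hi_c <= lo_c) {
    return(NULL)
  }
  for (i in seq_len(max_tries)) {
    cr <- runif(1, lo_r, hi_r)
    cc <- runif(1, lo_c, hi_c)
    if (nrow(placed) == 0L) {
      return(c(cr, cc))
    }
    d <- sqrt((placed[, 1L] - cr)^2 + (placed[, 2L] - cc)^2)
    if (all(d > placed[, 3L] + radius + margin)) {
      return(c(cr, cc))
    }
  }
  NULL
}

# Linear indices of pixels inside a rotated ellipse (centre cr,cc; semi-axes
# a >= b; orientation theta).
rasterize_ellipse <- function(cr, cc, a, b, theta, nr, nc) {
  rr <- max(1L, floor(cr - a)):min(nr, ceiling(cr + a))
  cols <- max(1L, floor(cc - a)):min(nc, ceiling(cc + a))
  dr <- outer(rr - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rr)), cols - cc)
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ri <- matrix(rr, length(rr), length(cols))
  ci <- matrix(cols, length(rr), length(cols), byrow = TRUE)
  (ci[inside] - 1L) * nr + ri[inside]
}

#' Generate an SHG phantom with ground-truth collagen mask
#'
#' Emulates a second-harmonic-generation image: bright curvilinear collagen
#' fibers (smoothed random walks of fixed stroke width) on a dark background.
#' Fibers are added until the ground-truth mask covers the target area
#' fraction; generation fails rather than returning a mask more than 2
#' percentage points away from target. Identical parameters and seed give
#' bit-identical output.
#'
#' @param image_shape Integer `(rows, cols)`.
#' @param target_collagen_fraction_pct Target foreground fraction in `[0, 100]`.
#' @param fiber_width_px Stroke width of each fiber in pixels.
#' @param fiber_level_range Intensity interval (above background) from which
#'   each fiber's level is drawn.
#' @param background_level Background intensity.
#' @param noise_sd Additive Gaussian noise SD.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed.
#' @param max_fibers Placement iteration cap before raising a generation error.
#'
#' @return A list with `image` ([mpm_image()], SHG role), `mask` (ground-truth
#'   \{0, 255\} matrix), `achieved_fraction_pct`, and `target_fraction_pct`.
#' @export
generate_shg <- function(image_shape = c(256L, 256L),
                         target_collagen_fraction_pct = 22.81,
                         fiber_width_px = 3L,
                         fiber_level_range = c(120, 220),
                         background_level = 10,
                         noise_sd = 6,
                         bit_depth = 8L,
                         seed = 1L,
                         max_fibers = 20000L) {
  stopifnot(
    length(image_shape) == 2L, all(image_shape >= 16L),
    target_collagen_fraction_pct >= 0, target_collagen_fraction_pct <= 100,
    fiber_width_px >= 1L, length(fiber_level_range) == 2L,
    fiber_level_range[1L] <= fiber_level_range[2L],
    fiber_level_range[1L] > background_level,
    noise_sd >= 0
  )
  maxval <- 2^bit_depth - 1
  nr <- as.integer(image_shape[1L])
  nc <- as.integer(image_shape[2L])
  total <- nr * nc
  target <- target_collagen_fraction_pct

  # disk stamp offsets for the stroke width
  rad <- fiber_width_px / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad), dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2, , drop = FALSE]

  withr::with_seed(as.integer(seed), {
    fg <- matrix(FALSE, nr, nc)
    img <- matrix(background_level, nr, nc)
    base_steps <- max(12L, round(0.35 * min(nr, nc)))
    step_len <- 1.5
    n_fibers <- 0L
    covered <- 0L
    while (covered / total * 100 < target && n_fibers < max_fibers) {
      remaining_px <- target / 100 * total - covered
      # shorten the last fibers so a single stroke cannot overshoot the band
      steps <- min(base_steps, max(6L, ceiling(remaining_px / (step_len * fiber_width_px))))
      pts <- fiber_walk(nr, nc, steps, step_len)
      level <- runif(1, fiber_level_range[1L], fiber_level_range[2L])
      idx <- stamp_points(pts, off, nr, nc)
      newpx <- idx[!fg[idx]]
      fg[newpx] <- TRUE
      img[idx] <- pmax(img[idx], level)
      covered <- covered + length(newpx)
      n_fibers <- n_fibers + 1L
    }
    achieved <- covered / total * 100
    if (abs(achieved - target) > 2) {
      stop(sprintf(
        "could not reach target collagen fraction %.1f%% (achieved %.1f%% after %d fibers)",
        target, achieved, n_fibers
      ), call. = FALSE)
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(total, 0, noise_sd), nr, nc)
    }
    img <- round(clip_to_range(img, 0, maxval))
    list(
      image = mpm_image(img, channel = "SHG", bit_depth = bit_depth,
        provenance = sprintf("shg phantom seed %d", as.integer(seed))
      ),
      mask = matrix(ifelse(fg, 255L, 0L), nr, nc),
      achieved_fraction_pct = achieved,
      target_fraction_pct = target
    )
  })
}

# Smoothed random walk: uniform start, direction diffusing by a small
# von-Mises-like Gaussian increment, reflected at the image border.
fiber_walk <- function(nr, nc, steps, step_len) {
  r <- runif(1, 1, nr)
  c <- runif(1, 1, nc)
  ang <- runif(1, 0, 2 * pi)
  pts <- matrix(0, steps + 1L, 2L)
  pts[1L, ] <- c(r, c)
  for (i in seq_len(steps)) {
    ang <- ang + rnorm(1, 0, 0.3)
    r <- r + step_len * sin(ang)
    c <- c + step_len * cos(ang)
    if (r < 1) {
      r <- 2 - r
      ang <- -ang
    } else if (r > nr) {
      r <- 2 * nr - r
      ang <- -ang
    }
    if (c < 1) {
      c <- 2 - c
      ang <- pi - ang
    } else if (c > nc) {
      c <- 2 * nc - c
      ang <- pi - ang
    }
    pts[i + 1L, ] <- c(r, c)
  }
  pts
}

stamp_points <- function(pts, off, nr, nc) {
  rr <- round(rep(pts[, 1L], each = nrow(off)) + off$dr)
  cc <- round(rep(pts[, 2L], each = nrow(off)) + off$dc)
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[keep] - 1L) * nr + rr[keep])
}

#' Cohort specification for the synthetic-study generator
#'
#' Bundles the per-group parameters of a two-arm (pre-/post-treatment) imaging
#' study. Defaults reproduce the published group summaries: nuclear area
#' 596.56 +/- 208.69 px^2 and collagen content 22.81 +/- 10.23 % before
#' therapy (n = 30), and 856.22 +/- 255.74 px^2 and 36.10 +/- 12.42 % after
#' therapy (n = 30). Per-sample targets are drawn from truncated normal
#' distributions with these moments (areas truncated to be positive, collagen
#' to `[0, 100]` %).
#'
#' @param pre,post Named lists with entries `n_samples`,
#'   `nuclear_area_mean`, `nuclear_area_sd`, `collagen_mean_pct`,
#'   `collagen_sd_pct`.
#' @param master_seed Integer master seed; per-sample child seeds are derived
#'   deterministically from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(pre = list(
                          n_samples = 30L, nuclear_area_mean = 596.56,
                          nuclear_area_sd = 208.69, collagen_mean_pct = 22.81,
                          collagen_sd_pct = 10.23
                        ),
                        post = list(
                          n_samples = 30L, nuclear_area_mean = 856.22,
                          nuclear_area_sd = 255.74, collagen_mean_pct = 36.10,
                          collagen_sd_pct = 12.42
                        ),
                        master_seed = 20200221L) {
  need <- c(
    "n_samples", "nuclear_area_mean", "nuclear_area_sd",
    "collagen_mean_pct", "collagen_sd_pct"
  )
  for (g in list(pre = pre, post = post)) {
    miss <- setdiff(need, names(g))
    if (length(miss)) {
      stop(sprintf("cohort group is missing fields: %s", paste(miss, collapse = ", ")),
        call. = FALSE
      )
    }
    stopifnot(
      g$n_samples >= 1L, g$nuclear_area_mean > 0, g$nuclear_area_sd >= 0,
      g$collagen_mean_pct >= 0, g$collagen_mean_pct <= 100, g$collagen_sd_pct >= 0
    )
  }
  structure(list(pre = pre, post = post, master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic two-arm cohort
#'
#' Draws one target nuclear-area mean and one target collagen fraction per
#' sample from the group-level truncated normal distributions of a
#' [cohort_spec()], then (optionally) renders each sample's TPAF and SHG
#' phantom with a deterministically derived child seed. With `render = FALSE`
#' only the manifest of drawn targets is returned, which is what
#' replicate-level power or type-I-error simulations need.
#'
#' @param spec A [cohort_spec()].
#' @param render If `TRUE`, generate the phantom image pairs (as list
#'   columns); if `FALSE`, return the manifest only.
#' @param image_shape Phantom shape when rendering.
#' @param n_nuclei_per_image Nuclei per TPAF phantom.
#' @param noise_sd Phantom noise SD (both channels).
#' @param n_bright_blobs Bright blob count per TPAF phantom.
#' @return A tibble manifest with one row per sample: `sample_id`, `group`
#'   (`"pre"`/`"post"`), `seed`, `target_nuclear_area_px2`,
#'   `target_collagen_pct`, and when rendering also `achieved_collagen_pct`
#'   plus list columns `tpaf`, `tpaf_labels`, `tpaf_truth`, `shg`, `shg_mask`.
#' @examples
#' spec <- cohort_spec(
#'   pre = list(
#'     n_samples = 2L, nuclear_area_mean = 600, nuclear_area_sd = 100,
#'     collagen_mean_pct = 20, collagen_sd_pct = 5
#'   ),
#'   post = list(
#'     n_samples = 2L, nuclear_area_mean = 850, nuclear_area_sd = 100,
#'     collagen_mean_pct = 36, collagen_sd_pct = 5
#'   ),
#'   master_seed = 7L
#' )
#' generate_cohort(spec, render = FALSE)
#' @export
generate_cohort <- function(spec = cohort_spec(), render = TRUE,
                            image_shape = c(256L, 256L),
                            n_nuclei_per_image = 8L,
                            noise_sd = 6,
                            n_bright_blobs = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  global_index <- 0L
  for (group in c("pre", "post")) {
    g <- spec[[group]]
    for (i in seq_len(g$n_samples)) {
      global_index <- global_index + 1L
      child <- derive_seed(spec$master_seed, global_index)
      sample_id <- sprintf("%s_%02d", group, i)
      row <- withr::with_seed(child, {
        tibble::tibble(
          sample_id = sample_id,
          group = group,
          seed = child,
          target_nuclear_area_px2 = rtruncnorm1(1, g$nuclear_area_mean,
            g$nuclear_area_sd,
            lower = 100
          ),
          target_collagen_pct = rtruncnorm1(1, g$collagen_mean_pct,
            g$collagen_sd_pct,
            lower = 0, upper = 100
          )
        )
      })
      if (render) {
        sample <- tryCatch(
          {
            tp <- generate_tpaf(
              image_shape = image_shape,
              n_nuclei = n_nuclei_per_image,
              nucleus_area_mean_px2 = row$target_nuclear_area_px2,
              nucleus_area_sd_px2 = 0.15 * row$target_nuclear_area_px2,
              noise_sd = noise_sd,
              n_bright_blobs = n_bright_blobs,
              seed = derive_seed(child, 1L)
            )
            sh <- generate_shg(
              image_shape = image_shape,
              target_collagen_fraction_pct = row$target_collagen_pct,
              noise_sd = noise_sd,
              seed = derive_seed(child, 2L)
            )
            list(tp = tp, sh = sh)
          },
          error = function(e) {
            stop(sprintf("sample %s: %s", sample_id, conditionMessage(e)),
              call. = FALSE
            )
          }
        )
        row$achieved_collagen_pct <- sample$sh$achieved_fraction_pct
        row$tpaf <- list(sample$tp$image)
        row$tpaf_labels <- list(sample$tp$labels)
        row$tpaf_truth <- list(sample$tp$nuclei)
        row$shg <- list(sample$sh$image)
        row$shg_mask <- list(sample$sh$mask)
      }
      rows[[global_index]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
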