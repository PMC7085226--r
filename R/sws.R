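#' Configuration for spatially constrained watershed superpixels
#'
#' @param seed_spacing_px Spacing of the square seed grid in pixels. A
#'   nucleus can only be recovered as its own (set of) superpixel(s) if at
#'   least one seed falls inside it, which is guaranteed when
#'   `seed_spacing_px <= sqrt(2) * b` for the smallest nuclear semi-minor
#'   axis `b` of interest; the default 12 covers the nuclear size range of
#'   the bundled cohort generator.
#' @param regularization_lambda Weight of the distance-to-seed term added to
#'   the gradient relief (0 = plain marker watershed on the gradient).
#' @param min_nucleus_area_px2,max_nucleus_area_px2 Area filter applied to
#'   merged nuclear components (defaults 50 and 20000 px^2).
#' @param merge_adjacent_nuclear If `TRUE` (default), 4-connected unions of
#'   nuclear superpixels are reported as single nuclei.
#' @param exclude_border If `TRUE`, drop nuclei touching the image border
#'   (default `FALSE`: border nuclei are kept).
#' @return A list of class `sws_config`.
#' @export
sws_config <- function(seed_spacing_px = 12L,
                       regularization_lambda = 0.5,
                       min_nucleus_area_px2 = 50L,
                       max_nucleus_area_px2 = 20000L,
                       merge_adjacent_nuclear = TRUE,
                       exclude_border = FALSE) {
  if (!is.numeric(seed_spacing_px) || seed_spacing_px < 2) {
    stop("`seed_spacing_px` must be a positive integer >= 2", call. = FALSE)
  }
  if (!is.numeric(regularization_lambda) || regularization_lambda < 0) {
    stop("`regularization_lambda` must be non-negative", call. = FALSE)
  }
  if (min_nucleus_area_px2 >= max_nucleus_area_px2) {
    stop("`min_nucleus_area_px2` must be below `max_nucleus_area_px2`", call. = FALSE)
  }
  structure(
    list(
      seed_spacing_px = as.integer(seed_spacing_px),
      regularization_lambda = regularization_lambda,
      min_nucleus_area_px2 = as.integer(min_nucleus_area_px2),
      max_nucleus_area_px2 = as.integer(max_nucleus_area_px2),
      merge_adjacent_nuclear = isTRUE(merge_adjacent_nuclear),
      exclude_border = isTRUE(exclude_border)
    ),
    class = "sws_config"
  )
}

# Centered square seed grid over an nr x nc image.
sws_seed_grid <- function(nr, nc, spacing) {
  n_r <- (nr - 1L) %/% spacing + 1L
  n_c <- (nc - 1L) %/% spacing + 1L
  start_r <- (nr - (n_r - 1L) * spacing) %/% 2L + 1L
  start_c <- (nc - (n_c - 1L) * spacing) %/% 2L + 1L
  rows <- start_r + spacing * (seq_len(n_r) - 1L)
  cols <- start_c + spacing * (seq_len(n_c) - 1L)
  list(rows = rows, cols = cols)
}

#' Spatially constrained watershed superpixel segmentation
#'
#' Partitions an image into one compact superpixel per seed of a regular
#' grid. The relief flooded by the marker watershed is the Sobel gradient
#' magnitude of the (preprocessed) image plus a distance-to-nearest-seed
#' regularization term,
#' `g(p) + lambda * (2 / spacing) * d(p, nearest seed)`,
#' so region boundaries snap to intensity edges while the spatial term keeps
#' regions compact and seed-anchored. On a gradient-free image the relief
#' reduces to the distance transform and the partition is the nearest-seed
#' (Voronoi) tessellation up to flooding-order tie-breaking; ties on relief
#' value are always resolved by first-in-first-out queue order, so the result
#' is deterministic.
#'
#' @param prep Numeric matrix, typically the output of [preprocess_tpaf()].
#' @param cfg An [sws_config()].
#' @return An object of class `sws_labeling`: list with `labels` (integer
#'   matrix, values `1..K`, each 4-connected region containing its seed) and
#'   `seeds` (tibble `seed_id`, `row`, `col`).
#' @export
sws_superpixels <- function(prep, cfg = sws_config()) {
  stopifnot(is.matrix(prep), inherits(cfg, "sws_config"))
  nr <- nrow(prep)
  nc <- ncol(prep)
  if (cfg$seed_spacing_px >= min(nr, nc)) {
    stop("`seed_spacing_px` must be smaller than both image dimensions", call. = FALSE)
  }
  grid <- sws_seed_grid(nr, nc, cfg$seed_spacing_px)
  seed_rows <- rep(grid$rows, times = length(grid$cols))
  seed_cols <- rep(grid$cols, each = length(grid$rows))
  if (length(seed_rows) == 0L) {
    stop("seed grid is empty", call. = FALSE)
  }
  g <- sobel_magnitude(prep)
  # separable exact Euclidean distance to the nearest grid seed
  dr2 <- vapply(seq_len(nr), function(r) min((r - grid$rows)^2), numeric(1))
  dc2 <- vapply(seq_len(nc), function(c) min((c - grid$cols)^2), numeric(1))
  d <- sqrt(outer(dr2, dc2, `+`))
  relief <- g + cfg$regularization_lambda * (2 / cfg$seed_spacing_px) * d
  labels <- .watershed_flood(relief, as.integer(seed_rows), as.integer(seed_cols))
  structure(
    list(
      labels = labels,
      seeds = tibble::tibble(
        seed_id = seq_along(seed_rows),
        row = seed_rows, col = seed_cols
      )
    ),
    class = "sws_labeling"
  )
}

#' @export
print.sws_labeling <- function(x, ...) {
  cat(sprintf(
    "<sws_labeling> %d x %d px, %d superpixels\n",
    nrow(x$labels), ncol(x$labels), nrow(x$seeds)
  ))
  invisible(x)
}

#' Classify superpixels as nuclear (dark) or background
#'
#' Signal-void nuclei are the dark class of a TPAF image. Each superpixel's
#' mean intensity on the preprocessed image is computed and the set of means
#' is split with Otsu's criterion; labels on the dark side of the split are
#' returned. If all means are equal no split exists and the result is empty.
#'
#' @param labeling An [sws_superpixels()] result.
#' @param prep The matching preprocessed intensity matrix.
#' @return Integer vector of nuclear superpixel labels (possibly empty).
#' @export
classify_nuclear_superpixels <- function(labeling, prep) {
  stopifnot(inherits(labeling, "sws_labeling"), is.matrix(prep))
  if (!all(dim(labeling$labels) == dim(prep))) {
    stop("`labeling` and `prep` shapes differ", call. = FALSE)
  }
  means <- superpixel_means(labeling$labels, prep)
  t <- otsu_split(means)
  if (is.na(t)) {
    return(integer(0))
  }
  as.integer(names(means)[means <= t])
}

superpixel_means <- function(labels, prep) {
  sums <- rowsum(as.numeric(prep), as.vector(labels))
  counts <- rowsum(rep(1, length(labels)), as.vector(labels))
  setNames(as.numeric(sums / counts), rownames(sums))
}

#' Measure segmented nuclei
#'
#' Nuclear area is the pixel count of the associated superpixel; with
#' `merge_adjacent_nuclear` (the default) 4-connected unions of nuclear
#' superpixels are measured as single nuclei, so a nucleus spanning several
#' superpixels is counted once. Components outside the configured area range
#' are discarded, as (optionally) are components touching the image border.
#'
#' @param labeling An [sws_superpixels()] result.
#' @param nuclear Integer vector of nuclear superpixel labels, from
#'   [classify_nuclear_superpixels()].
#' @param prep Preprocessed intensity matrix (for mean intensities).
#' @param cfg The [sws_config()] holding the area filter.
#' @return A tibble with one row per nucleus: `nucleus_id`, `area_px2`,
#'   `centroid_row`, `centroid_col`, `mean_intensity`, ordered by
#'   `nucleus_id`.
#' @export
measure_nuclei <- function(labeling, nuclear, prep, cfg = sws_config()) {
  stopifnot(inherits(labeling, "sws_labeling"), inherits(cfg, "sws_config"))
  empty <- tibble::tibble(
    nucleus_id = integer(), area_px2 = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    mean_intensity = numeric()
  )
  if (length(nuclear) == 0L) {
    return(empty)
  }
  if (!all(nuclear %in% labeling$labels)) {
    stop("`nuclear` contains labels absent from the labeling", call. = FALSE)
  }
  mask <- matrix(labeling$labels %in% nuclear, nrow(labeling$labels))
  comp <- if (cfg$merge_adjacent_nuclear) {
    m <- EBImage::bwlabel(mask) # 4-connected components
    matrix(as.integer(m), nrow(mask))
  } else {
    out <- matrix(0L, nrow(mask), ncol(mask))
    for (i in seq_along(nuclear)) {
      out[labeling$labels == nuclear[i]] <- i
    }
    out
  }
  ids <- sort(unique(comp[comp > 0L]))
  rows <- lapply(ids, function(id) {
    px <- which(comp == id)
    idx <- arrayInd(px, dim(comp))
    tibble::tibble(
      area_px2 = length(px),
      centroid_row = mean(idx[, 1L]),
      centroid_col = mean(idx[, 2L]),
      mean_intensity = mean(prep[px]),
      touches_border = any(idx[, 1L] %in% c(1L, nrow(comp))) ||
        any(idx[, 2L] %in% c(1L, ncol(comp)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(
    out,
    .data$area_px2 >= cfg$min_nucleus_area_px2,
    .data$area_px2 <= cfg$max_nucleus_area_px2
  )
  if (cfg$exclude_border) {
    out <- dplyr::filter(out, !.data$touches_border)
  }
  out$touches_border <- NULL
  out$nucleus_id <- seq_len(nrow(out))
  dplyr::select(
    out, "nucleus_id", "area_px2", "centroid_row", "centroid_col",
    "mean_intensity"
  )
}

#' Mean nuclear area of a sample
#'
#' @param records Nucleus tibble from [measure_nuclei()].
#' @return Arithmetic mean of `area_px2`.
#' @export
mean_nuclear_area <- function(records) {
  if (nrow(records) == 0L) {
    stop("no nuclei were segmented in this sample; it must be flagged, not scored as zero",
      call. = FALSE
    )
  }
  mean(records$area_px2)
}

#' Segment nuclei in a TPAF image (full branch)
#'
#' Convenience wrapper chaining [preprocess_tpaf()], [sws_superpixels()],
#' [classify_nuclear_superpixels()] and [measure_nuclei()].
#'
#' @param img TPAF-role [mpm_image()].
#' @param preprocess_cfg A [preprocess_config()].
#' @param sws_cfg An [sws_config()].
#' @return An object of class `nucleus_segmentation`: list with the input
#'   `image`, the preprocessed matrix `prep`, the `labeling`, the
#'   `nuclear_labels`, and the `nuclei` tibble.
#' @export
segment_nuclei <- function(img, preprocess_cfg = preprocess_config(),
                           sws_cfg = sws_config()) {
  prep <- preprocess_tpaf(img, preprocess_cfg)
  labeling <- sws_superpixels(prep, sws_cfg)
  nuclear <- classify_nuclear_superpixels(labeling, prep)
  nuclei <- measure_nuclei(labeling, nuclear, prep, sws_cfg)
  structure(
    list(
      image = img, prep = prep, labeling = labeling,
      nuclear_labels = nuclear, nuclei = nuclei
    ),
    class = "nucleus_segmentation"
  )
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf(
    "<nucleus_segmentation> %d x %d px, %d superpixels, %d nuclei",
    nrow(x$prep), ncol(x$prep), nrow(x$labeling$seeds), nrow(x$nuclei)
  ))
  if (nrow(x$nuclei) > 0L) {
    cat(sprintf(", mean area %.1f px^2", mean(x$nuclei$area_px2)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname segment_nuclei
#' @param x A `nucleus_segmentation` object.
#' @param ... Unused.
#' @method tidy nucleus_segmentation
#' @export
tidy.nucleus_segmentation <- function(x, ...) {
  x$nuclei
}

#' @rdname segment_nuclei
#' @method glance nucleus_segmentation
#' @export
glance.nucleus_segmentation <- function(x, ...) {
  tibble::tibble(
    n_superpixels = nrow(x$labeling$seeds),
    n_nuclei = nrow(x$nuclei),
    mean_area_px2 = if (nrow(x$nuclei)) mean(x$nuclei$area_px2) else NA_real_,
    sd_area_px2 = if (nrow(x$nuclei) > 1L) sd(x$nuclei$area_px2) else NA_real_
  )
}
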