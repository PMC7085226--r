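#' Multiphoton image container
#'
#' An `mpm_image` is a plain numeric matrix of pixel intensities carrying the
#' metadata the quantification pipeline needs: which multiphoton channel the
#' image represents (`"TPAF"` two-photon autofluorescence, in which cells are
#' bright and nuclei are signal-void, or `"SHG"` second-harmonic generation,
#' in which only fibrillar collagen is bright), the bit depth of the original
#' raster, and optionally the pixel size in microns. All quantification is
#' performed on raw intensities in the native `[0, 2^bit_depth - 1]` range;
#' display rescaling happens only at rendering time.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param channel `"TPAF"` or `"SHG"`.
#' @param bit_depth 8 or 16. Defaults to 8 unless intensities exceed 255.
#' @param pixel_size_um Optional positive micron-per-pixel scalar, purely
#'   pass-through metadata (all reported areas are in pixels).
#' @param provenance Free-text source identifier (e.g. a file path).
#'
#' @return An object of class `mpm_image`: the pixel matrix with metadata
#'   attributes.
#' @examples
#' img <- mpm_image(matrix(0:24, 5, 5), channel = "TPAF")
#' img
#' @export
mpm_image <- function(pixels, channel = c("TPAF", "SHG"), bit_depth = NULL,
                      pixel_size_um = NULL, provenance = "") {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("`pixels` must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("intensities must be non-negative and finite", call. = FALSE)
  }
  if (is.null(bit_depth)) {
    bit_depth <- if (max(pixels) > 255) 16L else 8L
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (max(pixels) > 2^bit_depth - 1) {
    stop("intensities exceed the declared bit depth", call. = FALSE)
  }
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0)) {
    stop("`pixel_size_um` must be a positive number", call. = FALSE)
  }
  structure(
    unclass(pixels),
    channel = channel,
    bit_depth = bit_depth,
    pixel_size_um = pixel_size_um,
    provenance = provenance,
    class = c("mpm_image", "matrix", "array")
  )
}

#' @export
print.mpm_image <- function(x, ...) {
  cat(sprintf(
    "<mpm_image> %s, %d x %d px, %d-bit, intensity range [%g, %g]\n",
    attr(x, "channel"), nrow(x), ncol(x), attr(x, "bit_depth"),
    min(x), max(x)
  ))
  if (!is.null(attr(x, "pixel_size_um"))) {
    cat(sprintf("  pixel size: %g um/px\n", attr(x, "pixel_size_um")))
  }
  invisible(x)
}

as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(img))
  m
}

#' Read a single-channel microscopy image
#'
#' Reads a grayscale 8- or 16-bit TIFF (or PNG) as an [mpm_image()] with
#' intensities unmodified. An RGB raster is accepted by extracting the channel
#' matching the display convention for the requested role: red for TPAF and
#' green for SHG.
#'
#' @param path File path to a TIFF or PNG image.
#' @param channel `"TPAF"` or `"SHG"`; stored on the result and used to pick
#'   the channel of an RGB input.
#' @inheritParams mpm_image
#' @return An [mpm_image()].
#' @export
read_mpm_image <- function(path, channel = c("TPAF", "SHG"),
                           pixel_size_um = NULL) {
  channel <- match.arg(channel)
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required to read PNG files", call. = FALSE)
    }
    raw <- png::readPNG(path)
    raw <- raw * 255 # PNG is decoded to [0,1]; display-grade 8-bit assumed
    bits <- 8L
  } else {
    raw <- tryCatch(
      suppressWarnings(tiff::readTIFF(path, as.is = TRUE, info = TRUE)),
      error = function(e) {
        stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
          call. = FALSE
        )
      }
    )
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
    # as.is decoding only applies to single-channel rasters, so fractional
    # values in a 2-D grid mean genuine floating-point samples
    if (length(dim(raw)) == 2L && is.double(raw) && any(raw != floor(raw))) {
      stop(sprintf("unsupported format in '%s': floating-point samples", path),
        call. = FALSE
      )
    }
  }
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3L]
    if (nch > 3L) {
      stop(sprintf("unsupported format in '%s': %d channels (at most 3 supported)", path, nch),
        call. = FALSE
      )
    }
    # multi-channel rasters decode to [0,1]; restore the stored levels
    if (is.double(raw) && max(raw) <= 1 && any(raw != floor(raw))) {
      raw <- raw * (2^bits - 1)
    }
    pick <- if (channel == "TPAF") 1L else min(2L, nch)
    raw <- raw[, , pick]
  }
  m <- matrix(as.numeric(raw), nrow = dim(raw)[1L], ncol = dim(raw)[2L])
  mpm_image(round(m), channel = channel, bit_depth = as.integer(bits),
    pixel_size_um = pixel_size_um, provenance = path
  )
}

#' Write a binary mask as an 8-bit TIFF
#'
#' Foreground pixels carry value 255 and background 0, the convention used
#' for binarized collagen masks. The round trip through [read_mask()] is
#' lossless.
#'
#' @param mask Matrix over \{0, 255\}.
#' @param path Destination TIFF path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  ok <- tryCatch(
    {
      tiff::writeTIFF(unclass(mask) / 255, path, bits.per.sample = 8L)
      TRUE
    },
    error = function(e) {
      stop(sprintf("cannot write mask to '%s': %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  invisible(path)
}

#' Read a binary \{0, 255\} mask written by [write_mask()]
#' @param path TIFF path.
#' @return An integer matrix over \{0, 255\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read mask: file '%s' does not exist", path), call. = FALSE)
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  m <- matrix(as.integer(m), nrow = dim(m)[1L])
  check_binary_mask(m)
  m
}

check_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 255))) {
    stop("a binary mask must be a matrix containing only 0 and 255", call. = FALSE)
  }
  invisible(mask)
}

#' Assemble a montage from fixed-size tiles
#'
#' Places tiles block-wise in row-major order with no blending, registration
#' or intensity correction, reproducing the plain large-area assembly of
#' 512x512 acquisition tiles.
#'
#' @param tiles List of [mpm_image()] tiles in row-major order; all tiles must
#'   share shape, bit depth and channel role.
#' @param grid_rows,grid_cols Montage grid dimensions;
#'   `grid_rows * grid_cols` must equal `length(tiles)`.
#' @return An [mpm_image()] of shape
#'   `(grid_rows * tile_rows, grid_cols * tile_cols)`.
#' @export
assemble_montage <- function(tiles, grid_rows, grid_cols) {
  if (length(tiles) != grid_rows * grid_cols) {
    stop(sprintf(
      "grid %d x %d requires %d tiles, got %d",
      grid_rows, grid_cols, grid_rows * grid_cols, length(tiles)
    ), call. = FALSE)
  }
  stopifnot(length(tiles) >= 1L)
  ref <- tiles[[1L]]
  tr <- nrow(ref)
  tc <- ncol(ref)
  for (t in tiles) {
    if (nrow(t) != tr || ncol(t) != tc) {
      stop("all tiles must share the same shape", call. = FALSE)
    }
    if (!identical(attr(t, "bit_depth"), attr(ref, "bit_depth")) ||
      !identical(attr(t, "channel"), attr(ref, "channel"))) {
      stop("all tiles must share bit depth and channel role", call. = FALSE)
    }
  }
  out <- matrix(0, grid_rows * tr, grid_cols * tc)
  for (r in seq_len(grid_rows)) {
    for (c in seq_len(grid_cols)) {
      tile <- tiles[[(r - 1L) * grid_cols + c]]
      out[(r - 1L) * tr + seq_len(tr), (c - 1L) * tc + seq_len(tc)] <-
        as_pixel_matrix(tile)
    }
  }
  mpm_image(out,
    channel = attr(ref, "channel"), bit_depth = attr(ref, "bit_depth"),
    pixel_size_um = attr(ref, "pixel_size_um"),
    provenance = sprintf("montage %dx%d", grid_rows, grid_cols)
  )
}

#' Render the red/green pseudo-color overlay of a TPAF/SHG pair
#'
#' Follows the display convention of marking the TPAF channel in red and the
#' SHG channel in green; blue is always zero. Each channel is independently
#' min-max rescaled to 8 bits for display; a constant channel is scaled by
#' its bit range instead so an all-zero channel renders black and a saturated
#' one renders at full intensity. The overlay is for visualization only —
#' quantification never uses display-rescaled values.
#'
#' @param tpaf,shg Same-shape [mpm_image()] pair.
#' @return An integer array `(rows, cols, 3)` over `[0, 255]`.
#' @export
render_overlay <- function(tpaf, shg) {
  if (!all(dim(tpaf) == dim(shg))) {
    stop("TPAF and SHG images must have the same shape", call. = FALSE)
  }
  rescale8 <- function(img) {
    m <- as_pixel_matrix(img)
    rng <- range(m)
    if (rng[1L] == rng[2L]) {
      return(round(255 * m / (2^attr(img, "bit_depth") - 1)))
    }
    round(255 * (m - rng[1L]) / (rng[2L] - rng[1L]))
  }
  out <- array(0L, dim = c(nrow(tpaf), ncol(tpaf), 3L))
  out[, , 1L] <- rescale8(tpaf)
  out[, , 2L] <- rescale8(shg)
  out
}

#' Write an RGB overlay as an 8-bit TIFF
#' @param overlay Array from [render_overlay()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(overlay, path) {
  stopifnot(length(dim(overlay)) == 3L, dim(overlay)[3L] == 3L)
  tiff::writeTIFF(overlay / 255, path, bits.per.sample = 8L)
  invisible(path)
}
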