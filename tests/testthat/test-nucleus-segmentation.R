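test_that("preprocessing preserves constants and the intensity range", {
  const <- mpm_image(matrix(120, 32, 32), "TPAF")
  out <- preprocess_tpaf(const)
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(abs(out - 120) < 1e-6))

  ph <- generate_tpaf(n_nuclei = 4, seed = 2)
  prep <- preprocess_tpaf(ph$image)
  expect_true(all(prep >= 0) && all(prep <= 255))
  # erosion stage is anti-extensive relative to the raw extrema
  expect_gte(min(prep), 0)
  expect_lte(max(prep), 255)
})

test_that("erosion spreads dark minima over at least the disk extent", {
  # dark speck in a bright field: after grayscale erosion with a radius-2
  # disk, the global minimum forms a plateau at least as large as the disk
  # (every pixel whose disk neighbourhood contains the minimum takes it)
  m <- matrix(200, 15, 15)
  m[7:9, 7:9] <- 10
  img <- mpm_image(m, "TPAF")
  cfg <- preprocess_config(erosion_radius_px = 2, use_reconstruction = FALSE)
  prep <- preprocess_tpaf(img, cfg)
  brush <- EBImage::makeBrush(5, "disc")
  expect_gte(sum(prep <= min(prep) + 1e-9), sum(brush))
  # a larger structuring element erodes at least as strongly, pointwise
  prep3 <- preprocess_tpaf(img, preprocess_config(
    erosion_radius_px = 3, use_reconstruction = FALSE
  ))
  expect_true(all(prep3 <= prep + 1e-9))
  # reconstruction by dilation can only raise the eroded image
  prep_rec <- preprocess_tpaf(img, preprocess_config(
    erosion_radius_px = 2, use_reconstruction = TRUE
  ))
  expect_true(all(prep_rec >= prep - 1e-9))
})

test_that("preprocessing rejects images smaller than the structuring element", {
  tiny <- mpm_image(matrix(5, 3, 3), "TPAF")
  expect_error(preprocess_tpaf(tiny, preprocess_config(erosion_radius_px = 2)),
    "structuring element"
  )
  expect_error(preprocess_tpaf(mpm_image(matrix(5, 3, 3), "SHG")), "TPAF")
})

test_that("superpixels always form a partition with one region per seed", {
  withr::with_seed(31L, {
    for (rep in 1:5) {
      prep <- matrix(runif(64 * 64, 0, 255), 64, 64)
      sp <- sws_superpixels(prep, sws_config(seed_spacing_px = 16))
      k <- nrow(sp$seeds)
      expect_setequal(unique(as.vector(sp$labels)), seq_len(k))
      expect_equal(sum(tabulate(sp$labels, k)), 64 * 64)
      # each region contains its own seed
      expect_equal(
        sp$labels[cbind(sp$seeds$row, sp$seeds$col)],
        sp$seeds$seed_id
      )
    }
  })
})

test_that("on a uniform image superpixels equal the Voronoi tessellation", {
  prep <- matrix(50, 48, 48)
  sp <- sws_superpixels(prep, sws_config(seed_spacing_px = 12))
  d2 <- vapply(seq_len(nrow(sp$seeds)), function(i) {
    outer((1:48 - sp$seeds$row[i])^2, (1:48 - sp$seeds$col[i])^2, `+`)
  }, matrix(0, 48, 48))
  nearest <- apply(d2, c(1, 2), which.min)
  margin <- apply(d2, c(1, 2), function(v) sqrt(sort(v)[2]) - sqrt(sort(v)[1]))
  # away from equidistant boundaries the tessellation must be exact
  expect_true(all((nearest == sp$labels)[margin > 1]))
  expect_gt(mean(nearest == sp$labels), 0.99)
})

test_that("no superpixel floods across a strong vertical edge", {
  # flooding oracle on a 16x16 two-level instance
  prep <- matrix(20, 16, 16)
  prep[, 9:16] <- 220
  sp <- sws_superpixels(prep, sws_config(seed_spacing_px = 5))
  left_labels <- unique(as.vector(sp$labels[, 1:7]))
  right_labels <- unique(as.vector(sp$labels[, 10:16]))
  expect_length(intersect(left_labels, right_labels), 0)
})

test_that("dark-superpixel classification finds exactly the nucleus cover", {
  ph <- generate_tpaf(
    n_nuclei = 5, nucleus_area_mean_px2 = 700,
    nucleus_area_sd_px2 = 100, noise_sd = 0, seed = 17
  )
  prep <- preprocess_tpaf(ph$image)
  sp <- sws_superpixels(prep, sws_config())
  nuclear <- classify_nuclear_superpixels(sp, prep)
  covered <- sp$labels %in% nuclear
  truth <- ph$labels > 0
  # the nuclear superpixel union and the ground-truth mask agree closely
  expect_gt(sum(covered & truth) / sum(covered | truth), 0.85)

  # constant image: no dark class
  flat <- sws_superpixels(matrix(9, 32, 32), sws_config(seed_spacing_px = 8))
  expect_length(classify_nuclear_superpixels(flat, matrix(9, 32, 32)), 0)
})

test_that("measurement merges adjacent nuclear superpixels and filters areas", {
  labels <- matrix(1L, 12, 12)
  labels[, 5:8] <- 2L
  labels[, 9:12] <- 3L
  labeling <- structure(
    list(labels = labels, seeds = tibble::tibble(
      seed_id = 1:3, row = c(6L, 6L, 6L), col = c(2L, 6L, 10L)
    )),
    class = "sws_labeling"
  )
  prep <- matrix(10, 12, 12)
  # two adjacent nuclear superpixels merge into one nucleus of 96 px
  merged <- measure_nuclei(labeling, c(2L, 3L), prep, sws_config())
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$area_px2, 96L)
  # merging off: two records, sorted by id
  apart <- measure_nuclei(labeling, c(2L, 3L), prep,
    sws_config(merge_adjacent_nuclear = FALSE, min_nucleus_area_px2 = 10)
  )
  expect_equal(apart$area_px2, c(48L, 48L))
  expect_equal(apart$nucleus_id, 1:2)
  # components below the minimum area are filtered out
  kept <- measure_nuclei(labeling, 2L, prep, sws_config(min_nucleus_area_px2 = 40))
  expect_equal(kept$area_px2, 48L)
  none <- measure_nuclei(labeling, 2L, prep, sws_config(min_nucleus_area_px2 = 50))
  expect_equal(nrow(none), 0L)
})

test_that("mean nuclear area averages records and flags empty samples", {
  rec <- tibble::tibble(area_px2 = c(500, 700))
  expect_equal(mean_nuclear_area(rec), 600)
  expect_equal(mean_nuclear_area(tibble::tibble(area_px2 = 600)), 600)
  expect_error(mean_nuclear_area(tibble::tibble(area_px2 = numeric())), "flagged")
})

test_that("measured areas recover rasterized truth on clean phantoms", {
  ph <- generate_tpaf(
    n_nuclei = 6, nucleus_area_mean_px2 = 800, nucleus_area_sd_px2 = 250,
    noise_sd = 0, seed = 29
  )
  seg <- segment_nuclei(ph$image)
  expect_equal(nrow(seg$nuclei), nrow(ph$nuclei))
  matched <- match_nuclei(seg$nuclei, ph$nuclei)
  rel <- abs(seg$nuclei$area_px2 - matched$area_px2) / matched$area_px2
  expect_lt(max(rel), 0.15)
  expect_lt(
    abs(mean(seg$nuclei$area_px2) - mean(ph$nuclei$area_px2)) /
      mean(ph$nuclei$area_px2), 0.05
  )
})

test_that("scaling every ellipse up increases every matched measured area", {
  base <- generate_tpaf(
    image_shape = c(200, 200), n_nuclei = 4,
    nucleus_area_mean_px2 = 500, nucleus_area_sd_px2 = 0, noise_sd = 0, seed = 41
  )
  big <- generate_tpaf(
    image_shape = c(200, 200), n_nuclei = 4,
    nucleus_area_mean_px2 = 500 * 1.5, nucleus_area_sd_px2 = 0, noise_sd = 0,
    seed = 41
  )
  seg_base <- segment_nuclei(base$image)
  seg_big <- segment_nuclei(big$image)
  expect_equal(nrow(seg_base$nuclei), 4L)
  expect_equal(nrow(seg_big$nuclei), 4L)
  # same seed places nuclei at the same centres, so match by centroid
  m_base <- match_nuclei(seg_base$nuclei, base$nuclei)
  m_big <- match_nuclei(seg_big$nuclei, big$nuclei)
  ord_base <- order(m_base$nucleus_id)
  ord_big <- order(m_big$nucleus_id)
  expect_true(all(
    seg_big$nuclei$area_px2[ord_big] > seg_base$nuclei$area_px2[ord_base]
  ))
})

test_that("segmentation is deterministic for a fixed image and config", {
  ph <- generate_tpaf(n_nuclei = 5, seed = 53)
  a <- segment_nuclei(ph$image)
  b <- segment_nuclei(ph$image)
  expect_identical(a$labeling$labels, b$labeling$labels)
  expect_identical(a$nuclei, b$nuclei)
})

test_that("tidy and glance expose the nucleus table and its summary", {
  ph <- generate_tpaf(n_nuclei = 3, seed = 61)
  seg <- segment_nuclei(ph$image)
  expect_identical(tidy(seg), seg$nuclei)
  g <- glance(seg)
  expect_equal(g$n_nuclei, nrow(seg$nuclei))
  expect_equal(g$mean_area_px2, mean(seg$nuclei$area_px2))
})
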