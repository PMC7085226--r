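test_that("TPAF phantom honours its degenerate and deterministic contracts", {
  flat <- generate_tpaf(
    image_shape = c(64, 64), n_nuclei = 0, noise_sd = 0,
    cytoplasm_level = 180, seed = 1
  )
  expect_true(all(flat$image == 180))
  expect_true(all(flat$labels == 0L))
  expect_equal(nrow(flat$nuclei), 0L)

  a <- generate_tpaf(n_nuclei = 5, seed = 99)
  b <- generate_tpaf(n_nuclei = 5, seed = 99)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$labels, b$labels)
})

test_that("rasterized ellipse area matches the closed form pi*a*b within 2%", {
  # a = 20, b = 10 at eccentricity sqrt(1 - (10/20)^2) ~ 0.866
  ecc <- sqrt(1 - 0.25)
  ph <- generate_tpaf(
    image_shape = c(128, 128), n_nuclei = 1,
    nucleus_area_mean_px2 = pi * 20 * 10, nucleus_area_sd_px2 = 0,
    nucleus_eccentricity_range = c(ecc, ecc), noise_sd = 0, seed = 5
  )
  expect_equal(ph$nuclei$area_px2, pi * 20 * 10, tolerance = 0.02)
  expect_equal(ph$nuclei$semi_major_px, 20, tolerance = 1e-6)
  expect_equal(ph$nuclei$semi_minor_px, 10, tolerance = 1e-6)
})

test_that("phantom nuclei are disjoint, dark, and as numerous as requested", {
  for (seed in c(2L, 12L, 22L)) {
    ph <- generate_tpaf(n_nuclei = 9, n_bright_blobs = 2, seed = seed)
    expect_equal(sort(unique(as.vector(ph$labels))), 0:9)
    expect_equal(nrow(ph$nuclei), 9L)
    # label areas equal the per-nucleus truth table
    counts <- as.vector(table(ph$labels[ph$labels > 0]))
    expect_equal(counts, ph$nuclei$area_px2)
    # nuclei are signal voids: darker than the cytoplasm on average
    expect_lt(mean(ph$image[ph$labels > 0]), mean(ph$image[ph$labels == 0]))
  }
})

test_that("nucleus placement fails loudly when the field cannot hold them", {
  expect_error(
    generate_tpaf(
      image_shape = c(64, 64), n_nuclei = 40,
      nucleus_area_mean_px2 = 900, nucleus_area_sd_px2 = 0, seed = 1
    ),
    "could not place nucleus"
  )
})

test_that("SHG phantom hits its target fraction and is seed-deterministic", {
  none <- generate_shg(target_collagen_fraction_pct = 0, noise_sd = 0, seed = 1)
  expect_true(all(none$mask == 0L))
  expect_true(all(none$image == 10))

  half <- generate_shg(
    image_shape = c(256, 256), target_collagen_fraction_pct = 50, seed = 8
  )
  frac <- 100 * mean(half$mask == 255)
  expect_gte(frac, 48)
  expect_lte(frac, 52)
  expect_equal(frac, half$achieved_fraction_pct)

  a <- generate_shg(target_collagen_fraction_pct = 30, seed = 77)
  b <- generate_shg(target_collagen_fraction_pct = 30, seed = 77)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$mask, b$mask)

  # every emitted mask is within the contract band of its target
  for (tgt in c(5, 25, 45)) {
    ph <- generate_shg(target_collagen_fraction_pct = tgt, seed = tgt)
    expect_lte(abs(ph$achieved_fraction_pct - tgt), 2)
  }
})

test_that("unreachable collagen fractions raise a generation error", {
  expect_error(
    generate_shg(
      image_shape = c(64, 64), target_collagen_fraction_pct = 95,
      seed = 1, max_fibers = 25
    ),
    "could not reach"
  )
})

test_that("cohort draws are reproducible and respect degenerate SDs", {
  spec <- cohort_spec(
    pre = list(
      n_samples = 1L, nuclear_area_mean = 600, nuclear_area_sd = 100,
      collagen_mean_pct = 20, collagen_sd_pct = 5
    ),
    post = list(
      n_samples = 1L, nuclear_area_mean = 850, nuclear_area_sd = 100,
      collagen_mean_pct = 36, collagen_sd_pct = 5
    ),
    master_seed = 11L
  )
  a <- generate_cohort(spec, render = TRUE, image_shape = c(128L, 128L),
    n_nuclei_per_image = 3L
  )
  b <- generate_cohort(spec, render = TRUE, image_shape = c(128L, 128L),
    n_nuclei_per_image = 3L
  )
  expect_equal(nrow(a), 2L)
  expect_identical(a$seed, b$seed)
  expect_identical(unclass(a$tpaf[[1]]), unclass(b$tpaf[[1]]))
  expect_identical(a$shg_mask[[2]], b$shg_mask[[2]])

  degen <- cohort_spec(
    pre = list(
      n_samples = 4L, nuclear_area_mean = 600, nuclear_area_sd = 0,
      collagen_mean_pct = 20, collagen_sd_pct = 0
    ),
    post = list(
      n_samples = 4L, nuclear_area_mean = 850, nuclear_area_sd = 0,
      collagen_mean_pct = 36, collagen_sd_pct = 0
    ),
    master_seed = 3L
  )
  manifest <- generate_cohort(degen, render = FALSE)
  expect_true(all(manifest$target_nuclear_area_px2[manifest$group == "pre"] == 600))
  expect_true(all(manifest$target_collagen_pct[manifest$group == "post"] == 36))
})

test_that("cohort target means recover the published group parameters", {
  # stochastic sanity bound: empirical mean of drawn targets within 3 SE
  manifest <- generate_cohort(cohort_spec(master_seed = 421L), render = FALSE)
  for (g in c("pre", "post")) {
    rows <- manifest[manifest$group == g, ]
    expect_equal(nrow(rows), 30L)
    mu <- if (g == "pre") 22.81 else 36.10
    sdv <- if (g == "pre") 10.23 else 12.42
    expect_lt(abs(mean(rows$target_collagen_pct) - mu), 3 * sdv / sqrt(30))
    mu_a <- if (g == "pre") 596.56 else 856.22
    sd_a <- if (g == "pre") 208.69 else 255.74
    expect_lt(abs(mean(rows$target_nuclear_area_px2) - mu_a), 3 * sd_a / sqrt(30))
  }
})
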