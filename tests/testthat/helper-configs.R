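# small, fast pipeline configuration shared by the run-level tests
small_cohort_cfg <- function(out_dir, seed = 5L, n = 2L) {
  list(
    output_dir = out_dir, seed = seed,
    cohort = list(
      pre = list(
        n_samples = n, nuclear_area_mean = 550, nuclear_area_sd = 80,
        collagen_mean_pct = 20, collagen_sd_pct = 6
      ),
      post = list(
        n_samples = n, nuclear_area_mean = 850, nuclear_area_sd = 80,
        collagen_mean_pct = 36, collagen_sd_pct = 6
      ),
      image_shape = c(192L, 192L), n_nuclei_per_image = 5L
    )
  )
}
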