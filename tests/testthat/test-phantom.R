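test_that("parameter maps rasterise lesions, background and air", {
  spec <- small_phantom()
  maps <- generate_parameter_maps(spec)
  # independent discrete-ellipsoid count by direct triple loop
  les <- spec$lesions[[1]]
  cnt <- 0L
  for (x in 1:12) for (y in 1:8) for (z in 1:4)
    if (sum(((c(x, y, z) - les$center) / les$semi_axes)^2) <= 1)
      cnt <- cnt + 1L
  expect_identical(sum(maps$label == 2L), cnt)
  expect_gt(cnt, 0L)
  expect_true(all(maps$D[maps$label == 2L] == les$params$D))
  expect_true(all(maps$s0[maps$label == 0L] == 0))
  # air slab occupies the declared fraction of the first axis
  expect_identical(sum(maps$label == 0L), 3L * 8L * 4L)
})

test_that("zero lesions give pure background; disjoint lesions get labels", {
  bg <- list(params = froc_params(1.5, 0.9, 4), s0 = 80)
  spec0 <- phantom_spec(c(10, 10, 3), lesions = list(), background = bg,
                        air_fraction = 0.2)
  maps0 <- generate_parameter_maps(spec0)
  expect_true(all(maps0$label %in% c(0L, 1L)))
  expect_true(all(maps0$D[maps0$label == 1L] == 1.5))
  two <- phantom_spec(
    c(16, 8, 4),
    lesions = list(
      list(center = c(6, 4, 2), semi_axes = c(2, 2, 1),
           params = froc_params(0.8, 0.75, 3), s0 = 100),
      list(center = c(13, 4, 2), semi_axes = c(2, 2, 1),
           params = froc_params(1.2, 0.85, 3), s0 = 100)),
    background = bg, air_fraction = 0)
  maps2 <- generate_parameter_maps(two)
  expect_identical(sort(unique(as.vector(maps2$label))), c(1L, 2L, 3L))
  # overlapping lesions: later wins, with a warning
  ovl <- phantom_spec(
    c(16, 8, 4),
    lesions = list(
      list(center = c(8, 4, 2), semi_axes = c(3, 3, 1),
           params = froc_params(0.8, 0.75, 3), s0 = 100),
      list(center = c(9, 4, 2), semi_axes = c(3, 3, 1),
           params = froc_params(1.2, 0.85, 3), s0 = 100)),
    background = bg, air_fraction = 0)
  expect_warning(mo <- generate_parameter_maps(ovl), "overlap")
  expect_equal(mo$D[9, 4, 2], 1.2)
  expect_error(phantom_spec(c(8, 8, 4),
                            lesions = list(list(center = c(1, 4, 2),
                                                semi_axes = c(3, 2, 1),
                                                params = froc_params(1, 0.8, 3),
                                                s0 = 1)),
                            background = bg), "outside")
})

test_that("noiseless simulation reproduces the forward model exactly", {
  spec <- small_phantom(noise_sigma = 0)
  sim <- simulate_phantom(spec)
  les <- spec$lesions[[1]]
  vox <- sim$series$data[8, 4, 2, ]
  expect_equal(vox, 100 * froc_signal(les$params, p14$b_values, p14),
               tolerance = 1e-12)
  bgvox <- sim$series$data[5, 1, 1, ]
  expect_equal(bgvox, 60 * froc_signal(spec$background$params,
                                       p14$b_values, p14),
               tolerance = 1e-12)
  expect_true(all(sim$series$data[1, , , ] == 0))  # air slab
})

test_that("air magnitudes follow the Rayleigh mean and seeds are exact", {
  proto1 <- dwi_protocol(c(0, 1000), n_averages = c(1, 1),
                         delta = 25.66, big_delta = 30.13)
  bg <- list(params = froc_params(1, 0.8, 3), s0 = 50)
  spec <- phantom_spec(c(30, 30, 6), lesions = list(), background = bg,
                       air_fraction = 0.5, noise_sigma = 2, seed = 4L)
  maps <- generate_parameter_maps(spec)
  s <- simulate_dwi_series(maps, proto1, noise_sigma = 2, seed = 4L)
  air <- s$data[, , , 1][maps$label == 0L]
  expect_equal(mean(air), 2 * sqrt(pi / 2), tolerance = 0.02)
  s2 <- simulate_dwi_series(maps, proto1, noise_sigma = 2, seed = 4L)
  expect_identical(s$data, s2$data)
  s3 <- simulate_dwi_series(maps, proto1, noise_sigma = 2, seed = 5L)
  expect_false(identical(s$data, s3$data))
})

test_that("tripling the averages shrinks the signal SD by about sqrt(3)", {
  nav1 <- dwi_protocol(c(0, 1000), n_averages = c(1, 1),
                       delta = 25.66, big_delta = 30.13)
  nav3 <- dwi_protocol(c(0, 1000), n_averages = c(3, 3),
                       delta = 25.66, big_delta = 30.13)
  bg <- list(params = froc_params(1, 0.8, 3), s0 = 100)
  spec <- phantom_spec(c(40, 40, 4), lesions = list(), background = bg,
                       air_fraction = 0, noise_sigma = 3)
  maps <- generate_parameter_maps(spec)
  s1 <- simulate_dwi_series(maps, nav1, noise_sigma = 3, seed = 7L)
  s3 <- simulate_dwi_series(maps, nav3, noise_sigma = 3, seed = 8L)
  ratio <- sd(s1$data[, , , 2]) / sd(s3$data[, , , 2])
  expect_equal(ratio, sqrt(3), tolerance = 0.05 * sqrt(3))
})

test_that("cohort draws respect the spec moments and domains", {
  mom <- default_cohort_moments()
  big <- cohort_spec(n_benign = 1e5, n_malignant = 10, moments = mom,
                     seed = 3L)
  co <- simulate_cohort(big)
  bss <- co[co$group == "benign" & co$sequence == "SSEPI", ]
  expect_equal(mean(bss$D), 1.17, tolerance = 0.01 * 1.17)
  expect_equal(sd(bss$D), 0.34, tolerance = 0.02)
  expect_true(all(bss$beta > 0 & bss$beta <= 1))
  expect_true(all(bss$D > 0 & bss$mu > 0 & bss$adc >= 0))
  # zero-SD spec collapses to the mean
  mom0 <- mom
  mom0$benign_sd <- 0; mom0$malignant_sd <- 0
  co0 <- simulate_cohort(cohort_spec(n_benign = 10, n_malignant = 10,
                                     moments = mom0, seed = 1L))
  d0 <- co0$D[co0$group == "benign" & co0$sequence == "SSEPI"]
  expect_true(all(d0 == 1.17))
})

test_that("default cohort at reference group sizes feeds the stats stage", {
  co <- simulate_cohort(cohort_spec(seed = 12L))
  expect_identical(nrow(co), (73L + 105L) * 2L)
  cs <- co[co$sequence == "SSEPI", ]
  cmp <- compare_groups(cs$D[cs$group == "benign"],
                        cs$D[cs$group == "malignant"])
  expect_lt(cmp$p, 0.001)
  # paired sequences are strongly correlated for D, moderately for mu
  wd <- merge(co[co$sequence == "SSEPI", c("lesion_id", "D", "mu")],
              co[co$sequence == "SMS", c("lesion_id", "D", "mu")],
              by = "lesion_id")
  expect_gt(cor(wd$D.x, wd$D.y, method = "spearman"), 0.85)
  expect_lt(cor(wd$mu.x, wd$mu.y, method = "spearman"), 0.85)
})

test_that("series, mask and cohort IO round-trip with contract errors", {
  spec <- phantom_spec(c(16, 16, 16), lesions = list(),
                       background = list(params = froc_params(1, 0.8, 3),
                                         s0 = 90),
                       air_fraction = 0.2, noise_sigma = 1, seed = 2L)
  sim <- simulate_phantom(spec)
  path <- file.path(tempdir(), "series.nii.gz")
  write_series(sim$series, path)
  back <- read_series(path)
  expect_equal(back$data, sim$series$data, tolerance = 1e-6)  # float32
  expect_equal(back$protocol$b_values, p14$b_values)
  # sidecar with fewer b-values than volumes is a format error
  bad <- dwi_protocol(p14$b_values[-14], p14$n_averages[-14],
                      p14$delta, p14$big_delta)
  write_protocol(bad, sidecar_path <- sub("\\.nii\\.gz$", ".yaml", path))
  expect_error(read_series(path), "does not match")
  mpath <- file.path(tempdir(), "mask.nii.gz")
  write_mask(generate_parameter_maps(spec)$label > 0, mpath)
  m <- read_mask(mpath, c(16, 16, 16))
  expect_identical(dim(m), c(16L, 16L, 16L))
  expect_error(read_mask(mpath, c(8, 8, 8)), "shape")
  cpath <- file.path(tempdir(), "cohort.csv")
  co <- simulate_cohort(cohort_spec(n_benign = 5, n_malignant = 5))
  write_cohort(co, cpath)
  expect_equal(read_cohort(cpath)$D, co$D)
  expect_error(read_cohort(write_protocol(p14, file.path(tempdir(),
                                                         "x.yaml"))))
})
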