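test_that("sum-to-one normalization is exact, idempotent and scale-free", {
  expect_equal(normalize_spectrum(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  s <- normalize_spectrum(stats::rexp(26))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(normalize_spectrum(s), s)
  raw <- c(2, 5, 3)
  expect_equal(normalize_spectrum(37.5 * raw), normalize_spectrum(raw))
  expect_error(normalize_spectrum(rep(0, 5)), "all-zero")
  expect_error(normalize_spectrum(c(1, -1, 3)), "non-negative")
})

test_that("CNR mask thresholds against background statistics", {
  set.seed(7)
  img <- matrix(stats::rnorm(64, mean = 1, sd = 1), 8, 8)
  img[3, 5] <- max(img) + 10
  bg <- matrix(TRUE, 8, 8); bg[3, 5] <- FALSE
  mask <- cnr_mask(img, bg, threshold = 2)
  # brute-force reference over all pixels
  ref <- (img - mean(img[bg])) / stats::sd(img[bg]) >= 2
  expect_identical(mask, ref)
  expect_true(mask[3, 5])
  # threshold 0 with positive contrast keeps everything
  img2 <- matrix(5, 4, 4); img2[1, 1] <- 0
  bg2 <- matrix(FALSE, 4, 4); bg2[1, ] <- TRUE
  expect_true(all(cnr_mask(img2, bg2, threshold = 0)[img2 > mean(img2[bg2])]))
  expect_error(cnr_mask(matrix(1, 4, 4), matrix(TRUE, 4, 4), 2),
               "degenerate")
})

test_that("an image drawn from the background law rarely passes CNR 2", {
  set.seed(11)
  hits <- replicate(200, {
    img <- matrix(stats::rnorm(400), 20, 20)
    mean(cnr_mask(img, matrix(TRUE, 20, 20), threshold = 2))
  })
  # P(Z >= 2) ~ 2.3%; the empirical pass rate stays close to that
  expect_lt(mean(hits), 0.05)
})

test_that("amplitude mask keeps pixels strictly above threshold", {
  img <- matrix(c(1e4, 2e4, 3e4, 5e4), 2, 2)
  expect_equal(sum(amplitude_mask(img, 2e4)), 2L)
  expect_false(any(amplitude_mask(img, max(img))))
  expect_true(all(amplitude_mask(img, -Inf)))
})

test_that("small connected components are removed at the 20-pixel rule", {
  mask <- matrix(FALSE, 20, 20)
  mask[2:20, 2] <- TRUE            # 19-pixel component
  mask[5:11, 10:12] <- TRUE        # 21-pixel component
  out <- filter_min_size(mask, min_pixels = 20)
  expect_false(any(out[, 2]))
  expect_true(all(out[5:11, 10:12]))
  expect_identical(filter_min_size(mask, min_pixels = 1), mask)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(filter_min_size(empty, 20), empty)
  # diagonal touching is not connected under 4-connectivity
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_false(any(filter_min_size(diagm, 2)))
})

test_that("frame averaging reduces noise variance by 1/k", {
  one <- matrix(stats::rnorm(25), 5, 5)
  frames <- array(rep(one, 10), dim = c(5, 5, 10))
  frames <- aperm(frames, c(3, 1, 2))
  expect_equal(average_frames(frames, k = 10), one)
  two <- array(c(matrix(0, 2, 2), matrix(2, 2, 2)), dim = c(2, 2, 2))
  expect_equal(average_frames(aperm(two, c(3, 1, 2)), k = 2),
               matrix(1, 2, 2))
  expect_error(average_frames(frames, k = 11), "frames")
  set.seed(3)
  noise <- array(stats::rnorm(10 * 30 * 30), dim = c(10, 30, 30))
  v1 <- stats::var(as.vector(noise[1, , ]))
  vk <- stats::var(as.vector(average_frames(noise, k = 10)))
  expect_equal(vk / v1, 0.1, tolerance = 0.05)
})

test_that("dataset rows are normalized vessel pixels labeled with truth", {
  v <- sample_flow(small_spec("flow", seed = 41))
  st <- simulate_multispectral(v, resolve_wavelengths("flow"))
  ds <- build_dataset(list(st), list(v), seed = 2)
  expect_s3_class(ds, "spectra_dataset")
  expect_gt(nrow(ds$spectra), 0)
  expect_true(all(abs(rowSums(ds$spectra) - 1) < 1e-9))
  expect_true(all(ds$so2 == v$ground_truth_so2[["2"]]))
  expect_true(all(ds$meta$tissue_label == "vessel"))
  expect_true(all(ds$so2 >= 0 & ds$so2 <= 1))
  # deterministic given the seed
  ds2 <- build_dataset(list(st), list(v), seed = 2)
  expect_identical(ds$spectra, ds2$spectra)
})

test_that("masks are monotone in the CNR threshold", {
  v <- sample_generic(small_spec("generic", seed = 43))
  st <- simulate_multispectral(v, resolve_wavelengths("generic"))
  n2 <- nrow(build_dataset(list(st), list(v), cnr_threshold = 2,
                           seed = 6)$spectra)
  n5 <- nrow(suppressWarnings(
    build_dataset(list(st), list(v), cnr_threshold = 5, seed = 6)$spectra))
  expect_lte(n5, n2)
})

test_that("spectra datasets round-trip through CSV", {
  v <- sample_flow(small_spec("flow", seed = 44))
  st <- simulate_multispectral(v, resolve_wavelengths("flow"))
  ds <- build_dataset(list(st), list(v), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_spectra_csv(ds, path)
  back <- read_spectra_csv(path)
  expect_equal(back$spectra, ds$spectra, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$so2, ds$so2)
  expect_equal(back$wavelengths, ds$wavelengths)
})
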