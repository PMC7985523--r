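test_that("seeded generation is bit-reproducible for all three domains", {
  for (kind in c("generic", "flow", "forearm")) {
    a <- sample_phantom(small_spec(kind, seed = 11))
    b <- sample_phantom(small_spec(kind, seed = 11))
    expect_identical(a$labels, b$labels)
    expect_identical(a$ground_truth_so2, b$ground_truth_so2)
    expect_identical(a$geometry, b$geometry)
    c <- sample_phantom(small_spec(kind, seed = 12))
    expect_false(identical(a$labels, c$labels) &&
                   identical(a$ground_truth_so2, c$ground_truth_so2))
  }
})

test_that("generic phantoms share one uniform oxygenation across structures", {
  so2 <- vapply(1:1000, function(i) {
    v <- sample_generic(small_spec("generic", seed = 1000 + i))
    expect_equal(length(unique(v$ground_truth_so2)), 1L)
    v$ground_truth_so2[[1]]
  }, numeric(1))
  expect_gt(stats::ks.test(so2, "punif")$p.value, 0.01)
})

test_that("vessel-class structures always carry 100% blood volume", {
  for (kind in c("generic", "flow", "forearm")) {
    v <- sample_phantom(small_spec(kind, seed = 5))
    vessel_labels <- names(v$tissue_class)[
      v$tissue_class %in% c("vessel", "artery", "vein")]
    expect_gt(length(vessel_labels), 0)
    for (l in vessel_labels)
      expect_equal(v$compositions[[l]]$blood_volume_fraction, 1.0)
  }
})

test_that("generic background has 0.5% blood volume and mu_s' = 10", {
  v <- sample_generic(small_spec("generic", seed = 3))
  bg <- v$compositions[["1"]]
  expect_equal(bg$blood_volume_fraction, 0.005)
  expect_equal(bg$mus_prime_ref, 10)
})

test_that("flow phantom samples match the stated parameter laws", {
  draws <- lapply(1:1000, function(i)
    sample_flow(small_spec("flow", seed = 2000 + i))$geometry)
  r <- vapply(draws, function(g) g$tube[["r"]], numeric(1))
  w <- vapply(draws, function(g) g$water_fraction, numeric(1))
  expect_true(all(r >= 0.5 & r <= 2.5))
  expect_true(all(w >= 0.5 & w <= 1.0))
  expect_gt(stats::ks.test((r - 0.5) / 2, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test((w - 0.5) / 0.5, "punif")$p.value, 0.01)
  v <- sample_flow(small_spec("flow", seed = 2001))
  expect_equal(v$compositions[["1"]]$mus_prime_ref, 5)
  expect_equal(v$compositions[["2"]]$hemoglobin_concentration, 150)
  expect_identical(v$illumination, "pencil")
})

test_that("forearm property sampling reproduces the table means", {
  set.seed(99)
  draws <- replicate(10000, unlist(lsdox:::sample_forearm_params()))
  means <- rowMeans(draws)
  # vein N(70, 10)%: clipping is negligible three sigma from the bounds
  expect_equal(unname(means["vein_oxy"]), 0.70, tolerance = 0.01)
  # artery N(95, 5)% clipped to [0, 1]: clipped mean is ~0.946
  expect_equal(unname(means["artery_oxy"]), 0.946, tolerance = 0.01)
  expect_equal(unname(means["dermis_oxy"]), 0.80, tolerance = 0.01)
  expect_equal(unname(means["bone_water"]), 0.19, tolerance = 0.005)
  expect_equal(unname(means["epidermis_melanin"]), 0.022, tolerance = 0.005)
  expect_gt(stats::ks.test(draws["vessel_oxy", ], "punif")$p.value, 0.01)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("forearm volumes are fully labeled with composition entries", {
  v <- sample_forearm(small_spec("forearm", seed = 8))
  labs <- sort(unique(as.vector(v$labels)))
  expect_true(all(as.character(labs) %in% names(v$compositions)))
  expect_true(all(as.character(labs) %in% names(v$tissue_class)))
  # gel pad carries no blood or melanin absorption
  gel <- v$compositions[["1"]]
  expect_equal(gel$blood_volume_fraction + gel$melanin_fraction +
                 gel$water_fraction, 0)
})

test_that("optical_volume binds compositions to per-voxel coefficients", {
  v <- sample_generic(small_spec("generic", seed = 21))
  opt <- optical_volume(v, 800)
  expect_identical(dim(opt$mu_a), dim(v$labels))
  expect_true(all(opt$mu_a >= 0))
  tab <- load_chromophore_table()
  bg_mu <- 0.005 * blood_absorption(v$ground_truth_so2[[1]], 150, 800, tab)
  expect_equal(opt$mu_a[v$labels == 1][1], bg_mu)
  # uniform single-label volume gives a constant grid
  u <- v; u$labels[] <- 1L
  bg_mu_750 <- 0.005 * blood_absorption(v$ground_truth_so2[[1]], 150, 750, tab)
  expect_equal(range(optical_volume(u, 750)$mu_a), rep(bg_mu_750, 2))
})
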