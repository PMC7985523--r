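test_that("layered model reproduces Beer-Lambert in non-scattering media", {
  nz <- 210; d <- 0.05  # mm; voxel centers span just past 1 cm depth
  mu_a <- matrix(1, 2, nz)
  msp <- matrix(0, 2, nz)
  fl <- fluence_layered(mu_a, msp, voxel_size_mm = d)
  zc <- (seq_len(nz) - 0.5) * d / 10  # voxel centers in cm
  expect_equal(fl$values[1, ], exp(-zc), tolerance = 1e-12)
  # interpolated value at 1 cm depth is e^-1
  phi_1cm <- stats::approx(zc, fl$values[1, ], xout = 1)$y
  expect_equal(phi_1cm, exp(-1), tolerance = 1e-4)
})

test_that("layered model has unit fluence without absorption", {
  fl <- fluence_layered(matrix(0, 3, 50), matrix(0, 3, 50))
  expect_true(all(fl$values == 1))
})

test_that("layered decay constant equals mu_eff in the diffusive regime", {
  nz <- 100
  fl <- fluence_layered(matrix(0.1, 1, nz), matrix(10, 1, nz),
                        voxel_size_mm = 0.1)
  dec <- -diff(log(fl$values[1, ])) / 0.01
  expect_equal(unname(dec[1]), sqrt(3 * 0.1 * 10.1), tolerance = 1e-9)
  expect_equal(unname(dec[50]), 1.7407, tolerance = 1e-4)
  # monotone non-increasing with depth
  expect_true(all(diff(fl$values[1, ]) <= 0))
  expect_error(fluence_layered(matrix(-1, 1, 5), matrix(0, 1, 5)),
               "non-negative")
})

test_that("initial pressure is Gamma * mu_a * phi", {
  mu_a <- matrix(c(0, 1, 2, 0.5), 2, 2)
  fl <- list(values = matrix(0.5, 2, 2))
  class(fl) <- "fluence_map"
  p1 <- initial_pressure(mu_a, fl, gruneisen = 1)
  expect_equal(p1, 0.5 * mu_a)
  expect_true(all(p1[mu_a == 0] == 0))
  expect_equal(initial_pressure(mu_a, fl, gruneisen = 2), 2 * p1)
  expect_error(initial_pressure(matrix(1, 3, 3), fl), "shape")
})

test_that("MC runs are seeded and bit-reproducible", {
  mu_a <- matrix(0.5, 8, 20); mu_s <- matrix(20, 8, 20)
  g <- matrix(0.9, 8, 20)
  cfg <- mc_config(photon_count = 2000, seed = 77)
  a <- fluence_mc(mu_a, mu_s, g, "slab", cfg)
  b <- fluence_mc(mu_a, mu_s, g, "slab", cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$totals, b$totals)
})

test_that("MC conserves packet weight to numerical precision", {
  mu_a <- matrix(0.5, 16, 40); mu_s <- matrix(30, 16, 40)
  g <- matrix(0.85, 16, 40)
  fl <- fluence_mc(mu_a, mu_s, g, "slab",
                   mc_config(photon_count = 5000, seed = 3))
  t <- fl$totals
  balance <- t[["absorbed"]] + t[["escaped"]] + t[["killed"]] - t[["gained"]]
  expect_equal(balance, t[["injected"]], tolerance = 1e-6)
  expect_true(all(fl$values >= 0))
  expect_true(all(is.finite(fl$values)))
})

test_that("MC matches Beer-Lambert in a non-scattering slab", {
  ny <- 5; nz <- 100; d_mm <- 0.1; d_cm <- d_mm / 10
  mu_a <- matrix(2, ny, nz); mu_s <- matrix(0, ny, nz)
  g <- matrix(0, ny, nz)
  n <- 1e5
  fl <- fluence_mc(mu_a, mu_s, g, "pencil",
                   mc_config(photon_count = n, seed = 9),
                   voxel_size_mm = d_mm)
  mid <- (ny + 1) %/% 2
  depths <- round(seq(5, 95, length.out = 10))
  for (iz in depths) {
    z1 <- (iz - 1) * d_cm; z2 <- iz * d_cm
    p <- exp(-2 * z1) - exp(-2 * z2)       # absorption probability in voxel
    se_phi <- sqrt(p * (1 - p) / n) / (2 * d_cm)
    expect_lt(abs(fl$values[mid, iz] - p / (2 * d_cm)), 3 * se_phi)
  }
})

test_that("MC deposits nothing in a non-absorbing medium", {
  mu_a <- matrix(0, 8, 30); mu_s <- matrix(50, 8, 30)
  g <- matrix(0.9, 8, 30)
  fl <- fluence_mc(mu_a, mu_s, g, "slab",
                   mc_config(photon_count = 3000, seed = 5))
  expect_equal(fl$totals[["absorbed"]], 0)
  expect_true(all(is.finite(fl$values)))
  expect_true(all(fl$values >= 0))
  expect_gt(max(fl$values), 0)  # track-length fluence still accumulates
})

test_that("MC asymptotic decay matches diffusion theory in a scattering slab", {
  # grid deep enough (2.56 cm) that the absorbing bottom boundary does not
  # reach back into the fit window
  ny <- 50; nz <- 256; d_mm <- 0.1
  mu_a <- matrix(0.1, ny, nz); mu_s <- matrix(100, ny, nz)
  g <- matrix(0.9, ny, nz)
  fl <- fluence_mc(mu_a, mu_s, g, "slab",
                   mc_config(photon_count = 1e5, seed = 13,
                             boundary = "periodic"),
                   voxel_size_mm = d_mm)
  prof <- colMeans(fl$values)
  zc <- (seq_len(nz) - 0.5) * d_mm / 10
  sel <- zc > 0.5 & zc < 1.2   # well past 3 transport mean free paths
  fit <- stats::lm(log(prof[sel]) ~ zc[sel])
  mu_eff <- sqrt(3 * 0.1 * (0.1 + 10))
  expect_equal(unname(-stats::coef(fit)[2]), mu_eff, tolerance = 0.1)
})

test_that("multispectral simulation yields one map per wavelength", {
  v <- sample_generic(small_spec("generic", seed = 31))
  st <- simulate_multispectral(v, resolve_wavelengths("generic"))
  expect_equal(dim(st$p0)[1], 26L)
  vf <- sample_flow(small_spec("flow", seed = 32))
  stf <- simulate_multispectral(vf, resolve_wavelengths("flow"))
  expect_equal(dim(stf$p0)[1], 17L)
  # p0 is zero only where mu_a is zero; here background absorbs everywhere
  expect_true(all(st$p0 >= 0))
  # deterministic MC stacks under a fixed seed
  cfg <- mc_config(photon_count = 500, seed = 4)
  s1 <- simulate_multispectral(v, c(700, 800), model = "mc", cfg = cfg)
  s2 <- simulate_multispectral(v, c(700, 800), model = "mc", cfg = cfg)
  expect_identical(s1$p0, s2$p0)
})

test_that("spectral coloring grows with depth and biases linear unmixing", {
  # one vessel geometry at two depths under an absorbing background
  spec <- phantom_spec("generic", grid_shape = c(40L, 120L),
                       voxel_size_mm = 0.1)
  tab <- load_chromophore_table()
  wl <- resolve_wavelengths("generic")
  make_vol <- function(depth_mm) {
    labels <- matrix(1L, 40, 120)
    co <- lsdox:::grid_coords(spec)
    labels <- lsdox:::paint_circle(labels, co, cy = 2, cz = depth_mm,
                                   r_mm = 0.4, value = 2L)
    comps <- list(`1` = tissue_composition(blood_volume_fraction = 0.005,
                                           oxygenation = 0.8,
                                           mus_prime_ref = 10),
                  `2` = tissue_composition(blood_volume_fraction = 1,
                                           oxygenation = 0.8,
                                           mus_prime_ref = 10))
    lsdox:::new_labeled_volume(labels, comps,
                               c(`1` = "background", `2` = "vessel"),
                               c(`1` = 0.8, `2` = 0.8), "slab", spec)
  }
  spectrum_at_top <- function(depth_mm) {
    vol <- make_vol(depth_mm)
    st <- simulate_multispectral(vol, wl, tab)
    iz <- which.max(apply(vol$labels == 2L, 2, any))  # top row of the vessel
    iy <- which(vol$labels[, iz] == 2L)[1]
    normalize_spectrum(st$p0[, iy, iz])
  }
  s_shallow <- spectrum_at_top(2)
  s_deep <- spectrum_at_top(9)
  expect_gt(sum(abs(s_deep - s_shallow)), 0)
  lu_sh <- linear_unmix(s_shallow, wl, tab)$so2
  lu_dp <- linear_unmix(s_deep, wl, tab)$so2
  expect_gt(abs(lu_dp - 0.8), abs(lu_sh - 0.8))
})
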