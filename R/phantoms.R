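#' Phantom generation specification
#'
#' Describes one synthetic tissue domain to draw from. Volumes are 2D
#' cross-sections of the imaging plane: `grid_shape = c(ny, nz)` voxels with
#' `ny` lateral columns and `nz` depth rows, the illuminated surface at depth
#' zero. Defaults mirror a 256 x 128 pixel image at 0.1 mm voxel size
#' (25.6 mm wide, 12.8 mm deep).
#'
#' @param dataset_kind one of `"generic"`, `"flow"`, `"forearm"`.
#' @param grid_shape integer vector `c(ny, nz)`.
#' @param voxel_size_mm voxel edge length in mm.
#' @param seed RNG seed for reproducible sampling, or `NULL`.
#' @param n_vessels_range integer range for the number of vessel tubes drawn
#'   uniformly (generic and forearm sets).
#' @param vessel_radius_mm radius range (mm) for generic/forearm vessels.
#' @param flow_radius_mm radius range (mm) for the single flow-phantom tube.
#' @param generic_mus_prime background reduced scattering of the generic set
#'   (cm^-1).
#' @param flow_mus_prime agar reduced scattering of the flow set (cm^-1).
#' @param scattering_is_reduced if `TRUE` (default) the generic set's
#'   "scattering coefficient of 10 cm^-1" is interpreted as the reduced
#'   coefficient mu_s'; if `FALSE` it is taken as mu_s and converted with the
#'   anisotropy g = 0.9.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dataset_kind = c("generic", "flow", "forearm"),
                         grid_shape = c(256L, 128L), voxel_size_mm = 0.1,
                         seed = NULL, n_vessels_range = c(1L, 5L),
                         vessel_radius_mm = c(0.3, 1.5),
                         flow_radius_mm = c(0.5, 2.5),
                         generic_mus_prime = 10, flow_mus_prime = 5,
                         scattering_is_reduced = TRUE) {
  dataset_kind <- match.arg(dataset_kind)
  if (length(grid_shape) != 2L || any(grid_shape < 1))
    stopf("grid_shape must be two positive integers c(ny, nz)")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be > 0")
  structure(list(dataset_kind = dataset_kind,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, seed = seed,
                 n_vessels_range = as.integer(n_vessels_range),
                 vessel_radius_mm = vessel_radius_mm,
                 flow_radius_mm = flow_radius_mm,
                 generic_mus_prime = generic_mus_prime,
                 flow_mus_prime = flow_mus_prime,
                 scattering_is_reduced = scattering_is_reduced),
            class = "phantom_spec")
}

# voxel-center coordinate grids in mm; labels is [ny, nz]
grid_coords <- function(spec) {
  d <- spec$voxel_size_mm
  list(y = (seq_len(spec$grid_shape[1]) - 0.5) * d,
       z = (seq_len(spec$grid_shape[2]) - 0.5) * d,
       width = spec$grid_shape[1] * d, depth = spec$grid_shape[2] * d)
}

# paint a filled circle (tube cross-section) into an integer label matrix
paint_circle <- function(labels, coords, cy, cz, r_mm, value) {
  dy2 <- outer((coords$y - cy)^2, (coords$z - cz)^2, `+`)
  labels[dy2 <= r_mm^2] <- value
  labels
}

new_labeled_volume <- function(labels, compositions, tissue_class,
                               ground_truth_so2, illumination, spec,
                               geometry = NULL) {
  lev <- sort(unique(as.vector(labels)))
  if (!all(as.character(lev) %in% names(compositions)))
    stopf("labeled volume is inconsistent: labels without composition entry")
  structure(list(labels = labels, compositions = compositions,
                 tissue_class = tissue_class,
                 ground_truth_so2 = ground_truth_so2,
                 illumination = illumination,
                 voxel_size_mm = spec$voxel_size_mm, spec = spec,
                 geometry = geometry),
            class = "labeled_volume")
}

# reduced scattering actually used for the homogeneous sets, honouring the
# mu_s vs mu_s' interpretation switch
homog_mus_prime <- function(spec, nominal, g = 0.9) {
  if (spec$scattering_is_reduced) nominal else nominal * (1 - g)
}

#' Sample a generic-tissue phantom
#'
#' Randomly placed vessel tubes with 100% blood volume fraction in a
#' homogeneous background with 0.5% blood volume fraction and constant
#' reduced scattering (10 cm^-1 by default). All structures, background
#' included, share one oxygenation value drawn uniformly from \[0, 1\].
#'
#' @param spec a [phantom_spec()] with `dataset_kind = "generic"`.
#' @return a `labeled_volume`.
#' @export
sample_generic <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$dataset_kind == "generic")
  with_seed(spec$seed, {
    co <- grid_coords(spec)
    so2 <- stats::runif(1)
    nv <- sample(seq(spec$n_vessels_range[1], spec$n_vessels_range[2]), 1)
    labels <- matrix(1L, spec$grid_shape[1], spec$grid_shape[2])
    tubes <- data.frame(cy = numeric(nv), cz = numeric(nv), r = numeric(nv))
    for (k in seq_len(nv)) {
      r <- stats::runif(1, spec$vessel_radius_mm[1], spec$vessel_radius_mm[2])
      if (2 * r > min(co$width, co$depth))
        stopf("vessel radius %.2f mm does not fit the grid", r)
      cy <- stats::runif(1, r, co$width - r)
      cz <- stats::runif(1, r, co$depth - r)
      tubes[k, ] <- c(cy, cz, r)
      labels <- paint_circle(labels, co, cy, cz, r, k + 1L)
    }
    msp <- homog_mus_prime(spec, spec$generic_mus_prime)
    comps <- list(`1` = tissue_composition(blood_volume_fraction = 0.005,
                                           oxygenation = so2,
                                           mus_prime_ref = msp))
    class_of <- c(`1` = "background")
    so2_of <- c(`1` = so2)
    for (k in seq_len(nv)) {
      key <- as.character(k + 1L)
      comps[[key]] <- tissue_composition(blood_volume_fraction = 1,
                                         oxygenation = so2,
                                         mus_prime_ref = msp)
      class_of[key] <- "vessel"
      so2_of[key] <- so2
    }
    new_labeled_volume(labels, comps, class_of, so2_of, "slab", spec,
                       geometry = list(vessels = tubes))
  })
}

#' Sample a blood-flow phantom
#'
#' A single blood-filled tube (hemoglobin 150 g/L, oxygenation uniform in
#' \[0, 1\], radius uniform in 0.5--2.5 mm) embedded in an agar background
#' with reduced scattering 5 cm^-1 and water content uniform in 50--100%.
#' Illumination is tagged as a pencil beam.
#'
#' @param spec a [phantom_spec()] with `dataset_kind = "flow"`.
#' @return a `labeled_volume`.
#' @export
sample_flow <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$dataset_kind == "flow")
  with_seed(spec$seed, {
    co <- grid_coords(spec)
    so2 <- stats::runif(1)
    water <- stats::runif(1, 0.5, 1.0)
    r <- stats::runif(1, spec$flow_radius_mm[1], spec$flow_radius_mm[2])
    if (2 * r > min(co$width, co$depth))
      stopf("tube radius %.2f mm exceeds the grid", r)
    cy <- co$width / 2 + stats::runif(1, -2, 2)
    zmin <- r + 0.3
    zmax <- min(co$depth - r - 0.3, 10)
    cz <- stats::runif(1, zmin, max(zmin, zmax))
    labels <- matrix(1L, spec$grid_shape[1], spec$grid_shape[2])
    labels <- paint_circle(labels, co, cy, cz, r, 2L)
    msp <- spec$flow_mus_prime
    comps <- list(
      `1` = tissue_composition(water_fraction = water, mus_prime_ref = msp),
      `2` = tissue_composition(blood_volume_fraction = 1, oxygenation = so2,
                               hemoglobin_concentration = 150,
                               mus_prime_ref = msp))
    new_labeled_volume(labels, comps, c(`1` = "agar", `2` = "vessel"),
                       c(`1` = NA_real_, `2` = so2), "pencil", spec,
                       geometry = list(tube = c(cy = cy, cz = cz, r = r),
                                       water_fraction = water))
  })
}

# Per-structure parameter draws for the forearm domain: uniform ranges X-Y,
# Gaussian ranges X +/- Y clipped to [0, 1]. Returned values are fractions.
sample_forearm_params <- function() {
  clip01 <- function(x) pmin(1, pmax(0, x))
  list(epidermis_melanin = clip01(stats::rnorm(1, 0.022, 0.01)),
       dermis_oxy  = clip01(stats::rnorm(1, 0.80, 0.10)),
       muscle_oxy  = clip01(stats::rnorm(1, 0.80, 0.10)),
       artery_oxy  = clip01(stats::rnorm(1, 0.95, 0.05)),
       vein_oxy    = clip01(stats::rnorm(1, 0.70, 0.10)),
       bone_water  = clip01(stats::rnorm(1, 0.19, 0.01)),
       vessel_oxy  = stats::runif(1))
}

#' Sample a forearm phantom
#'
#' Layered geometry (coupling gel pad, epidermis, dermis, muscle) with an
#' embedded bone, randomly placed vessel tubes, one artery and one vein.
#' Tissue compositions follow the forearm property table: dermis and muscle
#' carry 1% blood at oxygenation N(80%, 10%), the artery N(95%, 5%), the
#' vein N(70%, 10%), generic vessels U(0, 100%); the epidermis holds melanin
#' N(2.2%, 1%) and the bone water N(19%, 1%). Gaussian draws are clipped to
#' \[0, 1\]. Each blood-carrying vessel structure has 100% blood volume
#' fraction at 150 g/L hemoglobin.
#'
#' @param spec a [phantom_spec()] with `dataset_kind = "forearm"`.
#' @return a `labeled_volume`.
#' @export
sample_forearm <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$dataset_kind == "forearm")
  with_seed(spec$seed, {
    co <- grid_coords(spec)
    p <- sample_forearm_params()
    t_gel <- stats::runif(1, 1, 2)
    t_epi <- stats::runif(1, 0.1, 0.3)
    t_der <- stats::runif(1, 1, 2)
    z_der <- t_gel + t_epi          # top of dermis, mm
    z_mus <- z_der + t_der          # top of muscle, mm

    labels <- matrix(4L, spec$grid_shape[1], spec$grid_shape[2])  # muscle
    zc <- co$z
    labels[, zc <= z_mus] <- 3L     # dermis
    labels[, zc <= z_der] <- 2L     # epidermis
    labels[, zc <= t_gel] <- 1L     # gel pad

    # bone deep in the muscle; the circle may be truncated by the grid
    r_bone <- stats::runif(1, 2, 4)
    cy_bone <- stats::runif(1, r_bone, co$width - r_bone)
    cz_bone <- stats::runif(1, 9, 11.5)
    labels <- paint_circle(labels, co, cy_bone, cz_bone, r_bone, 5L)

    nv <- sample(seq(spec$n_vessels_range[1], spec$n_vessels_range[2]), 1)
    vessel_oxy <- numeric(nv)
    next_label <- 6L
    for (k in seq_len(nv)) {
      r <- stats::runif(1, spec$vessel_radius_mm[1], spec$vessel_radius_mm[2])
      cy <- stats::runif(1, r, co$width - r)
      cz <- stats::runif(1, z_der + r, min(co$depth - r, z_mus + 6))
      vessel_oxy[k] <- stats::runif(1)
      labels <- paint_circle(labels, co, cy, cz, r, next_label)
      next_label <- next_label + 1L
    }
    lab_artery <- next_label; lab_vein <- next_label + 1L
    r_a <- stats::runif(1, 0.5, 1.25)
    cy_a <- stats::runif(1, r_a, co$width - r_a)
    cz_a <- stats::runif(1, z_mus + r_a, min(co$depth - r_a, z_mus + 5))
    labels <- paint_circle(labels, co, cy_a, cz_a, r_a, lab_artery)
    r_v <- stats::runif(1, 0.5, 1.25)
    cy_v <- stats::runif(1, r_v, co$width - r_v)
    cz_v <- stats::runif(1, z_mus + r_v, min(co$depth - r_v, z_mus + 5))
    labels <- paint_circle(labels, co, cy_v, cz_v, r_v, lab_vein)

    blood <- function(oxy, msp, b) tissue_composition(
      blood_volume_fraction = 1, oxygenation = oxy,
      hemoglobin_concentration = 150, mus_prime_ref = msp, scatter_power = b)
    comps <- list(
      `1` = tissue_composition(mus_prime_ref = 1.0),
      `2` = tissue_composition(melanin_fraction = p$epidermis_melanin,
                               mus_prime_ref = 15, scatter_power = 1.5),
      `3` = tissue_composition(blood_volume_fraction = 0.01,
                               oxygenation = p$dermis_oxy,
                               water_fraction = 0.58,
                               mus_prime_ref = 12, scatter_power = 1.3),
      `4` = tissue_composition(blood_volume_fraction = 0.01,
                               oxygenation = p$muscle_oxy,
                               water_fraction = 0.68,
                               mus_prime_ref = 7, scatter_power = 0.9),
      `5` = tissue_composition(water_fraction = p$bone_water,
                               mus_prime_ref = 20, scatter_power = 0.9))
    class_of <- c(`1` = "gel_pad", `2` = "epidermis", `3` = "dermis",
                  `4` = "muscle", `5` = "bone")
    so2_of <- c(`1` = NA_real_, `2` = NA_real_, `3` = p$dermis_oxy,
                `4` = p$muscle_oxy, `5` = NA_real_)
    for (k in seq_len(nv)) {
      key <- as.character(5L + k)
      comps[[key]] <- blood(vessel_oxy[k], 2, 0.66)
      class_of[key] <- "vessel"
      so2_of[key] <- vessel_oxy[k]
    }
    comps[[as.character(lab_artery)]] <- blood(p$artery_oxy, 2, 0.66)
    class_of[as.character(lab_artery)] <- "artery"
    so2_of[as.character(lab_artery)] <- p$artery_oxy
    comps[[as.character(lab_vein)]] <- blood(p$vein_oxy, 2, 0.66)
    class_of[as.character(lab_vein)] <- "vein"
    so2_of[as.character(lab_vein)] <- p$vein_oxy

    geom <- list(layers_mm = c(gel = t_gel, epidermis = t_epi,
                               dermis = t_der),
                 bone = c(cy = cy_bone, cz = cz_bone, r = r_bone),
                 artery = c(cy = cy_a, cz = cz_a, r = r_a),
                 vein = c(cy = cy_v, cz = cz_v, r = r_v),
                 params = p)
    new_labeled_volume(labels, comps, class_of, so2_of, "slab", spec,
                       geometry = geom)
  })
}

#' Sample a phantom of any dataset kind
#'
#' Dispatches to [sample_generic()], [sample_flow()] or [sample_forearm()]
#' according to `spec$dataset_kind`.
#'
#' @param spec a [phantom_spec()].
#' @return a `labeled_volume`.
#' @export
sample_phantom <- function(spec) {
  switch(spec$dataset_kind,
         generic = sample_generic(spec),
         flow = sample_flow(spec),
         forearm = sample_forearm(spec))
}

#' Per-voxel optical properties of a labeled volume
#'
#' Binds each voxel's label composition to the chromophore model at one
#' wavelength.
#'
#' @param vol a `labeled_volume`.
#' @param wavelength wavelength in nm (scalar).
#' @param table chromophore table.
#' @return list of matrices `mu_a`, `mu_s`, `mu_s_prime` (cm^-1) and `g`.
#' @export
optical_volume <- function(vol, wavelength, table = load_chromophore_table()) {
  stopifnot(inherits(vol, "labeled_volume"), length(wavelength) == 1L)
  lev <- sort(unique(as.vector(vol$labels)))
  mua <- mus <- msp <- gg <- numeric(max(lev))
  for (l in lev) {
    comp <- vol$compositions[[as.character(l)]]
    if (is.null(comp)) stopf("label %d has no composition entry", l)
    mua[l] <- tissue_absorption(comp, wavelength, table)
    sc <- tissue_scattering(comp, wavelength)
    mus[l] <- sc$mu_s; msp[l] <- sc$mu_s_prime; gg[l] <- sc$g
  }
  shape <- dim(vol$labels)
  out <- lapply(list(mua, mus, msp, gg), function(v) {
    m <- v[vol$labels]; dim(m) <- shape; m
  })
  names(out) <- c("mu_a", "mu_s", "mu_s_prime", "g")
  out
}
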