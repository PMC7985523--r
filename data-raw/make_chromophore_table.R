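# Builds inst/extdata/chromophores_nir_synthetic.tsv
#
# Synthetic NIR chromophore compilation: smooth spectra interpolated through
# landmark anchor values of the standard tissue-optics literature (hemoglobin
# molar extinction compilations, pure-water absorption tables, and the
# parametric melanosome power law).  The table is a stand-in constructed for
# simulation and unmixing; it reproduces the qualitative landmarks that the
# oximetry problem depends on (Hb peak near 760 nm, Hb/HbO2 isosbestic point
# at 800 nm, rising HbO2 absorption beyond 800 nm, water shoulder at 740 nm
# and rise towards 970 nm) but is not a verbatim copy of any published table.
#
# Units: wavelength nm; absorption cm^-1.  Hemoglobin columns are whole-blood
# absorption at a total hemoglobin concentration of 150 g/L:
#   mu_a = ln(10) * eps [M^-1 cm^-1] * (150 g/L) / (64500 g/mol)

grid <- seq(650, 1000, by = 5)

# molar extinction anchors, M^-1 cm^-1
hb_anchor <- c(
  `650` = 3750, `660` = 3227, `680` = 2408, `700` = 1794, `710` = 1540,
  `720` = 1326, `730` = 1102, `740` = 1116, `750` = 1405, `760` = 1549,
  `770` = 1312, `780` = 1075, `790` = 900,  `800` = 780,  `810` = 717,
  `820` = 694,  `840` = 692,  `850` = 691,  `880` = 726,  `900` = 762,
  `920` = 780,  `940` = 794,  `950` = 796,  `960` = 798,  `980` = 780,
  `1000` = 764
)
hbo2_anchor <- c(
  `650` = 368,  `660` = 320,  `680` = 278,  `700` = 290,  `710` = 314,
  `720` = 348,  `730` = 390,  `740` = 446,  `750` = 518,  `760` = 586,
  `770` = 650,  `780` = 710,  `790` = 760,  `800` = 816,  `810` = 864,
  `820` = 916,  `840` = 1022, `850` = 1058, `880` = 1154, `900` = 1198,
  `920` = 1230, `940` = 1214, `950` = 1204, `960` = 1192, `980` = 1154,
  `1000` = 1096
)
# pure water absorption anchors, cm^-1
water_anchor <- c(
  `650` = 0.0034, `680` = 0.0050, `700` = 0.0060, `720` = 0.0104,
  `740` = 0.0270, `750` = 0.0266, `760` = 0.0257, `780` = 0.0223,
  `800` = 0.0206, `820` = 0.0237, `840` = 0.0306, `850` = 0.0433,
  `880` = 0.0561, `900` = 0.0679, `920` = 0.1120, `940` = 0.2670,
  `950` = 0.3880, `960` = 0.4200, `970` = 0.4500, `980` = 0.4300,
  `1000` = 0.3600
)

interp <- function(anchor, grid) {
  x <- as.numeric(names(anchor))
  y <- unname(anchor)
  pmax(stats::spline(x, y, xout = grid, method = "natural")$y, 1e-6)
}

eps_to_mua <- log(10) * 150 / 64500

tab <- data.frame(
  wavelength_nm = grid,
  mu_a_hbo2    = round(interp(hbo2_anchor, grid) * eps_to_mua, 6),
  mu_a_hb      = round(interp(hb_anchor, grid) * eps_to_mua, 6),
  mu_a_water   = round(interp(water_anchor, grid), 6),
  # melanosome interior power law: 1.70e12 * lambda^-3.48 cm^-1
  mu_a_melanin = round(1.70e12 * grid^-3.48, 6)
)

stopifnot(all(tab >= 0))
i800 <- which(grid == 800)
stopifnot(abs(tab$mu_a_hbo2[i800] - tab$mu_a_hb[i800]) / tab$mu_a_hb[i800] < 0.05)

header <- c(
  "# Synthetic NIR chromophore compilation (see data-raw/make_chromophore_table.R).",
  "# Smooth spectra interpolated through landmark anchor values from the standard",
  "# tissue-optics literature; a constructed stand-in, not a verbatim published table.",
  "# Columns: wavelength_nm, mu_a_hbo2, mu_a_hb (whole blood at 150 g/L hemoglobin,",
  "# cm^-1), mu_a_water (pure water, cm^-1), mu_a_melanin (melanosome interior, cm^-1)."
)
out <- "inst/extdata/chromophores_nir_synthetic.tsv"
writeLines(header, out)
suppressWarnings(write.table(tab, out, sep = "\t", quote = FALSE,
                             row.names = FALSE, append = TRUE))
cat("wrote", out, "with", nrow(tab), "rows\n")
cat("isosbestic mismatch at 800 nm:",
    abs(tab$mu_a_hbo2[i800] - tab$mu_a_hb[i800]) / tab$mu_a_hb[i800], "\n")
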