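#' Linear spectral unmixing of Hb and HbO2
#'
#' The conventional baseline: non-negative least-squares fit of the two
#' hemoglobin endmember spectra to a measured p0 spectrum, with sO2 taken as
#' the oxyhemoglobin share of the fitted coefficients,
#' `so2 = a_hbo2 / (a_hb + a_hbo2)`. The fit assumes the signal is
#' proportional to `mu_a` alone; wavelength-dependent fluence (spectral
#' coloring) violates that assumption and biases the estimate, which is the
#' effect the learned decoloring model corrects.
#'
#' The sO2 ratio is invariant under positive rescaling of the input, so raw
#' and sum-normalized spectra give identical estimates. Coefficients are
#' constrained non-negative by default (negative chromophore amounts are
#' unphysical and would push the ratio outside \[0, 1\]); `bounded = FALSE`
#' switches to the unconstrained least-squares fit.
#'
#' @param spectrum numeric vector of p0 values, one per wavelength.
#' @param wavelengths wavelength grid of the spectrum in nm.
#' @param table chromophore table supplying the endmember spectra.
#' @param bounded constrain coefficients to be non-negative (default TRUE).
#' @return object of class `unmix_result`: `coef_hb`, `coef_hbo2`, `so2`
#'   (`NA` when both coefficients vanish), `residual_norm`.
#' @export
linear_unmix <- function(spectrum, wavelengths,
                         table = load_chromophore_table(), bounded = TRUE) {
  if (length(spectrum) != length(wavelengths))
    stopf("spectrum and wavelength grid lengths differ")
  E <- cbind(hb = chromophore_absorption(table, "hb", wavelengths),
             hbo2 = chromophore_absorption(table, "hbo2", wavelengths))
  coef <- fit_endmembers(E, as.numeric(spectrum), bounded)
  tot <- sum(coef)
  structure(list(coef_hb = coef[1], coef_hbo2 = coef[2],
                 so2 = if (tot > 1e-12) coef[2] / tot else NA_real_,
                 residual_norm = sqrt(sum((spectrum - E %*% coef)^2))),
            class = "unmix_result")
}

fit_endmembers <- function(E, s, bounded = TRUE) {
  if (bounded) {
    fit <- pracma::lsqnonneg(E, s)
    pmax(fit$x, 0)
  } else {
    drop(qr.solve(E, s))
  }
}

# vectorized unmixing of a spectra matrix; returns per-row sO2
unmix_so2_matrix <- function(spectra, wavelengths,
                             table = load_chromophore_table(),
                             bounded = TRUE) {
  E <- cbind(chromophore_absorption(table, "hb", wavelengths),
             chromophore_absorption(table, "hbo2", wavelengths))
  apply(spectra, 1, function(s) {
    coef <- fit_endmembers(E, s, bounded)
    tot <- sum(coef)
    if (tot > 1e-12) coef[2] / tot else NA_real_
  })
}

#' Pixel-wise linear unmixing of a multispectral stack
#'
#' Applies [linear_unmix()] to every masked pixel of a p0 stack.
#'
#' @param stack a `p0_stack`.
#' @param mask logical matrix; default all pixels.
#' @param table chromophore table.
#' @param bounded see [linear_unmix()].
#' @return list of matrices `so2` and `residual` (`NA` outside the mask).
#' @export
unmix_image <- function(stack, mask = NULL,
                        table = load_chromophore_table(), bounded = TRUE) {
  stopifnot(inherits(stack, "p0_stack"))
  shape <- dim(stack$p0)[2:3]
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  sel <- which(mask)
  so2 <- resid <- matrix(NA_real_, shape[1], shape[2])
  if (!length(sel)) return(list(so2 = so2, residual = resid))
  nwl <- length(stack$wavelengths)
  E <- cbind(chromophore_absorption(table, "hb", stack$wavelengths),
             chromophore_absorption(table, "hbo2", stack$wavelengths))
  mat <- matrix(stack$p0, nrow = nwl)[, sel, drop = FALSE]
  for (j in seq_along(sel)) {
    coef <- fit_endmembers(E, mat[, j], bounded)
    tot <- sum(coef)
    so2[sel[j]] <- if (tot > 1e-12) coef[2] / tot else NA_real_
    resid[sel[j]] <- sqrt(sum((mat[, j] - E %*% coef)^2))
  }
  list(so2 = so2, residual = resid)
}
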