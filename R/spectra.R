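#' Sum-to-one spectrum normalization
#'
#' Divides a raw per-pixel p0 spectrum by its sum so the components sum to
#' one. This discards the amplitude information and with it the need to
#' calibrate simulated data to a device's absolute signal scale; only the
#' spectral shape is retained.
#'
#' @param s non-negative numeric vector (one entry per wavelength).
#' @return normalized spectrum summing to 1.
#' @export
normalize_spectrum <- function(s) {
  if (any(s < 0)) stopf("spectrum entries must be non-negative")
  tot <- sum(s)
  if (tot <= 0) stopf("cannot normalize an all-zero spectrum")
  s / tot
}

# row-wise normalization of a spectra matrix; rows with zero sum are dropped
normalize_rows <- function(m) {
  tot <- rowSums(m)
  keep <- tot > 0
  list(spectra = m[keep, , drop = FALSE] / tot[keep], keep = keep)
}

#' Contrast-to-noise-ratio pixel mask
#'
#' CNR is computed as `(signal - background mean) / background std`; the
#' mask keeps pixels with CNR at or above the threshold. In the source data
#' this is applied to the image at the 800 nm isosbestic point, where the
#' signal does not depend on oxygenation.
#'
#' @param image numeric matrix (typically the 800 nm image).
#' @param background_region logical matrix marking background pixels.
#' @param threshold CNR threshold (default 2).
#' @return logical mask of the same shape as `image`.
#' @export
cnr_mask <- function(image, background_region, threshold = 2) {
  if (!identical(dim(image), dim(background_region)))
    stopf("image and background region shapes differ")
  bg <- image[background_region]
  if (length(bg) == 0) stopf("background region is empty")
  s <- stats::sd(bg)
  if (!is.finite(s) || s == 0)
    stopf("degenerate background: zero noise standard deviation")
  (image - mean(bg)) / s >= threshold
}

#' Amplitude pixel mask
#'
#' Keeps pixels whose signal is strictly above an absolute threshold
#' (default 2e4, the instrument signal-unit threshold used for flow-phantom tube
#' segmentation).
#'
#' @param image numeric matrix.
#' @param threshold signal threshold.
#' @return logical mask.
#' @export
amplitude_mask <- function(image, threshold = 2e4) {
  image > threshold
}

#' Remove small connected components from a mask
#'
#' Labels connected components under 4-connectivity in the imaging plane and
#' removes components with fewer than `min_pixels` pixels (default 20, the
#' minimum vessel size used for forearm vessel masks).
#'
#' @param mask logical matrix.
#' @param min_pixels minimum component size to keep.
#' @return filtered logical mask.
#' @export
filter_min_size <- function(mask, min_pixels = 20) {
  if (min_pixels <= 1 || !any(mask)) return(mask)
  comp <- label_components(mask)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_pixels)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[comp %in% keep] <- TRUE
  out
}

# 4-connected component labelling by iterative flood fill
label_components <- function(mask) {
  ny <- nrow(mask); nz <- ncol(mask)
  comp <- matrix(0L, ny, nz)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      iy <- (v - 1L) %% ny + 1L
      iz <- (v - 1L) %/% ny + 1L
      for (nb in list(c(iy - 1L, iz), c(iy + 1L, iz),
                      c(iy, iz - 1L), c(iy, iz + 1L))) {
        if (nb[1] < 1L || nb[1] > ny || nb[2] < 1L || nb[2] > nz) next
        u <- (nb[2] - 1L) * ny + nb[1]
        if (mask[u] && comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

#' Average consecutive frames
#'
#' Arithmetic mean of `k` consecutive frames (default 10), the averaging
#' used to suppress pulse-energy fluctuations in repeated acquisitions.
#'
#' @param frames 3D array `[n_frames, ny, nz]` or list of matrices.
#' @param k number of consecutive frames to average.
#' @param start index of the first frame in the window.
#' @return averaged image matrix.
#' @export
average_frames <- function(frames, k = 10, start = 1) {
  if (is.list(frames)) {
    arr <- array(0, dim = c(length(frames), dim(frames[[1]])))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  n <- dim(frames)[1]
  if (start < 1 || start + k - 1 > n)
    stopf("need %d consecutive frames starting at %d, have %d", k, start, n)
  sel <- frames[start:(start + k - 1), , , drop = FALSE]
  apply(sel, c(2, 3), mean)
}

# classes counted as vascular ROI structures
VESSEL_CLASSES <- c("vessel", "artery", "vein")

#' Build a labeled spectra dataset from simulated stacks
#'
#' Extracts one normalized per-pixel p0 spectrum per masked vessel pixel,
#' labeled with that pixel's ground-truth sO2. Masking follows the ROI rule
#' of the source experiments: Gaussian noise (sigma = `noise_frac` times the
#' stack maximum) is added to the stack, and vessel-class pixels are kept
#' where the image nearest 800 nm has CNR >= `cnr_threshold` against the
#' non-vessel background.
#'
#' @param stacks list of `p0_stack` objects (see [simulate_multispectral()]).
#' @param volumes list of matching `labeled_volume` objects.
#' @param cnr_threshold CNR threshold (default 2).
#' @param noise_frac Gaussian noise sigma as a fraction of the per-stack
#'   maximum signal (default 0.01); 0 disables noise (and CNR masking, since
#'   noise-free synthetic data has no noise floor).
#' @param spectra_noise if `TRUE` the extracted spectra themselves carry the
#'   noise; by default (`FALSE`) noise enters only the 800 nm image that
#'   realizes the CNR mask, and spectra are read from the clean stack, which
#'   matches training on simulated p0 tuples directly.
#' @param min_pixels minimum connected-component size within the mask
#'   (default 0 = keep all).
#' @param seed RNG seed for the noise draws.
#' @return object of class `spectra_dataset`: `spectra` matrix `[N, n]` of
#'   sum-normalized rows, `so2` labels, `wavelengths`, and `meta` data frame
#'   (`phantom_id`, `depth_mm`, `tissue_label`).
#' @export
build_dataset <- function(stacks, volumes, cnr_threshold = 2,
                          noise_frac = 0.01, spectra_noise = FALSE,
                          min_pixels = 0, seed = NULL) {
  stopifnot(length(stacks) == length(volumes))
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(stacks)) {
      st <- stacks[[i]]; vol <- volumes[[i]]
      p0 <- clean <- st$p0
      if (noise_frac > 0) {
        sigma <- noise_frac * max(p0)
        p0 <- p0 + array(stats::rnorm(length(p0), 0, sigma), dim = dim(p0))
        p0[p0 < 0] <- 0
      }
      if (!spectra_noise) p0_rows <- clean else p0_rows <- p0
      i800 <- which.min(abs(st$wavelengths - 800))
      img800 <- p0[i800, , ]
      cls <- vol$tissue_class[as.character(vol$labels)]
      dim(cls) <- dim(vol$labels)
      vessel_px <- cls %in% VESSEL_CLASSES
      dim(vessel_px) <- dim(vol$labels)
      mask <- vessel_px
      if (noise_frac > 0) {
        bg <- !vessel_px
        mask <- mask & cnr_mask(img800, bg, cnr_threshold)
      }
      if (min_pixels > 0) mask <- filter_min_size(mask, min_pixels)
      sel <- which(mask)
      if (!length(sel)) next
      nwl <- length(st$wavelengths)
      mat <- t(matrix(p0_rows, nrow = nwl)[, sel, drop = FALSE])
      nr <- normalize_rows(mat)
      sel <- sel[nr$keep]
      if (!length(sel)) next
      iz <- (sel - 1L) %/% nrow(vol$labels) + 1L
      labs <- vol$labels[sel]
      rows[[length(rows) + 1L]] <- list(
        spectra = nr$spectra,
        so2 = unname(vol$ground_truth_so2[as.character(labs)]),
        meta = data.frame(
          phantom_id = i,
          depth_mm = (iz - 0.5) * vol$voxel_size_mm,
          tissue_label = unname(vol$tissue_class[as.character(labs)]),
          stringsAsFactors = FALSE))
    }
    if (!length(rows)) {
      warning("empty ROI: no pixels passed the mask rule")
      return(structure(list(spectra = matrix(0, 0, length(stacks[[1]]$wavelengths)),
                            so2 = numeric(0),
                            wavelengths = stacks[[1]]$wavelengths,
                            meta = data.frame(phantom_id = integer(0),
                                              depth_mm = numeric(0),
                                              tissue_label = character(0))),
                       class = "spectra_dataset"))
    }
    structure(list(spectra = do.call(rbind, lapply(rows, `[[`, "spectra")),
                   so2 = unlist(lapply(rows, `[[`, "so2")),
                   wavelengths = stacks[[1]]$wavelengths,
                   meta = do.call(rbind, lapply(rows, `[[`, "meta"))),
              class = "spectra_dataset")
  })
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d spectra x %d wavelengths (%g-%g nm), %d phantoms\n",
              nrow(x$spectra), length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), length(unique(x$meta$phantom_id))))
  invisible(x)
}

#' Write / read a spectra dataset as CSV
#'
#' Columns: one `wl_<nm>` column per wavelength, then `so2`, `phantom_id`,
#' `depth_mm`, `tissue_label`.
#'
#' @param dataset a `spectra_dataset`.
#' @param path output CSV path.
#' @return `path` (write) or a `spectra_dataset` (read), invisibly for write.
#' @export
write_spectra_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$spectra)
  names(df) <- paste0("wl_", dataset$wavelengths)
  df$so2 <- dataset$so2
  df <- cbind(df, dataset$meta)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  structure(list(spectra = as.matrix(df[wl_cols]),
                 so2 = df$so2,
                 wavelengths = as.numeric(sub("^wl_", "", wl_cols)),
                 meta = df[c("phantom_id", "depth_mm", "tissue_label")]),
            class = "spectra_dataset")
}
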