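#' Resolve a wavelength specification
#'
#' Accepts an explicit numeric grid, a `list(start, stop, step)` in nm, or a
#' named preset: `"generic"` and `"forearm"` give the 26 equidistant
#' wavelengths 700-950 nm in 10 nm steps; `"flow"` gives the 17 acquisition
#' wavelengths {660, 664, 680, 684, 694, 700, 708, 715, 730, 735, 760, 770,
#' 775, 779, 800, 850, 950} nm.
#'
#' @param spec numeric vector, `list(start, stop, step)`, or preset name.
#' @return sorted numeric wavelength grid with at least two entries.
#' @export
resolve_wavelengths <- function(spec) {
  wl <- if (is.character(spec)) {
    switch(match.arg(spec, c("generic", "forearm", "flow")),
           generic = ,
           forearm = seq(700, 950, by = 10),
           flow = c(660, 664, 680, 684, 694, 700, 708, 715, 730, 735,
                    760, 770, 775, 779, 800, 850, 950))
  } else if (is.list(spec)) {
    if (is.null(spec$start) || is.null(spec$stop) || is.null(spec$step))
      stopf("wavelength list spec needs start, stop and step")
    if (spec$stop <= spec$start || spec$step <= 0)
      stopf("wavelength spec must be increasing")
    seq(spec$start, spec$stop, by = spec$step)
  } else {
    as.numeric(spec)
  }
  if (length(wl) < 2)
    stopf("wavelength grid must hold at least 2 wavelengths (unmixing needs 2)")
  if (is.unsorted(wl, strictly = TRUE)) {
    if (anyDuplicated(wl)) stopf("wavelength grid has duplicate entries")
    wl <- sort(wl)
  }
  wl
}

# per-domain phantom counts for the desk-scale experiments
default_n_phantoms <- function(kind) {
  switch(kind, generic = 96L, flow = 96L, forearm = 48L)
}

#' Simulate a labeled spectra dataset for one synthetic domain
#'
#' Generates seeded phantoms, runs the optical forward model per wavelength,
#' and extracts the masked, normalized, labeled pixel spectra.
#'
#' @param kind `"generic"`, `"flow"` or `"forearm"`.
#' @param n_phantoms number of phantoms (defaults per domain: 96 generic,
#'   96 flow, 48 forearm).
#' @param wavelengths wavelength grid or spec (default: the domain preset).
#' @param seed master seed; phantom and noise seeds are derived from it.
#' @param model forward model, `"layered"` or `"mc"`.
#' @param cfg_mc [mc_config()] for `model = "mc"`.
#' @param noise_frac Gaussian noise level for extraction (see
#'   [build_dataset()]).
#' @param cnr_threshold CNR masking threshold.
#' @param table chromophore table.
#' @param spec_options named list of extra [phantom_spec()] arguments.
#' @return list with `dataset` (a `spectra_dataset`), `volumes`, `stacks`.
#' @export
simulate_dataset <- function(kind, n_phantoms = default_n_phantoms(kind),
                             wavelengths = kind, seed = 1,
                             model = c("layered", "mc"), cfg_mc = mc_config(),
                             noise_frac = 0.01, spectra_noise = FALSE,
                             cnr_threshold = 2,
                             table = load_chromophore_table(),
                             spec_options = list()) {
  model <- match.arg(model)
  wl <- resolve_wavelengths(wavelengths)
  volumes <- vector("list", n_phantoms)
  stacks <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    args <- c(list(dataset_kind = kind, seed = seed + i), spec_options)
    sp <- do.call(phantom_spec, args)
    volumes[[i]] <- sample_phantom(sp)
    cfg_i <- cfg_mc
    if (model == "mc") cfg_i$seed <- seed + 100000L + i
    stacks[[i]] <- simulate_multispectral(volumes[[i]], wl, table, model,
                                          cfg_i)
  }
  dataset <- build_dataset(stacks, volumes, cnr_threshold = cnr_threshold,
                           noise_frac = noise_frac,
                           spectra_noise = spectra_noise,
                           seed = seed + 200000L)
  list(dataset = dataset, volumes = volumes, stacks = stacks)
}

#' Run one in-silico LSD experiment end to end
#'
#' The desk-scale twin of the in-silico study design: simulate a synthetic
#' domain, extract labeled spectra, train the LSD regressor on 75% of the
#' phantoms, and evaluate on the held-out 20% test split. Optionally runs
#' the linear-unmixing baseline on the same test rows.
#'
#' @inheritParams simulate_dataset
#' @param profile `"desk"` (40 epochs of 100 batches of 512 with three
#'   validation-selected restarts, the default) or `"paper"` (100 epochs of
#'   500 batches of 1e4, single run).
#' @param compare_lu also unmix the test rows and summarize their errors.
#' @param train_options named list of [lsd_config()] overrides applied on
#'   top of the profile (e.g. `list(epochs = 5)` for quick runs).
#' @return list of class `lsd_experiment`: `model`, `dataset`, `test_index`,
#'   `estimates`, `truth`, `summary` (an `error_summary`), and `lu_estimates`
#'   / `lu_summary` when requested.
#' @export
run_insilico_experiment <- function(kind,
                                    n_phantoms = default_n_phantoms(kind),
                                    seed = 1,
                                    profile = c("desk", "paper"),
                                    compare_lu = FALSE,
                                    model = "layered",
                                    noise_frac = 0.01,
                                    spectra_noise = FALSE,
                                    table = load_chromophore_table(),
                                    spec_options = list(),
                                    train_options = list()) {
  profile <- match.arg(profile)
  sim <- simulate_dataset(kind, n_phantoms, kind, seed, model,
                          noise_frac = noise_frac,
                          spectra_noise = spectra_noise, table = table,
                          spec_options = spec_options)
  dataset <- sim$dataset
  n_wl <- length(dataset$wavelengths)
  targs <- utils::modifyList(list(seed = seed + 300000L), train_options)
  cfg <- if (profile == "desk") {
    do.call(lsd_config_desk, c(list(n_inputs = n_wl), targs))
  } else {
    do.call(lsd_config, c(list(n_inputs = n_wl), targs))
  }
  fit <- train_lsd(dataset, cfg)
  te <- fit$split$test
  est <- predict(fit, dataset$spectra[te, , drop = FALSE])
  truth <- dataset$so2[te]
  out <- list(kind = kind, model = fit, dataset = dataset, test_index = te,
              estimates = est, truth = truth,
              summary = error_summary(est, truth))
  if (compare_lu) {
    out$lu_estimates <- unmix_so2_matrix(dataset$spectra[te, , drop = FALSE],
                                         dataset$wavelengths, table)
    ok <- !is.na(out$lu_estimates)
    out$lu_summary <- error_summary(out$lu_estimates[ok], truth[ok])
  }
  class(out) <- "lsd_experiment"
  out
}

#' @export
print.lsd_experiment <- function(x, ...) {
  cat(sprintf("<lsd_experiment> %s set: %d test spectra from %d phantoms\n",
              x$kind, length(x$truth),
              length(unique(x$dataset$meta$phantom_id[x$test_index]))))
  cat("LSD "); print(x$summary)
  if (!is.null(x$lu_summary)) { cat("LU "); print(x$lu_summary) }
  invisible(x)
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration (see the presets under
#' `system.file("presets", package = "lsdox")`) and fills unset fields with
#' the domain defaults.
#'
#' @param path YAML file path, or a preset name (`"generic"`, `"flow"`,
#'   `"forearm"`).
#' @return named list of pipeline settings.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    preset <- system.file("presets", paste0(path, ".yaml"), package = "lsdox")
    if (!nzchar(preset)) stopf("config file or preset '%s' not found", path)
    path <- preset
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$dataset_kind)) stopf("config must set dataset_kind")
  defaults <- list(n_phantoms = default_n_phantoms(cfg$dataset_kind),
                   wavelengths = cfg$dataset_kind, seed = 1,
                   profile = "desk", model = "layered", noise_frac = 0.01,
                   compare_lu = TRUE)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

#' Run the full pipeline and write its artifacts
#'
#' Chains simulate, extract, train and evaluate, writing the dataset (CSV),
#' the trained model (RDS), the error summary (JSON) and a run manifest
#' (JSON with the config snapshot, package version, seeds, per-artifact MD5
#' hashes and timestamps) into `out_dir`.
#'
#' @param config a config list from [load_pipeline_config()], a YAML path,
#'   or a preset name.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly; the experiment is attached as
#'   `attr(, "experiment")`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("lsdrun")) {
  if (is.character(config)) config <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  exp <- run_insilico_experiment(config$dataset_kind,
                                 n_phantoms = config$n_phantoms,
                                 seed = config$seed,
                                 profile = config$profile,
                                 compare_lu = isTRUE(config$compare_lu),
                                 model = config$model,
                                 noise_frac = config$noise_frac,
                                 spec_options = if (is.null(config$spec_options))
                                   list() else config$spec_options,
                                 train_options = if (is.null(config$train_options))
                                   list() else config$train_options)
  paths <- list(dataset = file.path(out_dir, "dataset.csv"),
                model = file.path(out_dir, "model.rds"),
                summary = file.path(out_dir, "summary.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_spectra_csv(exp$dataset, paths$dataset)
  save_lsd_model(exp$model, paths$model)
  summ <- list(lsd = unclass(exp$summary))
  if (!is.null(exp$lu_summary)) summ$lu <- unclass(exp$lu_summary)
  jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    stages = c("simulate", "extract", "train", "evaluate"),
    config = config,
    package_version = as.character(utils::packageVersion("lsdox")),
    seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = lapply(paths[c("dataset", "model", "summary")], function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  attr(manifest, "experiment") <- exp
  invisible(manifest)
}
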