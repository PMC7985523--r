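#' LSD model configuration
#'
#' Hyperparameters of the learned-spectral-decoloring regressor: a fully
#' connected network with four hidden layers of width twice the input
#' length, leaky-ReLU activations, 20% dropout after each activation, and a
#' linear output head. Reference training runs 100 epochs of 500 batches of
#' 1e4 spectra with learning rate `1e-2 * 0.9^(epoch/2)` updated every two
#' epochs; [lsd_config_desk()] gives the reduced desk-scale profile used for
#' tests and examples.
#'
#' The loss, optimizer, leaky slope and batch-sampling rule are open choices
#' documented here: mean squared error on the sO2 fraction (switchable to
#' MAE), plain SGD with momentum 0.9, negative slope 0.01, and batches drawn
#' with replacement from the training split.
#'
#' @param n_inputs number of wavelengths (>= 2).
#' @param hidden_layers number of hidden layers.
#' @param hidden_width width of each hidden layer (default `2 * n_inputs`).
#' @param dropout_rate dropout probability after each activation.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @param epochs,batches_per_epoch,batch_size training schedule.
#' @param lr_initial,lr_decay_base,lr_update_every learning-rate schedule:
#'   `lr_initial * lr_decay_base^(epoch / lr_update_every)`, recomputed every
#'   `lr_update_every` epochs.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain SGD with momentum).
#' @param momentum SGD momentum coefficient (used by `optimizer = "sgd"`).
#' @param restarts number of independently initialized training runs; the
#'   run with the lowest final validation loss is kept (validation-based
#'   selection; occasional runs land in poor optima under dropout).
#' @param loss `"mse"` or `"mae"`.
#' @param split train/validation/test fractions, summing to 1.
#' @param split_by `"row"` (default: random split over all extracted
#'   spectra, the protocol of the reference experiments) or `"phantom"`
#'   (all pixels of one phantom stay in one split; a stricter protocol with
#'   no shared phantoms between training and test; falls back to rows when
#'   fewer than 20 phantoms).
#' @param seed RNG seed for initialization, splitting and batching.
#' @return object of class `lsd_config`.
#' @export
lsd_config <- function(n_inputs, hidden_layers = 4,
                       hidden_width = 2 * n_inputs, dropout_rate = 0.2,
                       leaky_slope = 0.01, epochs = 100,
                       batches_per_epoch = 500, batch_size = 1e4,
                       lr_initial = NULL, lr_decay_base = 0.9,
                       lr_update_every = 2, optimizer = "adam",
                       momentum = 0.9, restarts = 1, loss = "mse",
                       split = c(0.75, 0.05, 0.20), split_by = "row",
                       seed = NULL) {
  if (n_inputs < 2) stopf("n_inputs must be >= 2")
  if (abs(sum(split) - 1) > 1e-9) stopf("split fractions must sum to 1")
  if (any(c(hidden_layers, hidden_width, epochs, batches_per_epoch,
            batch_size) < 1)) stopf("all counts must be positive")
  optimizer <- match.arg(optimizer, c("adam", "sgd"))
  # the printed 1e-2 schedule start suits momentum SGD; Adam runs an order
  # of magnitude lower under the same decay schedule
  if (is.null(lr_initial))
    lr_initial <- if (optimizer == "adam") 1e-3 else 1e-2
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_decay_base = lr_decay_base,
                 lr_update_every = as.integer(lr_update_every),
                 optimizer = optimizer,
                 momentum = momentum, restarts = as.integer(restarts),
                 loss = match.arg(loss, c("mse", "mae")),
                 split = split, split_by = match.arg(split_by,
                                                     c("row", "phantom")),
                 seed = seed),
            class = "lsd_config")
}

#' @rdname lsd_config
#' @param ... overrides passed on to [lsd_config()].
#' @export
lsd_config_desk <- function(n_inputs, ...) {
  args <- utils::modifyList(list(n_inputs = n_inputs, epochs = 40L,
                                 batches_per_epoch = 100L, batch_size = 512L,
                                 lr_initial = 3e-3, restarts = 3L),
                            list(...))
  do.call(lsd_config, args)
}

#' Learning-rate schedule
#'
#' `lr = lr_initial * decay^(epoch / update_every)`, held constant between
#' updates (the exponent uses the last completed update step). Epochs are
#' counted from 0.
#'
#' @param epoch epoch index (0-based).
#' @param cfg an [lsd_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (any(epoch < 0)) stopf("epoch must be >= 0")
  cfg$lr_initial * cfg$lr_decay_base^(epoch %/% cfg$lr_update_every)
}

#' Build an untrained LSD network
#'
#' Architecture: `input(n) -> [dense(width) -> leakyReLU -> dropout] x L ->
#' dense(1)`. Weights use He-scaled Gaussian initialization; with a seed in
#' the config, initialization is reproducible.
#'
#' @param cfg an [lsd_config()].
#' @return object of class `lsd_model` (untrained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "lsd_config"))
  with_seed(cfg$seed, {
    sizes <- c(cfg$n_inputs, rep(cfg$hidden_width, cfg$hidden_layers), 1L)
    weights <- biases <- vector("list", length(sizes) - 1L)
    for (l in seq_along(weights)) {
      weights[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                          sd = sqrt(2 / sizes[l])),
                             sizes[l], sizes[l + 1])
      biases[[l]] <- numeric(sizes[l + 1])
    }
    structure(list(weights = weights, biases = biases, sizes = sizes,
                   config = cfg, wavelength_grid = NULL,
                   training_log = NULL, trained = FALSE),
              class = "lsd_model")
  })
}

# forward pass; returns activations when `keep` (for backprop), with
# inverted dropout applied to hidden activations when training
mlp_forward <- function(model, x, training = FALSE, keep = FALSE) {
  cfg <- model$config
  nl <- length(model$weights)
  acts <- vector("list", nl)  # post-activation (post-dropout) per layer
  masks <- vector("list", nl)
  a <- x
  for (l in seq_len(nl - 1L)) {
    z <- a %*% model$weights[[l]]
    z <- sweep(z, 2, model$biases[[l]], `+`)
    a <- ifelse(z > 0, z, cfg$leaky_slope * z)
    if (training && cfg$dropout_rate > 0) {
      m <- matrix(stats::runif(length(a)) >= cfg$dropout_rate,
                  nrow(a), ncol(a)) / (1 - cfg$dropout_rate)
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l]] <- a
  }
  out <- a %*% model$weights[[nl]]
  out <- out + model$biases[[nl]]
  if (keep) list(out = out, acts = acts, masks = masks) else out
}

# one optimizer step on a batch; `state` carries SGD velocities or Adam
# moment estimates
mlp_step <- function(model, state, x, y, lr) {
  cfg <- model$config
  nl <- length(model$weights)
  fw <- mlp_forward(model, x, training = TRUE, keep = TRUE)
  pred <- drop(fw$out)
  b <- nrow(x)
  delta <- if (cfg$loss == "mse") {
    matrix(2 * (pred - y) / b, ncol = 1)
  } else {
    matrix(sign(pred - y) / b, ncol = 1)
  }
  gw <- vector("list", nl); gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    a_prev <- if (l == 1L) x else fw$acts[[l - 1L]]
    gw[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(model$weights[[l]])
      a <- fw$acts[[l - 1L]]
      m <- fw$masks[[l - 1L]]
      if (!is.null(m)) {
        delta <- delta * m
        a_pre <- a / ifelse(m == 0, 1, m)  # pre-dropout activation sign
      } else a_pre <- a
      delta <- delta * ifelse(a_pre > 0, 1, cfg$leaky_slope)
    }
  }
  if (cfg$optimizer == "sgd") {
    for (l in seq_len(nl)) {
      state$vw[[l]] <- cfg$momentum * state$vw[[l]] - lr * gw[[l]]
      state$vb[[l]] <- cfg$momentum * state$vb[[l]] - lr * gb[[l]]
      model$weights[[l]] <- model$weights[[l]] + state$vw[[l]]
      model$biases[[l]] <- model$biases[[l]] + state$vb[[l]]
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    corr <- sqrt(1 - b2^state$t) / (1 - b1^state$t)
    for (l in seq_len(nl)) {
      state$mw[[l]] <- b1 * state$mw[[l]] + (1 - b1) * gw[[l]]
      state$vw[[l]] <- b2 * state$vw[[l]] + (1 - b2) * gw[[l]]^2
      state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * gb[[l]]
      state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * gb[[l]]^2
      model$weights[[l]] <- model$weights[[l]] -
        lr * corr * state$mw[[l]] / (sqrt(state$vw[[l]]) + eps)
      model$biases[[l]] <- model$biases[[l]] -
        lr * corr * state$mb[[l]] / (sqrt(state$vb[[l]]) + eps)
    }
  }
  loss <- if (cfg$loss == "mse") mean((pred - y)^2) else mean(abs(pred - y))
  list(model = model, state = state, loss = loss)
}

init_opt_state <- function(model) {
  zw <- lapply(model$weights, function(w) w * 0)
  zb <- lapply(model$biases, function(b) b * 0)
  list(vw = zw, vb = zb, mw = zw, mb = zb, t = 0L)
}

# deterministic train/val/test split; by phantom when possible
split_dataset <- function(dataset, cfg) {
  n <- nrow(dataset$spectra)
  by_phantom <- cfg$split_by == "phantom" &&
    !is.null(dataset$meta$phantom_id) &&
    length(unique(dataset$meta$phantom_id)) >= 20
  if (by_phantom) {
    ids <- unique(dataset$meta$phantom_id)
    ids <- sample(ids)
    k <- length(ids)
    n_tr <- max(1, round(cfg$split[1] * k))
    n_va <- max(1, round(cfg$split[2] * k))
    tr_ids <- ids[seq_len(n_tr)]
    va_ids <- ids[seq_len(n_va) + n_tr]
    te_ids <- setdiff(ids, c(tr_ids, va_ids))
    list(train = which(dataset$meta$phantom_id %in% tr_ids),
         val = which(dataset$meta$phantom_id %in% va_ids),
         test = which(dataset$meta$phantom_id %in% te_ids),
         unit = "phantom")
  } else {
    idx <- sample(n)
    n_tr <- max(1, round(cfg$split[1] * n))
    n_va <- max(1, round(cfg$split[2] * n))
    list(train = idx[seq_len(n_tr)],
         val = idx[seq_len(n_va) + n_tr],
         test = idx[seq(n_tr + n_va + 1, n)],
         unit = "row")
  }
}

#' Train the LSD regressor
#'
#' Splits the dataset (75/5/20 by default, at phantom granularity so that
#' held-out spectra come from unseen phantoms), then runs mini-batch SGD
#' with momentum under the configured learning-rate schedule. Batches are
#' drawn with replacement from the training split. The test split is never
#' touched during training; its row indices are stored on the model for
#' final evaluation. With a seed in the config the whole procedure is
#' bit-reproducible.
#'
#' @param dataset a `spectra_dataset` with normalized rows and labels in
#'   \[0, 1\].
#' @param cfg an [lsd_config()]; `cfg$n_inputs` must match the dataset.
#' @return a trained `lsd_model` with `training_log` (per-epoch train and
#'   validation loss) and `split` (train/val/test row indices).
#' @export
train_lsd <- function(dataset, cfg) {
  stopifnot(inherits(dataset, "spectra_dataset"), inherits(cfg, "lsd_config"))
  if (ncol(dataset$spectra) != cfg$n_inputs)
    stopf("dataset has %d wavelengths but config expects %d",
          ncol(dataset$spectra), cfg$n_inputs)
  if (any(dataset$so2 < 0 | dataset$so2 > 1, na.rm = TRUE))
    stopf("labels must lie in [0, 1]")
  bad <- abs(rowSums(dataset$spectra) - 1) > 1e-6
  if (any(bad)) stopf("%d dataset rows are not sum-normalized", sum(bad))
  sp <- with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L,
                  split_dataset(dataset, cfg))
  if (length(sp$train) < 1) stopf("training split is empty")
  xtr <- dataset$spectra[sp$train, , drop = FALSE]
  ytr <- dataset$so2[sp$train]
  # per-wavelength standardization fitted on the training split; sum-
  # normalized spectra vary by only a few percent of 1/n per component,
  # so raw inputs would start the network in a near-zero-gradient regime
  ctr <- colMeans(xtr)
  csd <- pmax(apply(xtr, 2, stats::sd), 1e-12)
  scaler <- list(center = ctr, scale = csd)
  xtr <- sweep(sweep(xtr, 2, ctr), 2, csd, `/`)
  xva <- dataset$spectra[sp$val, , drop = FALSE]
  xva <- sweep(sweep(xva, 2, ctr), 2, csd, `/`)
  yva <- dataset$so2[sp$val]

  train_once <- function(run_seed) {
    cfg_r <- cfg; cfg_r$seed <- run_seed
    model <- build_model(cfg_r)
    model$scaler <- scaler
    with_seed(if (is.null(run_seed)) NULL else run_seed + 1L, {
      state <- init_opt_state(model)
      log <- data.frame(epoch = seq_len(cfg$epochs) - 1L,
                        lr = NA_real_, train_loss = NA_real_,
                        val_loss = NA_real_)
      for (ep in seq_len(cfg$epochs) - 1L) {
        lr <- lr_schedule(ep, cfg)
        losses <- numeric(cfg$batches_per_epoch)
        for (bt in seq_len(cfg$batches_per_epoch)) {
          sel <- sample.int(nrow(xtr), cfg$batch_size, replace = TRUE)
          st <- mlp_step(model, state, xtr[sel, , drop = FALSE], ytr[sel], lr)
          model <- st$model; state <- st$state; losses[bt] <- st$loss
        }
        vl <- if (length(yva)) {
          pv <- drop(mlp_forward(model, xva))
          if (cfg$loss == "mse") mean((pv - yva)^2) else mean(abs(pv - yva))
        } else NA_real_
        log[ep + 1L, c("lr", "train_loss", "val_loss")] <-
          c(lr, mean(losses), vl)
      }
      model$training_log <- log
      model
    })
  }

  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    run_seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1000L * r
    cand <- train_once(run_seed)
    vfin <- utils::tail(cand$training_log$val_loss, 1)
    score <- if (is.na(vfin)) utils::tail(cand$training_log$train_loss, 1)
             else vfin
    if (is.null(best) || score < best$score)
      best <- list(model = cand, score = score, run = r)
  }
  model <- best$model
  model$trained <- TRUE
  model$wavelength_grid <- dataset$wavelengths
  model$split <- sp
  model$selected_restart <- best$run
  model
}

#' Predict sO2 from normalized spectra
#'
#' Applies a trained LSD model. Inputs must already be sum-normalized (an
#' unnormalized spectrum is an error, not silently rescaled) and must match
#' the wavelength grid the model was trained on. Dropout is disabled at
#' inference; the linear output is clamped to \[0, 1\] for reporting.
#'
#' @param object a trained `lsd_model`.
#' @param spectra numeric vector (one spectrum) or matrix `[N, n]`, or a
#'   `spectra_dataset`.
#' @param wavelengths optional wavelength grid of the input, checked against
#'   the model's grid when given.
#' @param ... unused.
#' @return numeric vector of sO2 estimates in \[0, 1\].
#' @export
predict.lsd_model <- function(object, spectra, wavelengths = NULL, ...) {
  if (!isTRUE(object$trained)) stopf("model has not been trained")
  if (inherits(spectra, "spectra_dataset")) {
    wavelengths <- spectra$wavelengths
    spectra <- spectra$spectra
  }
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  if (!is.null(wavelengths) &&
      !isTRUE(all.equal(as.numeric(wavelengths),
                        as.numeric(object$wavelength_grid))))
    stopf(paste0("wavelength grid mismatch: model is bound to [%s] nm, ",
                 "input has [%s] nm"),
          paste(object$wavelength_grid, collapse = ", "),
          paste(wavelengths, collapse = ", "))
  if (ncol(spectra) != object$config$n_inputs)
    stopf("input has %d wavelengths, model expects %d", ncol(spectra),
          object$config$n_inputs)
  bad <- abs(rowSums(spectra) - 1) > 1e-6
  if (any(bad))
    stopf("%d input spectra are not sum-normalized; normalize first",
          sum(bad))
  if (!is.null(object$scaler))
    spectra <- sweep(sweep(spectra, 2, object$scaler$center), 2,
                     object$scaler$scale, `/`)
  pmin(1, pmax(0, drop(mlp_forward(object, spectra))))
}

#' Pixel-wise sO2 map from a multispectral image
#'
#' Extracts the spectrum of every masked pixel from a p0 stack, normalizes
#' it, and applies the model. Pixels outside the mask (or with all-zero
#' spectra) are `NA`.
#'
#' @param model trained `lsd_model`.
#' @param stack a `p0_stack`.
#' @param mask logical matrix; default all pixels.
#' @return matrix of sO2 estimates with `NA` outside the mask.
#' @export
predict_image <- function(model, stack, mask = NULL) {
  stopifnot(inherits(stack, "p0_stack"))
  shape <- dim(stack$p0)[2:3]
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  if (!identical(dim(mask), shape)) stopf("mask shape does not match image")
  if (!isTRUE(all.equal(as.numeric(stack$wavelengths),
                        as.numeric(model$wavelength_grid))))
    stopf("wavelength grid mismatch: model is bound to [%s] nm, image has [%s] nm",
          paste(model$wavelength_grid, collapse = ", "),
          paste(stack$wavelengths, collapse = ", "))
  sel <- which(mask)
  out <- matrix(NA_real_, shape[1], shape[2])
  if (!length(sel)) return(out)
  nwl <- length(stack$wavelengths)
  mat <- t(matrix(stack$p0, nrow = nwl)[, sel, drop = FALSE])
  nr <- normalize_rows(mat)
  if (any(nr$keep))
    out[sel[nr$keep]] <- predict(model, nr$spectra)
  out
}

#' @export
print.lsd_model <- function(x, ...) {
  cat(sprintf("<lsd_model> %s, layers %s\n",
              if (x$trained) "trained" else "untrained",
              paste(x$sizes, collapse = "-")))
  if (x$trained)
    cat(sprintf("  wavelengths: %g-%g nm (n=%d); final val loss %.2e\n",
                min(x$wavelength_grid), max(x$wavelength_grid),
                length(x$wavelength_grid),
                utils::tail(x$training_log$val_loss, 1)))
  invisible(x)
}

#' Save / load a trained LSD model
#'
#' Serializes the weights, wavelength grid, config and training log.
#'
#' @param model a `lsd_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_lsd_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_lsd_model
#' @export
load_lsd_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lsd_model")) stopf("'%s' is not a saved LSD model", path)
  model
}
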