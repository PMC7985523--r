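# build a small learnable dataset: labels are a smooth function of the
# spectrum so a few epochs suffice
toy_dataset <- function(n = 3000, k = 8, seed = 1, constant = NULL) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * k), n, k)
  m <- m / rowSums(m)
  so2 <- if (is.null(constant)) {
    pmin(1, pmax(0, m[, 1] / (m[, 1] + m[, 2])))
  } else rep(constant, n)
  structure(list(spectra = m, so2 = so2, wavelengths = seq(700, by = 10,
                                                           length.out = k),
                 meta = data.frame(phantom_id = rep(1:30, length.out = n),
                                   depth_mm = 1, tissue_label = "vessel")),
            class = "spectra_dataset")
}

tiny_cfg <- function(k = 8, ...) {
  lsd_config(k, epochs = 4, batches_per_epoch = 30, batch_size = 128,
             restarts = 1, seed = 11, ...)
}

test_that("network widths follow the twice-the-input rule", {
  m26 <- build_model(lsd_config(26, seed = 1))
  expect_equal(m26$sizes, c(26L, 52L, 52L, 52L, 52L, 1L))
  expect_equal(dim(m26$weights[[1]]), c(26L, 52L))
  expect_equal(dim(m26$weights[[5]]), c(52L, 1L))
  m17 <- build_model(lsd_config(17, seed = 1))
  expect_equal(m17$sizes[2], 34L)
  # parameter count is a deterministic function of the input length
  n_par <- function(m) sum(vapply(m$weights, length, 1)) +
    sum(vapply(m$biases, length, 1))
  expect_equal(n_par(m26), 26 * 52 + 3 * 52^2 + 52 * 1 + 4 * 52 + 1)
  expect_error(lsd_config(1), "n_inputs")
})

test_that("identical seeds give identical initial parameters", {
  a <- build_model(lsd_config(12, seed = 5))
  b <- build_model(lsd_config(12, seed = 5))
  expect_identical(a$weights, b$weights)
  c <- build_model(lsd_config(12, seed = 6))
  expect_false(identical(a$weights, c$weights))
})

test_that("learning rate follows the stepped decay schedule", {
  cfg <- lsd_config(26, optimizer = "sgd", seed = 1)
  expect_equal(lr_schedule(0, cfg), 1e-2)
  expect_equal(lr_schedule(1, cfg), 1e-2)          # held between updates
  expect_equal(lr_schedule(2, cfg), 1e-2 * 0.9)
  expect_equal(lr_schedule(3, cfg), 1e-2 * 0.9)
  expect_equal(lr_schedule(100, cfg), 1e-2 * 0.9^50)
  expect_error(lr_schedule(-1, cfg), "epoch")
})

test_that("training a constant-label dataset regresses to that constant", {
  ds <- toy_dataset(n = 2000, constant = 0.5)
  cfg <- lsd_config(8, epochs = 24, batches_per_epoch = 50,
                    batch_size = 256, lr_initial = 5e-3, restarts = 1,
                    seed = 11)
  fit <- train_lsd(ds, cfg)
  est <- predict(fit, ds$spectra[fit$split$test, , drop = FALSE])
  expect_true(all(abs(est - 0.5) < 0.02))
})

test_that("training reduces the validation loss and logs every epoch", {
  ds <- toy_dataset()
  fit <- train_lsd(ds, tiny_cfg())
  log <- fit$training_log
  expect_equal(nrow(log), 4L)
  expect_lt(log$val_loss[4], log$val_loss[1])
  expect_true(all(is.finite(log$train_loss)))
  expect_equal(log$lr[1], 1e-3)
})

test_that("seeded training is reproducible end to end", {
  ds <- toy_dataset()
  f1 <- train_lsd(ds, tiny_cfg())
  f2 <- train_lsd(ds, tiny_cfg())
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$training_log, f2$training_log)
  expect_identical(f1$split, f2$split)
})

test_that("prediction is stateless, clamped and input-checked", {
  ds <- toy_dataset()
  fit <- train_lsd(ds, tiny_cfg())
  x <- ds$spectra[1:20, ]
  batch <- predict(fit, x)
  rowwise <- vapply(1:20, function(i) predict(fit, x[i, ]), numeric(1))
  expect_equal(batch, rowwise)
  expect_true(all(batch >= 0 & batch <= 1))
  expect_error(predict(fit, 2 * x), "normalized")
  expect_error(predict(fit, x, wavelengths = seq(800, by = 10,
                                                 length.out = 8)),
               "mismatch")
  expect_error(predict(fit, x[, 1:5]), "wavelengths")
  expect_error(predict(build_model(tiny_cfg()), x), "trained")
})

test_that("image prediction matches per-pixel prediction inside the mask", {
  v <- sample_flow(small_spec("flow", seed = 51))
  wl <- resolve_wavelengths("flow")
  st <- simulate_multispectral(v, wl)
  ds <- build_dataset(list(st), list(v), seed = 1)
  cfg <- lsd_config(17, epochs = 3, batches_per_epoch = 20, batch_size = 128,
                    restarts = 1, seed = 3, split_by = "row")
  fit <- train_lsd(ds, cfg)
  mask <- matrix(FALSE, dim(st$p0)[2], dim(st$p0)[3])
  px <- which(v$labels == 2L)[1]
  mask[px] <- TRUE
  map <- predict_image(fit, st, mask)
  expect_equal(sum(!is.na(map)), 1L)
  s <- normalize_spectrum(st$p0[, (px - 1) %% nrow(mask) + 1,
                                (px - 1) %/% nrow(mask) + 1])
  expect_equal(map[px], predict(fit, s))
  full <- predict_image(fit, st)
  expect_identical(dim(full), dim(v$labels))
})

test_that("model save/load round-trips predictions", {
  ds <- toy_dataset()
  fit <- train_lsd(ds, tiny_cfg())
  path <- tempfile(fileext = ".rds")
  save_lsd_model(fit, path)
  back <- load_lsd_model(path)
  x <- ds$spectra[1:5, ]
  expect_identical(predict(back, x), predict(fit, x))
})
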