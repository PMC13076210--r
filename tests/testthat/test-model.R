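mf <- asNamespace("multifrag")

tiny_cfg <- function(dict_size = 10, max_len = 6) {
  model_config(dict_size = dict_size, embed_dim = 4, encoder_units = 3,
               decoder_units = 5, max_len = max_len, preset = "custom")
}

tiny_model <- function(seed = 7, ...) {
  cfg <- tiny_cfg(...)
  list(params = withr::with_seed(seed, mf$model_init_params(cfg)),
       config = cfg)
}

test_that("masked spectral distance hits its closed-form landmarks", {
  x <- c(0.2, 0.8, 0.5)
  expect_equal(masked_spectral_distance(x, x), 0)
  expect_equal(masked_spectral_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(masked_spectral_distance(c(1, 0), c(1, 1)), 0.5)
  # masked entries are invisible
  expect_equal(
    masked_spectral_distance(c(1, 0, 99), c(1, 1, -1)), 0.5
  )
  # bounds hold under float noise
  set.seed(31)
  for (i in 1:200) {
    p <- rnorm(20); t <- runif(20)
    t[sample(20, 5)] <- -1
    l <- masked_spectral_distance(p, t)
    expect_true(l >= 0 && l <= 1)
  }
  # degenerate all-masked / zero-norm targets contribute 0
  expect_equal(masked_spectral_distance(c(1, 2), c(-1, -1)), 0)
  expect_equal(masked_spectral_distance(c(1, 2), c(0, 0)), 0)
})

test_that("loss gradient matches finite differences and masks out -1", {
  set.seed(32)
  pred <- matrix(rnorm(2 * 8), 2, 8)
  target <- matrix(runif(2 * 8), 2, 8)
  target[1, c(2, 5)] <- -1
  target[2, 7] <- -1
  g <- mf$masked_spectral_distance_grad(pred, target)
  eps <- 1e-6
  for (i in 1:2) {
    for (j in 1:8) {
      p1 <- pred; p2 <- pred
      p1[i, j] <- p1[i, j] + eps
      p2[i, j] <- p2[i, j] - eps
      num <- (masked_spectral_distance(p1, target) -
                masked_spectral_distance(p2, target)) / (2 * eps)
      expect_equal(g[i, j], num, tolerance = 1e-5)
      if (target[i, j] == -1) expect_identical(g[i, j], 0)
    }
  }
})

test_that("metadata encoding is deterministic and separates methods", {
  m <- tiny_model()
  v1 <- encode_metadata(2, "HCD", m)
  v2 <- encode_metadata(2, "HCD", m)
  expect_identical(v1, v2)
  expect_equal(ncol(v1), m$config$latent_dim)
  v3 <- encode_metadata(2, "ECD", m)
  expect_false(isTRUE(all.equal(v1, v3)))
  expect_error(encode_metadata(0, "HCD", m), "charge")
  expect_warning(encode_metadata(9, "HCD", m), "clamped")
  expect_error(encode_metadata(2, "XYZ", m), "unknown")
})

test_that("training gradients flow to both metadata one-hot blocks", {
  m <- tiny_model()
  cfg <- m$config
  tokens <- mf$tokenize_batch(c("PEPTK", "AGLYK"), cfg)
  onehot <- mf$metadata_onehot(c(2, 3), c("HCD", "ECD"), cfg)
  target <- withr::with_seed(1, matrix(runif(2 * cfg$dict_size), 2))
  fwd <- mf$model_forward(tokens, onehot, m$params, cfg)
  grads <- mf$model_backward(
    mf$masked_spectral_distance_grad(fwd$pred, target), fwd$cache,
    m$params, cfg
  )
  n_charge <- length(cfg$charge_range)
  charge_rows <- grads$meta_W[seq_len(n_charge), ]
  method_rows <- grads$meta_W[n_charge + seq_along(cfg$methods), ]
  expect_true(any(charge_rows != 0))
  expect_true(any(method_rows != 0))
  # finite-difference spot check on one weight in each block
  loss_at <- function(params) {
    masked_spectral_distance(
      mf$model_forward(tokens, onehot, params, cfg)$pred, target
    )
  }
  eps <- 1e-6
  for (row in c(2L, n_charge + 1L)) {
    p1 <- m$params; p2 <- m$params
    p1$meta_W[row, 1] <- p1$meta_W[row, 1] + eps
    p2$meta_W[row, 1] <- p2$meta_W[row, 1] - eps
    num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
    expect_equal(grads$meta_W[row, 1], num, tolerance = 1e-5)
  }
})

test_that("model backprop matches finite differences everywhere", {
  m <- tiny_model(seed = 9)
  cfg <- m$config
  tokens <- mf$tokenize_batch(c("PEPTK", "AGLYK"), cfg)
  onehot <- mf$metadata_onehot(c(2, 3), c("UVPD", "EID"), cfg)
  target <- withr::with_seed(2, {
    t <- matrix(runif(2 * cfg$dict_size), 2)
    t[1, c(1, 4)] <- -1
    t
  })
  fwd <- mf$model_forward(tokens, onehot, m$params, cfg)
  grads <- mf$model_backward(
    mf$masked_spectral_distance_grad(fwd$pred, target), fwd$cache,
    m$params, cfg
  )
  loss_at <- function(params) {
    masked_spectral_distance(
      mf$model_forward(tokens, onehot, params, cfg)$pred, target
    )
  }
  eps <- 1e-6
  check <- function(get, set, g, label) {
    set.seed(40)
    for (k in sample(length(g), min(4, length(g)))) {
      p1 <- set(m$params, k, eps)
      p2 <- set(m$params, k, -eps)
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-5, label = label)
    }
  }
  paths <- list(
    c("embedding"), c("meta_W"), c("out_W"), c("out_b"),
    c("encoder", "fwd", "Wn"), c("encoder", "bwd", "Uz"),
    c("decoder", "fwd", "Ur"), c("decoder", "bwd", "bn")
  )
  for (path in paths) {
    g <- grads
    for (k in path) g <- g[[k]]
    setter <- function(params, idx, d) {
      f <- function(x, ks) {
        if (length(ks) == 0) { x[idx] <- x[idx] + d; x }
        else { x[[ks[1]]] <- f(x[[ks[1]]], ks[-1]); x }
      }
      f(params, path)
    }
    check(NULL, setter, g, paste(path, collapse = "/"))
  }
})

test_that("predictions have the dictionary length and permute with it", {
  m <- tiny_model(seed = 10)
  class(m) <- "intensity_model"
  newdata <- tibble::tibble(
    peptide = c("PEPTK", "AGLYK", "MKWVTF"),
    charge = c(2, 3, 2), method = c("HCD", "ECD", "UVPD")
  )
  out <- predict(m, newdata)
  expect_true(all(lengths(out$prediction) == m$config$dict_size))
  # permuting the dictionary together with the output layer permutes
  # the predictions identically
  perm <- withr::with_seed(3, sample(m$config$dict_size))
  m2 <- m
  m2$params$out_W <- m$params$out_W[, perm]
  m2$params$out_b <- m$params$out_b[perm]
  out2 <- predict(m2, newdata)
  for (i in seq_len(nrow(newdata))) {
    expect_equal(out2$prediction[[i]], out$prediction[[i]][perm])
  }
  expect_error(predict(m, dplyr::mutate(newdata, peptide = "PEPTZ")),
               "token|tokenise")
})

test_that("training reduces the loss and is bit-reproducible", {
  pipe <- small_pipeline()
  records <- pipe$records[1:30, ]
  cfg <- model_config(dict_size = nrow(pipe$dict), preset = "tiny")
  tc <- train_config(epochs = 5, lr = 5e-3, warmup_steps = 5,
                     batch_size = 16, seed = 3)
  f1 <- fit_intensity_model(records, pipe$dict, cfg, tc)
  f2 <- fit_intensity_model(records, pipe$dict, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_lt(utils::tail(f1$history$train_loss, 1),
            f1$history$train_loss[1])
  expect_error(
    fit_intensity_model(records, pipe$dict,
                        model_config(dict_size = 3, preset = "tiny"), tc),
    "dict_size"
  )
  # broom-style accessors
  expect_identical(tidy(f1), f1$history)
  expect_equal(glance(f1)$epochs, 5)
})

test_that("per-spectrum Pearson handles exact and degenerate cases", {
  t <- c(1, 2, 4) / 4
  expect_equal(pearson_per_spectrum(t, t), 1)
  expect_equal(pearson_per_spectrum(1 - t, t), -1)
  expect_equal(pearson_per_spectrum(c(1, 2, 3), c(1, 2, 4)), 0.9820,
               tolerance = 1e-3)
  # masked entries excluded from the correlation
  expect_equal(
    pearson_per_spectrum(c(1, 2, 3, 99), c(1, 2, 4, -1)), 0.9820,
    tolerance = 1e-3
  )
  # degenerate variance is NA, never zero
  expect_true(is.na(pearson_per_spectrum(c(1, 1, 1), c(0, 0.5, 1))))
  expect_true(is.na(pearson_per_spectrum(c(1, 2), c(0.5, -1))))
})

test_that("checkpoints round-trip weights, config and dictionary", {
  pipe <- small_pipeline()
  records <- pipe$records[1:10, ]
  cfg <- model_config(dict_size = nrow(pipe$dict), preset = "tiny")
  fit <- fit_intensity_model(records, pipe$dict, cfg,
                             train_config(epochs = 1, lr = 1e-3,
                                          warmup_steps = 2,
                                          batch_size = 8, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(back$dictionary$ion, fit$dictionary$ion)
  newdata <- records[1:3, c("peptide", "charge", "method")]
  expect_equal(predict(back, newdata)$prediction,
               predict(fit, newdata)$prediction, tolerance = 1e-12)
})
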