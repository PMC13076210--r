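#' Model architecture configuration
#'
#' The intensity model is a recurrent encoder-decoder: residue tokens
#' are embedded and encoded by a bidirectional GRU into a
#' per-position latent of size `2 * encoder_units`; the precursor
#' charge and fragmentation method, one-hot encoded and concatenated,
#' are linearly projected to the same size and combined with every
#' sequence position by elementwise multiplication; a bidirectional
#' GRU decoder then maps the fused sequence through a linear layer to
#' the ion-dictionary output space, followed by LeakyReLU and mean
#' pooling over the sequence dimension. Collision energy is not an
#' input.
#'
#' @param dict_size Number of ions in the output dictionary.
#' @param embed_dim Token embedding size.
#' @param encoder_units Encoder GRU hidden size per direction (the
#'   metadata projection equals `2 * encoder_units`, the per-position
#'   latent size, as required by the multiplicative fusion).
#' @param decoder_units Decoder GRU hidden size per direction.
#' @param max_len Maximum peptide length in residues (default 30).
#' @param charge_range Supported precursor charges for the one-hot
#'   encoding (default 1:6; higher charges are clamped with a
#'   warning).
#' @param methods Supported fragmentation methods.
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.01).
#' @param preset `"custom"` (use the sizes given), `"full"`
#'   (embed 32, encoder 128 -> latent 256, decoder 256) or `"tiny"`
#'   (embed 8, recurrent 16; intended for tests and desk-scale runs).
#' @return List of class `model_config`.
#' @export
model_config <- function(dict_size, embed_dim = 32L, encoder_units = 128L,
                         decoder_units = 256L, max_len = 30L,
                         charge_range = 1:6,
                         methods = fragmentation_methods(),
                         leaky_slope = 0.01,
                         preset = c("custom", "full", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    embed_dim <- 32L; encoder_units <- 128L; decoder_units <- 256L
  } else if (preset == "tiny") {
    embed_dim <- 8L; encoder_units <- 16L; decoder_units <- 16L
  }
  vocab <- c("<pad>", names(.TOKEN_MASSES))
  structure(
    list(
      dict_size = as.integer(dict_size),
      embed_dim = as.integer(embed_dim),
      encoder_units = as.integer(encoder_units),
      decoder_units = as.integer(decoder_units),
      latent_dim = 2L * as.integer(encoder_units),
      max_len = as.integer(max_len),
      charge_range = as.integer(charge_range),
      methods = methods,
      vocab = vocab,
      leaky_slope = leaky_slope,
      preset = preset
    ),
    class = "model_config"
  )
}

#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 30).
#' @param lr Adam learning rate (default 1e-4).
#' @param warmup_steps Linear learning-rate warmup steps (default
#'   20,000 at full scale; scale down proportionally for small runs).
#' @param batch_size Minibatch size.
#' @param seed RNG seed controlling initialisation and shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 30L, lr = 1e-4, warmup_steps = 20000L,
                         batch_size = 64L, seed = 1L) {
  stopifnot(epochs >= 1L, lr > 0, warmup_steps >= 0L, batch_size >= 1L)
  structure(
    list(epochs = as.integer(epochs), lr = lr,
         warmup_steps = as.integer(warmup_steps),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "train_config"
  )
}

# initialise all weights (caller controls the RNG seed)
model_init_params <- function(config) {
  V <- length(config$vocab)
  D <- config$latent_dim
  n_meta <- length(config$charge_range) + length(config$methods)
  list(
    embedding = init_matrix(V, config$embed_dim),
    encoder = bigru_init(config$embed_dim, config$encoder_units),
    meta_W = init_matrix(n_meta, D),
    meta_b = numeric(D),
    decoder = bigru_init(D, config$decoder_units),
    out_W = init_matrix(2L * config$decoder_units, config$dict_size),
    out_b = numeric(config$dict_size)
  )
}

# tokens -> integer matrix (batch x max_len), 1 = <pad>
tokenize_batch <- function(peptides, config) {
  mat <- matrix(1L, length(peptides), config$max_len)
  for (i in seq_along(peptides)) {
    tok <- peptide_tokens(peptides[i])
    if (length(tok) > config$max_len) {
      stop("peptide longer than max_len (", config$max_len, "): ",
           peptides[i], call. = FALSE)
    }
    idx <- match(tok, config$vocab)
    if (anyNA(idx)) stop("token outside model vocabulary in ", peptides[i],
                         call. = FALSE)
    mat[i, seq_along(idx)] <- idx
  }
  mat
}

#' Encode precursor charge and fragmentation method metadata
#'
#' One-hot encodes the charge and method, concatenates them and
#' applies the learned linear projection to the per-position latent
#' size, ready for multiplicative fusion with the sequence encoding.
#'
#' @param charge Integer vector of precursor charges.
#' @param method Character vector of fragmentation methods.
#' @param model Fitted or initialised model (list with `params` and
#'   `config`).
#' @return Matrix (length(charge) x latent_dim).
#' @export
encode_metadata <- function(charge, method, model) {
  onehot <- metadata_onehot(charge, method, model$config)
  sweep(onehot %*% model$params$meta_W, 2L, model$params$meta_b, "+")
}

metadata_onehot <- function(charge, method, config) {
  charge <- as.integer(charge)
  if (any(charge < min(config$charge_range))) {
    stop("charge below supported range", call. = FALSE)
  }
  if (any(charge > max(config$charge_range))) {
    warning("charge above supported range; clamped to ",
            max(config$charge_range), call. = FALSE)
    charge <- pmin(charge, max(config$charge_range))
  }
  mi <- match(method, config$methods)
  if (anyNA(mi)) stop("unknown fragmentation method: ",
                      paste(unique(method[is.na(mi)]), collapse = ", "),
                      call. = FALSE)
  B <- length(charge)
  nz <- length(config$charge_range)
  onehot <- matrix(0, B, nz + length(config$methods))
  onehot[cbind(seq_len(B), match(charge, config$charge_range))] <- 1
  onehot[cbind(seq_len(B), nz + mi)] <- 1
  onehot
}

# full forward pass; returns prediction matrix and cache for backward
model_forward <- function(tokens, onehot, params, config) {
  B <- nrow(tokens)
  T_ <- config$max_len
  X <- purrr::map(seq_len(T_), function(t) {
    params$embedding[tokens[, t], , drop = FALSE]
  })
  enc <- bigru_forward(X, params$encoder)
  meta <- sweep(onehot %*% params$meta_W, 2L, params$meta_b, "+")
  fused <- purrr::map(enc$H, function(h) h * meta)
  dec <- bigru_forward(fused, params$decoder)
  Z <- purrr::map(dec$H, function(h) {
    sweep(h %*% params$out_W, 2L, params$out_b, "+")
  })
  A <- purrr::map(Z, function(z) {
    ifelse(z > 0, z, config$leaky_slope * z)
  })
  pred <- Reduce(`+`, A) / T_
  list(pred = pred,
       cache = list(tokens = tokens, onehot = onehot, X = X, enc = enc,
                    meta = meta, fused = fused, dec = dec, Z = Z))
}

# backward pass from d(loss)/d(pred)
model_backward <- function(dpred, cache, params, config) {
  T_ <- config$max_len
  B <- nrow(dpred)
  g <- list()
  dZ <- purrr::map(cache$Z, function(z) {
    (dpred / T_) * ifelse(z > 0, 1, config$leaky_slope)
  })
  g$out_W <- Reduce(`+`, purrr::map2(cache$dec$H, dZ, function(h, dz) {
    t(h) %*% dz
  }))
  g$out_b <- Reduce(`+`, purrr::map(dZ, colSums))
  dDecH <- purrr::map(dZ, function(dz) dz %*% t(params$out_W))
  dec_back <- bigru_backward(cache$dec, params$decoder, dDecH)
  g$decoder <- dec_back$grads
  # fusion: fused_t = enc_t * meta
  dEncH <- purrr::map(dec_back$dX, function(df) df * cache$meta)
  dMeta <- Reduce(`+`, purrr::map2(dec_back$dX, cache$enc$H,
                                   function(df, h) df * h))
  g$meta_W <- t(cache$onehot) %*% dMeta
  g$meta_b <- colSums(dMeta)
  enc_back <- bigru_backward(cache$enc, params$encoder, dEncH)
  g$encoder <- enc_back$grads
  dEmb <- matrix(0, nrow(params$embedding), ncol(params$embedding))
  for (t in seq_len(T_)) {
    dx <- enc_back$dX[[t]]
    for (i in seq_len(B)) {
      v <- cache$tokens[i, t]
      dEmb[v, ] <- dEmb[v, ] + dx[i, ]
    }
  }
  g$embedding <- dEmb
  g[c("embedding", "encoder", "meta_W", "meta_b", "decoder", "out_W",
      "out_b")]
}

#' Fit the fragment-ion intensity model
#'
#' Trains the encoder-decoder on vectorized training records with the
#' masked spectral-distance loss and Adam (linear learning-rate
#' warmup). Fully reproducible given `train_config$seed`.
#'
#' @param records Training records ([vectorize_psms()]): columns
#'   `peptide`, `charge`, `method`, `target` list-column.
#' @param dictionary Ion dictionary the targets were built against.
#' @param config [model_config()]; its `dict_size` must equal
#'   `nrow(dictionary)`.
#' @param train [train_config()].
#' @param validation Optional validation records (same schema).
#' @return Object of class `intensity_model`: list with `params`,
#'   `config`, `train`, `dictionary` and `history` (tibble epoch x
#'   train/validation loss).
#' @export
fit_intensity_model <- function(records, dictionary, config,
                                train = train_config(),
                                validation = NULL) {
  stopifnot(nrow(records) > 0L)
  if (config$dict_size != nrow(dictionary)) {
    stop("config$dict_size (", config$dict_size,
         ") does not match the dictionary (", nrow(dictionary), ")",
         call. = FALSE)
  }
  check_targets <- function(recs, who) {
    if (any(lengths(recs$target) != config$dict_size)) {
      stop(who, " target vectors do not match the dictionary size",
           call. = FALSE)
    }
  }
  check_targets(records, "training")
  if (!is.null(validation)) check_targets(validation, "validation")

  withr::with_seed(train$seed, {
    params <- model_init_params(config)
    opt <- adam_init(params)
    n <- nrow(records)
    tokens_all <- tokenize_batch(records$peptide, config)
    onehot_all <- metadata_onehot(records$charge, records$method, config)
    target_all <- do.call(rbind, records$target)
    history <- vector("list", train$epochs)
    for (epoch in seq_len(train$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = train$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + train$batch_size - 1L, n)]
        fwd <- model_forward(tokens_all[idx, , drop = FALSE],
                             onehot_all[idx, , drop = FALSE],
                             params, config)
        tgt <- target_all[idx, , drop = FALSE]
        losses[bi] <- masked_spectral_distance(fwd$pred, tgt)
        dpred <- masked_spectral_distance_grad(fwd$pred, tgt)
        grads <- model_backward(dpred, fwd$cache, params, config)
        step <- adam_step(params, grads, opt, lr = train$lr,
                          warmup_steps = train$warmup_steps)
        params <- step$params
        opt <- step$state
      }
      val_loss <- NA_real_
      if (!is.null(validation) && nrow(validation) > 0L) {
        model_tmp <- list(params = params, config = config)
        vp <- predict_matrix(model_tmp, validation$peptide,
                             validation$charge, validation$method)
        val_loss <- masked_spectral_distance(
          vp, do.call(rbind, validation$target))
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = stats::weighted.mean(
          losses, diff(c(starts, n + 1L))),
        validation_loss = val_loss
      )
    }
    structure(
      list(params = params, config = config, train = train,
           dictionary = dictionary,
           history = dplyr::bind_rows(history)),
      class = "intensity_model"
    )
  })
}

# raw prediction matrix (rows = inputs, cols = dictionary entries)
predict_matrix <- function(model, peptide, charge, method) {
  tokens <- tokenize_batch(peptide, model$config)
  onehot <- metadata_onehot(charge, method, model$config)
  out <- matrix(NA_real_, length(peptide), model$config$dict_size)
  # forward in chunks to bound memory
  starts <- seq(1L, length(peptide), by = 256L)
  for (s in starts) {
    idx <- s:min(s + 255L, length(peptide))
    out[idx, ] <- model_forward(tokens[idx, , drop = FALSE],
                                onehot[idx, , drop = FALSE],
                                model$params, model$config)$pred
  }
  out
}

#' Predict fragment-ion intensities
#'
#' @param object Fitted `intensity_model`.
#' @param new_data Tibble with columns `peptide`, `charge`, `method`.
#' @param ... Unused.
#' @return `new_data` with an added `prediction` list-column (numeric
#'   vectors over the model's ion dictionary, in dictionary order).
#' @export
predict.intensity_model <- function(object, new_data, ...) {
  pred <- predict_matrix(object, new_data$peptide, new_data$charge,
                         new_data$method)
  new_data$prediction <- lapply(seq_len(nrow(pred)), function(i) pred[i, ])
  new_data
}

#' Per-spectrum Pearson correlation between prediction and target
#'
#' Computed over non-masked entries only (zeros included). Rows with
#' fewer than two non-masked entries or zero variance on either side
#' are flagged `NA` (never silently 0) and should be excluded from
#' medians.
#'
#' @param pred Matrix (or vector) of predictions.
#' @param target Matching matrix/vector with `-1` masks.
#' @return Numeric vector of correlations, `NA` where undefined.
#' @export
pearson_per_spectrum <- function(pred, target) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1L)
  stopifnot(all(dim(pred) == dim(target)))
  vapply(seq_len(nrow(pred)), function(i) {
    m <- target[i, ] != -1
    p <- pred[i, m]; tt <- target[i, m]
    if (length(p) < 2L || stats::sd(p) == 0 || stats::sd(tt) == 0) {
      return(NA_real_)
    }
    stats::cor(p, tt)
  }, numeric(1))
}

#' Evaluate a fitted model on a record set
#'
#' @param model Fitted `intensity_model`.
#' @param records Vectorized records (with `target`).
#' @return `records` with `prediction` list-column and `pearson`
#'   column (per-spectrum correlation over non-masked entries).
#' @export
evaluate_model <- function(model, records) {
  pred <- predict_matrix(model, records$peptide, records$charge,
                         records$method)
  records$prediction <- lapply(seq_len(nrow(pred)), function(i) pred[i, ])
  records$pearson <- pearson_per_spectrum(pred,
                                          do.call(rbind, records$target))
  records
}

#' @export
print.intensity_model <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat("<intensity_model>\n",
      sprintf("  preset: %s | dictionary: %d ions | parameters: %d\n",
              x$config$preset, x$config$dict_size, n_par),
      sprintf("  epochs: %d | final train loss: %.4f\n",
              nrow(x$history), utils::tail(x$history$train_loss, 1L)),
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of an intensity model
#' @param x Fitted `intensity_model`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `train_loss`,
#'   `validation_loss`.
#' @export
tidy.intensity_model <- function(x, ...) x$history

#' One-row model summary
#' @param x Fitted `intensity_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs and final losses.
#' @export
glance.intensity_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(rapply(x$params, length, how = "unlist")),
    dict_size = x$config$dict_size,
    epochs = nrow(x$history),
    train_loss = utils::tail(x$history$train_loss, 1L),
    validation_loss = utils::tail(x$history$validation_loss, 1L)
  )
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain-text JSON holding the weights, the model
#' configuration and the ion dictionary, so a saved model fully
#' reconstructs its output space.
#'
#' @param model Fitted `intensity_model`.
#' @param path Output path (`.json`).
#' @export
save_model <- function(model, path) {
  ser <- list(
    config = model$config[setdiff(names(model$config), "vocab")],
    vocab = model$config$vocab,
    dictionary = as.data.frame(model$dictionary),
    min_count = attr(model$dictionary, "min_count"),
    history = as.data.frame(model$history),
    params = rapply(model$params, identity, how = "list")
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- model_config(
    dict_size = ser$config$dict_size, embed_dim = ser$config$embed_dim,
    encoder_units = ser$config$encoder_units,
    decoder_units = ser$config$decoder_units,
    max_len = ser$config$max_len, charge_range = ser$config$charge_range,
    methods = ser$config$methods, leaky_slope = ser$config$leaky_slope
  )
  cfg$preset <- ser$config$preset
  restore <- function(x, template) {
    if (is.list(template)) {
      purrr::map2(x, template, restore)
    } else if (is.matrix(template)) {
      matrix(unlist(x), nrow(template), ncol(template))
    } else {
      as.numeric(unlist(x))
    }
  }
  template <- withr::with_seed(1L, model_init_params(cfg))
  dict <- tibble::as_tibble(ser$dictionary)
  dict <- structure(dict, class = c("ion_dictionary", class(dict)),
                    min_count = ser$min_count)
  structure(
    list(params = restore(ser$params, template), config = cfg,
         train = NULL, dictionary = dict,
         history = tibble::as_tibble(ser$history)),
    class = "intensity_model"
  )
}
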