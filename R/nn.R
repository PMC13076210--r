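# Minimal recurrent-network primitives (matrix forward/backward passes).
# Everything here is deterministic given the parameter list and inputs;
# gradients are hand-derived and verified against finite differences in
# the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform Glorot-style init, seeded by the caller
init_matrix <- function(nr, nc) {
  limit <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -limit, limit), nr, nc)
}

gru_init <- function(input_dim, hidden) {
  list(
    Wz = init_matrix(input_dim, hidden), Uz = init_matrix(hidden, hidden),
    bz = numeric(hidden),
    Wr = init_matrix(input_dim, hidden), Ur = init_matrix(hidden, hidden),
    br = numeric(hidden),
    Wn = init_matrix(input_dim, hidden), Un = init_matrix(hidden, hidden),
    bn = numeric(hidden)
  )
}

# X: list over time of (batch x input) matrices
# returns per-step hidden states plus the cache needed for backward
gru_forward <- function(X, p) {
  T_ <- length(X)
  B <- nrow(X[[1L]])
  H <- length(p$bz)
  h <- matrix(0, B, H)
  Hs <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- X[[t]]
    z <- sigmoid(sweep(x %*% p$Wz + h %*% p$Uz, 2L, p$bz, "+"))
    r <- sigmoid(sweep(x %*% p$Wr + h %*% p$Ur, 2L, p$br, "+"))
    n <- tanh(sweep(x %*% p$Wn + (r * h) %*% p$Un, 2L, p$bn, "+"))
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = x, h_prev = h, z = z, r = r, n = n)
    h <- h_new
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

# dY: list over time of gradients w.r.t. each per-step hidden output
gru_backward <- function(cache, p, dY) {
  T_ <- length(cache)
  B <- nrow(cache[[1L]]$x)
  H <- length(p$bz)
  g <- lapply(p, function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m))
              else numeric(length(m)))
  dX <- vector("list", T_)
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dY[[t]] + dh_next
    dz_pre <- dh * (cc$h_prev - cc$n) * cc$z * (1 - cc$z)
    dn_pre <- dh * (1 - cc$z) * (1 - cc$n^2)
    drh <- dn_pre %*% t(p$Un)
    dr_pre <- drh * cc$h_prev * cc$r * (1 - cc$r)
    dX[[t]] <- dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr) +
      dn_pre %*% t(p$Wn)
    dh_next <- dh * cc$z + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur) +
      drh * cc$r
    g$Wz <- g$Wz + t(cc$x) %*% dz_pre
    g$Wr <- g$Wr + t(cc$x) %*% dr_pre
    g$Wn <- g$Wn + t(cc$x) %*% dn_pre
    g$Uz <- g$Uz + t(cc$h_prev) %*% dz_pre
    g$Ur <- g$Ur + t(cc$h_prev) %*% dr_pre
    g$Un <- g$Un + t(cc$r * cc$h_prev) %*% dn_pre
    g$bz <- g$bz + colSums(dz_pre)
    g$br <- g$br + colSums(dr_pre)
    g$bn <- g$bn + colSums(dn_pre)
  }
  list(dX = dX, grads = g)
}

# bidirectional GRU: forward and time-reversed passes, outputs
# concatenated per position
bigru_init <- function(input_dim, hidden) {
  list(fwd = gru_init(input_dim, hidden), bwd = gru_init(input_dim, hidden))
}

bigru_forward <- function(X, p) {
  fw <- gru_forward(X, p$fwd)
  bw <- gru_forward(rev(X), p$bwd)
  T_ <- length(X)
  H <- purrr::map(seq_len(T_), function(t) {
    cbind(fw$H[[t]], bw$H[[T_ - t + 1L]])
  })
  list(H = H, fw = fw, bw = bw)
}

bigru_backward <- function(state, p, dY) {
  T_ <- length(dY)
  h <- ncol(state$fw$H[[1L]])
  dY_f <- purrr::map(dY, function(d) d[, seq_len(h), drop = FALSE])
  dY_b <- purrr::map(rev(dY), function(d) d[, h + seq_len(h), drop = FALSE])
  back_f <- gru_backward(state$fw$cache, p$fwd, dY_f)
  back_b <- gru_backward(state$bw$cache, p$bwd, dY_b)
  dX <- purrr::map(seq_len(T_), function(t) {
    back_f$dX[[t]] + back_b$dX[[T_ - t + 1L]]
  })
  list(dX = dX, grads = list(fwd = back_f$grads, bwd = back_b$grads))
}

#' Masked spectral distance between intensity vectors
#'
#' Angular distance between L2-normalised intensity vectors computed
#' only over non-masked entries (target entries of -1 mark ions that
#' cannot occur and are dropped so they contribute neither to the loss
#' nor to the gradient):
#' `loss = (2 / pi) * arccos(<p, t> / (|p| |t|))`, in `[0, 1]`.
#' The cosine is clamped to `[0, 1]` before the arccosine, so
#' anti-correlated predictions (possible because the model's LeakyReLU
#' output can be negative while targets are non-negative) saturate at
#' the maximal loss of 1. Rows whose non-masked target (or prediction)
#' has zero norm contribute a loss of 0 and zero gradient.
#'
#' @param pred Numeric vector or matrix (rows = spectra) of predicted
#'   intensities.
#' @param target Matching vector/matrix with entries in `{-1} U [0, 1]`.
#' @return Mean loss over rows (scalar). With `reduce = FALSE`, the
#'   per-row losses.
#' @param reduce Average over rows? (default TRUE)
#' @export
masked_spectral_distance <- function(pred, target, reduce = TRUE) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1L)
  stopifnot(all(dim(pred) == dim(target)))
  losses <- vapply(seq_len(nrow(pred)), function(i) {
    m <- target[i, ] != -1
    p <- pred[i, m]; tt <- target[i, m]
    np <- sqrt(sum(p^2)); nt <- sqrt(sum(tt^2))
    if (np == 0 || nt == 0) return(0)
    cosine <- min(1, max(0, sum(p * tt) / (np * nt)))
    2 / pi * acos(cosine)
  }, numeric(1))
  if (reduce) mean(losses) else losses
}

# gradient of the mean masked spectral distance w.r.t. pred
masked_spectral_distance_grad <- function(pred, target) {
  B <- nrow(pred)
  grad <- matrix(0, B, ncol(pred))
  eps <- 1e-7
  for (i in seq_len(B)) {
    m <- target[i, ] != -1
    p <- pred[i, m]; tt <- target[i, m]
    np <- sqrt(sum(p^2)); nt <- sqrt(sum(tt^2))
    if (np == 0 || nt == 0) next
    raw <- sum(p * tt) / (np * nt)
    if (raw <= 0) next   # clamped region: loss locally constant at 1
    cosine <- min(1 - eps, raw)
    dL_dcos <- -(2 / pi) / sqrt(1 - cosine^2)
    dcos_dp <- tt / (np * nt) - cosine * p / np^2
    grad[i, m] <- dL_dcos * dcos_dp / B
  }
  grad
}

# Adam with linear learning-rate warmup
adam_init <- function(params) {
  flat <- rapply(params, function(x) x * 0, how = "replace")
  list(m = flat, v = flat, step = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, warmup_steps = 0L,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  lr_t <- if (warmup_steps > 0L) lr * min(1, t / warmup_steps) else lr
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
           v = purrr::map(out, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr_t * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  state$m <- out$m
  state$v <- out$v
  list(params = out$p, state = state)
}
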