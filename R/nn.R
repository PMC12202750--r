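# Weight containers, initialization, and the forward/backward passes that
# orchestrate the compiled kernels. All randomness flows through R's RNG so a
# single set.seed() makes initialization, batching and dropout reproducible.

glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# block-orthogonal recurrent kernel: one orthogonal u x u block per gate
orthogonal_gates <- function(u) {
  do.call(cbind, lapply(1:4, function(g) qr.Q(qr(matrix(rnorm(u * u), u, u)))))
}

# Initialize a weight list for a spec. Embedding standard normal (unit-scale
# token vectors keep first-layer pre-activations well-conditioned, which
# matters for recurrent gates); conv/dense Glorot uniform; LSTM input kernels
# Glorot, recurrent kernels block-orthogonal, biases zero except forget gate
# at 1.
init_weights <- function(spec) {
  w <- NA_integer_
  weights <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    weights[[i]] <- switch(l$kind,
      embedding = list(W = matrix(rnorm(l$vocab * l$dim), l$vocab, l$dim)),
      conv1d = list(
        W = glorot_uniform(l$kernel * w, l$filters,
                           fan_in = l$kernel * w, fan_out = l$filters),
        b = numeric(l$filters)),
      bilstm = {
        u <- l$units
        mk <- function() list(
          Wx = glorot_uniform(w, 4L * u, fan_in = w, fan_out = u),
          Wh = orthogonal_gates(u),
          b = c(numeric(u), rep(1, u), numeric(2L * u)))
        fw <- mk(); bw <- mk()
        list(Wxf = fw$Wx, Whf = fw$Wh, bf = fw$b,
             Wxb = bw$Wx, Whb = bw$Wh, bb = bw$b)
      },
      dense = list(W = glorot_uniform(w, l$units), b = numeric(l$units)),
      list())
    w <- switch(l$kind,
      embedding = l$dim, conv1d = l$filters, bilstm = 2L * l$units,
      dense = l$units, w)
  }
  weights
}

#' Instantiate a model from a specification
#'
#' Draws initial weights from R's RNG (call `set.seed()` first, or pass
#' `seed`) and returns an untrained `kd_model`.
#'
#' @param spec A [kd_model_spec].
#' @param seed Optional integer seed for the initialization draw.
#' @return A `kd_model`: list with elements `spec` and `weights`.
#' @export
init_model <- function(spec, seed = NULL) {
  validate_model_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  structure(list(spec = spec, weights = init_weights(spec)),
            class = "kd_model")
}

#' @export
print.kd_model <- function(x, ...) {
  cat("<kd_model>\n")
  print(x$spec)
  invisible(x)
}

n_weights <- function(weights) {
  sum(vapply(weights, function(lw) sum(vapply(lw, length, numeric(1))),
             numeric(1)))
}

# Forward pass. x: integer token matrix (B x L, 0-based). Returns logits and,
# if cache = TRUE, per-layer caches for backprop. Dropout is applied only when
# training = TRUE (inverted dropout, mask drawn from R's RNG).
nn_forward <- function(model, x, training = FALSE, cache = FALSE) {
  stopifnot(is.matrix(x), ncol(x) == model$spec$input_length)
  act <- x
  caches <- vector("list", length(model$spec$layers))
  for (i in seq_along(model$spec$layers)) {
    l <- model$spec$layers[[i]]
    lw <- model$weights[[i]]
    if (l$kind == "embedding") {
      out <- nn_embed_fwd(act, lw$W)
      if (cache) caches[[i]] <- list(idx = act)
    } else if (l$kind == "conv1d") {
      out <- nn_conv_fwd(act, lw$W, lw$b, l$kernel, l$activation == "relu")
      if (cache) caches[[i]] <- list(X = act)
    } else if (l$kind == "bilstm") {
      out <- nn_bilstm_fwd(act, lw$Wxf, lw$Whf, lw$bf, lw$Wxb, lw$Whb, lw$bb)
      if (cache) caches[[i]] <- list(X = act)
    } else if (l$kind == "global_max_pool") {
      r <- nn_gmp_fwd(act)
      out <- r$out
      if (cache) caches[[i]] <- list(argmax = r$argmax, L = dim(act)[3])
    } else if (l$kind == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix((runif(length(act)) >= l$rate) / (1 - l$rate),
                       nrow(act), ncol(act))
        out <- act * mask
        if (cache) caches[[i]] <- list(mask = mask)
      } else {
        out <- act
        if (cache) caches[[i]] <- list(mask = NULL)
      }
    } else if (l$kind == "dense") {
      out <- act %*% lw$W + matrix(lw$b, nrow(act), length(lw$b), byrow = TRUE)
      if (cache) caches[[i]] <- list(X = act)
    }
    act <- out
  }
  if (cache) list(logits = act, caches = caches) else act
}

# Backward pass: dlogits (B x 2) -> list of per-layer weight gradients
# mirroring model$weights, given the caches from nn_forward(cache = TRUE).
nn_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$spec$layers))
  d <- dlogits
  for (i in rev(seq_along(model$spec$layers))) {
    l <- model$spec$layers[[i]]
    lw <- model$weights[[i]]
    cc <- caches[[i]]
    if (l$kind == "dense") {
      grads[[i]] <- list(W = t(cc$X) %*% d, b = colSums(d))
      d <- d %*% t(lw$W)
    } else if (l$kind == "dropout") {
      grads[[i]] <- list()
      if (!is.null(cc$mask)) d <- d * cc$mask
    } else if (l$kind == "global_max_pool") {
      grads[[i]] <- list()
      d <- nn_gmp_bwd(cc$argmax, d, cc$L)
    } else if (l$kind == "bilstm") {
      r <- nn_bilstm_bwd(cc$X, lw$Wxf, lw$Whf, lw$bf, lw$Wxb, lw$Whb, lw$bb, d)
      grads[[i]] <- list(Wxf = r$dWxf, Whf = r$dWhf, bf = as.numeric(r$dbf),
                         Wxb = r$dWxb, Whb = r$dWhb, bb = as.numeric(r$dbb))
      d <- r$dX
    } else if (l$kind == "conv1d") {
      r <- nn_conv_bwd(cc$X, lw$W, lw$b, d, l$kernel, l$activation == "relu")
      grads[[i]] <- list(W = r$dW, b = as.numeric(r$db))
      d <- r$dX
    } else if (l$kind == "embedding") {
      grads[[i]] <- list(W = nn_embed_bwd(cc$idx, d, l$vocab))
    }
  }
  grads
}

#' Compute logits for a batch of tokenized examples
#'
#' Deterministic inference-mode pass (dropout disabled): each row of the
#' result holds the two unnormalized class scores (non-site, site).
#'
#' @param model A `kd_model` (possibly inside a fitted object; see
#'   [predict.kd_fit()]).
#' @param x Integer token matrix (rows = examples, 0-based indices), a
#'   character vector of fragments, or a fragment tibble.
#' @return Numeric matrix with columns `logit0`, `logit1`.
#' @export
forward_logits <- function(model, x) {
  if (inherits(model, "kd_fit")) model <- model$model
  if (!is.matrix(x)) x <- tokenize(x)
  z <- nn_forward(model, x, training = FALSE)
  colnames(z) <- c("logit0", "logit1")
  z
}

#' Pooled penultimate-layer features
#'
#' The global-max-pooled feature vector feeding the logit layer — the
#' representation projected with t-SNE to visualize class separation before
#' and after training.
#'
#' @inheritParams forward_logits
#' @return Numeric matrix (examples x pooled feature width).
#' @export
pooled_features <- function(model, x) {
  if (inherits(model, "kd_fit")) model <- model$model
  if (!is.matrix(x)) x <- tokenize(x)
  r <- nn_forward(model, x, training = FALSE, cache = TRUE)
  dense_i <- length(model$spec$layers)
  r$caches[[dense_i]]$X
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(weights) {
  zeros_like <- function(ws) lapply(ws, function(w) w * 0)
  list(m = lapply(weights, zeros_like), v = lapply(weights, zeros_like),
       t = 0L)
}

adam_step <- function(state, weights, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(weights)) {
    for (nm in names(weights[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      mhat <- state$m[[i]][[nm]] / corr1
      vhat <- state$v[[i]][[nm]] / corr2
      weights[[i]][[nm]] <- weights[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(state = state, weights = weights)
}
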