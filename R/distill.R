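#' Distillation training configuration
#'
#' Defaults follow the training conventions used throughout the package:
#' mixing weight
#' `alpha = 0.5`, temperature `tau = 10`, Adam with learning rate 1e-4,
#' dropout 0.4, 50 epochs, batch size 16.
#'
#' @param alpha Weight of the student's hard-label loss in `[0, 1]`; `1 - alpha`
#'   weights the summed distillation losses.
#' @param tau Softmax temperature (> 0) applied to logits before the KL terms.
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout rate before the logit layer.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @return A `kd_config` list.
#' @export
distill_config <- function(alpha = 0.5, tau = 10, learning_rate = 1e-4,
                           dropout = 0.4, epochs = 50L, batch_size = 16L,
                           seed = 1L) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (tau <= 0) abort("tau must be > 0")
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1,
            epochs >= 1, batch_size >= 1)
  structure(list(alpha = alpha, tau = tau, learning_rate = learning_rate,
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "kd_config")
}

#' Temperature-softened softmax
#'
#' `softmax(z / tau)` rowwise: probabilities sum to one and are invariant to
#' adding a constant to all logits of a row. Larger `tau` yields softer
#' distributions that preserve inter-class similarity information.
#'
#' @param logits Numeric vector of length 2 or matrix with 2 columns.
#' @param tau Temperature (> 0).
#' @return Probabilities, same shape as `logits`.
#' @examples
#' soften(c(2, 0), tau = 2)
#' @export
soften <- function(logits, tau = 1) {
  if (tau <= 0) abort("tau must be > 0")
  vec <- is.vector(logits)
  z <- if (vec) matrix(logits, nrow = 1) else logits
  if (any(!is.finite(z))) abort("logits must be finite")
  z <- z / tau
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (vec) as.numeric(p) else p
}

#' Temperature-scaled distillation loss
#'
#' `tau^2 * KL(soften(teacher, tau) || soften(student, tau))`, averaged over
#' the batch when given matrices. The teacher distribution is a constant
#' target (no gradient flows through it); the `tau^2` factor keeps gradient
#' magnitudes comparable across temperatures.
#'
#' @param teacher_logits,student_logits Length-2 vectors or 2-column matrices.
#' @param tau Temperature (> 0).
#' @return Nonnegative scalar loss.
#' @examples
#' distill_loss(c(2, 0), c(0, 0), tau = 1) # ~0.3278
#' @export
distill_loss <- function(teacher_logits, student_logits, tau = 1) {
  p <- soften(teacher_logits, tau)
  q <- soften(student_logits, tau)
  if (is.vector(p)) { p <- matrix(p, 1); q <- matrix(q, 1) }
  kl <- rowSums(p * (log(p) - log(q)))
  tau^2 * mean(kl)
}

#' Combined distillation objective
#'
#' `alpha * l_student + (1 - alpha) * (l_d1 + l_d2)`: the student's hard-label
#' cross-entropy mixed with the summed teacher distillation losses. `alpha = 1`
#' disables distillation; `alpha = 0` trains on the teachers alone.
#'
#' @param l_student Hard-label cross-entropy of the student.
#' @param l_d1,l_d2 Distillation losses against teachers 1 and 2.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return The combined loss.
#' @export
total_loss <- function(l_student, l_d1, l_d2, alpha) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  alpha * l_student + (1 - alpha) * (l_d1 + l_d2)
}

# mean cross-entropy on hard labels + gradient wrt logits
softmax_ce <- function(logits, y) {
  p <- soften(logits, tau = 1)
  B <- nrow(p)
  ll <- log(p[cbind(seq_len(B), y + 1L)])
  onehot <- matrix(0, B, 2)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  list(loss = -mean(ll), dlogits = (p - onehot) / B)
}

prepare_xy <- function(data) {
  if (is.list(data) && !is.data.frame(data) && all(c("x", "y") %in% names(data))) {
    return(list(x = data$x, y = as.integer(data$y)))
  }
  if (is.data.frame(data)) {
    return(list(x = tokenize(data$fragment), y = as.integer(data$label)))
  }
  abort("data must be a fragment tibble or a list(x = tokens, y = labels)")
}

# Shared training loop. teachers = NULL trains on hard labels alone (the
# teacher protocol); with teachers, the per-batch gradient is
# alpha * dCE + (1 - alpha) * (dKD1 + dKD2), teachers frozen in inference
# mode. Epoch order of RNG use: init (once), then per epoch shuffle, then per
# batch dropout — identical with and without teachers, so alpha = 1
# distillation is loss-identical to plain training under the same seed.
train_loop <- function(spec, data, config, teachers = NULL) {
  xy <- prepare_xy(data)
  if (length(unique(xy$y)) < 2) abort("training data must contain both classes")
  distilling <- !is.null(teachers)
  alpha <- if (distilling) config$alpha else 1
  tau <- config$tau
  set.seed(config$seed)
  model <- list(spec = spec, weights = init_weights(spec))
  class(model) <- "kd_model"
  # training-time dropout rate comes from the config
  for (i in seq_along(model$spec$layers)) {
    if (model$spec$layers[[i]]$kind == "dropout") {
      model$spec$layers[[i]]$rate <- config$dropout
    }
  }
  opt <- adam_init(model$weights)
  nb <- nrow(xy$x)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nb)
    starts <- seq(1L, nb, by = config$batch_size)
    sums <- c(l_student = 0, l_distill1 = 0, l_distill2 = 0, l_total = 0)
    wsum <- 0
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, nb)]
      xb <- xy$x[rows, , drop = FALSE]
      yb <- xy$y[rows]
      fwd <- nn_forward(model, xb, training = TRUE, cache = TRUE)
      ce <- softmax_ce(fwd$logits, yb)
      d <- alpha * ce$dlogits
      l1 <- 0; l2 <- 0
      if (distilling) {
        B <- nrow(xb)
        qs <- soften(fwd$logits, tau)
        z1 <- nn_forward(teachers[[1]], xb, training = FALSE)
        z2 <- nn_forward(teachers[[2]], xb, training = FALSE)
        p1 <- soften(z1, tau)
        p2 <- soften(z2, tau)
        l1 <- tau^2 * mean(rowSums(p1 * (log(p1) - log(qs))))
        l2 <- tau^2 * mean(rowSums(p2 * (log(p2) - log(qs))))
        d <- d + (1 - alpha) * tau * ((qs - p1) + (qs - p2)) / B
      }
      grads <- nn_backward(model, fwd$caches, d)
      step <- adam_step(opt, model$weights, grads, config$learning_rate)
      opt <- step$state
      model$weights <- step$weights
      w <- length(rows)
      sums <- sums + w * c(ce$loss, l1, l2, total_loss(ce$loss, l1, l2, alpha))
      wsum <- wsum + w
    }
    avg <- sums / wsum
    history[[ep]] <- tibble(epoch = ep, l_student = avg[["l_student"]],
                            l_distill1 = avg[["l_distill1"]],
                            l_distill2 = avg[["l_distill2"]],
                            l_total = avg[["l_total"]])
  }
  list(model = model, history = dplyr::bind_rows(history))
}

new_kd_fit <- function(fit, config, role, teachers = NULL) {
  structure(list(model = fit$model, history = fit$history, config = config,
                 role = role, teachers = teachers),
            class = c(if (!is.null(teachers)) "kd_distilled", "kd_fit"))
}

#' Train a teacher network on hard labels
#'
#' Minimizes mean softmax cross-entropy with Adam over seeded shuffled
#' mini-batches for a fixed number of epochs (no early stopping). The fitted
#' teacher is frozen thereafter and used only in inference mode.
#'
#' @param data Fragment tibble (columns `fragment`, `label`) or
#'   `list(x = token matrix, y = labels)`.
#' @param spec A [kd_model_spec]; defaults to the Conv1D teacher.
#' @param config A [distill_config()].
#' @return A `kd_fit` object with elements `model`, `history` (per-epoch loss
#'   tibble) and `config`.
#' @export
train_teacher <- function(data, spec = build_teacher_cnn(),
                          config = distill_config()) {
  fit <- train_loop(spec, data, config, teachers = NULL)
  fit$history <- fit$history[c("epoch", "l_student")]
  names(fit$history)[2] <- "loss"
  new_kd_fit(fit, config, role = spec$role)
}

#' Distill a student from two frozen teachers
#'
#' Per batch the student sees three signals: hard-label cross-entropy
#' (temperature 1) and one temperature-scaled KL term per teacher, combined
#' as `alpha * L_student + (1 - alpha) * (L_distill1 + L_distill2)`. Teachers
#' are evaluated inside the loop in inference mode and receive no gradient.
#'
#' @param teacher1,teacher2 Fitted teachers (`kd_fit`) or bare `kd_model`s.
#' @param data Training fragments as in [train_teacher()].
#' @param student_spec Student architecture; defaults to the KD3 hybrid.
#' @param config A [distill_config()].
#' @return A `kd_distilled` fit whose `history` records the per-epoch mean
#'   loss breakdown (`l_student`, `l_distill1`, `l_distill2`, `l_total`).
#' @export
distill_student <- function(teacher1, teacher2, data,
                            student_spec = build_student("KD3"),
                            config = distill_config()) {
  as_model <- function(m) if (inherits(m, "kd_fit")) m$model else m
  teachers <- list(as_model(teacher1), as_model(teacher2))
  fit <- train_loop(student_spec, data, config, teachers = teachers)
  new_kd_fit(fit, config, role = "student", teachers = teachers)
}

#' Predict classes, probabilities or logits for fragments
#'
#' The decision rule is the argmax of the two logits (equivalently a 0.5
#' probability threshold), ties broken toward the non-site class.
#'
#' @param object A fitted `kd_fit`.
#' @param newdata Fragment tibble, fragment character vector, or token matrix.
#' @param type `"class"`, `"prob"` or `"logits"`.
#' @param ... Unused.
#' @return A tibble: `.pred_class` for `"class"`; `.pred_nonsite`,
#'   `.pred_site` for `"prob"`; `logit0`, `logit1` for `"logits"`.
#' @export
predict.kd_fit <- function(object, newdata, type = c("class", "prob", "logits"),
                           ...) {
  type <- match.arg(type)
  z <- forward_logits(object$model, newdata)
  if (type == "logits") return(as_tibble(z))
  if (type == "prob") {
    p <- soften(z, tau = 1)
    return(tibble(.pred_nonsite = p[, 1], .pred_site = p[, 2]))
  }
  tibble(.pred_class = predict_labels(z))
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<kd_fit>", x$role,
      if (x$model$spec$variant != "none") paste0("(", x$model$spec$variant, ")"),
      "- trained", max(x$history$epoch), "epochs\n")
  last <- x$history[nrow(x$history), ]
  cat("  final loss:",
      signif(last[[if ("l_total" %in% names(last)) "l_total" else "loss"]], 5),
      "\n")
  invisible(x)
}

#' Write a loss history to CSV
#'
#' @param fit A `kd_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
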