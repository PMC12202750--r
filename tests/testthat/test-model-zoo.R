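layer_kinds <- function(spec) {
  vapply(spec$layers, `[[`, character(1), "kind")
}

test_that("teacher architectures follow the declared layer stacks", {
  cnn <- build_teacher_cnn()
  expect_equal(layer_kinds(cnn),
               c("embedding", "conv1d", "conv1d", "global_max_pool",
                 "dropout", "dense"))
  expect_equal(sum(layer_kinds(cnn) == "conv1d"), 2L)

  bil <- build_teacher_bilstm()
  expect_equal(layer_kinds(bil),
               c("embedding", "bilstm", "bilstm", "global_max_pool",
                 "dropout", "dense"))
  # second bilstm consumes the 64-wide concatenated directions; pooled
  # feature width is also 64
  widths <- kdsucc:::layer_widths(bil)
  expect_equal(widths[2], 64L)
  expect_equal(widths[4], 64L)
})

test_that("student variants order their blocks as specified", {
  expect_equal(layer_kinds(build_student("KD1"))[2:3],
               c("conv1d", "global_max_pool"))
  expect_false("bilstm" %in% layer_kinds(build_student("KD1")))
  expect_false("conv1d" %in% layer_kinds(build_student("KD2")))
  expect_equal(layer_kinds(build_student("KD3"))[2:3], c("conv1d", "bilstm"))
  expect_equal(layer_kinds(build_student("KD4"))[2:3], c("bilstm", "conv1d"))
  expect_error(build_student("KD9"), "unknown student variant")
})

test_that("closed-form parameter counts match the standard formulas", {
  emb_only <- kdsucc:::new_model_spec(
    list(kdsucc:::layer_embedding(21, 300), kdsucc:::layer_gmp(),
         kdsucc:::layer_dense(2)))
  expect_equal(count_parameters(emb_only), 21L * 300L + 300L * 2L + 2L)

  cnn <- tidy(build_teacher_cnn())
  expect_equal(cnn$parameters[cnn$kind == "embedding"], 6300L)
  expect_equal(cnn$parameters[cnn$kind == "conv1d"][1], 300L * 3L * 32L + 32L)
  expect_equal(cnn$parameters[cnn$kind == "conv1d"][2], 32L * 3L * 32L + 32L)

  bil <- tidy(build_teacher_bilstm())
  expect_equal(bil$parameters[bil$kind == "bilstm"][1],
               2L * 4L * ((300L + 32L) * 32L + 32L))
  expect_equal(bil$parameters[bil$kind == "bilstm"][1], 85248L)
  expect_equal(bil$parameters[bil$kind == "dense"], 64L * 2L + 2L)
})

test_that("count_parameters agrees with instantiated weight tensors", {
  for (spec in list(build_teacher_cnn(), build_teacher_bilstm(),
                    build_student("KD1"), build_student("KD2"),
                    build_student("KD3"), build_student("KD4"))) {
    model <- init_model(spec, seed = 1)
    expect_equal(count_parameters(spec), kdsucc:::n_weights(model$weights))
  }
})

test_that("each student is smaller than the two teachers combined", {
  teachers <- count_parameters(build_teacher_cnn()) +
    count_parameters(build_teacher_bilstm())
  for (v in c("KD1", "KD2", "KD3", "KD4")) {
    expect_lt(count_parameters(build_student(v)), teachers)
  }
})

test_that("forward pass is deterministic, batch-consistent, and zero at zero", {
  spec <- tiny_student("KD3")
  model <- init_model(spec, seed = 3)
  set.seed(9)
  x <- matrix(sample(0:20, 5 * 9, TRUE), 5, 9)

  z1 <- forward_logits(model, x)
  z2 <- forward_logits(model, x)
  expect_identical(z1, z2)

  # each row's logits do not depend on the rest of the batch
  z_row <- forward_logits(model, x[2, , drop = FALSE])
  expect_equal(unname(z_row[1, ]), unname(z1[2, ]))

  # batch permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(forward_logits(model, x[perm, ])), unname(z1[perm, ]))

  zero <- model
  zero$weights <- lapply(zero$weights, function(lw) lapply(lw, function(w) w * 0))
  expect_equal(unname(forward_logits(zero, x)),
               matrix(0, 5, 2), tolerance = 1e-12)

  m2 <- init_model(spec, seed = 3)
  expect_identical(model$weights, m2$weights)
})

test_that("analytic gradients match finite differences on every architecture", {
  set.seed(42)
  L <- 7L
  x <- matrix(sample(0:20, 3 * L, TRUE), 3, L)
  y <- c(0L, 1L, 1L)
  ce_loss <- function(model) {
    z <- kdsucc:::nn_forward(model, x, training = FALSE)
    p <- soften(z, 1)
    -mean(log(p[cbind(seq_along(y), y + 1L)]))
  }
  specs <- list(build_teacher_cnn(embed_dim = 5, filters = 4, input_length = L),
                build_teacher_bilstm(embed_dim = 5, units = 3, input_length = L),
                build_student("KD3", embed_dim = 5, filters = 4, units = 3,
                              input_length = L),
                build_student("KD4", embed_dim = 5, filters = 4, units = 3,
                              input_length = L))
  for (spec in specs) {
    model <- init_model(spec, seed = 7)
    fwd <- kdsucc:::nn_forward(model, x, training = FALSE, cache = TRUE)
    ce <- kdsucc:::softmax_ce(fwd$logits, y)
    grads <- kdsucc:::nn_backward(model, fwd$caches, ce$dlogits)
    for (i in seq_along(model$weights)) {
      for (w in names(model$weights[[i]])) {
        W <- model$weights[[i]][[w]]
        for (j in sample(length(W), min(4, length(W)))) {
          eps <- 1e-5
          up <- model; up$weights[[i]][[w]][j] <- W[j] + eps
          dn <- model; dn$weights[[i]][[w]][j] <- W[j] - eps
          num <- (ce_loss(up) - ce_loss(dn)) / (2 * eps)
          ana <- grads[[i]][[w]][j]
          expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
        }
      }
    }
  }
})
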