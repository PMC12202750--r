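#' Model specifications
#'
#' A `kd_model_spec` is a declarative description of an embedding + layer
#' stack: an ordered list of layer specs starting with the trainable
#' embedding (vocab 21, dimension 300) and ending in a 2-unit dense layer that
#' emits unnormalized class logits (class 0 = non-site, class 1 = site). The
#' classification head shared by every architecture is global max pooling
#' over the sequence axis, dropout 0.4, and the dense logit layer.
#'
#' @name kd_model_spec
#' @param layers List of layer descriptions.
#' @param input_length Window length L (default 33).
#' @param role `"teacher1"`, `"teacher2"` or `"student"`.
#' @param variant Student variant (`"KD1"`..`"KD4"`) or `"none"`.
#' @return A `kd_model_spec` object.
#' @keywords internal
new_model_spec <- function(layers, input_length = 33L, role = "student",
                           variant = "none") {
  spec <- structure(
    list(layers = layers, input_length = as.integer(input_length),
         role = role, variant = variant),
    class = "kd_model_spec")
  validate_model_spec(spec)
  spec
}

validate_model_spec <- function(spec) {
  ls <- spec$layers
  if (ls[[1]]$kind != "embedding") abort("first layer must be the embedding")
  last <- ls[[length(ls)]]
  if (last$kind != "dense" || last$units != 2L) {
    abort("last layer must be a 2-unit dense logit layer")
  }
  for (l in ls) {
    switch(l$kind,
      embedding = stopifnot(l$vocab >= 1, l$dim >= 1),
      conv1d = stopifnot(l$filters >= 1, l$kernel >= 1, l$kernel %% 2 == 1),
      bilstm = stopifnot(l$units >= 1),
      dropout = stopifnot(l$rate >= 0, l$rate < 1),
      dense = stopifnot(l$units >= 1),
      global_max_pool = NULL,
      abort(paste0("unknown layer kind: ", l$kind)))
  }
  widths <- layer_widths(spec)
  if (any(is.na(widths))) abort("layer shapes do not chain")
  invisible(spec)
}

# output channel width after each layer (NA if shapes cannot chain)
layer_widths <- function(spec) {
  w <- NA_integer_
  vapply(spec$layers, function(l) {
    w <<- switch(l$kind,
      embedding = l$dim,
      conv1d = l$filters,
      bilstm = 2L * l$units,
      global_max_pool = w,
      dropout = w,
      dense = l$units)
    as.integer(w)
  }, integer(1))
}

layer_embedding <- function(vocab = 21L, dim = 300L) {
  list(kind = "embedding", vocab = as.integer(vocab), dim = as.integer(dim))
}
layer_conv1d <- function(filters = 32L, kernel = 3L, activation = "relu") {
  list(kind = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = activation)
}
layer_bilstm <- function(units = 32L, return_sequences = TRUE) {
  list(kind = "bilstm", units = as.integer(units),
       return_sequences = return_sequences)
}
layer_gmp <- function() list(kind = "global_max_pool")
layer_dropout <- function(rate = 0.4) list(kind = "dropout", rate = rate)
layer_dense <- function(units = 2L) list(kind = "dense", units = as.integer(units))

head_layers <- function(dropout = 0.4) {
  list(layer_gmp(), layer_dropout(dropout), layer_dense(2L))
}

#' Build the Conv1D teacher (Teacher 1)
#'
#' Embedding (21 x 300) followed by two length-preserving Conv1D layers
#' (32 filters, kernel 3, ReLU), then the shared classification head.
#'
#' @param embed_dim Embedding dimension (default 300).
#' @param filters,kernel Convolution width parameters (defaults 32 and 3).
#' @param dropout Dropout rate before the logit layer (default 0.4).
#' @param input_length Window length (default 33).
#' @return A [kd_model_spec].
#' @export
build_teacher_cnn <- function(embed_dim = 300L, filters = 32L, kernel = 3L,
                              dropout = 0.4, input_length = 33L) {
  new_model_spec(
    c(list(layer_embedding(21L, embed_dim),
           layer_conv1d(filters, kernel),
           layer_conv1d(filters, kernel)),
      head_layers(dropout)),
    input_length = input_length, role = "teacher1")
}

#' Build the Bi-LSTM teacher (Teacher 2)
#'
#' Embedding followed by two stacked bidirectional LSTM layers (32 units per
#' direction, sequence output), then the shared classification head.
#'
#' @inheritParams build_teacher_cnn
#' @param units LSTM units per direction (default 32).
#' @return A [kd_model_spec].
#' @export
build_teacher_bilstm <- function(embed_dim = 300L, units = 32L, dropout = 0.4,
                                 input_length = 33L) {
  new_model_spec(
    c(list(layer_embedding(21L, embed_dim),
           layer_bilstm(units),
           layer_bilstm(units)),
      head_layers(dropout)),
    input_length = input_length, role = "teacher2")
}

#' Build a student architecture
#'
#' The four distillation students: `KD1` = single Conv1D block, `KD2` =
#' single Bi-LSTM block, `KD3` = Conv1D then Bi-LSTM (local motifs first,
#' then long-range context), `KD4` = the reverse order. All share the
#' embedding front end and the pooled classification head.
#'
#' @param variant One of `"KD1"`, `"KD2"`, `"KD3"`, `"KD4"`
#'   (case-insensitive).
#' @inheritParams build_teacher_cnn
#' @param units LSTM units per direction (default 32).
#' @return A [kd_model_spec].
#' @export
build_student <- function(variant = "KD3", embed_dim = 300L, filters = 32L,
                          kernel = 3L, units = 32L, dropout = 0.4,
                          input_length = 33L) {
  variant <- toupper(variant)
  body <- switch(variant,
    KD1 = list(layer_conv1d(filters, kernel)),
    KD2 = list(layer_bilstm(units)),
    KD3 = list(layer_conv1d(filters, kernel), layer_bilstm(units)),
    KD4 = list(layer_bilstm(units), layer_conv1d(filters, kernel)),
    abort(paste0("unknown student variant: ", variant)))
  new_model_spec(
    c(list(layer_embedding(21L, embed_dim)), body, head_layers(dropout)),
    input_length = input_length, role = "student", variant = variant)
}

#' Count trainable parameters of a model specification
#'
#' Standard closed-form counts per layer: embedding `v * d`; Conv1D
#' `in * k * f + f`; Bi-LSTM `2 * 4 * (u * (in + u) + u)` (four gates per
#' direction); dense `in * out + out`.
#'
#' @param spec A [kd_model_spec].
#' @return Total trainable parameter count (integer).
#' @examples
#' count_parameters(build_teacher_cnn())
#' @export
count_parameters <- function(spec) {
  validate_model_spec(spec)
  total <- 0
  w <- NA_integer_
  for (l in spec$layers) {
    total <- total + switch(l$kind,
      embedding = l$vocab * l$dim,
      conv1d = w * l$kernel * l$filters + l$filters,
      bilstm = 2 * 4 * (l$units * (w + l$units) + l$units),
      dense = w * l$units + l$units,
      0)
    w <- switch(l$kind,
      embedding = l$dim, conv1d = l$filters, bilstm = 2L * l$units,
      dense = l$units, w)
  }
  as.integer(total)
}

#' @export
print.kd_model_spec <- function(x, ...) {
  cat("<kd_model_spec> role =", x$role,
      if (x$variant != "none") paste0("(", x$variant, ")") else "",
      " L =", x$input_length, "\n")
  for (l in x$layers) {
    desc <- switch(l$kind,
      embedding = paste0("embedding(", l$vocab, " -> ", l$dim, ")"),
      conv1d = paste0("conv1d(filters = ", l$filters, ", kernel = ", l$kernel,
                      ", ", l$activation, ", same padding)"),
      bilstm = paste0("bilstm(units = ", l$units, ", sequence output)"),
      global_max_pool = "global_max_pool",
      dropout = paste0("dropout(", l$rate, ")"),
      dense = paste0("dense(", l$units, " logits)"))
    cat("  -", desc, "\n")
  }
  cat("  parameters:", count_parameters(x), "\n")
  invisible(x)
}
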