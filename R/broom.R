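# broom-style tidiers for fitted objects and result containers

#' Tidy a fitted model's loss history
#'
#' @param x A `kd_fit` (teacher) or `kd_distilled` (student) object.
#' @param ... Unused.
#' @return The per-epoch loss tibble; distilled fits carry the full
#'   breakdown (`l_student`, `l_distill1`, `l_distill2`, `l_total`).
#' @method tidy kd_fit
#' @export
tidy.kd_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @return Tibble with role, variant, epochs, final loss, parameter count and
#'   the key hyperparameters.
#' @method glance kd_fit
#' @export
glance.kd_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(role = x$role, variant = x$model$spec$variant,
         epochs = max(x$history$epoch),
         final_loss = last[[if ("l_total" %in% names(last)) "l_total" else "loss"]],
         n_parameters = count_parameters(x$model$spec),
         alpha = x$config$alpha, tau = x$config$tau,
         learning_rate = x$config$learning_rate)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `kd_cv` from [cross_validate()].
#' @param ... Unused.
#' @return Per-fold metric tibble (one row per fold).
#' @method tidy kd_cv
#' @export
tidy.kd_cv <- function(x, ...) x$folds

#' Cross-validation summary in the mean +/- SD convention
#'
#' @param x A `kd_cv`.
#' @param ... Unused.
#' @return One-row tibble with `<metric>_mean` and `<metric>_sd` columns.
#' @method glance kd_cv
#' @export
glance.kd_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::mutate(wide, k = x$k, variant = x$variant)
}

#' Tidy a model specification into a layer table
#'
#' @param x A [kd_model_spec].
#' @param ... Unused.
#' @return Tibble with one row per layer: `layer`, `kind`, `width`,
#'   `parameters`.
#' @method tidy kd_model_spec
#' @export
tidy.kd_model_spec <- function(x, ...) {
  widths <- layer_widths(x)
  params <- vapply(seq_along(x$layers), function(i) layer_param_count(x, i),
                   integer(1))
  tibble(layer = seq_along(x$layers),
         kind = vapply(x$layers, `[[`, character(1), "kind"),
         width = widths, parameters = params)
}

layer_param_count <- function(spec, i) {
  w <- if (i == 1) NA_integer_ else layer_widths(spec)[i - 1]
  l <- spec$layers[[i]]
  as.integer(switch(l$kind,
    embedding = l$vocab * l$dim,
    conv1d = w * l$kernel * l$filters + l$filters,
    bilstm = 2 * 4 * (l$units * (w + l$units) + l$units),
    dense = w * l$units + l$units,
    0))
}
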