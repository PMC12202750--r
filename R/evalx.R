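#' Confusion counts for binary site predictions
#'
#' Class 1 is the succinylation site (positive) class.
#'
#' @param truth,estimate Equal-length binary (0/1) vectors.
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("truth and estimate lengths differ")
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  if (!all(c(truth, estimate) %in% c(0L, 1L))) abort("entries must be 0 or 1")
  tibble(tp = sum(truth == 1L & estimate == 1L),
         tn = sum(truth == 0L & estimate == 0L),
         fp = sum(truth == 0L & estimate == 1L),
         fn = sum(truth == 1L & estimate == 0L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `ACC = (TP+TN)/N` and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`, the balanced
#' summary preferred under class imbalance (`+1` perfect, `0` random, `-1`
#' fully inverted). A zero denominator yields `mcc = 0` with
#' `mcc_undefined = TRUE`.
#'
#' @param counts One-row tibble/list with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble `sen`, `spe`, `acc`, `mcc`, `mcc_undefined`.
#' @examples
#' metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  tibble(
    sen = tp / (tp + fn),
    spe = tn / (tn + fp),
    acc = (tp + tn) / (tp + tn + fp + fn),
    mcc = if (den == 0) 0 else (tp * tn - fn * fp) / sqrt(den),
    mcc_undefined = den == 0)
}

#' Logits to hard labels
#'
#' Argmax over the two logits, ties broken toward class 0 (non-site).
#'
#' @param logits 2-column matrix (or length-2 vector) of logits.
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(logits) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  if (any(!is.finite(logits))) abort("logits must be finite")
  as.integer(logits[, 2] > logits[, 1])
}

#' Evaluate a fitted model on labelled fragments
#'
#' @param fit A `kd_fit`.
#' @param data Fragment tibble (columns `fragment`, `label`).
#' @return One-row metric tibble as from [metrics()].
#' @export
evaluate <- function(fit, data) {
  xy <- prepare_xy(data)
  pred <- predict_labels(forward_logits(fit, xy$x))
  metrics(confusion(xy$y, pred))
}

# stratified fold assignment: within each class, shuffled examples are dealt
# round-robin so fold class counts differ by at most one
stratified_folds <- function(y, k, seed) {
  if (k < 2) abort("k must be at least 2")
  if (any(table(y) < k)) abort("each class needs at least k examples")
  set.seed(seed)
  fold <- integer(length(y))
  start <- 0L
  for (cl in unique(y)) {
    idx <- which(y == cl)
    # continue the round-robin across classes so overall fold sizes also
    # differ by at most one
    fold[idx[sample.int(length(idx))]] <-
      (start + seq_along(idx) - 1L) %% k + 1L
    start <- start + length(idx)
  }
  fold
}

#' Stratified k-fold cross-validation of the full distillation protocol
#'
#' Per fold, both teachers and the student are trained from scratch on the
#' other k-1 folds (teachers first, then distillation) and evaluated on the
#' held-out fold; the summary reports the mean and sample standard deviation
#' of each metric across folds. Set `retrain_teachers = FALSE` to reuse
#' teachers trained once on the full dataset (faster, optimistically biased).
#'
#' @param data Fragment tibble (columns `fragment`, `label`).
#' @param config A [distill_config()].
#' @param variant Student variant (default `"KD3"`).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment (training seeds come from
#'   `config$seed`).
#' @param retrain_teachers Retrain teachers inside each fold (default `TRUE`).
#' @param embed_dim Embedding dimension for all three networks (default 300).
#' @return A `kd_cv` object: `folds` (per-fold metric tibble with a `fold`
#'   column), `summary` (per-metric mean and sd), `fold_assignment`.
#' @export
cross_validate <- function(data, config = distill_config(), variant = "KD3",
                           k = 10L, seed = config$seed,
                           retrain_teachers = TRUE, embed_dim = 300L) {
  stopifnot(is.data.frame(data))
  L <- nchar(data$fragment[1])
  fold <- stratified_folds(data$label, k, seed)
  global_teachers <- NULL
  if (!retrain_teachers) {
    global_teachers <- list(
      train_teacher(data, build_teacher_cnn(embed_dim = embed_dim,
                                            input_length = L), config),
      train_teacher(data, build_teacher_bilstm(embed_dim = embed_dim,
                                               input_length = L), config))
  }
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    if (retrain_teachers) {
      t1 <- train_teacher(tr, build_teacher_cnn(embed_dim = embed_dim,
                                                input_length = L), config)
      t2 <- train_teacher(tr, build_teacher_bilstm(embed_dim = embed_dim,
                                                   input_length = L), config)
    } else {
      t1 <- global_teachers[[1]]; t2 <- global_teachers[[2]]
    }
    st <- distill_student(t1, t2, tr,
                          build_student(variant, embed_dim = embed_dim,
                                        input_length = L), config)
    dplyr::mutate(evaluate(st, te), fold = f, .before = 1)
  })
  long <- tidyr::pivot_longer(per_fold[c("fold", "sen", "spe", "acc", "mcc")],
                              -"fold", names_to = "metric")
  summ <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                           mean = mean(.data$value), sd = sd(.data$value),
                           .groups = "drop")
  structure(list(folds = per_fold, summary = summ, fold_assignment = fold,
                 k = k, variant = variant, config = config),
            class = "kd_cv")
}

#' @export
print.kd_cv <- function(x, ...) {
  cat("<kd_cv>", x$k, "folds, student", x$variant, "\n")
  print(x$summary)
  invisible(x)
}

#' Alpha/temperature ablation grid
#'
#' Trains one distilled student per (alpha, tau) combination and reports
#' cross-validated and independent-test accuracy and MCC, one row per
#' combination. Teachers do not depend on alpha or tau, so they are trained
#' once on the full training set (and once per fold) and reused across the
#' grid.
#'
#' @param dataset A `kd_dataset` (or list with fragment tibbles `train` and
#'   `test`).
#' @param alphas,taus Grids; defaults `c(0.3, 0.5, 0.7)` and `c(3, 5, 10)`.
#' @param config Base [distill_config()] (its `alpha`/`tau` are overridden).
#' @param k Cross-validation folds (default 10); `k = 0` skips the CV columns.
#' @param variant Student variant (default `"KD3"`).
#' @param embed_dim Embedding dimension (default 300).
#' @return A tibble with columns `alpha`, `tau`, `cv_acc`, `cv_mcc`,
#'   `test_acc`, `test_mcc`.
#' @export
ablation_grid <- function(dataset, alphas = c(0.3, 0.5, 0.7),
                          taus = c(3, 5, 10), config = distill_config(),
                          k = 10L, variant = "KD3", embed_dim = 300L) {
  if (length(alphas) == 0 || length(taus) == 0) abort("empty ablation grid")
  train <- dataset$train
  test <- dataset$test
  L <- nchar(train$fragment[1])
  t1 <- train_teacher(train, build_teacher_cnn(embed_dim = embed_dim,
                                               input_length = L), config)
  t2 <- train_teacher(train, build_teacher_bilstm(embed_dim = embed_dim,
                                                  input_length = L), config)
  fold <- if (k >= 2) stratified_folds(train$label, k, config$seed) else NULL
  fold_teachers <- if (k >= 2) {
    lapply(seq_len(k), function(f) {
      tr <- train[fold != f, , drop = FALSE]
      list(train_teacher(tr, build_teacher_cnn(embed_dim = embed_dim,
                                               input_length = L), config),
           train_teacher(tr, build_teacher_bilstm(embed_dim = embed_dim,
                                                  input_length = L), config))
    })
  }
  grid <- tidyr::expand_grid(tau = taus, alpha = alphas)[c("alpha", "tau")]
  purrr::pmap_dfr(grid, function(alpha, tau) {
    cfg <- config
    cfg$alpha <- alpha
    cfg$tau <- tau
    cv_acc <- NA_real_; cv_mcc <- NA_real_
    if (k >= 2) {
      fm <- purrr::map_dfr(seq_len(k), function(f) {
        tr <- train[fold != f, , drop = FALSE]
        st <- distill_student(fold_teachers[[f]][[1]], fold_teachers[[f]][[2]],
                              tr, build_student(variant, embed_dim = embed_dim, input_length = L),
                              cfg)
        evaluate(st, train[fold == f, , drop = FALSE])
      })
      cv_acc <- mean(fm$acc); cv_mcc <- mean(fm$mcc)
    }
    st <- distill_student(t1, t2, train,
                          build_student(variant, embed_dim = embed_dim, input_length = L), cfg)
    tm <- evaluate(st, test)
    tibble(alpha = alpha, tau = tau, cv_acc = cv_acc, cv_mcc = cv_mcc,
           test_acc = tm$acc, test_mcc = tm$mcc)
  })
}
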