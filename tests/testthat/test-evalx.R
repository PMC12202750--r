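# brute-force metric oracle: recompute everything by explicit looping
oracle_metrics <- function(truth, pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sen = tp / (tp + fn), spe = tn / (tn + fp),
       acc = (tp + tn) / length(truth),
       mcc = if (den == 0) 0 else (tp * tn - fn * fp) / sqrt(den))
}

test_that("confusion counts match the hand-traced example", {
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  cc <- confusion(truth, pred)
  expect_equal(unlist(cc), c(tp = 3L, tn = 4L, fp = 1L, fn = 2L))
  expect_equal(sum(unlist(cc)), length(truth))

  same <- confusion(truth, truth)
  expect_equal(same$fp + same$fn, 0L)
  allpos <- confusion(truth, rep(1, 10))
  expect_equal(allpos$tn + allpos$fn, 0L)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metrics reproduce the worked values and the MCC limits", {
  m <- metrics(confusion(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)))
  expect_equal(m$sen, 0.6)
  expect_equal(m$spe, 0.8)
  expect_equal(m$acc, 0.7)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-12)

  truth <- rep(c(1, 0), 10)
  expect_equal(metrics(confusion(truth, truth))$mcc, 1)
  expect_equal(metrics(confusion(truth, 1 - truth))$mcc, -1)

  und <- metrics(confusion(c(1, 1), c(1, 1)))
  expect_equal(und$mcc, 0)
  expect_true(und$mcc_undefined)
})

test_that("metrics match the brute-force oracle on random confusion tables", {
  set.seed(77)
  for (i in 1:500) {
    n <- sample(4:40, 1)
    truth <- sample(0:1, n, TRUE)
    pred <- sample(0:1, n, TRUE)
    m <- metrics(confusion(truth, pred))
    o <- oracle_metrics(truth, pred)
    if (!m$mcc_undefined) {
      expect_identical(c(m$sen, m$spe, m$acc, m$mcc),
                       c(o$sen, o$spe, o$acc, o$mcc))
    }
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
  }
})

test_that("predict_labels takes the argmax with ties toward non-site", {
  expect_equal(predict_labels(c(0, 0)), 0L)
  expect_equal(predict_labels(c(-1, 3)), 1L)
  z <- matrix(c(0, 0, -1, 3, 2, 1), ncol = 2, byrow = TRUE)
  expect_equal(predict_labels(z),
               vapply(seq_len(nrow(z)), function(i) predict_labels(z[i, ]),
                      integer(1)))
  expect_error(predict_labels(c(NaN, 1)), "finite")
})

test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c(1L, 0L), c(33, 67))
  fold <- kdsucc:::stratified_folds(y, k = 10, seed = 4)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  pos_per_fold <- table(fold[y == 1L])
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  fold2 <- kdsucc:::stratified_folds(y, k = 10, seed = 4)
  expect_identical(fold, fold2)
  expect_error(kdsucc:::stratified_folds(y, k = 1, seed = 1), "at least 2")
  expect_error(kdsucc:::stratified_folds(rep(c(0L, 1L), c(50, 2)), k = 5,
                                         seed = 1), "at least k")
})

test_that("cross_validate is a reproducible stratified protocol", {
  data <- toy_fragments(18, L = 9)
  cfg <- distill_config(epochs = 2, batch_size = 8, learning_rate = 5e-3,
                        seed = 13)
  cv <- cross_validate(data, cfg, variant = "KD3", k = 3, embed_dim = 8)
  expect_equal(nrow(cv$folds), 3)
  expect_equal(sort(unique(cv$fold_assignment)), 1:3)
  summ <- cv$summary
  expect_equal(summ$mean[summ$metric == "mcc"], mean(cv$folds$mcc))
  expect_equal(summ$sd[summ$metric == "acc"], sd(cv$folds$acc))

  cv2 <- cross_validate(data, cfg, variant = "KD3", k = 3, embed_dim = 8)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$folds, cv2$folds)

  g <- glance(cv)
  expect_equal(g$mcc_mean, mean(cv$folds$mcc))
})

test_that("ablation grid emits one row per combination with CV and test
           columns", {
  data <- toy_fragments(15, L = 9)
  ds <- list(train = data, test = toy_fragments(8, L = 9, seed = 2))
  cfg <- distill_config(epochs = 2, batch_size = 8, learning_rate = 5e-3,
                        seed = 3)
  grid <- ablation_grid(ds, alphas = c(0.3, 0.7), taus = 5, config = cfg,
                        k = 0, embed_dim = 8)
  expect_equal(nrow(grid), 2)
  expect_equal(grid$alpha, c(0.3, 0.7))
  expect_equal(grid$tau, c(5, 5))
  expect_true(all(c("cv_acc", "cv_mcc", "test_acc", "test_mcc") %in%
                    names(grid)))
  single <- ablation_grid(ds, alphas = 0.5, taus = 10, config = cfg, k = 0,
                          embed_dim = 8)
  expect_equal(nrow(single), 1)
  expect_error(ablation_grid(ds, alphas = numeric(0), taus = 5, config = cfg),
               "empty")
})

test_that("t-SNE projection is seeded and separates distinct clusters", {
  set.seed(8)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, mean = 0), ncol = 4),
             matrix(rnorm(n * 4, mean = 8), ncol = 4))
  labels <- rep(c(0L, 1L), each = n)
  proj <- tsne_project(x, seed = 42, perplexity = 10, labels = labels)
  expect_equal(nrow(proj), 2 * n)
  proj2 <- tsne_project(x, seed = 42, perplexity = 10, labels = labels)
  expect_identical(proj$tsne1, proj2$tsne1)

  # nearest-centroid split in 2-D recovers the clusters
  xy <- as.matrix(proj[c("tsne1", "tsne2")])
  c0 <- colMeans(xy[labels == 0L, ])
  c1 <- colMeans(xy[labels == 1L, ])
  d0 <- sqrt(rowSums((xy - matrix(c0, 2 * n, 2, byrow = TRUE))^2))
  d1 <- sqrt(rowSums((xy - matrix(c1, 2 * n, 2, byrow = TRUE))^2))
  assign <- as.integer(d1 < d0)
  expect_gte(mean(assign == labels), 0.95)

  expect_error(tsne_project(x[1:20, ], perplexity = 30), "3 \\* perplexity")
})

test_that("residue enrichment recovers a constructed positional signal", {
  set.seed(12)
  L <- 9L
  neg <- replicate(400, paste(sample(aa20, L, TRUE), collapse = ""))
  pos <- vapply(1:400, function(i) {
    chars <- sample(aa20, L, TRUE)
    chars[(L - 1L) / 2L] <- "E" # offset -1 from the center
    paste(chars, collapse = "")
  }, character(1))
  enr <- residue_enrichment(pos, neg)
  expect_s3_class(enr, "kd_enrichment")
  expect_false(0L %in% enr$offset)
  # per-position class frequencies are distributions
  sums <- dplyr::summarise(dplyr::group_by(enr, offset),
                           p = sum(freq_pos), n = sum(freq_neg))
  expect_equal(sums$p, rep(1, nrow(sums)))
  expect_equal(sums$n, rep(1, nrow(sums)))

  cell <- enr[enr$offset == -1L & enr$residue == "E", ]
  expect_equal(cell$diff, 1 - 1 / 20, tolerance = 0.05)
  expect_lt(cell$p_value, 0.05)
  top <- enrichment_hits(enr)
  expect_equal(top$offset[1], -1L)
  expect_equal(top$residue[1], "E")

  same <- residue_enrichment(neg, neg)
  expect_true(all(same$diff == 0))
  expect_error(residue_enrichment(character(0), neg), "non-empty")
})
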