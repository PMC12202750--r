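test_that("read_fasta parses records, uppercases, and preserves order", {
  path <- write_temp_fasta(list(p1 = "AKCDE"))
  rec <- read_fasta(path)
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "AKCDE")

  path2 <- write_temp_fasta(list(a = "akcde", b = "MKKL"))
  rec2 <- read_fasta(path2)
  expect_equal(rec2$id, c("a", "b"))
  expect_equal(rec2$sequence[1], "AKCDE")
})

test_that("read_fasta rejects empty and malformed files naming the line", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("AKCDE", ">p1"), bad)
  expect_error(read_fasta(bad), "line 1")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("extract_fragment pads with X and matches the hand-traced window", {
  expect_equal(extract_fragment("AKCDE", 2, n = 2), "XAKCD")
  expect_equal(extract_fragment("AKCDE", 3, n = 2), "AKCDE")
  expect_equal(nchar(extract_fragment("AKCDE", 1, n = 16)), 33)
  expect_error(extract_fragment("AKCDE", 6, n = 2), "out of range")
  expect_error(extract_fragment("AKCDE", 0, n = 2), "out of range")
})

test_that("fragment windows satisfy the length/center/padding contracts", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(2:16, 1)
    len <- sample(5:80, 1)
    seqc <- random_protein(len)
    pos <- sample(len, 1)
    frag <- extract_fragment(seqc, pos, n)
    expect_equal(nchar(frag), 2L * n + 1L)
    expect_equal(substr(frag, n + 1L, n + 1L), substr(seqc, pos, pos))
    chars <- strsplit(frag, "")[[1]]
    lpad <- max(0L, n - (pos - 1L))
    rpad <- max(0L, n - (len - pos))
    leading <- match(FALSE, chars == "X", nomatch = length(chars) + 1L) - 1L
    trailing <- match(FALSE, rev(chars) == "X", nomatch = length(chars) + 1L) - 1L
    expect_equal(leading, lpad)
    expect_equal(trailing, rpad)
  }
})

test_that("extract_fragments rejects non-lysine centers with a warning", {
  proteins <- tibble::tibble(id = "p1", sequence = "AKCDEKL")
  sites <- tibble::tibble(protein_id = "p1", position = c(2L, 3L, 6L),
                          label = c(1L, 1L, 0L))
  expect_warning(frags <- extract_fragments(proteins, sites, n = 2),
                 "not K")
  expect_equal(nrow(frags), 2L)
  expect_equal(frags$position, c(2L, 6L))
})

test_that("tokenization maps through the alphabetical 21-symbol vocabulary", {
  vocab <- aa_vocab()
  expect_length(vocab, 21)
  expect_equal(unname(vocab[c("A", "K", "X")]), c(0L, 8L, 20L))
  expect_equal(as.integer(tokenize("XAKCD")), c(20L, 0L, 8L, 1L, 2L))
  expect_equal(ncol(tokenize("MDKETVELEAELNQLKEENAQLKHALAPSAVEA")), 33L)
  expect_equal(as.integer(tokenize(strrep("X", 5))), rep(20L, 5))
})

test_that("tokenize is total and round-trips standard fragments", {
  expect_equal(as.integer(tokenize("BJZUO")), rep(20L, 5))
  set.seed(7)
  for (i in 1:20) {
    f <- random_fragment(33)
    idx <- tokenize(f)
    expect_true(all(idx >= 0L & idx <= 20L))
    expect_equal(detokenize(idx), f)
  }
})

test_that("fragment identity counts shared positions, X included", {
  expect_equal(fragment_identity("AKCDE", "AKCDE"), 1)
  expect_equal(fragment_identity("AAAAA", "CCCCC"), 0)
  expect_equal(fragment_identity("XAK", "XGK"), 2 / 3)
  a <- paste(rep(c("A", "C"), c(10, 23)), collapse = "")
  b <- paste(rep(c("A", "D"), c(10, 23)), collapse = "")
  expect_equal(fragment_identity(a, b), 10 / 33)
  expect_error(fragment_identity("AK", "AKC"), "equal length")
})

test_that("redundancy filter applies the greedy rule and verifies pairwise", {
  f <- random_fragment(33)
  expect_equal(redundancy_filter(c(f, f)), f)

  a <- strrep("A", 33)
  c_ <- strrep("C", 33)
  expect_equal(redundancy_filter(c(a, c_)), c(a, c_))

  # f2 is 50% identical to f1 and dropped; f3 is below the cutoff and kept
  f1 <- strrep("A", 33)
  f2 <- paste0(strrep("A", 17), strrep("C", 16))
  f3 <- paste0(strrep("A", 9), strrep("D", 24))
  expect_equal(redundancy_filter(c(f1, f2, f3)), c(f1, f3))

  set.seed(33)
  frags <- c(replicate(150, random_fragment(33)),
             replicate(30, paste0(strrep("A", 20), random_fragment(13))))
  kept <- redundancy_filter(frags, cutoff = 0.30)
  toks <- tokenize(kept)
  for (i in seq_along(kept)[-1]) {
    ident <- rowMeans(toks[seq_len(i - 1), , drop = FALSE] ==
                        matrix(toks[i, ], i - 1, 33, byrow = TRUE))
    expect_true(all(ident <= 0.30))
  }
  expect_identical(redundancy_filter(character(0)), character(0))
})

test_that("build_dataset enforces the negative:positive training ratio", {
  set.seed(5)
  proteins <- tibble::tibble(
    id = paste0("p", 1:12),
    sequence = replicate(12, {
      s <- sample(aa20, 60, TRUE)
      s[sample(60, 8)] <- "K"
      paste(s, collapse = "")
    }))
  sites <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    ks <- which(strsplit(proteins$sequence[i], "")[[1]] == "K")
    tibble::tibble(protein_id = proteins$id[i], position = ks[1], label = 1L)
  })
  ds <- build_dataset(proteins, sites, n = 5, ratio = 2, seed = 1,
                      cutoff = NULL)
  expect_equal(sum(ds$train$label == 0L), 2L * sum(ds$train$label == 1L))

  ds1 <- build_dataset(proteins, sites, n = 5, ratio = 1, seed = 1,
                       cutoff = NULL)
  expect_equal(sum(ds1$train$label == 0L), sum(ds1$train$label == 1L))

  # test proteins keep all negatives unless capped; origins stay disjoint
  ds2 <- build_dataset(proteins, sites, n = 5, ratio = 2, seed = 1,
                       cutoff = NULL, test_ids = c("p11", "p12"))
  expect_length(intersect(ds2$train$protein_id, ds2$test$protein_id), 0)
  expect_gt(sum(ds2$test$label == 0L), 2L * sum(ds2$test$label == 1L))

  ds3 <- build_dataset(proteins, sites, n = 5, ratio = 2, seed = 1,
                       cutoff = NULL, test_ids = c("p11", "p12"),
                       test_ratio = 3)
  expect_equal(sum(ds3$test$label == 0L), 3L * sum(ds3$test$label == 1L))

  expect_error(build_dataset(proteins, sites[0, ], n = 5),
               "no positive")
  expect_warning(build_dataset(proteins, sites, n = 5, ratio = 50, seed = 1,
                               cutoff = NULL), "keeping all")
})

test_that("fragment files round-trip", {
  frags <- toy_fragments(5, L = 33)
  path <- withr::local_tempfile(fileext = ".frag")
  write_fragments(frags, path)
  back <- read_fragments(path)
  expect_equal(back$fragment, frags$fragment)
  expect_equal(back$label, frags$label)
})
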