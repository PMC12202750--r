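#' Position-specific motif specification for the synthetic benchmark
#'
#' Describes how positive-class flanking residues deviate from background:
#' at each listed window offset, the named residue is drawn with probability
#' `strength * weight` (otherwise the background residue is kept), so per-
#' position distributions remain valid probability vectors and `strength`
#' interpolates linearly between pure background (0) and the full motif (1).
#'
#' Several rows may share an offset (a residue palette); their weights must
#' then sum to at most one. The default motif boosts a five-residue palette
#' at each of the six offsets -3..3 around the central lysine (total weight
#' 0.95 per offset) — a caricature of the positional over-representation
#' that two-sample logos reveal in real succinylation data. Palette width
#' and weight are chosen together so the class signal stays strong while
#' positive-positive sequence identity stays below the 30% redundancy
#' cutoff for nearly all pairs.
#'
#' @param boosts Tibble with columns `offset` (nonzero, within the window),
#'   `residue`, `weight` (in `[0, 1]`, summing to at most 1 per offset).
#' @param strength Global scalar in `[0, 1]`.
#' @return A `kd_motif` object.
#' @export
motif_spec <- function(boosts = NULL, strength = 1) {
  if (is.null(boosts)) {
    palettes <- list(`-3` = c("L", "I", "V", "M", "F"),
                     `-2` = c("D", "E", "N", "Q", "H"),
                     `-1` = c("E", "D", "S", "T", "G"),
                     `1` = c("A", "G", "P", "S", "C"),
                     `2` = c("V", "L", "F", "Y", "W"),
                     `3` = c("R", "H", "Q", "N", "T"))
    boosts <- purrr::map_dfr(names(palettes), function(o) {
      tibble(offset = as.integer(o), residue = palettes[[o]],
             weight = 0.95 / length(palettes[[o]]))
    })
  }
  per_offset <- tapply(boosts$weight, boosts$offset, sum)
  stopifnot(all(boosts$offset != 0L), all(boosts$weight >= 0),
            all(per_offset <= 1 + 1e-12), strength >= 0, strength <= 1,
            !anyDuplicated(boosts[c("offset", "residue")]))
  structure(list(boosts = boosts, strength = strength), class = "kd_motif")
}

#' Synthetic benchmark configuration
#'
#' Defaults mirror the benchmark conventions of curated succinylation
#' datasets: a 1:2 positive:negative training ratio and a more imbalanced
#' independent test set.
#'
#' @param n_train_pos,n_test_pos Positive site counts (defaults 1500 / 300).
#' @param train_ratio Training negative:positive ratio (default 2).
#' @param test_ratio Test negative:positive ratio (default 10, emulating the
#'   heavier imbalance of real independent test sets).
#' @param length_range Protein length range, uniform (default 100--160).
#' @param motif A [motif_spec()].
#' @param n Half-window size (default 16, 33-residue windows).
#' @param cutoff Redundancy-filter identity cutoff applied when assembling the
#'   dataset (default 0.30; `NULL` disables filtering).
#' @param seed Integer seed.
#' @return A `kd_synth_config` list.
#' @export
synth_config <- function(n_train_pos = 1500L, train_ratio = 2,
                         n_test_pos = 300L, test_ratio = 10,
                         length_range = c(100L, 160L), motif = motif_spec(),
                         n = 16L, cutoff = 0.30, seed = 1L) {
  stopifnot(n_train_pos >= 1, n_test_pos >= 0, train_ratio >= 1,
            is.null(test_ratio) || test_ratio >= 1,
            length(length_range) == 2, length_range[1] >= 2 * n + 1)
  structure(list(n_train_pos = as.integer(n_train_pos),
                 train_ratio = train_ratio,
                 n_test_pos = as.integer(n_test_pos), test_ratio = test_ratio,
                 length_range = as.integer(length_range), motif = motif,
                 n = as.integer(n), cutoff = cutoff, seed = as.integer(seed)),
            class = "kd_synth_config")
}

#' The default strong-motif benchmark configuration
#'
#' The documented end-to-end recovery surface: 1500/3000 training and 300/600
#' test fragments carrying the full-strength default motif — large enough for
#' the networks to reach high test MCC, small enough for minutes-scale CPU
#' training.
#'
#' @param seed Integer seed.
#' @param strength Motif strength (default 1).
#' @return A [synth_config()].
#' @export
default_benchmark_config <- function(seed = 1L, strength = 1) {
  synth_config(n_train_pos = 1500L, train_ratio = 2, n_test_pos = 300L,
               test_ratio = 2, motif = motif_spec(strength = strength),
               seed = seed)
}

# residue sampler: uniform over the 20 amino acids except lysine, whose
# probability is boosted so proteins reliably carry several candidate sites
sample_residues <- function(m, k_prob = 0.10) {
  letters20 <- names(aa_vocab())[1:20]
  probs <- rep((1 - k_prob) / 19, 20)
  probs[letters20 == "K"] <- k_prob
  sample(letters20, m, replace = TRUE, prob = probs)
}

#' Generate background proteins
#'
#' I.i.d. residues, uniform over the 20 amino acids except for a boosted
#' lysine density; any protein that still carries fewer than three lysines
#' has random non-terminal positions overwritten with `K`.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Length range (uniform integer draw).
#' @param seed Integer seed.
#' @param prefix Protein id prefix (default `"synth"`).
#' @return Protein tibble (`id`, `sequence`) as from [read_fasta()].
#' @export
generate_background <- function(n_proteins, length_range = c(100L, 160L),
                                seed = 1L, prefix = "synth") {
  stopifnot(n_proteins >= 1)
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(m) {
    res <- sample_residues(m)
    kcount <- sum(res == "K")
    if (kcount < 3) {
      res[sample(which(res != "K"), 3 - kcount)] <- "K"
    }
    paste(res, collapse = "")
  }, character(1))
  tibble(id = paste0(prefix, "_p", seq_len(n_proteins)), sequence = seqs)
}

# implant the motif around one K per protein; returns updated sequences and
# the annotated site table
implant_sites <- function(proteins, motif, n) {
  seqs <- strsplit(proteins$sequence, "", fixed = TRUE)
  pos <- integer(nrow(proteins))
  for (i in seq_along(seqs)) {
    res <- seqs[[i]]
    ks <- which(res == "K")
    # prefer an interior lysine so the motif offsets stay in range
    interior <- ks[ks > max(abs(motif$boosts$offset)) &
                   ks <= length(res) - max(abs(motif$boosts$offset))]
    p <- if (length(interior) > 0) sample(interior, 1) else sample(ks, 1)
    for (o in unique(motif$boosts$offset)) {
      at <- p + o
      if (at < 1 || at > length(res) || at == p) next
      rows <- motif$boosts[motif$boosts$offset == o, , drop = FALSE]
      # one multinomial draw per offset: palette residues at strength * weight
      # each, background residue kept with the remaining mass
      u <- runif(1)
      cum <- cumsum(motif$strength * rows$weight)
      hit <- which(u < cum)
      if (length(hit) > 0) res[at] <- rows$residue[hit[1]]
    }
    seqs[[i]] <- res
    pos[i] <- p
  }
  list(proteins = tibble(id = proteins$id,
                         sequence = vapply(seqs, paste, character(1),
                                           collapse = "")),
       sites = tibble(protein_id = proteins$id, position = pos, label = 1L))
}

#' Generate a synthetic lysine-site benchmark
#'
#' Draws disjoint train and test protein pools from the background model and
#' implants one motif-perturbed positive site per site-carrying protein.
#' Negative windows are drawn from lysines of separate background-only
#' proteins, so their flanks are pure background: a lysine neighbouring an
#' implanted site would otherwise carry the motif off-center inside its
#' window and blur the class boundary. Assembly goes through
#' [build_dataset()] so windowing, redundancy filtering and the class-ratio
#' conventions all apply.
#'
#' @param config A [synth_config()].
#' @return A list: `dataset` (a `kd_dataset`), `motif` (the ground-truth
#'   [motif_spec()]), `proteins`, `sites` (FASTA/TSV-ready tibbles).
#' @export
make_benchmark <- function(config = synth_config()) {
  # background-only proteins supplying the negative pools, sized with margin
  # from the expected lysines per protein
  k_per_protein <- 0.10 * config$length_range[1]
  n_bg_train <- ceiling(config$n_train_pos * config$train_ratio * 1.4 /
                          k_per_protein)
  test_r <- if (is.null(config$test_ratio)) 2 else config$test_ratio
  n_bg_test <- ceiling(max(1, config$n_test_pos) * test_r * 1.4 /
                         k_per_protein)
  pos_total <- config$n_train_pos + config$n_test_pos
  prot_pos <- generate_background(pos_total, config$length_range,
                                  seed = config$seed, prefix = "site")
  prot_bg <- generate_background(n_bg_train + n_bg_test, config$length_range,
                                 seed = config$seed + 10L, prefix = "bg")
  set.seed(config$seed + 1L)
  imp <- implant_sites(prot_pos, config$motif, config$n)
  proteins <- dplyr::bind_rows(imp$proteins, prot_bg)
  test_ids <- c(imp$proteins$id[seq_len(config$n_test_pos) + config$n_train_pos],
                prot_bg$id[seq_len(n_bg_test) + n_bg_train])
  ds <- build_dataset(proteins, imp$sites, n = config$n,
                      ratio = config$train_ratio, seed = config$seed + 2L,
                      cutoff = config$cutoff, test_ids = test_ids,
                      test_ratio = config$test_ratio,
                      negative_ids = prot_bg$id)
  list(dataset = ds, motif = config$motif, proteins = proteins,
       sites = imp$sites, config = config)
}

#' Write a benchmark to disk
#'
#' Emits the FASTA + site-TSV pair (exercising the full extraction path),
#' the pre-cut fragment files, and a JSON manifest with the ground-truth
#' motif, counts and seed.
#'
#' @param benchmark Result of [make_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", benchmark$proteins$id, "\n", benchmark$proteins$sequence),
             file.path(dir, "proteins.fasta"))
  sites <- benchmark$sites
  utils::write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_fragments(benchmark$dataset$train, file.path(dir, "train.frag"))
  write_fragments(benchmark$dataset$test, file.path(dir, "test.frag"))
  manifest <- list(
    counts = list(train_pos = sum(benchmark$dataset$train$label == 1L),
                  train_neg = sum(benchmark$dataset$train$label == 0L),
                  test_pos = sum(benchmark$dataset$test$label == 1L),
                  test_neg = sum(benchmark$dataset$test$label == 0L)),
    motif = list(boosts = benchmark$motif$boosts,
                 strength = benchmark$motif$strength),
    config = benchmark$config[setdiff(names(benchmark$config), "motif")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
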