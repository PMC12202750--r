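#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; characters outside the 20-letter amino-acid
#' alphabet are retained as-is and collapse to the `X` token later, at
#' tokenization time.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited word of the
#'   header) and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "AKCDE"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) abort(paste0("empty FASTA file: ", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("malformed FASTA header at line ", first, " of ", path,
                 ": expected a line starting with '>'"))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    warn("duplicate FASTA ids; records kept in file order")
  }
  tibble(id = ids, sequence = unname(toupper(as.character(seqs))))
}

#' Read site annotations from a delimited table
#'
#' @param path Path to a TSV/CSV file with columns `protein_id`, `position`
#'   (1-based residue index) and `label` (1 = succinylation site, 0 =
#'   non-site).
#' @param sep Field separator (default tab).
#' @return A tibble with columns `protein_id`, `position`, `label`.
#' @export
read_sites <- function(path, sep = "\t") {
  if (!file.exists(path)) abort(paste0("site table not found: ", path))
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(df))) {
    abort(paste0("site table must have columns: ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(df[need])
  out$position <- as.integer(out$position)
  out$label <- as.integer(out$label)
  if (!all(out$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
  out
}

#' Extract a lysine-centered sequence window
#'
#' Returns the `2n+1`-residue substring centered on `position`, with the
#' pseudo-residue `X` substituted wherever the window runs past either end of
#' the protein: the left pad has `max(0, n - (position - 1))` X's and the
#' right pad `max(0, n - (length - position))`.
#'
#' @param sequence Protein sequence (single string).
#' @param position 1-based index of the central residue.
#' @param n Number of residues on each side of the center; the window length
#'   is `2n + 1`. Default 16 (33-residue windows).
#' @return The window as a single string of length `2n + 1`.
#' @examples
#' extract_fragment("AKCDE", 2, n = 2) # "XAKCD"
#' @export
extract_fragment <- function(sequence, position, n = 16L) {
  len <- nchar(sequence)
  if (position < 1L || position > len) {
    abort(paste0("position ", position, " out of range for sequence of length ", len))
  }
  lo <- max(1L, position - n)
  hi <- min(len, position + n)
  core <- substr(sequence, lo, hi)
  lpad <- max(0L, n - (position - 1L))
  rpad <- max(0L, n - (len - position))
  paste0(strrep("X", lpad), core, strrep("X", rpad))
}

#' Extract windows for a table of annotated sites
#'
#' Vectorized companion of [extract_fragment()]. Sites whose central residue
#' is not lysine (`K`) are rejected with a warning (or kept, if
#' `require_lysine = FALSE`).
#'
#' @param proteins Tibble with columns `id`, `sequence` ([read_fasta()]).
#' @param sites Tibble with columns `protein_id`, `position`, `label`
#'   ([read_sites()]).
#' @param n Half-window size (window length `2n + 1`), default 16.
#' @param require_lysine Drop sites whose central residue is not `K`
#'   (default `TRUE`).
#' @return A tibble with columns `fragment`, `label`, `protein_id`,
#'   `position`.
#' @export
extract_fragments <- function(proteins, sites, n = 16L, require_lysine = TRUE) {
  unknown <- setdiff(sites$protein_id, proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("sites reference unknown proteins: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  seqs <- setNames(proteins$sequence, proteins$id)
  out <- dplyr::mutate(
    sites,
    .len = nchar(seqs[.data$protein_id]),
    .center = substr(seqs[.data$protein_id], .data$position, .data$position)
  )
  bad <- out$position < 1L | out$position > out$.len
  if (any(bad)) {
    abort(paste0(sum(bad), " site position(s) out of range (first: ",
                 out$protein_id[which(bad)[1]], ":", out$position[which(bad)[1]], ")"))
  }
  if (require_lysine && any(out$.center != "K")) {
    warn(paste0(sum(out$.center != "K"),
                " site(s) rejected: central residue is not K"))
    out <- out[out$.center == "K", , drop = FALSE]
  }
  frag <- vapply(seq_len(nrow(out)), function(i) {
    extract_fragment(seqs[[out$protein_id[i]]], out$position[i], n)
  }, character(1))
  tibble(fragment = frag, label = as.integer(out$label),
         protein_id = out$protein_id, position = as.integer(out$position))
}

#' Pairwise fragment identity
#'
#' Fraction of positions at which two equal-length fragments carry the same
#' character; `X` matches `X`.
#'
#' @param a,b Fragment strings of equal length.
#' @return Identity fraction in `[0, 1]`.
#' @export
fragment_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("fragments must have equal length")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}

#' Greedy identity-based redundancy filter
#'
#' Deterministic stand-in for a CD-HIT-style redundancy reduction at identity
#' cutoffs below CD-HIT's own floor: fragments are scanned in input order and
#' one is kept iff its identity to every previously kept fragment is at most
#' `cutoff`. `X` is treated as an ordinary character.
#'
#' @param fragments Character vector of equal-length fragments, or a fragment
#'   tibble with a `fragment` column.
#' @param cutoff Maximum allowed identity to any earlier kept fragment
#'   (default 0.30).
#' @return The kept fragments, in original order and original form (vector in,
#'   vector out; tibble in, tibble out).
#' @export
redundancy_filter <- function(fragments, cutoff = 0.30) {
  frag_chr <- if (is.data.frame(fragments)) fragments$fragment else fragments
  if (length(frag_chr) == 0) return(fragments)
  keep <- nn_greedy_filter(tokenize(frag_chr), cutoff)
  if (is.data.frame(fragments)) fragments[keep, , drop = FALSE] else fragments[keep]
}

#' Assemble a train/test dataset with benchmark class-ratio conventions
#'
#' Positives are the annotated sites (label 1); candidate negatives are every
#' other lysine in the same proteins. Both classes are windowed and
#' redundancy-filtered independently (training data only), then training
#' negatives are downsampled uniformly at random (seeded) to
#' `ratio` x positives — the 1:2 convention of the benchmark training sets.
#' Test proteins contribute all surviving fragments unless `test_ratio` caps
#' the negative count.
#'
#' @param proteins Tibble `id`, `sequence`.
#' @param sites Tibble `protein_id`, `position`, `label`; label-1 rows are
#'   positive sites, label-0 rows (optional) pin explicit negatives. Lysines
#'   without an annotation are treated as negatives.
#' @param n Half-window size (default 16).
#' @param ratio Target negative:positive ratio in the training set (default 2).
#' @param seed Integer seed for the negative downsampling.
#' @param cutoff Identity cutoff for [redundancy_filter()] (default 0.30);
#'   `NULL` disables filtering.
#' @param test_ids Protein ids forming the independent test set (default none).
#' @param test_ratio Optional negative:positive cap for the test set; `NULL`
#'   (default) keeps all surviving test negatives.
#' @param negative_ids Optional protein ids from which candidate negatives are
#'   drawn; `NULL` (default) uses every protein. Restricting the negative pool
#'   avoids negative windows that overlap annotated sites.
#' @return A `kd_dataset` object: list with fragment tibbles `train` and
#'   `test` and a `params` list.
#' @export
build_dataset <- function(proteins, sites, n = 16L, ratio = 2, seed = 1L,
                          cutoff = 0.30, test_ids = character(0),
                          test_ratio = NULL, negative_ids = NULL) {
  stopifnot(ratio >= 1)
  if (sum(sites$label == 1L) == 0) abort("no positive sites in annotation table")
  pos_keys <- paste(sites$protein_id[sites$label == 1L],
                    sites$position[sites$label == 1L])
  neg_pool <- if (is.null(negative_ids)) seq_len(nrow(proteins)) else
    which(proteins$id %in% negative_ids)
  # candidate negatives: every K (in the negative pool) not annotated as a
  # positive site
  neg <- purrr::map_dfr(neg_pool, function(i) {
    kpos <- which(strsplit(proteins$sequence[i], "", fixed = TRUE)[[1]] == "K")
    tibble(protein_id = proteins$id[i], position = kpos, label = 0L)
  })
  neg <- neg[!paste(neg$protein_id, neg$position) %in% pos_keys, , drop = FALSE]
  ann <- dplyr::bind_rows(sites[sites$label == 1L, ], neg)

  is_test <- ann$protein_id %in% test_ids
  build_half <- function(tab, filter, nratio, rng_seed) {
    if (nrow(tab) == 0) {
      return(tibble(fragment = character(0), label = integer(0),
                    protein_id = character(0), position = integer(0)))
    }
    frags <- extract_fragments(proteins, tab, n = n)
    pos <- frags[frags$label == 1L, , drop = FALSE]
    negs <- frags[frags$label == 0L, , drop = FALSE]
    if (filter && !is.null(cutoff)) {
      pos <- redundancy_filter(pos, cutoff)
      negs <- redundancy_filter(negs, cutoff)
    }
    if (!is.null(nratio) && is.finite(nratio)) {
      want <- as.integer(round(nratio * nrow(pos)))
      if (nrow(negs) < want) {
        warn(paste0("only ", nrow(negs), " negatives available for a target of ",
                    want, "; keeping all"))
      } else {
        set.seed(rng_seed)
        negs <- negs[sort(sample.int(nrow(negs), want)), , drop = FALSE]
      }
    }
    dplyr::bind_rows(pos, negs)
  }
  train <- build_half(ann[!is_test, , drop = FALSE], filter = TRUE,
                      nratio = ratio, rng_seed = seed)
  test <- build_half(ann[is_test, , drop = FALSE], filter = FALSE,
                     nratio = test_ratio, rng_seed = seed + 1L)
  if (sum(train$label == 1L) == 0) abort("no positive training fragments survived")
  structure(
    list(train = train, test = test,
         params = list(n = n, window = 2L * n + 1L, ratio = ratio,
                       test_ratio = test_ratio, cutoff = cutoff, seed = seed)),
    class = "kd_dataset")
}

#' @export
print.kd_dataset <- function(x, ...) {
  cat("<kd_dataset> window =", x$params$window, "\n")
  cat("  train:", sum(x$train$label == 1L), "pos /",
      sum(x$train$label == 0L), "neg\n")
  cat("  test: ", sum(x$test$label == 1L), "pos /",
      sum(x$test$label == 0L), "neg\n")
  invisible(x)
}

#' Write / read the plain fragment exchange format
#'
#' One `<fragment><TAB><0|1>` line per example — the minimal pre-cut input
#' format accepted everywhere a fragment tibble is.
#'
#' @param fragments Fragment tibble (columns `fragment`, `label`).
#' @param path Output file.
#' @return `write_fragments()` returns `path` invisibly; `read_fragments()`
#'   returns a fragment tibble.
#' @export
write_fragments <- function(fragments, path) {
  writeLines(paste0(fragments$fragment, "\t", fragments$label), path)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) abort(paste0("fragment file not found: ", path))
  df <- read.delim(path, header = FALSE, col.names = c("fragment", "label"),
                   stringsAsFactors = FALSE)
  out <- as_tibble(df)
  out$label <- as.integer(out$label)
  out
}
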