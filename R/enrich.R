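#' Position-specific residue enrichment between positive and negative windows
#'
#' Two-sample-logo-style analysis: per window offset (excluding the central
#' lysine, which is `K` by construction) and per residue, the frequency in
#' positive fragments, the frequency in negatives, their difference, and a
#' two-sided two-proportion z-test p-value. Within each class the frequencies
#' at a given offset sum to one.
#'
#' @param pos,neg Fragment tibbles or character vectors of equal-length
#'   fragments for the positive and negative classes.
#' @param residues Residue alphabet to tabulate (default the 21 vocabulary
#'   symbols).
#' @return A tibble with columns `offset` (-n..n, 0 excluded), `residue`,
#'   `freq_pos`, `freq_neg`, `diff`, `p_value`, of class `kd_enrichment`.
#' @export
residue_enrichment <- function(pos, neg, residues = names(aa_vocab())) {
  pos <- if (is.data.frame(pos)) pos$fragment else pos
  neg <- if (is.data.frame(neg)) neg$fragment else neg
  if (length(pos) == 0 || length(neg) == 0) abort("both classes must be non-empty")
  L <- unique(nchar(c(pos, neg)))
  if (length(L) != 1) abort("fragments must share a single length")
  if (L %% 2 == 0) abort("window length must be odd")
  n <- (L - 1L) / 2L
  cp <- matrix(unlist(strsplit(pos, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  cn <- matrix(unlist(strsplit(neg, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  offs <- setdiff(-n:n, 0L)
  out <- purrr::map_dfr(offs, function(o) {
    col <- o + n + 1L
    fp <- unname(vapply(residues, function(r) mean(cp[, col] == r), numeric(1)))
    fn_ <- unname(vapply(residues, function(r) mean(cn[, col] == r), numeric(1)))
    xp <- fp * length(pos)
    xn <- fn_ * length(neg)
    pool <- (xp + xn) / (length(pos) + length(neg))
    se <- sqrt(pool * (1 - pool) * (1 / length(pos) + 1 / length(neg)))
    z <- ifelse(se > 0, (fp - fn_) / se, 0)
    tibble(offset = o, residue = residues, freq_pos = fp, freq_neg = fn_,
           diff = fp - fn_, p_value = 2 * pnorm(-abs(z)))
  })
  class(out) <- c("kd_enrichment", class(out))
  out
}

#' Significant enrichment cells
#'
#' @param enrichment A [residue_enrichment()] table.
#' @param threshold Significance level (default 0.05).
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`, matching a per-cell logo rendering; use `"BH"` for a
#'   table-wide claim).
#' @return The significant rows, ordered by `|diff|` descending.
#' @export
enrichment_hits <- function(enrichment, threshold = 0.05, adjust = "none") {
  p <- stats::p.adjust(enrichment$p_value, method = adjust)
  hits <- enrichment[p < threshold, , drop = FALSE]
  hits[order(-abs(hits$diff)), , drop = FALSE]
}

#' Text rendering of an enrichment table
#'
#' A compact logo-like console view: for each offset, residues enriched in
#' positives (above the line) and depleted (below), filtered at `threshold`.
#'
#' @inheritParams enrichment_hits
#' @return The input, invisibly.
#' @export
print_enrichment <- function(enrichment, threshold = 0.05) {
  for (o in unique(enrichment$offset)) {
    rows <- enrichment[enrichment$offset == o & enrichment$p_value < threshold, ]
    up <- rows$residue[rows$diff > 0]
    dn <- rows$residue[rows$diff < 0]
    if (length(up) + length(dn) == 0) next
    cat(sprintf("%+3d  over: %-12s under: %s\n", o,
                paste(up, collapse = ""), paste(dn, collapse = "")))
  }
  invisible(enrichment)
}
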