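# fixtures built in code, shared across test files

aa20 <- names(aa_vocab())[1:20]

random_protein <- function(len) paste(sample(aa20, len, TRUE), collapse = "")

random_fragment <- function(len = 33L) {
  paste(sample(c(aa20, "X"), len, TRUE), collapse = "")
}

write_temp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# small specs keep network tests fast; architecture shape is unchanged
tiny_cnn <- function(L = 9L) {
  build_teacher_cnn(embed_dim = 8, filters = 4, input_length = L)
}
tiny_bilstm <- function(L = 9L) {
  build_teacher_bilstm(embed_dim = 8, units = 3, input_length = L)
}
tiny_student <- function(variant = "KD3", L = 9L) {
  build_student(variant, embed_dim = 8, filters = 4, units = 3, input_length = L)
}

# linearly separable toy fragments: positives carry E at the first position
toy_fragments <- function(n_per_class = 40, L = 9L, seed = 1) {
  set.seed(seed)
  pos <- replicate(n_per_class, paste0("E", paste(
    sample(setdiff(aa20, "E"), L - 1L, TRUE), collapse = "")))
  neg <- replicate(n_per_class, paste0("G", paste(
    sample(setdiff(aa20, "E"), L - 1L, TRUE), collapse = "")))
  tibble::tibble(fragment = c(pos, neg),
                 label = rep(c(1L, 0L), each = n_per_class))
}
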