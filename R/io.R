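#' Read and write pipeline tables
#'
#' Plain-text serializations: lexicons and matrices as TSV, token tables
#' as CSV. Matrices are written with a leading `word_id` column.
#'
#' @param x Object to write.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a tibble
#'   (or matrix for `read_ldl_matrix()`).
#' @name ldl_io
NULL

#' @rdname ldl_io
#' @param inventory Optional [phoneme_inventory()] to attach (and
#'   validate against) when reading a lexicon.
#' @export
read_lexicon <- function(path, inventory = default_inventory()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df <- as_tibble(df)
  validate_lexicon(df)
  for (tr in df$transcription) check_transcription(tr, inventory)
  new_ldl_lexicon(df, inventory)
}

#' @rdname ldl_io
#' @export
write_lexicon <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ldl_io
#' @export
write_ldl_matrix <- function(x, path) {
  df <- data.frame(word_id = rownames(x), unclass_matrix(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ldl_io
#' @export
read_ldl_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' @rdname ldl_io
#' @export
write_vector_store <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ldl_io
#' @export
read_vector_store <- function(path) {
  df <- as_tibble(utils::read.delim(path, sep = "\t",
                                    stringsAsFactors = FALSE))
  dims <- grep("^dim_", names(df), value = TRUE)
  if (!"lexome_id" %in% names(df) || length(dims) < 2L) {
    abort("not a vector-store table (need lexome_id and dim_* columns)")
  }
  structure(df, dimension = length(dims),
            class = c("lexome_store", class(df)))
}

#' @rdname ldl_io
#' @export
write_tokens <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ldl_io
#' @export
read_tokens <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
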