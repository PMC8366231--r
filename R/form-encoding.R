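#' Decompose a transcription into overlapping triphones
#'
#' The transcription is padded with one boundary symbol on each side and
#' all length-3 windows at stride 1 are returned, in order. A word of n
#' phones therefore yields exactly n triphones, e.g. `"k{t"` gives
#' `#k{`, `k{t`, `{t#`. The overlapping windows act as proxies for
#' transitions in the articulatory signal.
#'
#' @param transcription Phone string, one character per phone, no
#'   boundary symbols inside.
#' @param inventory Optional [phoneme_inventory()]; when supplied, symbols
#'   outside it raise an error naming the offender.
#' @param boundary Boundary padding symbol (taken from `inventory` when
#'   one is given).
#' @return Character vector of triphones, in word order.
#' @examples
#' to_triphones("k{t")
#' @export
to_triphones <- function(transcription, inventory = NULL, boundary = "#") {
  if (!is.null(inventory)) boundary <- boundary_symbol(inventory)
  phones <- check_transcription(transcription, inventory)
  if (is.null(inventory) && boundary %in% phones) {
    abort(paste0("boundary symbol ", sQuote(boundary),
                 " may not occur inside a transcription"))
  }
  padded <- c(boundary, phones, boundary)
  n <- length(phones)
  vapply(seq_len(n),
         function(i) paste(padded[i:(i + 2L)], collapse = ""),
         character(1))
}

#' Build the binary triphone cue matrix C
#'
#' Rows are words, columns the lexicographically sorted union of all
#' triphones occurring in the lexicon; cell (i, j) is 1 when triphone j
#' occurs in word i's padded transcription and 0 otherwise. Repeated
#' occurrences of a triphone within one word collapse to a single 1
#' (presence/absence coding).
#'
#' @param lexicon An `ldl_lexicon` or any data frame with `word_id` and
#'   `transcription` columns (a `phoneme_inventory` attribute is used for
#'   symbol validation when present).
#' @return A binary numeric matrix of class `ldl_cue_matrix` with word ids
#'   as row names and triphones as column names.
#' @examples
#' lex <- tibble::tibble(word_id = "cat", transcription = "k{t",
#'                       base_id = NA, category = NA)
#' build_cue_matrix(lex)
#' @export
build_cue_matrix <- function(lexicon) {
  if (anyDuplicated(lexicon$word_id)) {
    abort("duplicate word_id in lexicon")
  }
  inventory <- attr(lexicon, "inventory")
  tri <- lapply(lexicon$transcription, to_triphones, inventory = inventory)
  cues <- sort(unique(unlist(tri)))
  mat <- matrix(0, nrow = nrow(lexicon), ncol = length(cues),
                dimnames = list(lexicon$word_id, cues))
  for (i in seq_along(tri)) {
    mat[i, unique(tri[[i]])] <- 1
  }
  structure(mat, class = c("ldl_cue_matrix", class(mat)))
}

#' @export
tidy.ldl_cue_matrix <- function(x, ...) {
  idx <- which(x == 1, arr.ind = TRUE)
  tibble(word_id = rownames(x)[idx[, 1]],
         cue = colnames(x)[idx[, 2]],
         value = 1) |>
    dplyr::arrange(.data$word_id, .data$cue)
}
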