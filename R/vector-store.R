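#' Generate a synthetic lexome vector store
#'
#' Every word in the lexicon (content lexomes) and every affix category
#' (function lexomes) receives a real-valued semantic vector of length
#' `dimension`. Base-word vectors are i.i.d. normal per dimension with
#' standard deviation `scale` (default `1/sqrt(dimension)`, giving
#' unit-order vector norms). Each function lexome is an independent shift
#' vector with per-dimension sd `shift_scale * scale` (per affix). A
#' derived word's content vector is
#' `v(base) + v(category) + noise`, where the idiosyncratic noise is
#' i.i.d. normal with per-dimension sd `transparency_sd * scale`:
#' `transparency_sd = 0` yields fully transparent derivatives whose
#' meaning is exactly base plus category, while larger values make the
#' derivative increasingly idiosyncratic.
#'
#' @param lexicon An `ldl_lexicon` (see [generate_lexicon()]).
#' @param dimension Number of semantic dimensions D (>= 2).
#' @param transparency_sd Idiosyncratic-noise sd, relative to `scale`
#'   (>= 0).
#' @param scale Per-dimension sd of content vectors.
#' @param seed Integer seed.
#' @return A tibble of class `lexome_store` with columns `lexome_id`,
#'   `kind` (`"content"` or `"function"`), and `dim_1 ... dim_D`.
#' @examples
#' lex <- generate_lexicon(10, default_affixes(3), seed = 1)
#' store <- generate_vector_store(lex, dimension = 20, seed = 1)
#' @export
generate_vector_store <- function(lexicon, dimension = 100L,
                                  transparency_sd = 0.5,
                                  scale = 1 / sqrt(dimension),
                                  seed = 1L) {
  validate_lexicon(lexicon)
  if (dimension < 2L) abort("`dimension` must be >= 2")
  if (transparency_sd < 0) abort("`transparency_sd` must be >= 0")
  affixes <- attr(lexicon, "affixes")
  set.seed(as.integer(seed))

  categories <- unique(lexicon$category[!is.na(lexicon$category)])
  shift_scale <- rep(1, length(categories))
  names(shift_scale) <- categories
  if (!is.null(affixes)) {
    idx <- match(categories, affixes$category)
    shift_scale[!is.na(idx)] <- affixes$shift_scale[idx[!is.na(idx)]]
  }

  bases <- lexicon$word_id[is.na(lexicon$category)]
  derived <- lexicon[!is.na(lexicon$category), ]

  draw <- function(n, sd) matrix(rnorm(n * dimension, sd = sd),
                                 nrow = n, ncol = dimension)

  base_mat <- draw(length(bases), scale)
  rownames(base_mat) <- bases
  fun_mat <- draw(length(categories), scale)
  fun_mat <- fun_mat * shift_scale[categories]
  rownames(fun_mat) <- categories

  noise <- draw(nrow(derived), transparency_sd * scale)
  der_mat <- base_mat[derived$base_id, , drop = FALSE] +
    fun_mat[derived$category, , drop = FALSE] + noise
  rownames(der_mat) <- derived$word_id

  mat <- rbind(base_mat, der_mat, fun_mat)
  kind <- c(rep("content", length(bases) + nrow(derived)),
            rep("function", length(categories)))
  out <- as_tibble(mat, .name_repair = ~ paste0("dim_", seq_len(dimension)))
  out <- dplyr::bind_cols(tibble(lexome_id = rownames(mat), kind = kind), out)
  structure(out, dimension = as.integer(dimension),
            class = c("lexome_store", class(out)))
}

#' Extract the vector matrix from a lexome store
#'
#' @param store A `lexome_store` tibble (or any data frame with a
#'   `lexome_id` column followed by numeric dimension columns).
#' @return A numeric matrix with lexome ids as row names.
#' @export
store_matrix <- function(store) {
  if (!"lexome_id" %in% names(store)) abort("store lacks a `lexome_id` column")
  dims <- grep("^dim_", names(store), value = TRUE)
  if (length(dims) < 2L) abort("store must have at least 2 dimension columns")
  mat <- as.matrix(store[, dims])
  rownames(mat) <- store$lexome_id
  mat
}

#' Look up a lexome vector
#'
#' @inheritParams store_matrix
#' @param lexome_id Lexome identifier(s).
#' @param context Optional string naming the caller (used in error
#'   messages).
#' @return A numeric matrix, one row per requested lexome.
#' @export
store_vectors <- function(store, lexome_id, context = NULL) {
  mat <- store_matrix(store)
  missing <- setdiff(lexome_id, rownames(mat))
  if (length(missing)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    abort(paste0("missing lexome vector(s)", where, ": ",
                 paste(missing, collapse = ", ")))
  }
  mat[lexome_id, , drop = FALSE]
}
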