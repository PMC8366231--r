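#' Build the semantic matrix S under a network architecture
#'
#' Three architectures are supported. In all of them a monomorphemic
#' word's row is its own content-lexome vector. For a derived word:
#'
#' * `"idiosyncratic"` -- the derivative's own content vector only; the
#'   network receives no information about morphological categories.
#' * `"morphology"` -- the derivative's content vector plus its
#'   category's function vector (idiosyncratic meaning plus shared
#'   categorical meaning).
#' * `"base"` -- the base word's content vector plus the category's
#'   function vector (strictly compositional meaning, no idiosyncrasy).
#'
#' Rows are ordered exactly as the lexicon (and hence as the paired cue
#' matrix). Multi-affix derivatives (a derived word whose base is itself
#' derived) are rejected: their vectors are undefined under these
#' architectures.
#'
#' @param lexicon An `ldl_lexicon`.
#' @param store A `lexome_store` covering every word, every base of a
#'   derived word, and every category label.
#' @param variant One of `"idiosyncratic"`, `"morphology"`, `"base"`.
#' @return A numeric matrix of class `ldl_semantic_matrix` (words x
#'   dimensions) with word ids as row names.
#' @export
build_semantic_matrix <- function(lexicon, store,
                                  variant = c("idiosyncratic", "morphology",
                                              "base")) {
  variant <- match.arg(variant)
  validate_lexicon(lexicon)
  derived <- !is.na(lexicon$category)
  base_of_derived <- lexicon$base_id[derived]
  complex_base <- base_of_derived %in% lexicon$word_id[derived]
  if (any(complex_base)) {
    abort(paste0("multi-affix derivatives are not supported (base itself ",
                 "derived): ",
                 paste(lexicon$word_id[derived][complex_base], collapse = ", ")))
  }

  ctx <- paste0("variant = ", variant)
  own <- store_vectors(store, lexicon$word_id, context = ctx)
  out <- own
  if (any(derived) && variant != "idiosyncratic") {
    fun <- store_vectors(store, lexicon$category[derived], context = ctx)
    if (variant == "morphology") {
      out[derived, ] <- own[derived, , drop = FALSE] + fun
    } else {
      base_vec <- store_vectors(store, lexicon$base_id[derived], context = ctx)
      out[derived, ] <- base_vec + fun
    }
  }
  rownames(out) <- lexicon$word_id
  if (!all(is.finite(out))) abort("semantic matrix contains non-finite values")
  structure(out, variant = variant,
            class = c("ldl_semantic_matrix", class(out)))
}

#' @export
tidy.ldl_semantic_matrix <- function(x, ...) {
  out <- as_tibble(unclass(x), .name_repair = "minimal")
  dplyr::bind_cols(tibble(word_id = rownames(x)), out)
}

#' Mean row-wise Pearson correlation between two matrices
#'
#' Correlates the corresponding rows of two word-aligned matrices (for
#' example the predicted semantic matrices of two network variants) and
#' averages over words. Words whose row is constant in either matrix have
#' no defined correlation; they are excluded and their count attached as
#' the `"dropped"` attribute.
#'
#' @param a,b Numeric matrices with identical row names (any row order)
#'   and at least 3 columns.
#' @return Mean correlation (scalar), with attribute `dropped`.
#' @export
mean_row_correlation <- function(a, b) {
  if (is.null(rownames(a)) || is.null(rownames(b)) ||
      !setequal(rownames(a), rownames(b)) || nrow(a) != nrow(b)) {
    abort("`a` and `b` must have identical row (word) sets")
  }
  if (ncol(a) < 3L || ncol(a) != ncol(b)) {
    abort("matrices must share >= 3 columns")
  }
  b <- b[rownames(a), , drop = FALSE]
  sda <- apply(a, 1, sd)
  sdb <- apply(b, 1, sd)
  ok <- sda > 0 & sdb > 0
  r <- vapply(which(ok), function(i) cor(a[i, ], b[i, ]), numeric(1))
  structure(mean(r), dropped = sum(!ok))
}
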