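#' Moore--Penrose pseudoinverse via singular value decomposition
#'
#' Singular values below `eps * max(dim(x)) * max(d)` are treated as zero,
#' the standard relative cutoff for numerical rank determination.
#'
#' @param x Numeric matrix with finite entries.
#' @param eps Relative tolerance (defaults to machine precision).
#' @return The pseudoinverse of `x`.
#' @export
ldl_pinv <- function(x, eps = .Machine$double.eps) {
  if (!all(is.finite(x))) abort("matrix contains non-finite entries")
  s <- svd(x)
  tol <- eps * max(dim(x)) * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Solve a linear form-meaning mapping
#'
#' Returns the least-squares transformation `B = X^+ Y` minimizing the
#' Frobenius error ||XB - Y||. With `X = C` (cues) and `Y = S` (semantics)
#' this is the comprehension mapping F; with `X = S` and `Y = C` it is the
#' production mapping G.
#'
#' @param x,y Numeric matrices with equal row counts (one row per word).
#' @return The transformation matrix, `ncol(x)` x `ncol(y)`.
#' @export
solve_mapping <- function(x, y) {
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have equal row counts")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("mapping inputs contain non-finite entries")
  }
  structure(ldl_pinv(x) %*% y, dimnames = list(colnames(x), colnames(y)))
}

#' Fit a linear discriminative learning network
#'
#' Solves the comprehension mapping F (cues to semantics, `CF = S`) and
#' the production mapping G (semantics to cues, `SG = C`) by the
#' Moore--Penrose generalized inverse, forms the predicted matrices
#' `S_hat = CF` and `C_hat = SG`, and evaluates comprehension and
#' production accuracy by correlating each predicted row vector with all
#' target rows.
#'
#' @param cue Binary cue matrix (see [build_cue_matrix()]).
#' @param semantic Semantic matrix with identical row names in the same
#'   order (see [build_semantic_matrix()]).
#' @return An object of class `ldl_network`: a list with elements `C`,
#'   `S`, `F`, `G`, `S_hat`, `C_hat`, `comprehension` and `production`
#'   (accuracy reports, see [evaluate_accuracy()]), and `variant`.
#' @examples
#' lex <- generate_lexicon(15, default_affixes(4), seed = 2)
#' store <- generate_vector_store(lex, dimension = 20, seed = 2)
#' net <- ldl_network(build_cue_matrix(lex),
#'                    build_semantic_matrix(lex, store, "morphology"))
#' glance(net)
#' @export
ldl_network <- function(cue, semantic) {
  if (!identical(rownames(cue), rownames(semantic))) {
    abort("cue and semantic matrices must share identical row order")
  }
  f <- solve_mapping(cue, semantic)
  g <- solve_mapping(semantic, cue)
  s_hat <- cue %*% f
  c_hat <- semantic %*% g
  structure(
    list(C = unclass_matrix(cue), S = unclass_matrix(semantic),
         F = f, G = g, S_hat = s_hat, C_hat = c_hat,
         comprehension = evaluate_accuracy(s_hat, unclass_matrix(semantic)),
         production = evaluate_accuracy(c_hat, unclass_matrix(cue)),
         variant = attr(semantic, "variant") %||% NA_character_),
    class = "ldl_network"
  )
}

unclass_matrix <- function(x) {
  attr(x, "variant") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' @export
print.ldl_network <- function(x, ...) {
  cat("Linear discriminative learning network",
      if (!is.na(x$variant)) paste0("(", x$variant, " variant)"), "\n")
  cat(sprintf("  %d words, %d cues, %d semantic dimensions\n",
              nrow(x$C), ncol(x$C), ncol(x$S)))
  cat(sprintf("  comprehension accuracy: %.3f (ties: %d)\n",
              x$comprehension$accuracy, x$comprehension$ties))
  cat(sprintf("  production accuracy:    %.3f (ties: %d)\n",
              x$production$accuracy, x$production$ties))
  invisible(x)
}

#' @export
glance.ldl_network <- function(x, ...) {
  tibble(variant = x$variant,
         n_words = nrow(x$C),
         n_cues = ncol(x$C),
         n_dimensions = ncol(x$S),
         comprehension_accuracy = x$comprehension$accuracy,
         production_accuracy = x$production$accuracy)
}

#' @export
tidy.ldl_network <- function(x, ...) {
  dplyr::inner_join(
    dplyr::rename(x$comprehension$words, comprehension_rank = "rank",
                  comprehension_correct = "correct",
                  comprehension_tie = "tie"),
    dplyr::rename(x$production$words, production_rank = "rank",
                  production_correct = "correct",
                  production_tie = "tie"),
    by = "word_id"
  )
}

#' Accuracy of predicted vectors against their targets
#'
#' For every word the predicted row vector is Pearson-correlated with all
#' target row vectors; the word is counted correct when its own target
#' attains the strictly maximal correlation. Ties for the maximum are
#' counted and scored incorrect. Words with a constant (zero-variance)
#' predicted or target row are excluded and counted in `excluded`.
#'
#' @param predicted,targets Row-aligned numeric matrices (>= 2 rows).
#' @param tol Tolerance for calling two correlations tied.
#' @return List with `accuracy`, `ties`, `excluded`, and a per-word tibble
#'   `words` (`word_id`, `rank` of own target, `correct`, `tie`).
#' @export
evaluate_accuracy <- function(predicted, targets, tol = 1e-12) {
  if (nrow(predicted) < 2L || !identical(dim(predicted), dim(targets))) {
    abort("`predicted` and `targets` must be equal-shaped with >= 2 rows")
  }
  ids <- rownames(predicted) %||% as.character(seq_len(nrow(predicted)))
  ok <- apply(predicted, 1, sd) > 0 & apply(targets, 1, sd) > 0
  excluded <- sum(!ok)
  p <- predicted[ok, , drop = FALSE]
  t_ <- targets[ok, , drop = FALSE]
  # r[i, j] = cor(predicted row i, target row j)
  r <- cor(t(p), t(t_))
  n <- nrow(p)
  own <- diag(r)
  rank_own <- integer(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    rank_own[i] <- 1L + sum(r[i, ] > own[i] + tol) # others strictly better
    tie[i] <- any(abs(r[i, -i] - own[i]) <= tol)
  }
  correct <- rank_own == 1L & !tie
  list(
    accuracy = mean(correct),
    ties = sum(tie),
    excluded = excluded,
    words = tibble(word_id = ids[ok], rank = rank_own,
                   correct = correct, tie = tie)
  )
}
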