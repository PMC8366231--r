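#' Articulatory path of a word
#'
#' A word's articulatory path is its own ordered triphone sequence; each
#' triphone is a node, and consecutive nodes overlap in two symbols. The
#' path must be expressible in the network's cue inventory.
#'
#' @param transcription Phone string.
#' @param cue_inventory Character vector of known triphone cues (e.g. the
#'   column names of the cue matrix).
#' @param inventory Optional [phoneme_inventory()] for symbol validation.
#' @return Character vector of triphone nodes, in order.
#' @export
word_path <- function(transcription, cue_inventory, inventory = NULL) {
  path <- to_triphones(transcription, inventory = inventory)
  missing <- setdiff(path, cue_inventory)
  if (length(missing)) {
    abort(paste0("cue(s) missing from inventory for ", sQuote(transcription),
                 ": ", paste(missing, collapse = ", ")))
  }
  path
}

#' Semantic support for each node of an articulatory path
#'
#' Each node competes against all cues in the inventory that share its
#' two-symbol left context (its incoming transition). The support of a
#' node is its (negative-clamped) predicted cue activation divided by the
#' summed activations of its competitor set, i.e. the probability of this
#' triphone being selected against all the other possible triphones;
#' supports therefore lie in [0, 1], with maximum 1. When no competitor
#' (including the node itself) has positive activation the support is 0.
#'
#' @param path Character vector of triphone nodes (see [word_path()]).
#' @param c_hat_row Named numeric vector: the word's row of the predicted
#'   cue matrix `C_hat`, indexed by cue.
#' @param cue_inventory Cue names; defaults to `names(c_hat_row)`.
#' @return Numeric vector of supports, one per node.
#' @export
node_supports <- function(path, c_hat_row,
                          cue_inventory = names(c_hat_row)) {
  if (is.null(names(c_hat_row))) names(c_hat_row) <- cue_inventory
  act <- pmax(c_hat_row[cue_inventory], 0)
  left <- substr(cue_inventory, 1L, 2L)
  denom_by_context <- tapply(act, left, sum)
  vapply(path, function(node) {
    d <- denom_by_context[[substr(node, 1L, 2L)]]
    if (is.null(d) || d <= 0) return(0)
    unname(pmax(c_hat_row[[node]], 0) / d)
  }, numeric(1))
}

#' Path-based support summaries
#'
#' `path_sum()` is the summed semantic support a word's predicted
#' articulatory path receives: with five perfectly supported transitions
#' it takes the value 5. `mean_word_support()` divides the path sum by
#' path length, so that equally well-supported words of different lengths
#' receive identical values; the divisor defaults to the number of path
#' nodes, with `"transitions"` (nodes minus one) available as an
#' alternative convention. `path_entropy()` is the Shannon entropy (bits)
#' of the supports normalized to probabilities; a path whose support is
#' all concentrated on one node has entropy 0, and n equally supported
#' nodes give log2(n).
#'
#' @param supports Numeric vector of node supports in [0, 1].
#' @return A scalar; `path_entropy()` returns `NA` (flagged missing) when
#'   the summed support is 0.
#' @export
path_sum <- function(supports) {
  if (length(supports) == 0L) abort("empty path")
  sum(supports)
}

#' @rdname path_sum
#' @param path Character vector of path nodes.
#' @param divisor `"nodes"` (default) or `"transitions"`.
#' @export
mean_word_support <- function(supports, path = NULL,
                              divisor = c("nodes", "transitions")) {
  divisor <- match.arg(divisor)
  n_nodes <- if (is.null(path)) length(supports) else length(path)
  if (n_nodes == 0L) abort("empty path")
  d <- if (divisor == "nodes") n_nodes else max(n_nodes - 1L, 1L)
  path_sum(supports) / d
}

#' @rdname path_sum
#' @export
path_entropy <- function(supports) {
  if (length(supports) == 0L) abort("empty path")
  total <- sum(supports)
  if (total <= 0) return(NA_real_)
  p <- supports / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Semantic vector measures
#'
#' `semantic_vector_length()` is the L1 (city-block) norm of a predicted
#' semantic vector, a measure of semantic activation diversity.
#' `target_correlation()` is the Pearson correlation between a word's
#' predicted and target semantic vectors, a per-word measure of network
#' accuracy.
#'
#' @param s_hat_row Numeric vector (a row of `S_hat`).
#' @param s_row Numeric vector (the matching row of `S`).
#' @return A scalar; `target_correlation()` returns `NA` when either
#'   vector has zero variance.
#' @export
semantic_vector_length <- function(s_hat_row) {
  if (!all(is.finite(s_hat_row))) abort("non-finite semantic vector")
  sum(abs(s_hat_row))
}

#' @rdname semantic_vector_length
#' @export
target_correlation <- function(s_hat_row, s_row) {
  if (length(s_hat_row) < 3L || length(s_hat_row) != length(s_row)) {
    abort("vectors must have equal length >= 3")
  }
  if (sd(s_hat_row) == 0 || sd(s_row) == 0) return(NA_real_)
  cor(s_hat_row, s_row)
}

#' Semantic density: mean correlation with the top-k neighbors
#'
#' Correlates a word's predicted semantic vector with the semantic
#' vectors of all other words and averages the k largest correlations.
#' High density marks a word living in a tight semantic neighborhood
#' (a transparency proxy); low density marks an idiosyncratic word.
#'
#' @param word_id Word to score.
#' @param s_hat Predicted semantic matrix (word rows).
#' @param k Number of neighbors (default 8).
#' @param neighbors Matrix in which neighbor vectors live; defaults to
#'   `s_hat` itself (predicted space), but the target matrix `S` may be
#'   supplied instead.
#' @return Mean of the k largest neighbor correlations.
#' @export
semantic_density <- function(word_id, s_hat, k = 8L, neighbors = s_hat) {
  if (nrow(neighbors) < k + 1L) {
    abort(paste0("need at least k + 1 = ", k + 1L, " words for density"))
  }
  r <- neighbor_correlations(s_hat, neighbors)[word_id, ]
  mean(sort(r[setdiff(names(r), word_id)], decreasing = TRUE)[seq_len(k)])
}

neighbor_correlations <- function(s_hat, neighbors = s_hat) {
  r <- cor(t(s_hat), t(neighbors))
  dimnames(r) <- list(rownames(s_hat), rownames(neighbors))
  r
}

#' Per-word LDL measures
#'
#' Computes the five duration predictors for every word of a fitted
#' network: `mean_word_support` (with the underlying `path_sum`),
#' `path_entropies`, `semantic_vector_length`, `semantic_density`, and
#' `target_correlation`.
#'
#' @param network An [ldl_network()].
#' @param k Neighborhood size for semantic density.
#' @param divisor Path-length divisor for mean word support, `"nodes"`
#'   (default) or `"transitions"`.
#' @param density_space `"predicted"` (default: neighbors in `S_hat`) or
#'   `"target"` (neighbors in `S`).
#' @param lexicon The lexicon the network was built from; the words'
#'   articulatory paths are rebuilt from its transcriptions.
#' @return A tibble with one row per word.
#' @export
ldl_measures <- function(network, lexicon = NULL, k = 8L,
                         divisor = c("nodes", "transitions"),
                         density_space = c("predicted", "target")) {
  divisor <- match.arg(divisor)
  density_space <- match.arg(density_space)
  cues <- colnames(network$C)
  ids <- rownames(network$C)
  if (is.null(lexicon)) {
    abort("`lexicon` is required to reconstruct the words' paths")
  }
  validate_lexicon(lexicon)
  lexicon <- lexicon[match(ids, lexicon$word_id), ]
  if (anyNA(lexicon$word_id)) {
    abort("lexicon does not cover all network words")
  }

  neighbors <- if (density_space == "predicted") network$S_hat else network$S
  r_nb <- neighbor_correlations(network$S_hat, neighbors)
  if (nrow(neighbors) < k + 1L) {
    abort(paste0("need at least k + 1 = ", k + 1L, " words for density"))
  }

  rows <- purrr::map2_dfr(ids, lexicon$transcription, function(id, trans) {
    path <- word_path(trans, cues,
                      inventory = attr(lexicon, "inventory"))
    supports <- node_supports(path, network$C_hat[id, ], cues)
    nb <- r_nb[id, ]
    tibble(
      word_id = id,
      path_sum = path_sum(supports),
      mean_word_support = mean_word_support(supports, path, divisor),
      path_entropies = path_entropy(supports),
      semantic_vector_length = semantic_vector_length(network$S_hat[id, ]),
      semantic_density = mean(sort(nb[setdiff(names(nb), id)],
                                   decreasing = TRUE)[seq_len(k)]),
      target_correlation = target_correlation(network$S_hat[id, ],
                                              network$S[id, ])
    )
  })
  rows
}

#' Ranked semantic neighbors and category type diversity
#'
#' For each word, the k nearest semantic neighbors (by correlation of
#' predicted vectors) are listed; per morphological category, the number
#' of unique word types appearing in any member's top-k list summarizes
#' how diverse (or collapsed) the category's neighborhoods are.
#'
#' @inheritParams ldl_measures
#' @return A list of class `ldl_neighbor_report` with tibbles `neighbors`
#'   (`word_id`, `rank`, `neighbor_id`, `correlation`) and `diversity`
#'   (`category`, `n_members`, `n_unique_neighbors`).
#' @export
neighbor_report <- function(network, lexicon, k = 8L,
                            density_space = c("predicted", "target")) {
  density_space <- match.arg(density_space)
  validate_lexicon(lexicon)
  neighbors_mat <- if (density_space == "predicted") network$S_hat else network$S
  if (nrow(neighbors_mat) < k + 1L) {
    abort(paste0("need at least k + 1 = ", k + 1L, " words"))
  }
  r <- neighbor_correlations(network$S_hat, neighbors_mat)
  nb <- purrr::map_dfr(rownames(r), function(id) {
    others <- sort(r[id, setdiff(colnames(r), id)], decreasing = TRUE)
    tibble(word_id = id, rank = seq_len(k),
           neighbor_id = names(others)[seq_len(k)],
           correlation = unname(others[seq_len(k)]))
  })
  cats <- lexicon[!is.na(lexicon$category), c("word_id", "category")]
  diversity <- nb |>
    dplyr::inner_join(cats, by = "word_id") |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_members = dplyr::n_distinct(.data$word_id),
                     n_unique_neighbors = dplyr::n_distinct(.data$neighbor_id),
                     .groups = "drop")
  structure(list(neighbors = nb, diversity = diversity, k = k),
            class = "ldl_neighbor_report")
}

#' @export
print.ldl_neighbor_report <- function(x, ...) {
  cat("Top-", x$k, " semantic neighbor report\n", sep = "")
  print(x$diversity)
  invisible(x)
}

#' Compare a measure's distribution between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test; exact for small
#' samples without ties, normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param a,b Numeric vectors of measure values for the two groups.
#' @return The two-sided p-value.
#' @examples
#' compare_distributions(c(1, 2, 3), c(10, 11, 12))
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("both groups must be non-empty")
  }
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))$p.value
}
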