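# Small in-code fixtures shared across test files.

tiny_lexicon <- function() {
  # cat / happiness layout: one base, one NESS derivative, one extra base
  lex <- tibble::tibble(
    word_id = c("cat", "happy", "happiness"),
    transcription = c("k{t", "h{pI", "h{pInIs"),
    base_id = c(NA, NA, "happy"),
    category = c(NA, NA, "NESS")
  )
  structure(lex, inventory = default_inventory(),
            class = c("ldl_lexicon", class(lex)))
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- ldl_study(n_bases = 30, affixes = default_affixes(10L),
                          dimension = 40L, seed = 2)
    }
    cache
  }
})

# brute-force relative-importance oracle: average incremental R2 over all
# p! orderings of predictor entry
lmg_oracle <- function(data, response, preds) {
  r2_of <- function(members) {
    if (!length(members)) return(0)
    summary(lm(stats::reformulate(members, response), data = data))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  shares <- stats::setNames(numeric(length(preds)), preds)
  orderings <- perms(preds)
  for (ord in orderings) {
    for (j in seq_along(ord)) {
      shares[ord[j]] <- shares[ord[j]] +
        (r2_of(ord[1:j]) - r2_of(ord[seq_len(j - 1)]))
    }
  }
  shares / length(orderings)
}

# independent least-squares oracle: min-norm solution through the dual
# normal equations (the epsilon -> 0 limit of ridge regression)
ridge_limit_oracle <- function(x, y) {
  if (nrow(x) <= ncol(x)) {
    t(x) %*% solve(x %*% t(x), y)
  } else {
    solve(t(x) %*% x, t(x) %*% y)
  }
}
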