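#' Relative importance of predictors (lmg decomposition)
#'
#' Decomposes the model's explained variance among its predictors by the
#' lmg metric: each predictor's share is its incremental R^2 when added
#' to a subset of the other predictors, averaged over all orderings of
#' entry. Shares are non-negative in expectation-free form and sum
#' exactly to the full model's R^2 (standard models). For mixed models
#' the decomposition is computed on the marginal (fixed-effect) R^2 of
#' refitted submodels, so shares sum to the full model's marginal R^2.
#'
#' Exact enumeration over all 2^p subsets is used, so at most 10
#' predictors are supported.
#'
#' @param x A `duration_fit` (standard or mixed) or a plain `lm`.
#' @return A tibble of class `ldl_relimp` with columns `term` and `lmg`,
#'   plus attribute `total` (the full model's [adjusted-free] R^2, i.e.
#'   plain R^2 for standard fits and marginal R^2 for mixed fits).
#' @examples
#' d <- data.frame(y = rnorm(40), a = rnorm(40), b = rnorm(40))
#' lmg_importance(lm(y ~ a + b, data = d))
#' @export
lmg_importance <- function(x) {
  if (inherits(x, "lm") && !inherits(x, "duration_fit")) {
    x <- new_duration_fit(x, "standard", as_tibble(model.frame(x)))
  }
  stopifnot(inherits(x, "duration_fit"))
  f <- fit_formula(x)
  preds <- labels(terms(f))
  p <- length(preds)
  if (p == 0L) abort("model has no predictors")
  if (p > 10L) abort("more than 10 predictors; lmg enumeration refused, use a subset")
  response <- all.vars(f)[1]

  subset_r2 <- subset_r2_fun(x, response, preds)
  # R^2 for every subset, indexed by a bitmask over preds
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1L)) {
    members <- preds[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L]
    r2[mask + 1L] <- subset_r2(members)
  }

  # lmg_j = sum over subsets S not containing j of
  #         |S|! (p - |S| - 1)! / p! * (R2(S + j) - R2(S))
  lw <- lgamma(seq_len(p + 1)) # log factorials 0! .. p!
  weight <- function(s) exp(lw[s + 1L] + lw[p - s] - lw[p + 1L])
  shares <- setNames(numeric(p), preds)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^p - 1L)) {
      if (bitwAnd(mask, bit_j) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      shares[j] <- shares[j] +
        weight(s) * (r2[bitwOr(mask, bit_j) + 1L] - r2[mask + 1L])
    }
  }
  out <- tibble(term = preds, lmg = unname(shares))
  attr(out, "total") <- r2[2^p]
  class(out) <- c("ldl_relimp", class(out))
  out
}

subset_r2_fun <- function(x, response, preds) {
  if (x$kind == "standard") {
    data <- x$data
    y <- data[[response]]
    tss <- sum((y - mean(y))^2)
    function(members) {
      if (!length(members)) return(0)
      fit <- lm(reformulate(members, response = response), data = data)
      1 - sum(resid(fit)^2) / tss
    }
  } else {
    grp <- names(lme4::ranef(x$fit))[1]
    data <- x$data
    function(members) {
      rhs <- c(if (length(members)) members else "1",
               sprintf("(1 | %s)", grp))
      f <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
      unname(r2_mixed(lmerTest::lmer(f, data = data, REML = TRUE))["marginal"])
    }
  }
}
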