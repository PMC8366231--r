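#' Generate token-level durations from a known linear model
#'
#' For every word in `covariates`, a token count is drawn from a
#' zero-truncated geometric distribution (reproducing a realistic mix of
#' hapax and repeated types), a per-token speech rate is drawn from a
#' normal distribution, and the observed duration is
#'
#' `intercept + sum(coefficients * predictors) + residual noise`,
#'
#' where the predictor set is named by `coefficients` (word-level columns
#' of `covariates`, plus the token-level `speech_rate`). Non-positive
#' durations are physically impossible and are rejected and re-drawn; the
#' number of re-draws is recorded. The generating parameters are attached
#' as the `ground_truth` attribute so recovery can be tested.
#'
#' @param covariates Data frame with one row per word: `word_id` plus a
#'   column for every word-level predictor named in `coefficients`.
#' @param coefficients Named numeric vector of generating coefficients;
#'   the name `speech_rate` refers to the token-level rate draw, all
#'   other names must be columns of `covariates`.
#' @param intercept Intercept (ms).
#' @param residual_sd Gaussian residual sd (ms), >= 0.
#' @param tokens_per_type_prob Success probability of the zero-truncated
#'   geometric token-count distribution (mean count = 1/prob).
#' @param speech_rate_mean,speech_rate_sd Speech-rate distribution
#'   (syllables/second).
#' @param seed Integer seed.
#' @return A tibble with columns `token_id`, `word_id`, `speech_rate`,
#'   `observed_duration`, plus all word-level covariate columns;
#'   attributes `ground_truth` (list of generating parameters) and
#'   `n_redraws`.
#' @export
generate_tokens <- function(covariates, coefficients,
                            intercept = 60,
                            residual_sd = 20,
                            tokens_per_type_prob = 0.4,
                            speech_rate_mean = 5,
                            speech_rate_sd = 1,
                            seed = 1L) {
  if (!"word_id" %in% names(covariates)) {
    abort("`covariates` must have a `word_id` column")
  }
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("`coefficients` must be a fully named numeric vector")
  }
  word_level <- setdiff(names(coefficients), "speech_rate")
  missing <- setdiff(word_level, names(covariates))
  if (length(missing)) {
    abort(paste0("missing predictor column(s) in `covariates`: ",
                 paste(missing, collapse = ", ")))
  }
  if (residual_sd < 0) abort("`residual_sd` must be >= 0")
  if (speech_rate_sd < 0) abort("`speech_rate_sd` must be >= 0")
  set.seed(as.integer(seed))

  n_words <- nrow(covariates)
  counts <- 1L + rgeom(n_words, prob = tokens_per_type_prob)
  tokens <- covariates[rep(seq_len(n_words), counts), , drop = FALSE]
  n <- nrow(tokens)
  tokens <- as_tibble(tokens)
  tokens$speech_rate <- rnorm(n, speech_rate_mean, speech_rate_sd)

  xb <- rep(intercept, n)
  for (nm in word_level) xb <- xb + coefficients[[nm]] * tokens[[nm]]
  if ("speech_rate" %in% names(coefficients)) {
    xb <- xb + coefficients[["speech_rate"]] * tokens$speech_rate
  }

  dur <- xb + rnorm(n, 0, residual_sd)
  n_redraws <- 0L
  bad <- which(dur <= 0)
  iter <- 0L
  while (length(bad)) {
    iter <- iter + 1L
    if (iter > 1000L) {
      abort("could not draw positive durations; check generating parameters")
    }
    n_redraws <- n_redraws + length(bad)
    dur[bad] <- xb[bad] + rnorm(length(bad), 0, residual_sd)
    bad <- bad[dur[bad] <= 0]
  }

  out <- dplyr::bind_cols(
    tibble(token_id = sprintf("t%05d", seq_len(n))),
    tokens[, c("word_id", setdiff(names(tokens), c("word_id", "token_id")))]
  )
  out$observed_duration <- dur
  attr(out, "ground_truth") <- list(
    intercept = intercept, coefficients = coefficients,
    residual_sd = residual_sd, tokens_per_type_prob = tokens_per_type_prob,
    speech_rate_mean = speech_rate_mean, speech_rate_sd = speech_rate_sd
  )
  attr(out, "n_redraws") <- n_redraws
  out
}
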