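#' Baseline durations from segment means
#'
#' A word's baseline duration is the sum of the corpus-mean durations of
#' its segments: the duration expected from segmental makeup alone.
#'
#' @param lexicon Data frame with `word_id` and `transcription` columns.
#' @param segment_table Tibble with `phone` and `mean_duration` columns
#'   covering every phone used (see [generate_segment_table()]).
#' @return The lexicon with a `baseline_duration` column (ms) appended.
#' @export
baseline_duration <- function(lexicon, segment_table) {
  lookup <- setNames(segment_table$mean_duration, segment_table$phone)
  if (any(lookup <= 0)) abort("segment mean durations must be positive")
  bl <- vapply(lexicon$transcription, function(tr) {
    phones <- strsplit(tr, "", fixed = TRUE)[[1]]
    missing <- setdiff(phones, names(lookup))
    if (length(missing)) {
      abort(paste0("no mean duration for phone(s) ",
                   paste(sQuote(missing), collapse = ", "),
                   " in ", sQuote(tr)))
    }
    sum(lookup[phones])
  }, numeric(1), USE.NAMES = FALSE)
  dplyr::mutate(as_tibble(lexicon), baseline_duration = bl)
}

#' Construct the duration-difference response
#'
#' Observed duration is regressed on baseline duration by ordinary least
#' squares across all tokens, and the residuals become the response:
#' the difference between the observed duration and the duration expected
#' from segmental makeup, with the non-constant relationship between the
#' two factored in. By construction the response sums to zero and is
#' uncorrelated with baseline duration.
#'
#' @param tokens Token tibble with `observed_duration` and
#'   `baseline_duration` columns (>= 3 rows, non-constant baseline).
#' @return `tokens` with a `duration_difference` column appended; the
#'   baseline regression's coefficients are attached as attribute
#'   `baseline_fit`.
#' @export
duration_difference <- function(tokens) {
  need <- c("observed_duration", "baseline_duration")
  missing <- setdiff(need, names(tokens))
  if (length(missing)) {
    abort(paste0("token table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(tokens) < 3L) abort("need at least 3 tokens")
  if (sd(tokens$baseline_duration) == 0) {
    abort("baseline duration is constant; residualization undefined")
  }
  fit <- lm(observed_duration ~ baseline_duration, data = tokens)
  out <- dplyr::mutate(as_tibble(tokens),
                       duration_difference = unname(resid(fit)))
  attr(out, "baseline_fit") <- coef(fit)
  out
}

#' Shifted log transform for frequency-type covariates
#'
#' Natural log of (x + 1), mapping 0 to 0; defined for non-negative
#' counts and probabilities-scale covariates.
#'
#' @param x Non-negative numeric vector.
#' @return `log(x + 1)`.
#' @export
log_plus_one <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("`x` must be non-negative")
  log(x + 1)
}
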