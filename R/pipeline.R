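#' Run a full synthetic duration study
#'
#' Generates a lexicon, a lexome vector store, and a segment-duration
#' table; builds the cue matrix and the semantic matrices for the three
#' network architectures; fits the three networks; computes the per-word
#' measures; and simulates token durations from a known linear model on
#' baseline duration, the chosen network's measures, and speech rate.
#' This is the package's one-call entry point for simulation studies and
#' parameter-recovery checks.
#'
#' @param n_bases Number of monomorphemic bases.
#' @param affixes Affix specification (see [affix_spec()]).
#' @param dimension Semantic dimensions.
#' @param transparency_sd Idiosyncratic-noise sd of derived vectors.
#' @param variant Network whose measures drive token generation.
#' @param coefficients Named generating coefficients over
#'   `baseline_duration`, measure columns, and `speech_rate` (ms units).
#' @param intercept,residual_sd,tokens_per_type_prob,speech_rate_mean,speech_rate_sd
#'   Passed to [generate_tokens()].
#' @param divisor Path-length divisor for mean word support.
#' @param k Neighborhood size for semantic density.
#' @param seed Integer seed; every stage derives its stream from it.
#' @return A list of class `ldl_study`: `lexicon`, `store`,
#'   `segment_table`, `cue`, `networks` (named list of three
#'   [ldl_network()]s), `measures` (named list of measure tibbles),
#'   `covariates` (measures + baseline for the generating variant),
#'   `tokens`, `variant`, and `ground_truth`.
#' @examples
#' \donttest{
#' study <- ldl_study(n_bases = 30, affixes = default_affixes(10),
#'                    dimension = 30, seed = 1)
#' glance(study$networks$morphology)
#' }
#' @export
ldl_study <- function(n_bases = 60,
                      affixes = default_affixes(40L),
                      dimension = 100L,
                      transparency_sd = 0.5,
                      variant = "morphology",
                      coefficients = c(baseline_duration = 1,
                                       mean_word_support = 150,
                                       path_entropies = -30,
                                       semantic_vector_length = -5,
                                       speech_rate = -20),
                      intercept = 60,
                      residual_sd = 20,
                      tokens_per_type_prob = 0.3,
                      speech_rate_mean = 5,
                      speech_rate_sd = 1,
                      divisor = "nodes",
                      k = 8L,
                      seed = 1L) {
  seed <- as.integer(seed)
  lexicon <- generate_lexicon(n_bases, affixes, seed = seed)
  store <- generate_vector_store(lexicon, dimension = dimension,
                                 transparency_sd = transparency_sd,
                                 seed = seed + 1L)
  segment_table <- generate_segment_table(lexicon_inventory(lexicon),
                                          seed = seed + 2L)
  cue <- build_cue_matrix(lexicon)
  variants <- c("idiosyncratic", "morphology", "base")
  networks <- lapply(variants, function(v) {
    ldl_network(cue, build_semantic_matrix(lexicon, store, v))
  })
  names(networks) <- variants
  measures <- lapply(networks, ldl_measures, lexicon = lexicon, k = k,
                     divisor = divisor)

  covariates <- baseline_duration(lexicon, segment_table) |>
    dplyr::inner_join(measures[[variant]], by = "word_id")
  tokens <- generate_tokens(covariates, coefficients,
                            intercept = intercept,
                            residual_sd = residual_sd,
                            tokens_per_type_prob = tokens_per_type_prob,
                            speech_rate_mean = speech_rate_mean,
                            speech_rate_sd = speech_rate_sd,
                            seed = seed + 3L)
  structure(
    list(lexicon = lexicon, store = store, segment_table = segment_table,
         cue = cue, networks = networks, measures = measures,
         covariates = covariates, tokens = tokens, variant = variant,
         ground_truth = attr(tokens, "ground_truth")),
    class = "ldl_study"
  )
}

#' @export
print.ldl_study <- function(x, ...) {
  cat(sprintf("Synthetic LDL duration study: %d words, %d tokens (%s variant drives durations)\n",
              nrow(x$lexicon), nrow(x$tokens), x$variant))
  for (v in names(x$networks)) {
    g <- glance(x$networks[[v]])
    cat(sprintf("  %-13s comprehension %.2f, production %.2f\n", v,
                g$comprehension_accuracy, g$production_accuracy))
  }
  invisible(x)
}

#' Fit, trim, and simplify the duration regression for a token table
#'
#' Constructs the duration-difference response, fits the full model of
#' the response on the LDL measures plus speech rate, removes
#' observations with residuals beyond `trim_sd` standard deviations
#' (single pass), and eliminates non-significant terms stepwise at
#' `alpha` with speech rate forced to stay.
#'
#' @param tokens Token table containing `observed_duration`,
#'   `baseline_duration`, `speech_rate`, and the measure columns.
#' @param kind `"standard"` (OLS) or `"mixed"` (random intercept per word
#'   type, repeated types only).
#' @param terms Fixed terms of the full model.
#' @param alpha Retention level for the stepwise simplification.
#' @param trim_sd Residual trimming threshold in standard deviations.
#' @param forced Terms never eliminated.
#' @return A `duration_fit`.
#' @export
run_duration_analysis <- function(tokens,
                                  kind = c("standard", "mixed"),
                                  terms = c("mean_word_support",
                                            "path_entropies",
                                            "semantic_vector_length",
                                            "semantic_density",
                                            "target_correlation",
                                            "speech_rate"),
                                  alpha = 0.05,
                                  trim_sd = 2.5,
                                  forced = "speech_rate") {
  kind <- match.arg(kind)
  tokens <- duration_difference(tokens)
  f <- reformulate(terms, response = "duration_difference")
  fit <- if (kind == "standard") {
    # degenerate measures (e.g. a constant target correlation in the exact
    # interpolation regime) are left for the stepwise pass to discard
    fit_standard(tokens, f, check_rank = FALSE)
  } else {
    fit_mixed(tokens, f, group = "word_id")
  }
  fit <- trim_refit(fit, threshold = trim_sd)
  stepwise_eliminate(fit, alpha = alpha, forced = forced)
}
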