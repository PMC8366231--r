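#' Fit duration regressions
#'
#' `fit_standard()` fits an ordinary least-squares regression of the
#' response on the fixed terms. `fit_mixed()` first restricts the data to
#' word types observed more than once (hapax types carry no information
#' about between-type variation), then fits a linear mixed model with a
#' random intercept per word type by REML; fixed-effect p-values use
#' Satterthwaite degrees of freedom via \pkg{lmerTest}.
#'
#' @param data Token-level data frame containing the response and all
#'   terms (and, for `fit_mixed()`, the grouping column).
#' @param formula Model formula, response on the left, fixed terms on the
#'   right (no random-effect terms: `fit_mixed()` adds
#'   `(1 | group)` itself).
#' @return An object of class `duration_fit`: a list with the underlying
#'   fit (`fit`), `kind` (`"standard"` or `"mixed"`), the model `data`,
#'   and bookkeeping fields `dropped` (eliminated terms), `trimmed`
#'   (observations removed), `n_hapax_dropped`, and `singular` flag
#'   (mixed only).
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' glance(fit_standard(d, y ~ x))
#' @param check_rank Error on a rank-deficient (aliased) design (default
#'   `TRUE`); set to `FALSE` to keep the fit and let
#'   [stepwise_eliminate()] discard aliased terms.
#' @export
fit_standard <- function(data, formula, check_rank = TRUE) {
  data <- check_fit_data(data, formula)
  fit <- lm(formula, data = data)
  if (check_rank) check_rank_lm(fit)
  new_duration_fit(fit, "standard", data)
}

#' @rdname fit_standard
#' @param group Column name of the word-type grouping factor.
#' @export
fit_mixed <- function(data, formula, group = "word_id") {
  if (!group %in% names(data)) {
    abort(paste0("grouping column ", sQuote(group), " not found"))
  }
  data <- check_fit_data(data, formula, extra = group)
  counts <- table(data[[group]])
  keep <- names(counts)[counts > 1L]
  n_hapax <- sum(counts == 1L)
  data <- data[data[[group]] %in% keep, , drop = FALSE]
  if (nrow(data) < 3L) abort("too few repeated-type tokens for a mixed model")
  full <- update(formula,
                 paste(". ~ . +", sprintf("(1 | %s)", group)))
  fit <- lmerTest::lmer(full, data = data, REML = TRUE)
  res <- new_duration_fit(fit, "mixed", data)
  res$n_hapax_dropped <- n_hapax
  res$singular <- lme4::isSingular(fit)
  res
}

check_fit_data <- function(data, formula, extra = character(0)) {
  vars <- all.vars(formula)
  missing <- setdiff(c(vars, extra), names(data))
  if (length(missing)) {
    abort(paste0("data lacks column(s): ", paste(missing, collapse = ", ")))
  }
  data <- as_tibble(data)
  cc <- complete.cases(data[, vars])
  data <- data[cc, , drop = FALSE]
  n_terms <- length(labels(terms(formula)))
  if (n_terms > 0 && nrow(data) < 10L * n_terms) {
    warn(sprintf("only %d observations for %d terms (< 10 per term)",
                 nrow(data), n_terms))
  }
  data
}

check_rank_lm <- function(fit) {
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased)) {
    abort(paste0("rank-deficient design; aliased term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  invisible(fit)
}

new_duration_fit <- function(fit, kind, data) {
  structure(list(fit = fit, kind = kind, data = data,
                 dropped = character(0), trimmed = 0L,
                 trimmed_fraction = 0, n_hapax_dropped = 0L,
                 singular = FALSE),
            class = "duration_fit")
}

fit_formula <- function(x) {
  if (x$kind == "mixed") {
    lme4::nobars(stats::formula(x$fit, fixed.only = TRUE))
  } else {
    stats::formula(x$fit)
  }
}

refit_duration <- function(x, data = x$data, formula = NULL) {
  formula <- formula %||% fit_formula(x)
  out <- if (x$kind == "mixed") {
    grp <- names(lme4::ranef(x$fit))[1]
    full <- update(formula, paste(". ~ . +", sprintf("(1 | %s)", grp)))
    fit <- lmerTest::lmer(full, data = data, REML = TRUE)
    res <- new_duration_fit(fit, "mixed", data)
    res$singular <- lme4::isSingular(fit)
    res
  } else {
    new_duration_fit(lm(formula, data = data), "standard", data)
  }
  out$dropped <- x$dropped
  out$trimmed <- x$trimmed
  out$trimmed_fraction <- x$trimmed_fraction
  out$n_hapax_dropped <- x$n_hapax_dropped
  out
}

#' Trim high-residual observations and refit once
#'
#' Observations whose residual lies more than `threshold` standard
#' deviations from the mean residual are removed and the model is refit
#' a single time. Under clean Gaussian residuals the rule removes about
#' 2 * pnorm(-2.5), i.e. around 1.2% of the data; a removal fraction
#' above `max_fraction` signals suspect data and is an error.
#'
#' @param x A `duration_fit`.
#' @param threshold Standardized-residual cutoff (default 2.5).
#' @param max_fraction Abort if more than this fraction would be removed.
#' @return The refit `duration_fit`, with `trimmed` and
#'   `trimmed_fraction` recorded.
#' @export
trim_refit <- function(x, threshold = 2.5, max_fraction = 0.2) {
  stopifnot(inherits(x, "duration_fit"))
  r <- resid(x$fit)
  z <- (r - mean(r)) / sd(r)
  drop_idx <- which(abs(z) > threshold)
  frac <- length(drop_idx) / length(z)
  if (frac > max_fraction) {
    abort(sprintf("trimming would remove %.1f%% of observations (> %.0f%%)",
                  100 * frac, 100 * max_fraction))
  }
  if (length(drop_idx) == 0L) {
    x$trimmed <- 0L
    x$trimmed_fraction <- 0
    return(x)
  }
  data <- x$data[-drop_idx, , drop = FALSE]
  out <- refit_duration(x, data = data)
  out$trimmed <- length(drop_idx)
  out$trimmed_fraction <- frac
  out
}

term_p_values <- function(x) {
  f <- fit_formula(x)
  terms_now <- labels(terms(f))
  if (length(terms_now) == 0L) return(setNames(numeric(0), character(0)))
  if (x$kind == "mixed") {
    d1 <- suppressMessages(drop1(x$fit, ddf = "Satterthwaite"))
    p <- d1[["Pr(>F)"]]
    names(p) <- rownames(d1)
  } else {
    d1 <- drop1(x$fit, test = "F")
    p <- d1[["Pr(>F)"]][-1]
    names(p) <- rownames(d1)[-1]
  }
  p[terms_now]
}

#' Stepwise elimination of non-significant terms
#'
#' Starting from the full model, the non-forced term with the highest
#' p-value at or above `alpha` is removed and the model refit; this
#' repeats until every retained (non-forced) term is significant at
#' `alpha`. Term p-values come from single-term-deletion F tests
#' (Satterthwaite degrees of freedom for mixed models). Aliased terms in
#' a rank-deficient design are eliminated first. The elimination order is
#' recorded in `dropped`.
#'
#' @param x A `duration_fit`.
#' @param alpha Significance level for retention (default 0.05).
#' @param forced Character vector of terms never eligible for
#'   elimination (default `"speech_rate"`, the one non-network control).
#' @return The simplified `duration_fit`.
#' @export
stepwise_eliminate <- function(x, alpha = 0.05, forced = "speech_rate") {
  stopifnot(inherits(x, "duration_fit"))
  # aliased (perfectly collinear) terms can never be tested; drop them first
  if (x$kind == "standard") {
    while (anyNA(coef(x$fit))) {
      aliased <- names(coef(x$fit))[is.na(coef(x$fit))][1]
      cand <- intersect(labels(terms(fit_formula(x))), aliased)
      if (!length(cand)) cand <- aliased
      x <- drop_term(x, cand[1])
    }
  }
  repeat {
    p <- term_p_values(x)
    p <- p[!names(p) %in% forced & !is.na(p)]
    if (!length(p) || max(p) < alpha) break
    x <- drop_term(x, names(p)[which.max(p)])
  }
  x
}

drop_term <- function(x, term) {
  f <- update(fit_formula(x), paste(". ~ . -", term))
  out <- refit_duration(x, formula = f)
  out$dropped <- c(x$dropped, term)
  out
}

#' Variance inflation factors
#'
#' For each predictor, VIF = 1 / (1 - R^2) where R^2 comes from
#' regressing that predictor on all the others. Perfectly collinear
#' predictors get `Inf`.
#'
#' @param data Data frame holding the predictors.
#' @param predictors Character vector (>= 2) of predictor column names.
#' @return A tibble with columns `predictor` and `vif`.
#' @export
vif <- function(data, predictors) {
  if (length(predictors) < 2L) abort("need >= 2 predictors")
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    abort(paste0("data lacks predictor(s): ", paste(missing, collapse = ", ")))
  }
  vals <- vapply(predictors, function(p) {
    f <- reformulate(setdiff(predictors, p), response = p)
    r2 <- summary(lm(f, data = data))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(predictor = predictors, vif = unname(vals))
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-components formulas: the marginal R^2 is the fixed-effect
#' variance share var_f / (var_f + var_random + var_residual), and the
#' conditional R^2 adds the random-effect variance to the numerator.
#' var_f is the variance of the fixed-effect linear predictor.
#'
#' @param fit A fitted `lmerMod`/`lmerModLmerTest` model.
#' @return Named numeric vector with `marginal` and `conditional`.
#' @export
r2_mixed <- function(fit) {
  var_f <- var(as.vector(model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_e <- sigma(fit)^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' @export
print.duration_fit <- function(x, ...) {
  cat(sprintf("Duration regression (%s), n = %d\n", x$kind,
              nrow(x$data)))
  if (x$trimmed > 0) {
    cat(sprintf("  trimmed: %d observations (%.2f%%)\n", x$trimmed,
                100 * x$trimmed_fraction))
  }
  if (length(x$dropped)) {
    cat("  eliminated terms:", paste(x$dropped, collapse = ", "), "\n")
  }
  if (x$kind == "mixed" && x$n_hapax_dropped > 0) {
    cat(sprintf("  hapax types excluded: %d\n", x$n_hapax_dropped))
  }
  print(tidy(x))
  invisible(x)
}
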