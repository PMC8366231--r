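#' @export
tidy.duration_fit <- function(x, ...) {
  if (x$kind == "mixed") {
    s <- as.data.frame(summary(x$fit)$coefficients)
    tibble(term = rownames(s),
           estimate = s[["Estimate"]],
           std.error = s[["Std. Error"]],
           df = s[["df"]],
           statistic = s[["t value"]],
           p.value = s[["Pr(>|t|)"]])
  } else {
    s <- summary(x$fit)$coefficients
    tibble(term = rownames(s),
           estimate = s[, "Estimate"],
           std.error = s[, "Std. Error"],
           statistic = s[, "t value"],
           p.value = s[, "Pr(>|t|)"])
  }
}

#' @export
glance.duration_fit <- function(x, ...) {
  if (x$kind == "mixed") {
    r2 <- r2_mixed(x$fit)
    tibble(kind = "mixed",
           n = nrow(x$data),
           r.squared.marginal = unname(r2["marginal"]),
           r.squared.conditional = unname(r2["conditional"]),
           sigma = sigma(x$fit),
           n_trimmed = x$trimmed,
           n_hapax_dropped = x$n_hapax_dropped,
           n_terms_dropped = length(x$dropped),
           singular = x$singular)
  } else {
    s <- summary(x$fit)
    tibble(kind = "standard",
           n = nrow(x$data),
           r.squared = s$r.squared,
           adj.r.squared = s$adj.r.squared,
           sigma = s$sigma,
           n_trimmed = x$trimmed,
           n_hapax_dropped = 0L,
           n_terms_dropped = length(x$dropped),
           singular = FALSE)
  }
}

#' @export
augment.duration_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- unname(predict(x$fit))
  out$.resid <- unname(resid(x$fit))
  out
}
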