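#' Gender-specific quasi-Poisson attendance models
#'
#' Log-link count GLMs of male or female attendance on the selected event
#' factors. Point estimates are the Poisson maximum-likelihood estimates
#' (IRLS via `stats::glm.fit`); overdispersion is absorbed by a dispersion
#' parameter phi estimated from the Pearson statistic, which scales the
#' coefficient covariance but not the point estimates.
#'
#' @name attendance_models
NULL

#' Default model terms per outcome
#'
#' The term sets used when grouped selection is skipped: the male model keeps
#' trainer gender, venue, division, time of day and the division-by-time
#' interaction (with its lower-order terms); the female model keeps trainer
#' gender, time of day, month, venue and division.
#'
#' @param outcome `"males"` or `"females"`.
#' @return character vector of terms.
#' @export
default_terms <- function(outcome = c("males", "females")) {
  outcome <- match.arg(outcome)
  if (outcome == "males")
    c("trainer_gender", "venue", "division", "time_bin", "division:time_bin")
  else
    c("trainer_gender", "time_bin", "month", "venue", "division")
}

#' Fit a quasi-Poisson attendance model
#'
#' @param table an `event_table`.
#' @param terms factor names and `"a:b"` interactions to include (plus an
#'   intercept, always). Defaults to [default_terms()] for the outcome.
#' @param outcome `"males"` or `"females"`.
#' @param schema level sets.
#' @return an `attendance_model`: named `coefficients`, Pearson `phi`,
#'   `vcov` (phi-scaled), `terms`, `outcome`, `n_obs`, `converged`.
#' @export
fit_attendance <- function(table, terms = default_terms(outcome),
                           outcome = c("males", "females"),
                           schema = event_schema()) {
  outcome <- match.arg(outcome)
  y <- table[[outcome]]
  X <- build_term_matrix(as.data.frame(table), terms, schema, intercept = TRUE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients (n = ", n,
                   ", p = ", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  mu <- fit$fitted.values
  phi <- sum((y - mu)^2 / mu) / (n - p)
  XtWX <- crossprod(X * sqrt(mu))
  vcov <- phi * solve(XtWX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(outcome = outcome, terms = terms,
                 coefficients = stats::setNames(fit$coefficients, colnames(X)),
                 phi = phi, vcov = vcov, n_obs = n, n_coef = p,
                 converged = fit$converged, schema = schema,
                 fitted_sum = sum(mu), observed_sum = sum(y)),
            class = "attendance_model")
}

#' @export
print.attendance_model <- function(x, ...) {
  cat(sprintf("Quasi-Poisson attendance model: %s ~ %s\n", x$outcome,
              paste(x$terms, collapse = " + ")))
  cat(sprintf("  n = %d, p = %d, dispersion phi = %.3f\n",
              x$n_obs, x$n_coef, x$phi))
  invisible(x)
}

#' Predicted mean attendance at one event configuration
#'
#' @param model an `attendance_model`.
#' @param event_config named list (or one-row data.frame) with a level for
#'   every factor appearing in the model's terms; extra entries are ignored.
#' @param se also return the delta-method standard error
#'   `exp(x'b) * sqrt(x' Sigma x)`.
#' @return the expected count; with `se = TRUE`, a named vector
#'   `c(mean, se)`.
#' @export
predict_mean <- function(model, event_config, se = FALSE) {
  x <- config_row(model, event_config)
  mu <- exp(sum(x * model$coefficients))
  if (!se) return(mu)
  c(mean = mu, se = mu * sqrt(drop(t(x) %*% model$vcov %*% x)))
}

config_row <- function(model, event_config) {
  df <- if (length(event_config) == 0L) data.frame(row.names = 1L)
        else as.data.frame(event_config, stringsAsFactors = FALSE)
  for (f in term_factors(model$terms))
    if (is.null(df[[f]]))
      stop("configuration is missing a level for required term '", f, "'")
  drop(build_term_matrix(df, model$terms, model$schema, intercept = TRUE))
}

#' Combined prediction from the two gender models
#'
#' Total attendance is the sum of the male- and female-model predictions; the
#' female share is female / total (0, flagged, when the total is 0).
#'
#' @param male_model,female_model fitted `attendance_model`s.
#' @param event_config named list of levels covering both models' terms.
#' @return named list: `male`, `female`, `total`, `proportion_female`,
#'   `zero_total` flag.
#' @export
predict_total <- function(male_model, female_model, event_config) {
  m <- predict_mean(male_model, event_config)
  f <- predict_mean(female_model, event_config)
  tot <- m + f
  list(male = m, female = f, total = tot,
       proportion_female = if (tot > 0) f / tot else 0,
       zero_total = tot == 0)
}

#' Serialize / load an attendance model (JSON)
#'
#' The round trip reproduces predictions exactly: predictions depend only on
#' the stored coefficients, covariance, terms and schema.
#'
#' @param model an `attendance_model`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(outcome = model$outcome, terms = model$terms,
                  coefficients = as.list(model$coefficients),
                  phi = model$phi,
                  vcov = list(names = colnames(model$vcov),
                              values = as.vector(model$vcov)),
                  n_obs = model$n_obs, converged = model$converged,
                  schema = model$schema)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  p <- length(x$coefficients)
  vc <- matrix(x$vcov$values, p, p,
               dimnames = list(x$vcov$names, x$vcov$names))
  schema <- lapply(x$schema, as.character)
  structure(list(outcome = x$outcome, terms = x$terms,
                 coefficients = unlist(x$coefficients), phi = x$phi,
                 vcov = vc, n_obs = x$n_obs, n_coef = p,
                 converged = x$converged, schema = schema),
            class = "attendance_model")
}
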