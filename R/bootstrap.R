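#' Bootstrap the fit-and-predict procedure
#'
#' Draws B nonparametric bootstrap replicates (events resampled with
#' replacement), refits the male and female quasi-Poisson models on each with
#' the term sets held fixed, and keeps the replicate coefficient vectors so
#' that any mesh point or scenario can later be summarized with percentile
#' confidence intervals. Replicates whose fit fails (e.g. a rare level absent
#' from the resample) are redrawn; more than 5% redraws aborts.
#'
#' @param table an `event_table`.
#' @param male_terms,female_terms term sets (defaults: [default_terms()]).
#' @param B number of replicates (study default 1,000).
#' @param seed integer.
#' @param schema level sets.
#' @return a `bootstrap_ensemble`: coefficient matrices `male_coefs`,
#'   `female_coefs` (p x B), the point-estimate `male_model` / `female_model`
#'   fitted on the original table, `B`, `seed`, `n_redraws`.
#' @export
bootstrap_models <- function(table,
                             male_terms = default_terms("males"),
                             female_terms = default_terms("females"),
                             B = 1000L, seed = 1L,
                             schema = event_schema()) {
  n <- nrow(table)
  if (n == 0L) stop("table is empty")
  df <- as.data.frame(table)
  male_model <- fit_attendance(table, male_terms, "males", schema)
  female_model <- fit_attendance(table, female_terms, "females", schema)
  max_fail <- max(1, ceiling(0.05 * B))

  with_seed(stage_seed(seed, "bootstrap"), {
    male_coefs <- matrix(NA_real_, male_model$n_coef, B,
                         dimnames = list(names(male_model$coefficients), NULL))
    female_coefs <- matrix(NA_real_, female_model$n_coef, B,
                           dimnames = list(names(female_model$coefficients), NULL))
    n_redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        rep_tab <- new_event_table(df[idx, , drop = FALSE], data.frame(), schema)
        mm <- try(fit_attendance(rep_tab, male_terms, "males", schema),
                  silent = TRUE)
        fm <- try(fit_attendance(rep_tab, female_terms, "females", schema),
                  silent = TRUE)
        if (!inherits(mm, "try-error") && !inherits(fm, "try-error")) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_fail)
          stop("more than 5% of bootstrap replicates failed to fit (",
               n_redraws, " redraws); check for very rare levels")
      }
      male_coefs[, b] <- mm$coefficients
      female_coefs[, b] <- fm$coefficients
    }
    structure(list(male_coefs = male_coefs, female_coefs = female_coefs,
                   male_model = male_model, female_model = female_model,
                   male_terms = male_terms, female_terms = female_terms,
                   B = B, seed = seed, n_redraws = n_redraws, schema = schema),
              class = "bootstrap_ensemble")
  })
}

# Percentile interval with the linear-interpolation quantile rule.
pct_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
}

# Replicate prediction matrices over a set of configurations:
# rows = configs, cols = replicates.
ensemble_predictions <- function(ensemble, configs) {
  Xm <- build_term_matrix(configs, ensemble$male_terms, ensemble$schema,
                          intercept = TRUE)
  Xf <- build_term_matrix(configs, ensemble$female_terms, ensemble$schema,
                          intercept = TRUE)
  list(male = exp(Xm %*% ensemble$male_coefs),
       female = exp(Xf %*% ensemble$female_coefs),
       point_male = exp(drop(Xm %*% ensemble$male_model$coefficients)),
       point_female = exp(drop(Xf %*% ensemble$female_model$coefficients)))
}

#' Summarize bootstrap predictions over a mesh of configurations
#'
#' For every configuration: the bootstrap mean and 95% percentile interval of
#' predicted total attendance, female attendance and the proportion of female
#' attendance (the ratio computed per replicate, then summarized).
#'
#' @param ensemble a `bootstrap_ensemble`.
#' @param mesh data.frame of event configurations, e.g. from [build_mesh()].
#' @param level confidence level (default 0.95).
#' @return a `mesh_summary` data.frame: the config columns plus
#'   `total_mean/lo/hi`, `female_mean/lo/hi`, `prop_mean/lo/hi` and the
#'   point-estimate columns `total_point`, `female_point`.
#' @export
summarize_mesh <- function(ensemble, mesh, level = 0.95) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"), nrow(mesh) > 0)
  pr <- ensemble_predictions(ensemble, mesh)
  tot <- pr$male + pr$female
  prop <- pr$female / tot
  prop[tot == 0] <- 0
  ci_t <- t(apply(tot, 1, pct_ci, level = level))
  ci_f <- t(apply(pr$female, 1, pct_ci, level = level))
  ci_p <- t(apply(prop, 1, pct_ci, level = level))
  out <- cbind(
    mesh,
    data.frame(total_mean = rowMeans(tot), total_lo = ci_t[, 1], total_hi = ci_t[, 2],
               female_mean = rowMeans(pr$female), female_lo = ci_f[, 1],
               female_hi = ci_f[, 2],
               prop_mean = rowMeans(prop), prop_lo = ci_p[, 1], prop_hi = ci_p[, 2],
               total_point = pr$point_male + pr$point_female,
               female_point = pr$point_female)
  )
  rownames(out) <- NULL
  class(out) <- c("mesh_summary", "data.frame")
  attr(out, "axes") <- attr(mesh, "axes")
  attr(out, "level") <- level
  out
}
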