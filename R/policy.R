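#' Policy simulation over the mesh of feasible training events
#'
#' The mesh is the Cartesian grid over the categorical axes retained by either
#' gender model. Mesh points are ranked by predicted total or female
#' attendance, and the X% mixing policy replaces the lower X% of the top-total
#' list with the top X% of the top-female list, trading total attendance
#' against female participation.
#'
#' @name policy_sim
NULL

#' Enumerate feasible event configurations
#'
#' Cartesian product over the union of factors appearing in either model's
#' terms (interaction terms contribute their parent factors); factors in
#' neither model are excluded. Month is not an axis: when a model uses month,
#' predictions are evaluated at a fixed month — by default the study's last
#' month, where female attendance peaked — so the mesh represents
#' configurations plannable going forward.
#'
#' @param male_terms,female_terms model term sets.
#' @param schema level sets.
#' @param month_level fixed month used when either model includes month.
#' @return data.frame of configurations with attribute `axes`.
#' @export
build_mesh <- function(male_terms = default_terms("males"),
                       female_terms = default_terms("females"),
                       schema = event_schema(),
                       month_level = "jan2019") {
  facs <- union(term_factors(male_terms), term_factors(female_terms))
  if (length(facs) == 0L) stop("no factors retained by either model")
  axes <- setdiff(intersect(schema_factors(schema), facs), "month")
  grid <- expand.grid(lapply(stats::setNames(axes, axes), function(f) schema[[f]]),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if ("month" %in% facs) {
    stopifnot(month_level %in% schema$month)
    grid$month <- month_level
  }
  attr(grid, "axes") <- axes
  grid
}

config_key <- function(df, axes) {
  do.call(paste, c(lapply(axes, function(a) df[[a]]), sep = "|"))
}

#' Rank mesh points by a criterion
#'
#' Descending sort by the criterion's bootstrap mean; ties are broken by the
#' other criterion's mean, then by lexicographic configuration order, so top
#' lists are fully deterministic.
#'
#' @param summary a `mesh_summary` from [summarize_mesh()].
#' @param criterion `"total"` or `"female"`.
#' @return the summary reordered, with a `rank` column and attribute
#'   `criterion`.
#' @export
rank_mesh <- function(summary, criterion = c("total", "female")) {
  criterion <- match.arg(criterion)
  axes <- attr(summary, "axes")
  primary <- summary[[paste0(criterion, "_mean")]]
  secondary <- summary[[paste0(setdiff(c("total", "female"), criterion), "_mean")]]
  ord <- order(-primary, -secondary, config_key(summary, axes))
  out <- summary[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "criterion") <- criterion
  attr(out, "axes") <- axes
  out
}

#' Mix the top-total and top-female lists
#'
#' Selects the top N-k entries of the total list and the top k of the female
#' list, k = round(X * N / 100) (half-up). Configurations appearing in both
#' sub-lists are deduplicated by backfilling from the female list's next
#' ranks, preserving the female-emphasis intent and the list size N.
#'
#' @param total_list,female_list ranked lists from [rank_mesh()].
#' @param N list size.
#' @param X mixing percentage in [0, 100].
#' @return the selected N rows (a `mesh_summary` subset) with attributes `N`,
#'   `X`.
#' @export
mix_lists <- function(total_list, female_list, N, X) {
  if (X < 0 || X > 100) stop("X must be in [0, 100]")
  if (nrow(total_list) < N || nrow(female_list) < N)
    stop("both lists must have at least N entries")
  axes <- attr(total_list, "axes")
  k <- round_half_up(X * N / 100)
  keep_total <- utils::head(total_list, N - k)
  chosen_keys <- config_key(keep_total, axes)
  fem_keys <- config_key(female_list, axes)
  add_idx <- integer(0)
  for (i in seq_len(nrow(female_list))) {
    if (length(add_idx) == k) break
    if (!fem_keys[i] %in% chosen_keys) {
      add_idx <- c(add_idx, i)
      chosen_keys <- c(chosen_keys, fem_keys[i])
    }
  }
  if (length(add_idx) < k)
    stop("not enough distinct mesh points to fill a list of size ", N)
  sel <- rbind(as.data.frame(keep_total), as.data.frame(female_list[add_idx, ]))
  rownames(sel) <- NULL
  attr(sel, "axes") <- axes
  attr(sel, "N") <- N
  attr(sel, "X") <- X
  sel
}

#' Bootstrap metrics of a selected event list
#'
#' Per bootstrap replicate, the average predicted total and female attendance
#' over the selected configurations and the attendance-weighted female share
#' (sum of female predictions over sum of totals); summarized as replicate
#' means with 95% percentile intervals. The unweighted mean of per-event
#' female shares is also reported.
#'
#' @param selection rows of mesh configurations (e.g. from [mix_lists()]).
#' @param ensemble a `bootstrap_ensemble`.
#' @param level confidence level.
#' @return a one-row data.frame of scenario metrics.
#' @export
evaluate_scenario <- function(selection, ensemble, level = 0.95) {
  stopifnot(nrow(selection) > 0)
  pr <- ensemble_predictions(ensemble, selection)
  tot <- pr$male + pr$female
  mean_total_b <- colMeans(tot)
  mean_female_b <- colMeans(pr$female)
  prop_b <- colSums(pr$female) / colSums(tot)
  ratio <- pr$female / tot
  prop_unweighted_b <- colMeans(ratio)
  ci_t <- pct_ci(mean_total_b, level)
  ci_f <- pct_ci(mean_female_b, level)
  ci_p <- pct_ci(prop_b, level)
  data.frame(
    N = nrow(selection),
    X = if (!is.null(attr(selection, "X"))) attr(selection, "X") else NA_real_,
    mean_total = mean(mean_total_b), total_lo = ci_t[1], total_hi = ci_t[2],
    mean_female = mean(mean_female_b), female_lo = ci_f[1], female_hi = ci_f[2],
    prop_female = mean(prop_b), prop_lo = ci_p[1], prop_hi = ci_p[2],
    prop_female_unweighted = mean(prop_unweighted_b)
  )
}

#' Sweep list sizes and mixing fractions
#'
#' Evaluates every (N, X) scenario on the default menu — lists of the top 100,
#' 50 and 10 events and X from 0 to 100% in 10% steps — yielding the
#' trade-off table behind the attendance-versus-inclusivity curves.
#'
#' @param total_list,female_list ranked lists from [rank_mesh()].
#' @param ensemble a `bootstrap_ensemble`.
#' @param N_menu list sizes.
#' @param X_grid mixing percentages.
#' @param level confidence level.
#' @return data.frame with one row per scenario (columns `N`, `X`, metric
#'   means and CI bounds).
#' @export
sweep_policies <- function(total_list, female_list, ensemble,
                           N_menu = c(100, 50, 10),
                           X_grid = seq(0, 100, by = 10),
                           level = 0.95) {
  rows <- list()
  for (N in N_menu) {
    if (N > nrow(total_list)) {
      warning("list size ", N, " exceeds mesh size ", nrow(total_list),
              "; skipped")
      next
    }
    for (X in X_grid) {
      sel <- mix_lists(total_list, female_list, N, X)
      rows[[length(rows) + 1L]] <- evaluate_scenario(sel, ensemble, level)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a scenario against the observed benchmark
#'
#' The policy goal is for the scenario's lower 95% confidence limits to
#' strictly exceed the observed per-event averages under intuition-based
#' scheduling (study context: 122.0 total, 23.0 female).
#'
#' @param scenario one row of scenario metrics ([evaluate_scenario()]).
#' @param benchmark named numeric, `total` and `female` per-event averages.
#' @return list with `exceeds_total`, `exceeds_female` logicals and the
#'   margins.
#' @export
benchmark_compare <- function(scenario, benchmark = c(total = 122, female = 23)) {
  stopifnot(all(benchmark >= 0))
  list(exceeds_total = scenario$total_lo > benchmark[["total"]],
       exceeds_female = scenario$female_lo > benchmark[["female"]],
       total_margin = scenario$total_lo - benchmark[["total"]],
       female_margin = scenario$female_lo - benchmark[["female"]])
}

#' Division-balanced list mixing
#'
#' Applies [mix_lists()] within each division to fill that division's quota of
#' the N slots, so that gains in attendance are not concentrated in one
#' region. Quota shares are converted to integer counts by largest remainder.
#'
#' @param total_list,female_list ranked lists from [rank_mesh()].
#' @param N list size.
#' @param X mixing percentage.
#' @param quota named numeric over divisions, summing to 1 (default equal
#'   shares).
#' @return the selected N rows with attributes `N`, `X`, `quota`.
#' @export
balanced_selection <- function(total_list, female_list, N, X,
                               quota = NULL) {
  schema <- event_schema()
  divs <- schema$division
  if (is.null(quota)) quota <- stats::setNames(rep(1 / length(divs), length(divs)), divs)
  if (abs(sum(quota) - 1) > 1e-8) stop("quota must sum to 1")
  if (!all(names(quota) %in% divs)) stop("quota names must be divisions")
  raw <- quota * N
  counts <- floor(raw)
  rem <- N - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  parts <- list()
  for (d in names(quota)) {
    nd <- counts[[d]]
    if (nd == 0) next
    tl <- total_list[total_list$division == d, , drop = FALSE]
    fl <- female_list[female_list$division == d, , drop = FALSE]
    attr(tl, "axes") <- attr(total_list, "axes")
    attr(fl, "axes") <- attr(total_list, "axes")
    if (nrow(tl) < nd)
      stop("quota for division '", d, "' (", nd,
           ") exceeds its mesh points (", nrow(tl), ")")
    parts[[d]] <- mix_lists(tl, fl, nd, X)
  }
  sel <- do.call(rbind, parts)
  rownames(sel) <- NULL
  attr(sel, "axes") <- attr(total_list, "axes")
  attr(sel, "N") <- N
  attr(sel, "X") <- X
  attr(sel, "quota") <- quota
  sel
}
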