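#' Model-input specification
#'
#' Declares the candidate main factors and first-order interactions from which
#' the grouped selection chooses. Defaults: all six event factors plus the
#' division-by-time, division-by-venue and division-by-trainer-gender
#' interactions.
#'
#' @param main_factors factor names, each a group of dummy columns.
#' @param interactions character vector of `"a:b"` pairs; both sides must be
#'   main factors.
#' @param schema level sets (fix the reference level as each factor's first
#'   level).
#' @return a `design_spec` list.
#' @export
design_spec <- function(main_factors = schema_factors(event_schema()),
                        interactions = c("division:time_bin",
                                         "division:venue",
                                         "division:trainer_gender"),
                        schema = event_schema()) {
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% main_factors))
      stop("interaction '", ia, "' must pair two main factors")
  }
  unknown <- setdiff(main_factors, schema_factors(schema))
  if (length(unknown)) stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  structure(list(main_factors = main_factors, interactions = interactions,
                 schema = schema),
            class = "design_spec")
}

#' Build a grouped dummy-coded design matrix
#'
#' Treatment coding against each factor's reference (first) level; a factor
#' with L levels contributes L-1 columns in one group, an interaction of
#' L1 x L2 levels contributes (L1-1)(L2-1) columns in one group. The intercept
#' is not part of the matrix (it is handled unpenalized by the path solver).
#'
#' @param table an `event_table` (or data.frame of levels).
#' @param spec a [design_spec()].
#' @return a `grouped_design`: `X` (n x p matrix), `groups` (integer per
#'   column), `group_names`, `spec`.
#' @export
build_design <- function(table, spec = design_spec()) {
  terms <- c(spec$main_factors, spec$interactions)
  X <- build_term_matrix(as.data.frame(table), terms, spec$schema,
                         intercept = FALSE)
  groups <- integer(0)
  for (i in seq_along(terms))
    groups <- c(groups, rep(i, length(term_columns(terms[i], spec$schema))))
  structure(list(X = X, groups = groups, group_names = terms, spec = spec),
            class = "grouped_design")
}

#' Split an event table into learning and testing sets
#'
#' Simple random split; the learning set has round(fraction * n) rows
#' (half-up rounding), the testing set the remainder. Seeded and reproducible.
#'
#' @param table an `event_table`.
#' @param fraction learning share in (0, 1); default 0.8.
#' @param seed integer.
#' @return list with `train`, `test` (both `event_table`s), `seed`, `fraction`.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L) {
  n <- nrow(table)
  if (n == 0L) stop("table is empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- round_half_up(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  schema <- attr(table, "schema")
  if (is.null(schema)) schema <- event_schema()
  excl <- attr(table, "excluded")
  if (is.null(excl)) excl <- data.frame()
  df <- as.data.frame(table)
  list(train = new_event_table(df[sort(idx), , drop = FALSE], excl, schema),
       test = new_event_table(df[-sort(idx), , drop = FALSE],
                              excl[0, , drop = FALSE], schema),
       seed = seed, fraction = fraction)
}

#' Drop terms that are not estimable on a table
#'
#' A selected interaction whose factor-level combinations include empty cells
#' makes the unpenalized GLM design rank deficient (the penalized path handles
#' this by rank reduction, a plain GLM cannot). This helper drops interaction
#' terms, from highest rank deficiency down, until the dummy design on
#' `table` has full column rank; main effects are never dropped.
#'
#' @param table an `event_table`.
#' @param terms candidate terms.
#' @param schema level sets.
#' @return the estimable subset of `terms`, with attribute `dropped`.
#' @export
estimable_terms <- function(table, terms, schema = event_schema()) {
  df <- as.data.frame(table)
  dropped <- character(0)
  rank_deficiency <- function(tm) {
    X <- build_term_matrix(df, tm, schema, intercept = TRUE)
    ncol(X) - qr(X)$rank
  }
  while (rank_deficiency(terms) > 0) {
    ints <- terms[grepl(":", terms, fixed = TRUE)]
    if (!length(ints))
      stop("main-effect design is rank deficient; a factor level is unobserved")
    # drop the interaction whose removal repairs the most rank deficiency
    gain <- vapply(ints, function(ia)
      rank_deficiency(terms) - rank_deficiency(setdiff(terms, ia)), numeric(1))
    worst <- ints[which.max(gain)]
    dropped <- c(dropped, worst)
    terms <- setdiff(terms, worst)
  }
  attr(terms, "dropped") <- dropped
  terms
}

# Weak heredity: every selected interaction pulls in its parent main effects.
apply_weak_heredity <- function(groups) {
  parents <- unlist(lapply(groups[grepl(":", groups, fixed = TRUE)],
                           function(g) strsplit(g, ":", fixed = TRUE)[[1]]))
  union(groups, parents)
}

#' Select model inputs by grouped penalized regression
#'
#' Splits the data 80/20 into learning and testing sets, runs a
#' cross-validated grouped-penalty fit per shrinkage method on the learning
#' set, scores each method's lambda-star model on the testing set by
#' root-mean-square error, and keeps the most accurate method's nonzero
#' groups. Ties are broken toward fewer selected groups, then by the fixed
#' order group MCP, group SCAD, group Lasso. Weak heredity is enforced: a
#' selected interaction adds its parent main effects to the final term set.
#'
#' @param table an `event_table`.
#' @param spec a [design_spec()].
#' @param outcome `"males"` or `"females"`.
#' @param methods shrinkage approaches to compare.
#' @param seed integer; drives both the split and the CV folds.
#' @param fraction learning share (default 0.8).
#' @param nfolds CV folds (default 10).
#' @param ... passed to [cross_validate_lambda()] (e.g. `nlambda`).
#' @return a `selection_result`: chosen `method`, `terms` (after heredity),
#'   per-method `smse`, `nmse`, `lambda_star`, selected groups, plus split
#'   metadata.
#' @export
select_inputs <- function(table, spec = design_spec(),
                          outcome = c("males", "females"),
                          methods = c("group_mcp", "group_scad", "group_lasso"),
                          seed = 1L, fraction = 0.8, nfolds = 10L, ...) {
  outcome <- match.arg(outcome)
  split <- split_train_test(table, fraction, stage_seed(seed, "split"))
  dtrain <- build_design(split$train, spec)
  Xtest <- build_term_matrix(as.data.frame(split$test),
                             c(spec$main_factors, spec$interactions),
                             spec$schema, intercept = FALSE)
  ytrain <- split$train[[outcome]]
  ytest <- split$test[[outcome]]

  per_method <- lapply(methods, function(m) {
    cv <- cross_validate_lambda(dtrain, ytrain, method = m,
                                nfolds = nfolds, seed = stage_seed(seed, "cv"),
                                ...)
    pred <- predict(cv$fit, Xtest, lambda_index = cv$index_star)
    grp <- selected_groups(cv$fit, cv$index_star)
    list(method = m, lambda_star = cv$lambda_star, cv = cv,
         smse = evaluate_smse(ytest, pred),
         nmse = evaluate_smse(ytest, pred, type = "nmse"),
         groups = grp, n_groups = length(grp))
  })
  names(per_method) <- methods

  order_pref <- c("group_mcp", "group_scad", "group_lasso")
  smse <- vapply(per_method, `[[`, numeric(1), "smse")
  ngrp <- vapply(per_method, `[[`, numeric(1), "n_groups")
  pref <- match(methods, order_pref)
  best <- order(smse, ngrp, pref)[1]
  chosen <- per_method[[best]]

  structure(list(
    outcome = outcome,
    method = chosen$method,
    lambda_star = chosen$lambda_star,
    selected_groups = chosen$groups,
    terms = apply_weak_heredity(chosen$groups),
    smse = smse,
    nmse = vapply(per_method, `[[`, numeric(1), "nmse"),
    n_groups = ngrp,
    per_method = per_method,
    split_seed = split$seed, fraction = fraction,
    n_train = nrow(split$train), n_test = nrow(split$test), seed = seed
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Input selection for '%s' (%d learning / %d testing events)\n",
              x$outcome, x$n_train, x$n_test))
  for (m in names(x$smse))
    cat(sprintf("  %-12s SMSE %8.3f  (%d groups)%s\n", m, x$smse[[m]],
                x$n_groups[[m]], if (m == x$method) "  <- chosen" else ""))
  cat("  terms (after weak heredity): ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a `selection_result`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
selection_to_json <- function(result, path = NULL) {
  payload <- list(
    outcome = result$outcome, method = result$method,
    lambda_star = result$lambda_star,
    smse = as.list(result$smse), nmse = as.list(result$nmse),
    n_groups = as.list(result$n_groups),
    selected_groups = result$selected_groups, terms = result$terms,
    split = list(seed = result$split_seed, fraction = result$fraction,
                 n_train = result$n_train, n_test = result$n_test)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
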