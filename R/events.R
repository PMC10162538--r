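#' Event tables
#'
#' An `event_table` is a data.frame with one validated row per training event
#' (six categorical fields plus the `males` and `females` counts) and an
#' `excluded` attribute holding the raw records that failed validation, each
#' tagged with a reason code (`missing_information`, `unknown_level`,
#' `negative_count`, `non_integer_count`). Source row order is preserved.
#'
#' @name event_table
NULL

event_fields <- function(schema = event_schema()) {
  c(schema_factors(schema), schema$counts)
}

new_event_table <- function(rows, excluded, schema = event_schema()) {
  rownames(rows) <- NULL
  structure(rows, excluded = excluded, schema = schema,
            class = c("event_table", "data.frame"))
}

#' Assemble an event table from a data.frame
#'
#' Validates rows the same way [read_events()] does; invalid rows move to the
#' `excluded` attribute with a reason code.
#'
#' @param df data.frame with the nine event fields.
#' @param schema level sets, see [event_schema()].
#' @return An `event_table`.
#' @export
as_event_table <- function(df, schema = event_schema()) {
  fields <- event_fields(schema)
  missing_cols <- setdiff(fields, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[fields]
  n <- nrow(df)
  reason <- rep(NA_character_, n)

  for (f in schema_factors(schema)) {
    v <- normalize_label(df[[f]])
    v[v == ""] <- NA_character_
    df[[f]] <- v
    miss <- is.na(v)
    reason[is.na(reason) & miss] <- "missing_information"
    unknown <- !miss & !(v %in% schema[[f]])
    reason[is.na(reason) & unknown] <- "unknown_level"
  }
  for (cn in schema$counts) {
    raw <- df[[cn]]
    num <- suppressWarnings(as.numeric(as.character(raw)))
    blank <- is.na(raw) | trimws(as.character(raw)) == ""
    reason[is.na(reason) & blank] <- "missing_information"
    unparseable <- !blank & is.na(num)
    reason[is.na(reason) & unparseable] <- "missing_information"
    reason[is.na(reason) & !is.na(num) & num < 0] <- "negative_count"
    reason[is.na(reason) & !is.na(num) & num != floor(num)] <- "non_integer_count"
    df[[cn]] <- num
  }

  keep <- is.na(reason)
  rows <- df[keep, , drop = FALSE]
  for (cn in schema$counts) rows[[cn]] <- as.integer(rows[[cn]])
  excluded <- df[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  excluded$source_row <- which(!keep)
  new_event_table(rows, excluded, schema)
}

#' Read training-event records from CSV
#'
#' The file must have a header naming the nine fields (`trainer_gender`,
#' `time_bin`, `day_of_week`, `month`, `venue`, `division`, `males`,
#' `females`). Category labels are normalized to lower_snake_case. Rows with
#' any missing, unparseable or out-of-schema field are excluded whole, with a
#' reason code, and kept in the table's `excluded` attribute for auditing.
#'
#' @param path CSV file path.
#' @param schema level sets, see [event_schema()].
#' @return An `event_table`.
#' @export
read_events <- function(path, schema = event_schema()) {
  if (!file.exists(path)) stop("cannot read events file: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                        na.strings = c("", "NA"))
  as_event_table(df, schema)
}

#' Write an event table to CSV
#'
#' Column order is fixed by the schema; excluded rows are not written.
#'
#' @param table an `event_table`.
#' @param path output CSV path.
#' @export
write_events <- function(table, path) {
  df <- as.data.frame(table)[event_fields(attr(table, "schema"))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Audit excluded records
#'
#' Reports how many source rows were excluded and whether the excluded events
#' differ from the included ones in average male or female attendance
#' (unequal-variance Welch two-sample t-test per outcome). Also exposes the
#' attendee totals of both groups without reconciling them.
#'
#' @param table an `event_table` from [read_events()].
#' @return A list of class `exclusion_audit`: counts, exclusion percent,
#'   per-outcome test results (or `"not computable"` when either group has
#'   fewer than two usable counts), and attendee totals.
#' @export
audit_exclusions <- function(table) {
  schema <- attr(table, "schema")
  excluded <- attr(table, "excluded")
  n_inc <- nrow(table)
  n_exc <- if (is.null(excluded)) 0L else nrow(excluded)
  n_tot <- n_inc + n_exc

  one_test <- function(outcome) {
    a <- as.numeric(table[[outcome]])
    b <- suppressWarnings(as.numeric(excluded[[outcome]]))
    b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(list(computable = FALSE, statistic = NA_real_, p_value = NA_real_,
                  mean_included = mean(a), mean_excluded = if (length(b)) mean(b) else NA_real_))
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
      return(list(computable = TRUE, statistic = 0, p_value = 1,
                  mean_included = mean(a), mean_excluded = mean(b)))
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(computable = TRUE, statistic = unname(tt$statistic),
         p_value = tt$p.value, mean_included = mean(a), mean_excluded = mean(b))
  }

  exc_counts <- vapply(schema$counts, function(cn) {
    v <- suppressWarnings(as.numeric(excluded[[cn]]))
    sum(v, na.rm = TRUE)
  }, numeric(1))

  structure(list(
    n_source_rows = n_tot,
    n_included = n_inc,
    n_excluded = n_exc,
    exclusion_percent = if (n_tot > 0) round(100 * n_exc / n_tot, 1) else NA_real_,
    reasons = if (n_exc) table(excluded$reason) else table(character()),
    tests = list(males = one_test("males"), females = one_test("females")),
    included_attendees = sum(table$males) + sum(table$females),
    excluded_attendees_recorded = sum(exc_counts)
  ), class = "exclusion_audit")
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat(sprintf("Exclusion audit: %d of %d source rows excluded (%.1f%%)\n",
              x$n_excluded, x$n_source_rows, x$exclusion_percent))
  for (o in names(x$tests)) {
    t <- x$tests[[o]]
    if (t$computable)
      cat(sprintf("  %s: Welch t = %.3f, p = %.3f (included mean %.1f vs excluded %.1f)\n",
                  o, t$statistic, t$p_value, t$mean_included, t$mean_excluded))
    else cat(sprintf("  %s: mean-difference test not computable\n", o))
  }
  cat(sprintf("  attendees: %d included; %d recorded on excluded rows\n",
              x$included_attendees, x$excluded_attendees_recorded))
  invisible(x)
}

#' Descriptive summary by one factor
#'
#' Per-level event counts and shares, and mean/SD/min/max of male and female
#' attendance, in the style of a study descriptives table. Sample SD uses the
#' n-1 denominator; the SD of a single observation is reported as 0 and the
#' level flagged in `single_obs`.
#'
#' @param table an `event_table`.
#' @param factor one of the six categorical field names.
#' @return data.frame with one row per level, plus attributes
#'   `mean_total_attendance` and `mean_female_attendance` over all events.
#' @export
summarize_events <- function(table, factor) {
  schema <- attr(table, "schema")
  if (!factor %in% schema_factors(schema))
    stop("'", factor, "' is not a categorical event field")
  if (nrow(table) == 0L) stop("no data")
  lev <- schema[[factor]]
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  rows <- lapply(lev, function(l) {
    sub <- table[table[[factor]] == l, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(level = l, n_events = 0L, percent = 0,
                        males_mean = NA_real_, males_sd = NA_real_,
                        males_min = NA_real_, males_max = NA_real_,
                        females_mean = NA_real_, females_sd = NA_real_,
                        females_min = NA_real_, females_max = NA_real_,
                        single_obs = FALSE))
    data.frame(level = l, n_events = nrow(sub),
               percent = round(100 * nrow(sub) / nrow(table), 1),
               males_mean = mean(sub$males), males_sd = sd0(sub$males),
               males_min = min(sub$males), males_max = max(sub$males),
               females_mean = mean(sub$females), females_sd = sd0(sub$females),
               females_min = min(sub$females), females_max = max(sub$females),
               single_obs = nrow(sub) == 1L)
  })
  out <- do.call(rbind, rows)
  attr(out, "factor") <- factor
  attr(out, "mean_total_attendance") <- mean(table$males + table$females)
  attr(out, "mean_female_attendance") <- mean(table$females)
  out
}
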