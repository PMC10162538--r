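#' Event-record schema
#'
#' The closed level sets of the six categorical fields describing a training
#' event, in their canonical order. The first level of each factor is the
#' reference level under treatment (dummy) coding. Labels are
#' lower_snake_case; CSV input is normalized to this form on read.
#'
#' @return A named list of character vectors, one per categorical field, plus
#'   the two count fields named in `$counts`.
#' @export
event_schema <- function() {
  list(
    trainer_gender = c("female", "male"),
    time_bin = c("before_11", "11_to_1530", "after_1530"),
    day_of_week = c("sunday", "monday", "tuesday", "wednesday", "thursday",
                    "friday", "saturday"),
    month = c("oct2018", "nov2018", "dec2018", "jan2019"),
    venue = c("educational_institution", "farmers_house", "marketplace",
              "religious_institution", "shop", "tea_stall", "union_parishad",
              "other"),
    division = c("rangpur", "khulna", "dhaka", "rajshahi"),
    counts = c("males", "females")
  )
}

#' @keywords internal
schema_factors <- function(schema = event_schema()) {
  setdiff(names(schema), "counts")
}

#' Normalize a categorical label to lower_snake_case
#' @keywords internal
normalize_label <- function(x) {
  x <- trimws(as.character(x))
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# Round-half-up, used for split sizes and list-mixing counts so that
# e.g. N = 10, X = 50 gives k = 5 regardless of the platform's rounding mode.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic fan-out of one master seed into per-stage seeds so each
# pipeline stage can be rerun in isolation. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(generate = 11L, split = 23L, cv = 37L, bootstrap = 53L,
               selection = 71L, replicate = 89L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}

# Evaluate an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so generators never perturb the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- Design-row construction shared by the generator, the penalized path and
# ---- the GLMs. Terms are factor names ("venue") or interaction pairs
# ---- ("division:time_bin"); a factor with L levels contributes L - 1 dummy
# ---- columns named "<factor>=<level>", an interaction (L1-1)(L2-1) columns
# ---- named "<f1>=<l1>:<f2>=<l2>". Treatment coding against the schema's
# ---- first level.

term_factors <- function(terms) {
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

main_term_columns <- function(factor_name, schema) {
  lev <- schema[[factor_name]]
  paste0(factor_name, "=", lev[-1])
}

term_columns <- function(term, schema) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(main_term_columns(term, schema))
  if (length(parts) != 2L) stop("only first-order interactions are supported: ", term)
  a <- main_term_columns(parts[1], schema)
  b <- main_term_columns(parts[2], schema)
  as.vector(t(outer(a, b, paste, sep = ":")))
}

#' Build a dummy-coded design matrix for a set of terms
#'
#' @param data data.frame with one column per factor used by `terms`, values
#'   drawn from the schema level sets.
#' @param terms character vector of factor names and `"a:b"` interaction pairs.
#' @param schema level sets as from [event_schema()].
#' @param intercept prepend an all-ones column named `(Intercept)`.
#' @return numeric matrix, one row per row of `data`.
#' @export
build_term_matrix <- function(data, terms, schema = event_schema(),
                              intercept = TRUE) {
  n <- nrow(data)
  facs <- term_factors(terms)
  ind <- list()  # per factor: n x (L-1) indicator block
  for (f in facs) {
    lev <- schema[[f]]
    if (is.null(lev)) stop("unknown factor: ", f)
    v <- as.character(data[[f]])
    bad <- !(v %in% lev)
    if (any(bad)) stop("unseen level(s) for ", f, ": ",
                       paste(unique(v[bad]), collapse = ", "))
    m <- matrix(0, n, length(lev) - 1L,
                dimnames = list(NULL, main_term_columns(f, schema)))
    for (j in seq_along(lev)[-1]) m[v == lev[j], j - 1L] <- 1
    ind[[f]] <- m
  }
  blocks <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) return(ind[[tm]])
    a <- ind[[parts[1]]]; b <- ind[[parts[2]]]
    out <- matrix(0, n, ncol(a) * ncol(b),
                  dimnames = list(NULL, term_columns(tm, schema)))
    k <- 0L
    for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
      k <- k + 1L
      out[, k] <- a[, i] * b[, j]
    }
    out
  })
  X <- if (length(blocks)) do.call(cbind, blocks)
       else matrix(numeric(0), n, 0)
  if (intercept) X <- cbind(`(Intercept)` = rep(1, n), X)
  X
}

# Linear predictor for one configuration (named list / one-row data.frame of
# levels) under a named coefficient vector whose names follow term_columns().
config_linear_predictor <- function(config, coefficients,
                                    schema = event_schema()) {
  eta <- 0
  for (nm in names(coefficients)) {
    if (nm == "(Intercept)") {
      eta <- eta + coefficients[[nm]]
      next
    }
    on <- TRUE
    for (part in strsplit(nm, ":", fixed = TRUE)[[1]]) {
      kv <- strsplit(part, "=", fixed = TRUE)[[1]]
      f <- kv[1]; lev <- kv[2]
      val <- config[[f]]
      if (is.null(val) || is.na(val))
        stop("configuration is missing a level for '", f, "'")
      if (!val %in% schema[[f]])
        stop("unknown level '", val, "' for factor '", f, "'")
      if (as.character(val) != lev) { on <- FALSE; break }
    }
    if (on) eta <- eta + coefficients[[nm]]
  }
  eta
}
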