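# Fixture builders shared across test files. Everything is generated in code;
# no data files ship with the tests.

# A data.frame of n valid events with cycled covariates and fixed counts.
valid_event_rows <- function(n, males = 100, females = 20,
                             division = NULL) {
  schema <- event_schema()
  cyc <- function(lev) rep_len(lev, n)
  df <- data.frame(
    trainer_gender = cyc(schema$trainer_gender),
    time_bin = cyc(schema$time_bin),
    day_of_week = cyc(schema$day_of_week),
    month = cyc(schema$month),
    venue = cyc(schema$venue),
    division = if (is.null(division)) cyc(schema$division) else division,
    males = rep_len(males, n),
    females = rep_len(females, n),
    stringsAsFactors = FALSE
  )
  df
}

# CSV mirroring the study's printed counts: 1,080 source rows of which 13 have
# a blank count field, and division counts 527/295/202/43 among the 1,067 kept.
printed_counts_fixture <- function(path = tempfile(fileext = ".csv")) {
  div <- rep(c("rangpur", "khulna", "dhaka", "rajshahi"),
             times = c(527, 295, 202, 43))
  good <- valid_event_rows(1067, division = div)
  bad <- valid_event_rows(13)
  bad$males <- ""   # missing count information excludes the whole row
  df <- rbind(good, bad)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Hand-built bootstrap ensemble with intercept-plus-division models, used to
# test summaries and policy arithmetic against exact hand computations.
# male_mu / female_mu: B-column matrices of per-replicate means by division
# (rows ordered rangpur, khulna, dhaka, rajshahi) or single numbers recycled.
manual_ensemble <- function(male_mu, female_mu) {
  schema <- event_schema()
  div_coefs <- function(mu) {
    # mu: 4 x B matrix of division means
    rbind("(Intercept)" = log(mu[1, ]),
          "division=khulna" = log(mu[2, ]) - log(mu[1, ]),
          "division=dhaka" = log(mu[3, ]) - log(mu[1, ]),
          "division=rajshahi" = log(mu[4, ]) - log(mu[1, ]))
  }
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(x, 4, length(x), byrow = TRUE)
  }
  mm <- as_mat(male_mu); fm <- as_mat(female_mu)
  stopifnot(ncol(mm) == ncol(fm))
  mc <- div_coefs(mm); fc <- div_coefs(fm)
  structure(list(
    male_coefs = mc, female_coefs = fc,
    male_model = list(coefficients = rowMeans(mc)),
    female_model = list(coefficients = rowMeans(fc)),
    male_terms = "division", female_terms = "division",
    B = ncol(mc), seed = 0L, n_redraws = 0L, schema = schema
  ), class = "bootstrap_ensemble")
}

division_mesh <- function() {
  mesh <- data.frame(division = event_schema()$division,
                     stringsAsFactors = FALSE)
  attr(mesh, "axes") <- "division"
  mesh
}
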