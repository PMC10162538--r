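# Small real ensemble shared across policy tests (no interactions, so every
# resample keeps full rank at this size).
policy_ensemble <- local({
  ens <- NULL
  function() {
    if (is.null(ens)) {
      ev <- generate_events(generator_config(n_events = 800, seed = 14))
      tm <- c("trainer_gender", "time_bin", "venue", "division")
      tf <- c("trainer_gender", "time_bin", "month", "venue", "division")
      ens <<- bootstrap_models(ev, tm, tf, B = 60, seed = 14)
    }
    ens
  }
})

test_that("the mesh is the product of retained axes, month held fixed", {
  mesh <- build_mesh()
  expect_equal(nrow(mesh), 192L)           # 2 x 3 x 8 x 4
  expect_equal(sort(attr(mesh, "axes")),
               sort(c("trainer_gender", "time_bin", "venue", "division")))
  expect_false("day_of_week" %in% names(mesh))
  expect_true(all(mesh$month == "jan2019"))
  expect_identical(mesh, build_mesh())     # deterministic

  single <- build_mesh("division", "division")
  expect_equal(nrow(single), 4L)
  expect_equal(names(single), "division")
  expect_error(build_mesh(character(0), character(0)), "no factors")
})

test_that("ranking sorts by the criterion with deterministic tie-breaks", {
  ens <- manual_ensemble(matrix(c(100, 100, 80, 120), 4, 3),
                         matrix(c(30, 40, 40, 10), 4, 3))
  ms <- summarize_mesh(ens, division_mesh())
  # totals: rangpur 130, khulna 140, dhaka 120, rajshahi 130
  tl <- rank_mesh(ms, "total")
  expect_equal(tl$division[1], "khulna")                    # argmax total
  expect_equal(tl$total_mean, sort(tl$total_mean, decreasing = TRUE))
  # total tie rangpur/rajshahi broken by female mean (rangpur higher)
  expect_equal(tl$division, c("khulna", "rangpur", "rajshahi", "dhaka"))
  fl <- rank_mesh(ms, "female")
  # female tie khulna/dhaka broken by total mean (khulna higher)
  expect_equal(fl$division, c("khulna", "dhaka", "rangpur", "rajshahi"))
  expect_identical(rank_mesh(ms, "female"), fl)
  expect_error(rank_mesh(ms, "males"), "arg")
})

test_that("list mixing honors boundaries, rounding and deduplication", {
  ens <- policy_ensemble()
  ms <- summarize_mesh(ens, build_mesh(ens$male_terms, ens$female_terms))
  tl <- rank_mesh(ms, "total")
  fl <- rank_mesh(ms, "female")
  axes <- attr(tl, "axes")
  key <- function(df) do.call(paste, df[axes])

  s0 <- mix_lists(tl, fl, 100, 0)
  expect_identical(key(s0), key(utils::head(tl, 100)))      # X = 0 boundary
  s100 <- mix_lists(tl, fl, 100, 100)
  expect_identical(key(s100), key(utils::head(fl, 100)))    # X = 100 boundary

  s50 <- mix_lists(tl, fl, 100, 50)
  expect_equal(nrow(s50), 100L)
  expect_equal(anyDuplicated(key(s50)), 0L)
  expect_true(all(key(utils::head(tl, 50)) %in% key(s50)))

  # half-up rounding of the mixed count
  s5 <- mix_lists(tl, fl, 10, 50)
  expect_equal(sum(key(s5) %in% key(utils::head(tl, 5))), 5L)

  expect_error(mix_lists(tl, fl, 500, 50), "at least N")
  expect_error(mix_lists(tl, fl, 10, 150), "X must be")
})

test_that("scenario metrics match hand arithmetic and degenerate cases", {
  # single replicate, three divisions: female {20,30,40}, male 80 each
  ens <- manual_ensemble(matrix(80, 4, 1),
                         matrix(c(20, 30, 40, 5), 4, 1))
  sel <- division_mesh()[1:3, , drop = FALSE]
  attr(sel, "axes") <- "division"
  sc <- evaluate_scenario(sel, ens)
  expect_equal(sc$mean_female, 30, tolerance = 1e-9)
  expect_equal(sc$mean_total, 110, tolerance = 1e-9)
  expect_equal(sc$prop_female, 90 / 330, tolerance = 1e-9)
  expect_equal(sc$female_lo, sc$female_hi)                 # B = 1: zero width
  # unweighted share differs from the attendance-weighted one
  expect_equal(sc$prop_female_unweighted,
               mean(c(20 / 100, 30 / 110, 40 / 120)), tolerance = 1e-9)

  # singleton selection equals that point's mesh summary
  ens2 <- policy_ensemble()
  mesh <- build_mesh(ens2$male_terms, ens2$female_terms)
  ms <- summarize_mesh(ens2, mesh)
  one <- mesh[7, , drop = FALSE]
  attr(one, "axes") <- attr(mesh, "axes")
  sc1 <- evaluate_scenario(one, ens2)
  expect_equal(sc1$mean_total, ms$total_mean[7], tolerance = 1e-9)
  expect_equal(sc1$total_lo, ms$total_lo[7], tolerance = 1e-9)
  expect_equal(sc1$prop_female, ms$prop_mean[7], tolerance = 1e-9)
})

test_that("the policy sweep traces the attendance/inclusivity trade-off", {
  ens <- policy_ensemble()
  ms <- summarize_mesh(ens, build_mesh(ens$male_terms, ens$female_terms))
  tl <- rank_mesh(ms, "total")
  fl <- rank_mesh(ms, "female")
  sw <- sweep_policies(tl, fl, ens)
  expect_equal(nrow(sw), 33L)                               # 3 N x 11 X
  for (N in c(100, 50, 10)) {
    s <- sw[sw$N == N, ]
    expect_equal(s$X, seq(0, 100, by = 10))
    # the pure top-total list dominates every mixed selection on mean total
    expect_true(all(s$mean_total <= s$mean_total[s$X == 0] + 1e-9))
  }
  expect_warning(sweep_policies(tl, fl, ens, N_menu = c(500, 10)), "skipped")

  # disjoint lists: mean female attendance is monotone non-decreasing in X
  ensd <- manual_ensemble(matrix(c(200, 180, 160, 140), 4, 2),
                          matrix(c(10, 20, 30, 40), 4, 2))
  msd <- summarize_mesh(ensd, division_mesh())
  tld <- rank_mesh(msd, "total")
  fld <- rank_mesh(msd, "female")
  expect_equal(length(intersect(tld$division[1:2], fld$division[1:2])), 0L)
  swd <- sweep_policies(tld, fld, ensd, N_menu = 2, X_grid = seq(0, 100, 10))
  expect_true(all(diff(swd$mean_female) >= -1e-12))
})

test_that("benchmark comparison requires strict exceedance of the lower limit", {
  sc <- data.frame(total_lo = 125, female_lo = 23)
  bc <- benchmark_compare(sc, c(total = 122, female = 23))
  expect_true(bc$exceeds_total)
  expect_false(bc$exceeds_female)                           # boundary: strict
  expect_equal(bc$total_margin, 3)
})

test_that("division-balanced mixing fills quotas without collapsing attendance", {
  ens <- policy_ensemble()
  ms <- summarize_mesh(ens, build_mesh(ens$male_terms, ens$female_terms))
  tl <- rank_mesh(ms, "total")
  fl <- rank_mesh(ms, "female")

  bal <- balanced_selection(tl, fl, 100, 50)
  expect_equal(nrow(bal), 100L)
  expect_equal(unname(table(bal$division)[event_schema()$division]),
               rep(25L, 4), ignore_attr = TRUE)

  # all mass on one division equals plain mixing within that division
  q <- c(rangpur = 1, khulna = 0, dhaka = 0, rajshahi = 0)
  bal1 <- balanced_selection(tl, fl, 20, 50, quota = q)
  tl_r <- tl[tl$division == "rangpur", ]
  fl_r <- fl[fl$division == "rangpur", ]
  attr(tl_r, "axes") <- attr(tl, "axes")
  attr(fl_r, "axes") <- attr(tl, "axes")
  direct <- mix_lists(tl_r, fl_r, 20, 50)
  expect_equal(bal1$venue, direct$venue)
  expect_equal(bal1$total_mean, direct$total_mean)

  # the constrained selection cannot beat the unconstrained one on mean total
  un <- evaluate_scenario(mix_lists(tl, fl, 100, 0), ens)
  attr(bal, "X") <- 0
  bal0 <- balanced_selection(tl, fl, 100, 0)
  expect_lte(evaluate_scenario(bal0, ens)$mean_total, un$mean_total + 1e-9)

  expect_error(balanced_selection(tl, fl, 100, 50,
                                  quota = c(rangpur = 0.5, khulna = 0.4)),
               "sum to 1")
})
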