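small_config <- function(seed = 1, ...) {
  generator_config(n_female = 20, n_male = 60, n_weeks = 3, seed = seed,
                   ...)
}

test_that("generation is deterministic down to the written bytes", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(generate(small_config(seed = 5)), d1)
  write_fixture(generate(small_config(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = paste("bytes of", f))
  }
})

test_that("fixtures round-trip through read_cohort", {
  d <- withr::local_tempdir()
  m <- generate(small_config(seed = 3))
  write_fixture(m, d)
  rt <- read_cohort(d)
  expect_identical(rt$cohort$participants, m$cohort$participants)
  expect_identical(rt$cohort$active_weeks, m$cohort$active_weeks)
  expect_equal(rt$traits$neuroticism, m$traits$neuroticism)
  for (ch in CHANNELS)
    expect_equal(names(rt$networks[[ch]]$weekly_graphs),
                 names(m$networks[[ch]]$weekly_graphs))
  # weekly edge weights survive the round trip
  g1 <- m$networks$proximity$weekly_graphs[[1]]
  g2 <- rt$networks$proximity$weekly_graphs[[1]]
  expect_equal(igraph::ecount(g1), igraph::ecount(g2))
  expect_equal(sum(igraph::E(g1)$weight), sum(igraph::E(g2)$weight))
})

test_that("gender composition and channel density ordering match the study
           conditions", {
  m <- generate(generator_config(n_female = 166, n_male = 601, n_weeks = 1,
                                 seed = 2))
  share <- mean(m$cohort$participants$gender == "M")
  expect_equal(share, 601 / 767, tolerance = 1e-12)
  expect_equal(round(100 * share), 78)
  dens <- vapply(c("proximity", "facebook_friend", "call"), function(ch) {
    g <- m$networks[[ch]]$weekly_graphs[["0"]]
    if (is.null(g)) return(0)
    active_dyad_fraction(g, 767)
  }, numeric(1))
  expect_true(dens["proximity"] > 10 * dens["facebook_friend"])
  expect_true(dens["facebook_friend"] > dens["call"])
})

test_that("h = 0 reproduces the random-mixing same-gender fraction", {
  profs <- list(proximity = list(density = 0.15, homophily = 0,
                                 weight_mean = 1))
  fracs <- vapply(1:25, function(s) {
    m <- generate(generator_config(
      n_female = 25, n_male = 75, n_weeks = 1, seed = s,
      channel_profiles = profs, missing_rate = 0, p_active = 1))
    d <- count_motifs(m$networks$proximity$weekly_graphs[["0"]])$dyads
    (d[["FF"]] + d[["MM"]]) / sum(d)
  }, numeric(1))
  expect_equal(mean(fracs), expected_same_gender_fraction(25, 75, 0),
               tolerance = 0.02)
})

test_that("same-gender dyad fraction increases monotonically in h", {
  expect_true(all(diff(vapply(seq(0, 0.9, 0.1), function(h)
    expected_same_gender_fraction(166, 601, h), numeric(1))) > 0))
  obs <- vapply(c(0, 0.4, 0.8), function(h) {
    m <- generate(generator_config(
      n_female = 30, n_male = 70, n_weeks = 2, seed = 10,
      channel_profiles = list(proximity = list(density = 0.2,
                                               homophily = h,
                                               weight_mean = 1)),
      missing_rate = 0, p_active = 1))
    d <- count_motifs(m$networks$proximity$weekly_graphs[["0"]])$dyads
    (d[["FF"]] + d[["MM"]]) / sum(d)
  }, numeric(1))
  expect_true(all(diff(obs) > 0))
})

test_that("per-category missingness hits the configured MCAR rate", {
  m <- generate(generator_config(n_female = 150, n_male = 450, n_weeks = 1,
                                 seed = 8, missing_rate = 0.2))
  expect_equal(mean(m$missing_categories), 0.2, tolerance = 0.035)
  # masked personality rows really are blank in the trait table
  masked <- rownames(m$missing_categories)[m$missing_categories[, "personality"]]
  expect_true(all(is.na(m$traits[m$traits$id %in% masked, "neuroticism"])))
})

test_that("infeasible density and homophily combinations are rejected", {
  cfg <- generator_config(
    n_female = 10, n_male = 10, n_weeks = 1,
    channel_profiles = list(proximity = list(density = 0.95,
                                             homophily = 0.9,
                                             weight_mean = 1)))
  expect_error(generate(cfg), "infeasible")
  expect_error(generator_config(channel_profiles = list(
    proximity = list(density = 0.1, homophily = 1.4, weight_mean = 1))),
    "homophily")
})
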