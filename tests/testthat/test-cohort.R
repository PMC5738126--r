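test_that("weekly aggregation merges unordered pairs and conserves weight", {
  coh <- tiny_cohort()
  rec <- data.frame(channel = "proximity", week = c(3L, 3L),
                    source = c("a", "b"), target = c("b", "a"),
                    weight = c(1, 2), duration_s = NA_real_,
                    initiator_is_source = NA)
  s <- aggregate_weekly(rec, "proximity", coh)
  expect_named(s$weekly_graphs, "3")
  g <- s$weekly_graphs[["3"]]
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 3)

  # records in different weeks give one graph each
  rec2 <- data.frame(channel = "proximity", week = c(1L, 2L),
                     source = "a", target = "b", weight = c(2, 5),
                     duration_s = NA_real_, initiator_is_source = NA)
  s2 <- aggregate_weekly(rec2, "proximity", coh)
  expect_setequal(names(s2$weekly_graphs), c("1", "2"))
  total <- sum(vapply(s2$weekly_graphs,
                      function(g) sum(igraph::E(g)$weight), numeric(1)))
  expect_equal(total, sum(rec2$weight))

  # empty record set -> empty series
  s3 <- aggregate_weekly(rec2[0, ], "proximity", coh)
  expect_length(s3$weekly_graphs, 0)
})

test_that("weight conservation holds on randomly generated record sets", {
  set.seed(42)
  ids <- sprintf("u%02d", 1:8)
  coh <- cohort(data.frame(id = ids,
                           gender = rep(c("F", "M"), 4)), 0:5)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    src <- sample(ids, n, replace = TRUE)
    tgt <- sample(ids, n, replace = TRUE)
    keep <- src != tgt
    rec <- data.frame(channel = "text", week = sample(0:5, sum(keep), TRUE),
                      source = src[keep], target = tgt[keep],
                      weight = sample(1:4, sum(keep), TRUE),
                      duration_s = NA_real_,
                      initiator_is_source = TRUE)
    s <- aggregate_weekly(rec, "text", coh)
    total <- sum(vapply(s$weekly_graphs,
                        function(g) sum(igraph::E(g)$weight), numeric(1)))
    expect_equal(total, sum(rec$weight))
  }
})

test_that("activity filter keeps >= 4 active weeks and is idempotent", {
  parts <- data.frame(id = c("a", "b", "c"), gender = c("F", "M", "M"))
  coh <- cohort(parts, 0:9,
                active_weeks = list(a = 0:2, b = 0:3, c = integer(0)))
  f <- filter_active(coh)
  expect_equal(f$participants$id, "b")     # 3 active weeks are excluded
  expect_identical(filter_active(f)$participants, f$participants)
  expect_equal(nrow(filter_active(cohort(parts, 0:9))$participants), 0)
})

test_that("weekly averaging skips undefined weeks and propagates missing", {
  expect_equal(weekly_average(c(2, 4)), 3)
  expect_equal(weekly_average(5), 5)
  expect_equal(weekly_average(c(1, NA, 4)), 2.5)
  expect_true(is.na(weekly_average(numeric(0))))
})

test_that("cohort construction enforces its invariants", {
  parts <- data.frame(id = c("a", "a"), gender = c("F", "M"))
  expect_error(cohort(parts, 0:1), "unique")
  expect_error(cohort(data.frame(id = "a", gender = "X"), 0:1), "gender")
  expect_error(cohort(data.frame(id = "a", gender = "F"), c(0, 2)),
               "contiguous")
  expect_error(cohort(data.frame(id = "a", gender = "F"), 0:1,
                      active_weeks = list(a = 5L)), "within")
})

test_that("read_cohort rejects dangling ids and malformed files", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(id = c("a", "b"), gender = c("F", "M")),
            file.path(dir, "participants.csv"), row.names = FALSE)
  write.csv(data.frame(channel = "call", week = 0, source = "a",
                       target = "zz", weight = 1, duration_s = 10,
                       initiator_is_source = TRUE),
            file.path(dir, "interactions.csv"), row.names = FALSE)
  write.csv(data.frame(id = character(0), week = integer(0),
                       location_id = character(0),
                       time_fraction = numeric(0)),
            file.path(dir, "locations.csv"), row.names = FALSE)
  write.csv(data.frame(id = "a", neuroticism = 1),
            file.path(dir, "traits.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "referential-integrity")

  # fix the dangling id: now loads, with one weekly call edge
  write.csv(data.frame(channel = "call", week = 0, source = "a",
                       target = "b", weight = 1, duration_s = 10,
                       initiator_is_source = TRUE),
            file.path(dir, "interactions.csv"), row.names = FALSE)
  model <- read_cohort(dir, n_weeks = 2)
  expect_equal(nrow(model$cohort$participants), 2)
  expect_equal(igraph::ecount(model$networks$call$weekly_graphs[["0"]]), 1)
  expect_length(model$networks$proximity$weekly_graphs, 0)

  # a column missing entirely is a parse error naming the file
  unlink(file.path(dir, "traits.csv"))
  write.csv(data.frame(x = 1), file.path(dir, "traits.csv"),
            row.names = FALSE)
  expect_error(read_cohort(dir), "traits.csv")
})
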