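test_that("degree and same-gender fraction handle isolates and alters", {
  gen <- c(a = "F", b = "F", c = "F", d = "M", e = "M")
  g <- make_graph(cbind(from = c("a", "a", "a"),
                        to = c("b", "c", "d")), gen)
  expect_equal(node_degree(g, "a"), 3)
  expect_equal(same_gender_fraction(g, "a"), 2 / 3)
  expect_equal(node_degree(g, "e"), 0)
  expect_true(is.na(same_gender_fraction(g, "e")))
  # unknown-gender alters count for degree but not for homophily
  gen2 <- c(a = "F", b = "F", x = NA)
  g2 <- make_graph(cbind(from = c("a", "a"), to = c("b", "x")), gen2)
  expect_equal(node_degree(g2, "a"), 2)
  expect_equal(same_gender_fraction(g2, "a"), 1)
})

test_that("betweenness matches hand values on path, star and cycle", {
  gen <- c(a = "F", b = "M", c = "F")
  path <- make_graph(cbind(c("a", "b"), c("b", "c")), gen)
  expect_equal(unname(betweenness_centrality(path, "b")), 1)
  gen4 <- c(h = "F", l1 = "M", l2 = "M", l3 = "F")
  star <- make_graph(cbind(rep("h", 3), c("l1", "l2", "l3")), gen4)
  expect_equal(unname(betweenness_centrality(star, "h")), 3)
  cyc <- make_graph(cbind(c("h", "l1", "l2", "l3"),
                          c("l1", "l2", "l3", "h")), gen4)
  expect_equal(unname(betweenness_centrality(cyc)), rep(0.5, 4))
})

test_that("betweenness agrees exactly with the all-pairs BFS oracle", {
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    adj <- random_adj(n, runif(1, 0.1, 0.5))
    g <- adj_to_graph(adj)
    expect_equal(unname(betweenness_centrality(g)), brute_betweenness(adj),
                 tolerance = 1e-12)
  }
})

test_that("interaction entropy hits closed forms and its bound", {
  expect_equal(interaction_entropy(rep(1, 4)), 2, tolerance = 1e-9)
  expect_equal(interaction_entropy(5), 0)
  expect_equal(interaction_entropy(c(2, 1, 1)), 1.5, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:15) {
    w <- rgamma(sample(2:10, 1), 2)
    expect_lte(interaction_entropy(w), log2(length(w)) + 1e-12)
  }
  expect_error(interaction_entropy(c(1, 0)), "positive")
  expect_true(is.na(interaction_entropy(numeric(0))))
})

test_that("motif counts classify dyads/triads and conserve totals", {
  gen <- c(a = "F", b = "F", c = "M", d = "M")
  ff <- make_graph(cbind("a", "b"), gen)
  expect_equal(count_motifs(ff)$dyads, c(FF = 1L, MM = 0L, FM = 0L))
  k4 <- make_graph(cbind(c("a", "a", "a", "b", "b", "c"),
                         c("b", "c", "d", "c", "d", "d")), gen)
  m <- count_motifs(k4)
  expect_equal(sum(m$dyads), igraph::ecount(k4))
  expect_equal(m$triads, c(FFF = 0L, MMM = 0L, mixed = 4L))
  tri <- make_graph(cbind(c("a", "b", "x"), c("b", "x", "a")),
                    c(a = "F", b = "F", x = "F"))
  expect_equal(count_motifs(tri)$triads, c(FFF = 1L, MMM = 0L, mixed = 0L))
})

test_that("motif totals match a brute-force triangle enumerator", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    adj <- random_adj(n, runif(1, 0.15, 0.5))
    gen <- sample(c("F", "M"), n, replace = TRUE)
    g <- adj_to_graph(adj, gen)
    m <- count_motifs(g)
    tris <- brute_triangles(adj)
    expect_equal(sum(m$triads), length(tris))
    expect_equal(sum(m$dyads), sum(adj) / 2)
    nf <- vapply(tris, function(t) sum(gen[t] == "F"), numeric(1))
    expect_equal(unname(m$triads["FFF"]), sum(nf == 3))
    expect_equal(unname(m$triads["MMM"]), sum(nf == 0))
  }
})

test_that("active dyad fraction is edges over potential dyads", {
  gen <- setNames(rep(c("F", "M"), length.out = 5), letters[1:5])
  g <- make_graph(cbind(c("a", "b", "c"), c("b", "c", "d")), gen)
  expect_equal(active_dyad_fraction(g, 5), 0.3)
  k4 <- make_graph(cbind(c("a", "a", "a", "b", "b", "c"),
                         c("b", "c", "d", "c", "d", "d")),
                   gen[1:4])
  expect_equal(active_dyad_fraction(k4, 4), 1)
  empty <- make_graph(cbind(character(0), character(0)), gen)
  expect_equal(active_dyad_fraction(empty, 10), 0)
  expect_error(active_dyad_fraction(g, 1), "at least 2")
})

test_that("call duration means are stratified by ordered gender pair", {
  labels <- c(m1 = "M", m2 = "M", f1 = "F", f2 = "F")
  ev <- data.frame(initiator = c("m1", "m2", "f1"),
                   receiver = c("f1", "f2", "f2"),
                   duration_s = c(100, 134, 60))
  s <- call_duration_stats(ev, labels)
  expect_equal(unname(s["MF"]), 117)
  expect_equal(unname(s["FF"]), 60)
  expect_true(is.na(s["MM"]))
  # same-gender strata are direction-symmetric: initiator order irrelevant
  ev2 <- data.frame(initiator = c("f1", "f2"), receiver = c("f2", "f1"),
                    duration_s = c(10, 30))
  expect_equal(unname(call_duration_stats(ev2, labels)["FF"]), 20)
})

test_that("network indicator table averages weekly metrics per participant", {
  coh <- cohort(data.frame(id = c("a", "b", "c"),
                           gender = c("F", "M", "M")), 0:1,
                active_weeks = list(a = 0:1, b = 0:1, c = 0:1))
  rec <- data.frame(
    channel = "call", week = c(0L, 0L, 1L),
    source = c("a", "a", "a"), target = c("b", "c", "b"),
    weight = c(2, 2, 1), duration_s = 30, initiator_is_source = TRUE)
  networks <- setNames(lapply(CHANNELS, function(ch)
    aggregate_weekly(rec, ch, coh)), CHANNELS)
  tab <- network_indicator_table(coh, networks)
  expect_equal(tab["a", "call_degree"], mean(c(2, 1)))
  expect_equal(tab["a", "call_entropy"], mean(c(1, 0)))
  expect_equal(tab["a", "call_same_gender_fraction"], 0)
  # empty channels leave their columns missing
  expect_true(all(is.na(tab$proximity_degree)))
})
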