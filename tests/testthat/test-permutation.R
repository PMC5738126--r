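test_that("gender permutation conserves label counts and is seeded", {
  labels <- setNames(rep(c("F", "M"), c(16, 60)), sprintf("p%02d", 1:76))
  p1 <- permute_genders(labels, seed = 4)
  expect_equal(sort(names(p1)), sort(names(labels)))
  expect_equal(sum(p1 == "F"), sum(labels == "F"))
  expect_equal(sum(p1 == "M"), sum(labels == "M"))
  expect_identical(p1, permute_genders(labels, seed = 4))
  # 2-node cohort: both assignments occur
  two <- c(a = "F", b = "M")
  set.seed(1)
  seen <- unique(replicate(50, paste(permute_genders(two), collapse = "")))
  expect_setequal(seen, c("FM", "MF"))
})

test_that("z-score matches hand computation and flags degenerate nulls", {
  expect_equal(z_score(5, c(2, 4)), sqrt(2))
  expect_equal(z_score(3, c(2, 4)), 0)
  expect_equal(z_score(5, c(3, 3, 3)), Inf)
  expect_equal(z_score(1, c(3, 3, 3)), -Inf)
  expect_equal(z_score(3, c(3, 3, 3)), 0)
})

test_that("permutation p-values count strictly beyond the observed value", {
  null <- 1:10
  expect_equal(permutation_pvalue(11, null, "greater"), 0)
  expect_equal(permutation_pvalue(0, null, "less"), 0)
  expect_equal(permutation_pvalue(5, null, "greater"), 0.5)
  expect_equal(permutation_pvalue(5, null, "less"), 0.4)
  expect_equal(permutation_pvalue(5, null, "greater", correction = TRUE),
               6 / 11)
})

test_that("sampled homophily test matches exhaustive label enumeration on a
           6-node graph", {
  # 6 nodes, 2 female: C(6,2)=15 equally likely placements
  gen <- c(a = "F", b = "F", c = "M", d = "M", e = "M", f = "M")
  g <- make_graph(cbind(c("a", "a", "b", "c", "d", "e", "a"),
                        c("b", "c", "c", "d", "e", "f", "f")), gen)
  el <- igraph::as_edgelist(g, names = FALSE)
  placements <- combn(6, 2)
  exact_ff <- apply(placements, 2, function(fem) {
    lab <- rep("M", 6); lab[fem] <- "F"
    sum(lab[el[, 1]] == "F" & lab[el[, 2]] == "F")
  })
  ht <- homophily_test(g, n_perm = 4000, seed = 9)
  z_exact <- (ht$observed[["dyad_FF"]] - mean(exact_ff)) / sd(exact_ff)
  expect_lt(abs(ht$z[["dyad_FF"]] - z_exact), 0.15)
  p_exact <- mean(exact_ff > ht$observed[["dyad_FF"]])
  expect_lt(abs(ht$p_greater[["dyad_FF"]] - p_exact), 0.03)
})

test_that("labels independent of topology give near-zero mean z", {
  set.seed(31)
  zs <- replicate(30, {
    adj <- random_adj(18, 0.3)
    gen <- sample(rep(c("F", "M"), c(6, 12)))
    g <- adj_to_graph(adj, gen)
    homophily_test(g, n_perm = 120)$z[["dyad_FF"]]
  })
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("complementary indicators have equal and opposite z when totals are
           fixed", {
  set.seed(12)
  adj <- random_adj(20, 0.3)
  gen <- sample(rep(c("F", "M"), 10))
  ht <- homophily_test(adj_to_graph(adj, gen), n_perm = 300, seed = 2)
  same <- ht$observed[["dyad_FF"]] + ht$observed[["dyad_MM"]]
  null_same <- ht$null_values[, "dyad_FF"] + ht$null_values[, "dyad_MM"]
  expect_equal(z_score(same, null_same),
               -ht$z[["dyad_FM"]], tolerance = 1e-10)
  # every permuted realization conserves the edge total
  expect_true(all(rowSums(
    ht$null_values[, c("dyad_FF", "dyad_MM", "dyad_FM")]) ==
      igraph::ecount(adj_to_graph(adj, gen))))
})
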