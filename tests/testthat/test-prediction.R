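# Small separable/noise feature builders shared by the protocol tests.
# The signal is a two-point mass (+/-1) so the classes are separated by a
# margin every split-based learner places its threshold inside.
sep_data <- function(n = 80, seed = 1) {
  set.seed(seed)
  lab <- factor(rep(c("M", "F"), length.out = n), levels = c("M", "F"))
  x <- data.frame(s1 = ifelse(lab == "F", 1, -1),
                  s2 = rnorm(n), s3 = rnorm(n))
  rownames(x) <- sprintf("p%03d", 1:n)
  list(x = x, y = lab)
}

test_that("random baselines reflect the class imbalance analytically", {
  lab <- rep(c("F", "M"), c(166, 601))
  b <- random_baselines(lab)
  expect_equal(b$auc_random, 0.5)
  expect_equal(b$f1_random, 166 / 767)
  expect_equal(round(b$f1_random, 2), 0.22)
  expect_equal(random_baselines(rep(c("F", "M"), 50))$f1_random, 0.5)
  expect_error(random_baselines(rep("M", 10)), "both classes")
  mc <- random_f1_montecarlo(lab, n_sim = 2e4, seed = 1)
  expect_equal(mc, 166 / 767, tolerance = 0.01)
})

test_that("F1 and AUC follow the female-positive convention", {
  truth <- c("F", "F", "M", "M")
  expect_equal(f1_score(truth, c("F", "M", "M", "M")), 2 / 3)
  expect_equal(f1_score(truth, c("M", "M", "M", "M")), 0)
  expect_equal(roc_auc(truth, c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(truth, c(0.1, 0.2, 0.8, 0.9)), 0)
  # invariance under strictly monotone transforms of the scores
  set.seed(8)
  sc <- rnorm(40); tr <- sample(c("F", "M"), 40, replace = TRUE)
  expect_equal(roc_auc(tr, sc), roc_auc(tr, exp(3 * sc)))
})

test_that("perfectly separable features give AUC 1 for every family", {
  d <- sep_data()
  rep_ <- tune_and_evaluate(d$x, d$y, grid = small_model_grid(60),
                            n_folds = 5, seed = 42)
  expect_setequal(rep_$models$model,
                  c("logistic", "random_forest", "gradient_boosting",
                    "adaboost", "svc"))
  expect_true(all(rep_$models$auc == 1))
  expect_true(all(rep_$models$f1 == 1))
})

test_that("permuted labels keep AUC near chance (no leakage)", {
  set.seed(303)
  grid <- list(logistic = data.frame(C = c(0.1, 1, 10)))
  aucs <- vapply(1:12, function(i) {
    n <- 150
    x <- data.frame(matrix(rnorm(n * 5), n))
    rownames(x) <- sprintf("p%03d", 1:n)
    y <- factor(sample(rep(c("M", "F"), c(110, 40))), levels = c("M", "F"))
    tune_and_evaluate(x, y, grid = grid, n_folds = 5)$models$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_true(all(abs(aucs - 0.5) < 0.2))
})

test_that("evaluation is reproducible for a fixed seed", {
  d <- sep_data(n = 60, seed = 2)
  g <- list(logistic = data.frame(C = 1),
            random_forest = data.frame(max_features = "sqrt",
                                       n_estimators = 50,
                                       stringsAsFactors = FALSE))
  r1 <- tune_and_evaluate(d$x, d$y, grid = g, n_folds = 5, seed = 7)
  r2 <- tune_and_evaluate(d$x, d$y, grid = g, n_folds = 5, seed = 7)
  expect_identical(r1$models, r2$models)
  expect_identical(r1$importance, r2$importance)
})

test_that("feature importance is normalized and finds the informative
           feature", {
  set.seed(55)
  hits <- vapply(1:10, function(i) {
    n <- 120
    y <- factor(sample(rep(c("M", "F"), c(90, 30))), levels = c("M", "F"))
    x <- data.frame(signal = ifelse(y == "F", 1.5, 0) + rnorm(n),
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    noise3 = rnorm(n))
    imp <- feature_importance(x, y, n_estimators = 150)
    imp$feature[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(56)
  y <- factor(sample(rep(c("M", "F"), c(90, 30))), levels = c("M", "F"))
  x <- data.frame(a = rnorm(120), b = rnorm(120))
  imp <- feature_importance(x, y, n_estimators = 100)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
})

test_that("assemble_features tags every column with one family", {
  m <- generate(generator_config(n_female = 10, n_male = 30, n_weeks = 2,
                                 seed = 4, missing_rate = 0))
  coh <- filter_active(m$cohort, 1)
  mob <- mobility_indicator_table(coh, m$locations)
  net <- network_indicator_table(coh, m$networks)
  asm <- assemble_features(coh, m$traits, mob, net)
  expect_equal(nrow(asm$features), nrow(coh$participants))
  expect_setequal(unique(asm$families),
                  c("BFI", "personality", "mobility", "network"))
  expect_equal(sum(asm$families == "BFI"), 5)
  expect_named(asm$families, names(asm$features))
  expect_equal(levels(asm$labels), c("M", "F"))
})
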