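test_that("feature and misclassification intersections follow set algebra", {
  res <- structure(list(
    per_method = list(
      sprm = list(selected_features = c("A", "B", "C")),
      rskc = list(selected_features = c("B", "C")),
      enetlts = list(selected_features = c("B", "C", "D")))),
    class = "rosie_result")
  common <- Reduce(intersect, lapply(res$per_method, `[[`, "selected_features"))
  expect_setequal(common, c("B", "C"))
})

test_that("three identical rankings reproduce that ranking's order", {
  s <- c(9, 2, 7, 4, 1)
  cons <- consensus_outliers(list(a = s, b = s, c = s), paste0("x", 1:5))
  expect_equal(order(cons$table$rp), order(-s))
  expect_equal(cons$table$rp, rank_with_ties(s)^3)
})

test_that("single-point grids are returned as-is and choices are deterministic", {
  fx <- make_separable_fixture(n = 30, p = 8, delta = 4)
  ctl <- rosie_control(sprm = list(n_components_grid = 1L, eta_grid = 0.6),
                       rskc = list(alpha_grid = 0.1, l1_grid = 2,
                                   n_init = 2L, n_permutations = 3L),
                       enetlts = list(alpha_grid = 0.5, lambda_grid = 0.05,
                                      n_starts = 5L, n_keep = 2L))
  hp_s <- optimize_hyperparameters(fx$X, fx$labels, "sprm", ctl, seed = 1)
  expect_equal(hp_s, list(n_components = 1L, eta = 0.6))
  hp_r <- optimize_hyperparameters(fx$X, fx$labels, "rskc", ctl, seed = 1)
  expect_equal(hp_r, list(alpha = 0.1, l1_bound = 2))
  hp_e <- optimize_hyperparameters(fx$X, fx$labels, "enetlts", ctl, seed = 1)
  expect_equal(hp_e, list(alpha_mix = 0.5, lambda = 0.05))
  # determinism under a fixed seed with real grids
  ctl2 <- rosie_control(sprm = list(n_components_grid = 1:2,
                                    eta_grid = c(0.3, 0.7)))
  a <- optimize_hyperparameters(fx$X, fx$labels, "sprm", ctl2, seed = 5)
  b <- optimize_hyperparameters(fx$X, fx$labels, "sprm", ctl2, seed = 5)
  expect_identical(a, b)
})

test_that("CV prefers the sparser SPRM model among equal-error grid points", {
  fx <- make_separable_fixture(n = 40, p = 10, delta = 6)
  ctl <- rosie_control(sprm = list(n_components_grid = 1L,
                                   eta_grid = c(0, 0.5, 0.9)))
  hp <- optimize_hyperparameters(fx$X, fx$labels, "sprm", ctl, seed = 2)
  # every eta separates this fixture perfectly; the largest (sparsest) wins
  expect_equal(hp$eta, 0.9)
})

test_that("an end-to-end run flags planted outliers and intersects features", {
  sim <- simulate_scenario("label_switch_5", n = 60, p = 80,
                           n_informative = 16, effect_size = 1.6, seed = 1)
  res <- run_rosie(sim$X, sim$y_observed, control = fast_control(),
                   seed = 1, optimize = FALSE)
  expect_s3_class(res, "rosie_result")
  expect_length(res$consensus$table$rp, 60L)
  # planted outliers sit below the median rank product
  expect_true(all(res$consensus$table$rp[sim$outlier_truth] <
                    median(res$consensus$table$rp)))
  expect_true(all(res$common_features %in%
                    res$per_method$sprm$selected_features))
  expect_lte(length(res$common_features),
             min(vapply(res$per_method, function(m)
               length(m$selected_features), numeric(1))))
  # same seed reproduces the result
  res2 <- run_rosie(sim$X, sim$y_observed, control = fast_control(),
                    seed = 1, optimize = FALSE)
  expect_equal(res$consensus$table, res2$consensus$table)
  expect_equal(res$common_features, res2$common_features)
})

test_that("shuffling sample order leaves influential IDs and features unchanged", {
  sim <- simulate_scenario("label_switch_5", n = 60, p = 80,
                           n_informative = 16, effect_size = 1.6, seed = 2)
  res1 <- run_rosie(sim$X, sim$y_observed, control = fast_control(),
                    seed = 3, optimize = FALSE)
  set.seed(77)
  perm <- sample(60)
  Xp <- expression_matrix(sim$X$values[perm, ], sim$X$sample_ids[perm],
                          sim$X$feature_ids)
  labp <- class_labels(sim$y_observed$y[perm], Xp$sample_ids)
  res2 <- run_rosie(Xp, labp, control = fast_control(),
                    seed = 3, optimize = FALSE)
  expect_setequal(res1$consensus$influential, res2$consensus$influential)
  expect_setequal(res1$common_features, res2$common_features)
})

test_that("a failing ensemble member aborts the run naming the method", {
  fx <- make_separable_fixture(n = 20, p = 6, delta = 4)
  ctl <- fast_control()
  ctl$sprm$n_components_grid <- 50L  # exceeds rank -> sprm must fail
  expect_error(run_rosie(fx$X, fx$labels, control = ctl, seed = 1,
                         optimize = FALSE,
                         hyperparameters = list(
                           sprm = list(n_components = 50L, eta = 0.5))),
               "sprm")
})

test_that("result files are written in the documented layout", {
  sim <- simulate_scenario("label_switch_5", n = 40, p = 40,
                           n_informative = 10, effect_size = 2, seed = 4)
  res <- run_rosie(sim$X, sim$y_observed, control = fast_control(),
                   seed = 1, optimize = FALSE)
  dir <- tempfile("rosie_out")
  write_rosie_result(res, dir)
  expect_true(file.exists(file.path(dir, "consensus.tsv")))
  expect_true(file.exists(file.path(dir, "common_features.tsv")))
  cons <- read.delim(file.path(dir, "consensus.tsv"))
  expect_equal(nrow(cons), 40L)
  expect_true(all(c("sample_id", "rp", "p", "q", "influential") %in%
                    names(cons)))
})
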