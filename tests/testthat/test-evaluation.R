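test_that("masked RMSE matches hand arithmetic and rejects empty masks", {
  expect_equal(rmse_masked(c(1, 5), c(1, 5)), 0)
  expect_equal(rmse_masked(c(3, 3), c(1, 5)), 2)
  expect_equal(rmse_masked(c(3, 999), c(1, 5), c(TRUE, FALSE)), 2)
  expect_error(rmse_masked(c(3, 3), c(1, 5), c(FALSE, FALSE)),
               "no evaluable")
  expect_error(rmse_masked(c(1, 2, 3), c(1, 2)), "equal shape")
})

test_that("masked RMSE ignores masked values entirely and is symmetric", {
  withr::with_seed(6, {
    for (i in 1:10) {
      p <- rnorm(20); a <- rnorm(20)
      mask <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.7, 0.3))
      if (!any(mask)) mask[1] <- TRUE
      base <- rmse_masked(p, a, mask)
      fuzzed <- p
      fuzzed[!mask] <- rnorm(sum(!mask), 0, 1e6)
      expect_identical(rmse_masked(fuzzed, a, mask), base)
      expect_equal(rmse_masked(a, p, mask), base)
    }
  })
})

test_that("walk-forward makes 387 examples from a 2322-sample test series", {
  n <- 2322
  tgt <- make_cgm(rep(120, n) + sin(seq_len(n) / 40))
  rep_ <- walk_forward_evaluate(NULL, matrix(tgt$values, ncol = 1), tgt,
                                window_spec(),
                                predict_fn = function(inp) {
                                  matrix(120, dim(inp)[1], 6)
                                })
  expect_equal(rep_$n_examples, 387)
  expect_equal(rep_$n_evaluated + rep_$n_masked, 387 * 6)
})

test_that("a perfect oracle scores zero and persistence beats nothing", {
  withr::with_seed(12, x <- 120 + cumsum(rnorm(300)))
  tgt <- make_cgm(x)
  mat <- matrix(x, ncol = 1)
  oracle <- function(inp) {
    offs <- seq(0, by = 6, length.out = dim(inp)[1])
    t(vapply(offs, function(o) {
      out <- x[(o + 7):(o + 12)]
      out[is.na(out)] <- 0
      out
    }, numeric(6)))
  }
  perfect <- walk_forward_evaluate(NULL, mat, tgt, window_spec(),
                                   predict_fn = oracle)
  expect_equal(perfect$rmse, 0)

  persistence <- walk_forward_evaluate(NULL, mat, tgt, window_spec(),
                                       predict_fn = function(inp) {
                                         matrix(inp[, 6, 1], dim(inp)[1], 6)
                                       })
  expect_gt(persistence$rmse, 0)
})

test_that("a converged model beats the persistence baseline (seed median)", {
  rec <- simulate_patient(simulation_config(seed = 21, days = 14,
                                            gap_rate_per_day = 0,
                                            spike_prob = 0))
  rmses <- vapply(1:3, function(s) {
    suppressMessages(run_pipeline(
      rec, "C-03", window_spec(),
      mspec = model_spec(layer1_units = 32, layer2_units = 16),
      tspec = training_spec(max_epochs = 150, early_stop_patience = 15,
                            seed = s)))$report$rmse
  }, numeric(1))
  test <- assemble_feature_matrix(rec, "C-03", "test")
  persistence <- walk_forward_evaluate(NULL, test$matrix, test$target,
                                       window_spec(),
                                       predict_fn = function(inp) {
                                         matrix(inp[, 6, 1], dim(inp)[1], 6)
                                       })
  expect_lt(median(rmses), persistence$rmse)
})

test_that("evaluation report satisfies its count identity", {
  rec <- simulate_patient(simulation_config(seed = 3, days = 7))
  rec <- suppressMessages(preprocess_record(rec))
  test <- assemble_feature_matrix(rec, "C-01", "test")
  rep_ <- walk_forward_evaluate(NULL, test$matrix, test$target, window_spec(),
                                predict_fn = function(inp) {
                                  matrix(rowMeans(inp[, , 1, drop = FALSE]),
                                         dim(inp)[1], 6)
                                })
  expect_equal(rep_$n_evaluated + rep_$n_masked, rep_$n_examples * 6)
  expect_true(is.finite(rep_$rmse))
  expect_length(rep_$per_step_rmse, 6)
})

test_that("compare_configurations emits one row per cell and a median grid", {
  rec <- simulate_patient(simulation_config(seed = 5, days = 7))
  cmp <- suppressMessages(compare_configurations(
    rec, configs = "C-01", horizons_mins = 30,
    mspec = model_spec(layer1_units = 6, layer2_units = 3),
    tspec = training_spec(max_epochs = 3, early_stop_patience = 3),
    seeds = 1))
  expect_equal(nrow(cmp$runs), 1)
  expect_equal(nrow(cmp$summary), 1)
  expect_true(is.finite(cmp$summary$median_rmse))
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(cmp, path)
  expect_equal(nrow(read.csv(path)), 1)
})

test_that("without meal or insulin effects the extra channels are uninformative", {
  rec <- simulate_patient(simulation_config(seed = 8, days = 7,
                                            carb_gain_mgdl_per_g = 0,
                                            insulin_gain_mgdl_per_u = 0,
                                            gap_rate_per_day = 0,
                                            spike_prob = 0))
  cmp <- suppressMessages(compare_configurations(
    rec, configs = c("C-01", "C-03"), horizons_mins = 30,
    mspec = model_spec(layer1_units = 8, layer2_units = 4),
    tspec = training_spec(max_epochs = 10, early_stop_patience = 10),
    seeds = 1:3))
  med <- cmp$summary$median_rmse
  expect_true(all(is.finite(med)))
  # ablation control: with zero gains neither configuration should hold a
  # large systematic advantage
  expect_lt(abs(diff(med)) / min(med), 0.5)
})
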