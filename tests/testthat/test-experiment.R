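tiny_config <- function(...) {
  experiment_config(tau_list = 20, grid_list = 16, out_pixels = 16,
                    epochs = 8, train_beats = 25, val_beats = 10,
                    seed = 0, ...)
}

tiny_fit <- function() {
  fixture("tiny_fit", function() {
    ports <- small_portraits()
    parts <- split_beats(ports, 25, 10)
    train_model(parts$train, parts$validation, spec = tiny_spec(3),
                config = tiny_config())
  })
}

test_that("beat splitting is chronological and per subject", {
  beats <- tibble::tibble(
    subject_id = rep(c("a", "b"), c(125, 126)),
    beat = c(seq_len(125), seq_len(126))
  )
  parts <- split_beats(beats, 100, 25)
  expect_equal(nrow(parts$train), 200)
  expect_equal(nrow(parts$validation), 50)
  a_train <- parts$train$beat[parts$train$subject_id == "a"]
  a_val <- parts$validation$beat[parts$validation$subject_id == "a"]
  expect_equal(a_train, 1:100)
  expect_equal(a_val, 101:125)
  expect_length(intersect(a_train, a_val), 0)
  # subject b's 126th beat goes unused
  expect_false(126 %in% parts$validation$beat)

  short <- tibble::tibble(subject_id = "c", beat = seq_len(120))
  expect_message(parts2 <- split_beats(short, 100, 25), "dropping")
  expect_equal(nrow(parts2$train), 0)
})

test_that("training identifies subjects and is deterministic in its seed", {
  fit <- tiny_fit()
  expect_s3_class(fit, "psr_model")
  expect_equal(nrow(fit$trace), 8)
  expect_true(all(fit$trace$val_accuracy >= 0 &
                    fit$trace$val_accuracy <= 100))
  expect_gte(max(fit$trace$val_accuracy), 90)

  ports <- small_portraits()
  parts <- split_beats(ports, 25, 10)
  fit2 <- train_model(parts$train, parts$validation, spec = tiny_spec(3),
                      config = tiny_config())
  expect_identical(fit$trace, fit2$trace)
})

test_that("an untrained network scores at chance level", {
  ports <- small_portraits()
  parts <- split_beats(ports, 25, 10)
  cfg <- tiny_config()
  cfg$epochs <- 0L
  fit0 <- train_model(parts$train, parts$validation, spec = tiny_spec(3),
                      config = cfg)
  expect_equal(nrow(fit0$trace), 0)
  acc <- evaluate_model(fit0, parts$validation)
  n <- nrow(parts$validation)
  chance <- 100 / 3
  sd3 <- 3 * 100 * sqrt((1 / 3) * (2 / 3) / n)
  expect_lte(abs(acc - chance), sd3)
})

test_that("evaluation computes percent-correct under arg-max prediction", {
  fit <- tiny_fit()
  ports <- small_portraits()
  parts <- split_beats(ports, 25, 10)
  val <- parts$validation
  acc <- evaluate_model(fit, val)
  # manual recomputation from the predicted probabilities
  p <- predict_proba(fit$model, val$portrait)
  pred <- fit$classes[max.col(t(p), ties.method = "first")]
  expect_equal(acc, 100 * mean(pred == val$subject_id))
  # known prediction tables: all correct and one error
  all_right <- val
  all_right$subject_id <- pred
  expect_equal(evaluate_model(fit, all_right), 100)
  one_wrong <- all_right
  other <- setdiff(fit$classes, one_wrong$subject_id[1])[1]
  one_wrong$subject_id[1] <- other
  expect_equal(evaluate_model(fit, one_wrong),
               100 * (nrow(val) - 1) / nrow(val))
  expect_error(evaluate_model(fit, val[0, ]), "empty")
})

test_that("randomly permuted labels score near chance", {
  fit <- tiny_fit()
  ports <- small_portraits()
  parts <- split_beats(ports, 25, 10)
  val <- parts$validation
  withr::with_seed(17, {
    accs <- replicate(20, {
      shuffled <- val
      shuffled$subject_id <- sample(shuffled$subject_id)
      evaluate_model(fit, shuffled)
    })
  })
  expect_lt(abs(mean(accs) - 100 / 3), 10)
})

test_that("stage averages cover the four 15-epoch blocks", {
  st <- stage_averages(rep(100, 75))
  expect_equal(st$mean_accuracy, rep(100, 4))
  expect_equal(st$epochs, c("16~30", "31~45", "46~60", "61~75"))
  st2 <- stage_averages(as.numeric(1:75))
  expect_equal(st2$mean_accuracy, c(23, 38, 53, 68))
  # short traces report only complete stages
  expect_equal(nrow(stage_averages(as.numeric(1:45))), 2)
  withr::with_seed(2, tr <- runif(75, 0, 100))
  st3 <- stage_averages(tr)
  expect_true(all(st3$mean_accuracy >= vapply(
    list(16:30, 31:45, 46:60, 61:75), function(i) min(tr[i]), numeric(1))))
  expect_true(all(st3$mean_accuracy <= vapply(
    list(16:30, 31:45, 46:60, 61:75), function(i) max(tr[i]), numeric(1))))
})

test_that("the factorial sweep enumerates and completes its cells", {
  expect_equal(nrow(sweep_cells(experiment_config())), 50)
  expect_equal(nrow(sweep_cells(experiment_config(tau_list = 20,
                                                  grid_list = 32))), 1)

  cfg <- experiment_config(tau_list = c(8, 20), grid_list = c(8, 16),
                           out_pixels = 16, epochs = 2, train_beats = 25,
                           val_beats = 10, seed = 1)
  sweep <- run_sweep(small_beats(), cfg,
                     spec_builder = function(k) tiny_spec(k, px = 16))
  expect_s3_class(sweep, "psr_sweep")
  expect_equal(nrow(dplyr::distinct(sweep$results, tau_ms, grid)), 4)
  expect_equal(nrow(sweep$results), 4 * 2)
  expect_equal(nrow(sweep$failed), 0)
})

test_that("a failing sweep cell is recorded and the sweep continues", {
  # grid 64 cannot be resized down to 16 pixels -> that cell must fail
  cfg <- experiment_config(tau_list = 20, grid_list = c(16, 64),
                           out_pixels = 16, epochs = 1, train_beats = 25,
                           val_beats = 10, seed = 1)
  sweep <- run_sweep(small_beats(), cfg,
                     spec_builder = function(k) tiny_spec(k, px = 16))
  expect_equal(nrow(sweep$failed), 1)
  expect_equal(sweep$failed$grid, 64)
  expect_match(sweep$failed$reason, "out_pixels|>=")
  expect_equal(unique(sweep$results$grid), 16)
})

test_that("tidy and glance summarize fits and sweeps", {
  fit <- tiny_fit()
  td <- tidy(fit)
  expect_named(td, c("epoch", "val_accuracy"))
  gl <- glance(fit)
  expect_equal(gl$n_classes, 3)
  expect_equal(gl$final_accuracy, fit$trace$val_accuracy[8])
})
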