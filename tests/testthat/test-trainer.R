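test_that("learning-rate schedule halves every period", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(49999, cfg), 1e-4)
  expect_equal(lr_schedule(50000, cfg), 5e-5)
  expect_equal(lr_schedule(150000, cfg), 1.25e-5)
  expect_error(lr_schedule(-1, cfg))
})

test_that("training reduces the loss on a tiny focus task", {
  cfg <- train_config(lr = 3e-3, seed = 1)
  m <- tiny_model(base = 4L, seed = 1)
  data <- make_focus_dataset(4, c(16, 16), seed = 2, min_m = 2, max_m = 2)
  task <- task_spec("multi_focus", data, supervised = TRUE, epochs = 20)
  res <- train_task(m, task, ewc_state(), cfg, max_iterations = 60)
  tr <- res$trace
  expect_equal(nrow(tr), 60)
  expect_lt(mean(tail(tr$loss, 10)), mean(head(tr$loss, 10)))
  expect_true(all(diff(tr$lr) <= 0))
})

test_that("runs are deterministic and EWC weight zero matches an empty state", {
  cfg <- train_config(lr = 1e-3, seed = 7)
  data <- make_exposure_dataset(4, c(16, 16), seed = 3, K = 2)
  task <- task_spec("multi_exposure", data, supervised = TRUE, epochs = 5)
  m <- tiny_model(base = 4L, seed = 7)
  r1 <- train_task(m, task, ewc_state(), cfg, max_iterations = 20)
  r2 <- train_task(m, task, ewc_state(), cfg, max_iterations = 20)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$trace, r2$trace)
  # a non-empty state with lambda_ewc = 0 leaves the trajectory unchanged
  st <- ewc_accumulate(ewc_state(), lapply(m$params, function(p) p * 0 + 1),
                       m$params)
  w0 <- loss_weights(TRUE, lambda3 = 0)
  task0 <- task_spec("multi_exposure", data, supervised = TRUE, weights = w0,
                     epochs = 5)
  r3 <- train_task(m, task0, st, cfg, max_iterations = 20)
  expect_identical(r3$model$params, r1$model$params)
})

test_that("an interrupted run resumed from its checkpoint matches the straight run", {
  cfg <- train_config(lr = 1e-3, seed = 4)
  data <- make_focus_dataset(4, c(16, 16), seed = 5, min_m = 2, max_m = 2)
  task <- task_spec("multi_focus", data, supervised = TRUE, epochs = 8)
  m <- tiny_model(base = 4L, seed = 4)
  straight <- train_task(m, task, ewc_state(), cfg, max_iterations = 24)
  part1 <- train_task(m, task, ewc_state(), cfg, max_iterations = 12)
  part2 <- train_task(part1$model, task, ewc_state(), cfg,
                      max_iterations = 12,
                      resume = list(opt = part1$opt, done = 12L))
  expect_identical(part2$model$params, straight$model$params)
  expect_identical(part2$model$buffers, straight$model$buffers)
})

test_that("the trainer never mutates the EWC anchor or importance", {
  cfg <- train_config(lr = 1e-3, seed = 9)
  data <- make_focus_dataset(2, c(16, 16), seed = 9, min_m = 2, max_m = 2)
  task <- task_spec("multi_focus", data, supervised = TRUE, epochs = 5)
  m <- tiny_model(base = 4L, seed = 9)
  st <- ewc_accumulate(ewc_state(),
                       lapply(m$params, function(p) abs(p) + 0.1), m$params)
  snapshot <- st
  res <- train_task(m, task, st, cfg, max_iterations = 10)
  expect_identical(st$anchor, snapshot$anchor)
  expect_identical(st$importance, snapshot$importance)
  expect_true(all(res$trace$ewc >= 0))
  expect_gt(tail(res$trace$ewc, 1), 0)  # parameters moved off the anchor
})

test_that("a curriculum accumulates importance additively and reports per task", {
  cfg <- train_config(lr = 1e-3, seed = 11)
  d1 <- make_exposure_dataset(3, c(16, 16), seed = 12, K = 2)
  d2 <- make_focus_dataset(3, c(16, 16), seed = 13, min_m = 2, max_m = 2)
  tasks <- list(
    task_spec("multi_exposure", d1, supervised = TRUE, epochs = 2,
              importance_subset_size = 3),
    task_spec("multi_focus", d2, supervised = TRUE, epochs = 2,
              importance_subset_size = 3)
  )
  res <- run_curriculum(tasks, cfg, model = tiny_model(base = 4L, seed = 11))
  expect_equal(res$ewc_state$tasks_seen, 2L)
  expect_equal(res$iterations, 12L)
  expect_equal(nrow(res$report), 4)  # 2 stages x 2 evaluated tasks
  # Omega after both tasks = Omega(task1 subset) + Omega(task2 subset)
  m_after1 <- run_curriculum(tasks[1], cfg,
                             model = tiny_model(base = 4L, seed = 11))
  om1 <- m_after1$ewc_state$importance
  om2 <- setfuse:::task_importance(res$model, tasks[[2]], cfg,
                                   subset_seed = 2L)
  for (nm in names(om1)) {
    expect_equal(res$ewc_state$importance[[nm]], om1[[nm]] + om2[[nm]],
                 tolerance = 1e-12, info = nm)
  }
  # anchor is the final model
  expect_identical(res$ewc_state$anchor, res$model$params)
})

test_that("supervised tasks demand references and warn on off-range EWC weights", {
  d <- make_exposure_dataset(2, c(16, 16), seed = 14, K = 2)
  d[[1]]$reference <- NULL
  expect_error(task_spec("multi_exposure", d, supervised = TRUE), "reference")
  d2 <- make_focus_dataset(2, c(16, 16), seed = 15, min_m = 2, max_m = 2)
  t_off <- task_spec("multi_focus", d2, supervised = TRUE,
                     weights = loss_weights(TRUE, lambda3 = 5e4), epochs = 1)
  m <- tiny_model(base = 4L, seed = 1)
  st <- ewc_accumulate(ewc_state(), lapply(m$params, function(p) p * 0 + 1),
                       m$params)
  expect_warning(train_task(m, t_off, st, train_config(seed = 1),
                            max_iterations = 1), "advisory")
})
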