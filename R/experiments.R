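# Scaled-down reference experiments.
#
# Two qualitative effects of the full-scale method are reproduced at desk
# scale on the package's synthetic generators: (1) EWC-based continual
# learning retains the first task's performance after training a second
# task; (2) max pooling across streams beats sum pooling on the exposure
# task. The study conditions (frame size, network width, learning rate,
# iteration counts, set counts) are frozen here as the functions' defaults
# and motivated in the methods vignette; both functions are deterministic
# per seed.

# shared toy conditions
toy_conditions <- function(seed) {
  list(
    size = c(16L, 16L),
    net = net_config(base_channels = 8L),
    config = train_config(lr = 3e-3, seed = seed),
    n_train = 16L,
    n_eval = 8L,
    exposures = 3L
  )
}

toy_exposure_task <- function(tc, seed) {
  train <- make_exposure_dataset(tc$n_train, tc$size, seed = seed * 101L,
                                 K = tc$exposures)
  eval <- make_exposure_dataset(tc$n_eval, tc$size, seed = seed * 101L + 7L,
                                K = tc$exposures)
  task_spec("multi_exposure", train, supervised = TRUE, epochs = 40L,
            eval_data = eval, importance_subset_size = tc$n_train)
}

toy_focus_task <- function(tc, seed) {
  train <- make_focus_dataset(tc$n_train, tc$size, seed = seed * 211L,
                              min_m = 2L, max_m = 3L)
  task_spec("multi_focus", train, supervised = TRUE, epochs = 40L,
            importance_subset_size = tc$n_train)
}

#' Scaled-down EWC retention study
#'
#' Trains the exposure task to its toy-scale plateau, then trains the focus
#' task twice from that model — once with the EWC penalty anchored at the
#' exposure solution, once without — and measures how much the exposure
#' task's held-out MEF-SSIM degrades in each case. With functioning
#' continual learning the degradation with EWC is smaller.
#'
#' @param seed Integer seed; every data draw and the initialization derive
#'   from it.
#' @param iterations Length-2 vector: iterations for the first and second
#'   task (defaults 500 each).
#' @return List: `base` (exposure MEF-SSIM after task 1), `drop_no_ewc`,
#'   `drop_ewc` (degradation of that score after task 2, without/with EWC),
#'   and `focus_no_ewc`, `focus_ewc` (task-2 training MEF-SSIM reached).
#' @export
retention_study <- function(seed = 1L, iterations = c(500L, 500L)) {
  tc <- toy_conditions(seed)
  t1 <- toy_exposure_task(tc, seed)
  t2 <- toy_focus_task(tc, seed)
  model <- init_fusion_net(tc$net, seed = seed)
  r1 <- train_task(model, t1, ewc_state(), tc$config,
                   max_iterations = iterations[1])
  base <- evaluate_sets(r1$model, t1$eval_data, tc$config)$mef_ssim
  omega <- task_importance(r1$model, t1, tc$config)
  state <- ewc_accumulate(ewc_state(), omega, r1$model$params)
  r_no <- train_task(r1$model, t2, ewc_state(), tc$config,
                     iter_offset = iterations[1],
                     max_iterations = iterations[2])
  r_ewc <- train_task(r1$model, t2, state, tc$config,
                      iter_offset = iterations[1],
                      max_iterations = iterations[2])
  list(
    base = base,
    drop_no_ewc = base -
      evaluate_sets(r_no$model, t1$eval_data, tc$config)$mef_ssim,
    drop_ewc = base -
      evaluate_sets(r_ewc$model, t1$eval_data, tc$config)$mef_ssim,
    focus_no_ewc = evaluate_sets(r_no$model, t2$data, tc$config)$mef_ssim,
    focus_ewc = evaluate_sets(r_ewc$model, t2$data, tc$config)$mef_ssim
  )
}

#' Scaled-down pooling-ablation study
#'
#' Trains two otherwise identical networks on the same exposure data — one
#' aggregating streams by element-wise max, one by sum — and compares their
#' held-out MEF-SSIM.
#'
#' @param seed Integer seed.
#' @param iterations Training iterations per model (default 200).
#' @return List with `max` and `sum` held-out MEF-SSIM scores.
#' @export
pooling_study <- function(seed = 1L, iterations = 200L) {
  tc <- toy_conditions(seed)
  t1 <- toy_exposure_task(tc, seed)
  score <- function(pool) {
    net <- net_config(base_channels = tc$net$base_channels, pool = pool)
    model <- init_fusion_net(net, seed = seed)
    r <- train_task(model, t1, ewc_state(), tc$config,
                    max_iterations = iterations)
    evaluate_sets(r$model, t1$eval_data, tc$config)$mef_ssim
  }
  list(max = score("max"), sum = score("sum"))
}
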