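# Sequential (continual-learning) training.
#
# Tasks are trained one after another. Each task optimizes its own composite
# loss (MAE + MEF-SSIM when a reference exists, MEF-SSIM alone otherwise)
# plus the EWC penalty anchored at the previous tasks' parameters; the first
# task gets EWC weight 0. After a task finishes, the diagonal Fisher
# importance is estimated on a small subset of its data and accumulated into
# the EWC state together with the new anchor. Adam, batch size 1, learning
# rate halved every `lr_half_period` iterations (the iteration counter runs
# across tasks).

#' Task specification
#'
#' @param name One of `"medical"`, `"infrared_visible"`, `"multi_exposure"`,
#'   `"multi_focus"`, or any label for synthetic tasks.
#' @param data List of training sets; each set is
#'   `list(sources = list of H x W matrices, reference = matrix or NULL)`.
#' @param supervised Whether a reference ground truth is used (multi-exposure
#'   and multi-focus: `TRUE`; medical and infrared/visible: `FALSE`).
#' @param weights A [loss_weights()]; defaults chosen by `supervised`.
#' @param epochs Passes over `data` (>= 1).
#' @param eval_data Optional held-out sets for the curriculum report.
#' @param importance_subset_size Number of sets used for the Fisher
#'   importance estimate after training (default 50, capped at the data size).
#' @return A `task_spec` list.
#' @export
task_spec <- function(name, data, supervised, weights = NULL, epochs = 1L,
                      eval_data = NULL, importance_subset_size = 50L) {
  stopifnot(epochs >= 1L, length(data) >= 1L)
  if (is.null(weights)) weights <- loss_weights(supervised)
  if (supervised) {
    has_ref <- vapply(data, function(s) !is.null(s$reference), logical(1))
    if (!all(has_ref)) stop("supervised task '", name, "' has sets without a reference")
  }
  structure(list(name = name, data = data, supervised = supervised,
                 weights = weights, epochs = as.integer(epochs),
                 eval_data = eval_data,
                 importance_subset_size = as.integer(importance_subset_size)),
            class = "task_spec")
}

#' Training configuration
#'
#' Adam with `beta1 = 0.9`, `beta2 = 0.99`, initial learning rate `1e-4`
#' halved after every `5e4` iterations, batch size 1.
#'
#' @param lr Initial learning rate.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param lr_half_period Iterations between halvings of the learning rate.
#' @param seed Master seed; the full run is deterministic given it.
#' @param mef_params A [mef_ssim_params()] used in all losses/evaluations.
#' @param lambda3_warn_range Advisory range for the EWC weight; values
#'   outside it trigger a warning (results degrade for much larger weights).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.99,
                         adam_eps = 1e-8, lr_half_period = 5e4, seed = 1L,
                         mef_params = mef_ssim_params(),
                         lambda3_warn_range = c(1e4, 3e4)) {
  stopifnot(lr > 0, lr_half_period > 0)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 lr_half_period = lr_half_period, batch_size = 1L,
                 seed = as.integer(seed), mef_params = mef_params,
                 lambda3_warn_range = lambda3_warn_range),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr * 0.5 ^ floor(iteration / lr_half_period)`: 1e-4 at iteration 0,
#' 5e-5 at 5e4, 1.25e-5 at 1.5e5 under the defaults.
#'
#' @param iteration 0-based global iteration count.
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(iteration, config = train_config()) {
  stopifnot(all(iteration >= 0))
  config$lr * 0.5^(iteration %/% config$lr_half_period)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like), t = 0L)
}

adam_step <- function(params, grads, st, lr, config) {
  st$t <- st$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + config$adam_eps)
  }
  list(params = params, state = st)
}

# ---- per-iteration loss + gradient -----------------------------------------

# gradient of the task IQA loss (no EWC term) for one set; used both by the
# training step and by the Fisher importance estimate.
iqa_loss_grad <- function(model, set, weights, mef_params,
                          update_stats = TRUE, pool = NULL, benv = NULL) {
  builder <- function(tp, out) {
    nref <- nd_mef_ssim_loss(tp, set$sources, out, mef_params)
    if (weights$supervised) {
      mae <- nd_mae_loss(tp, out, set$reference)
      nd_add(nd_mulc(mae, weights$lambda1), nd_mulc(nref, weights$lambda2))
    } else {
      nd_mulc(nref, weights$lambda1)
    }
  }
  net_loss_grad(model, set$sources, builder, training = TRUE,
                update_stats = update_stats, clamp = TRUE, pool = pool,
                benv = benv)
}

ewc_weight_of <- function(weights) {
  if (weights$supervised) weights$lambda3 else weights$lambda2
}

#' Train one task
#'
#' Runs `epochs` passes over the task's sets (batch size 1, random order per
#' epoch, seeded), optimizing the task loss plus `lambda_ewc` times the EWC
#' penalty of `ewc_state`. An empty state — or `first_task = TRUE` — drops
#' the penalty. Deterministic per `config$seed`.
#'
#' @param model A `fusenet_model`.
#' @param task A [task_spec()].
#' @param ewc_state An [ewc_state()].
#' @param config A [train_config()].
#' @param iter_offset Global iteration count before this task (drives the
#'   learning-rate schedule across tasks).
#' @param first_task Force EWC weight 0 (automatic when the state is empty).
#' @param max_iterations Optional cap on the iterations taken in this call
#'   (useful for interrupt/resume and for scaled-down experiments).
#' @param resume Optional list `list(opt, done)` from a previous partial run
#'   (`$opt` as returned in the result, `done` = iterations already taken):
#'   continues the identical trajectory, since the per-epoch sample order is
#'   derived from the config seed alone.
#' @return List with updated `model`, `trace` (data.frame: iteration, lr,
#'   loss, iqa, ewc), `iterations` (completed so far) and `opt` (optimizer
#'   state, for resuming).
#' @export
train_task <- function(model, task, ewc_state, config, iter_offset = 0L,
                       first_task = FALSE, max_iterations = NULL,
                       resume = NULL) {
  lam_ewc <- ewc_weight_of(task$weights)
  if (first_task || ewc_state$tasks_seen == 0L) lam_ewc <- 0
  wr <- config$lambda3_warn_range
  if (lam_ewc > 0 && (lam_ewc < wr[1] || lam_ewc > wr[2])) {
    warning("EWC weight ", lam_ewc, " outside the advisory range [",
            wr[1], ", ", wr[2], "]")
  }
  n_sets <- length(task$data)
  n_total <- task$epochs * n_sets
  done <- if (is.null(resume)) 0L else resume$done
  n_iter <- n_total
  if (!is.null(max_iterations)) n_iter <- min(n_iter, done + max_iterations)
  opt <- if (is.null(resume)) adam_init(model$params) else resume$opt
  rng <- local_rng(config$seed + 1000L)
  on.exit(rng())
  order_all <- unlist(lapply(seq_len(task$epochs),
                             function(e) sample.int(n_sets)))
  todo <- seq_len(n_iter)
  todo <- todo[todo > done]
  trace <- data.frame(iteration = integer(length(todo)),
                      lr = numeric(length(todo)),
                      loss = numeric(length(todo)),
                      iqa = numeric(length(todo)),
                      ewc = numeric(length(todo)))
  row <- 0L
  for (it in todo) {
    gi <- iter_offset + it - 1L
    lr <- lr_schedule(gi, config)
    set <- task$data[[order_all[it]]]
    res <- iqa_loss_grad(model, set, task$weights, config$mef_params)
    model$buffers <- res$buffers
    grads <- res$grads
    pen <- 0
    if (lam_ewc > 0) {
      pen <- ewc_penalty(model$params, ewc_state)
      pg <- ewc_penalty_grad(model$params, ewc_state)
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + lam_ewc * pg[[nm]]
    }
    upd <- adam_step(model$params, grads, opt, lr, config)
    model$params <- upd$params
    opt <- upd$state
    row <- row + 1L
    trace$iteration[row] <- gi
    trace$lr[row] <- lr
    trace$iqa[row] <- res$loss
    trace$ewc[row] <- pen
    trace$loss[row] <- res$loss + lam_ewc * pen
  }
  list(model = model, trace = trace, iterations = n_iter, opt = opt)
}

# Fisher importance of a task at the model's current parameters. Batch-norm
# uses training-mode statistics but running statistics are NOT updated, so
# the model is bit-identical before and after.
task_importance <- function(model, task, config, subset_seed = 0L) {
  n <- min(task$importance_subset_size, length(task$data))
  rng <- local_rng(config$seed + 2000L + subset_seed)
  idx <- sample.int(length(task$data), n)
  rng()
  samples <- task$data[idx]
  estimate_importance(model$params, samples, function(params, set) {
    iqa_loss_grad(model, set, task$weights, config$mef_params,
                  update_stats = FALSE)$grads
  })
}

#' Evaluate a model on a list of sets
#'
#' Mean MEF-SSIM of the fused output against the sources (and mean MAE
#' against the reference where present).
#'
#' @param model A `fusenet_model`.
#' @param sets List of sets (`sources`, optional `reference`).
#' @param config A [train_config()] (for the MEF-SSIM parameters).
#' @return List with `mef_ssim` and `mae` (NA if no references).
#' @export
evaluate_sets <- function(model, sets, config = train_config()) {
  scores <- matrix(NA_real_, length(sets), 2L)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    fused <- net_forward(model, s$sources)
    scores[i, 1] <- mef_ssim(s$sources, fused, config$mef_params)
    if (!is.null(s$reference)) scores[i, 2] <- mae_loss(fused, s$reference)
  }
  list(mef_ssim = mean(scores[, 1]), mae = mean(scores[, 2]))
}

#' Run a continual-learning curriculum
#'
#' Trains the tasks in order. Before and after every stage each task's
#' held-out split (its `eval_data`, falling back to its training data) is
#' scored by MEF-SSIM; after each stage the Fisher importance of the finished
#' task is estimated on a data subset and accumulated into the EWC state.
#'
#' @param tasks Ordered list of [task_spec()]s.
#' @param config A [train_config()].
#' @param model Optional starting model (default: fresh [init_fusion_net()]
#'   seeded from the config).
#' @param ewc_state Optional starting state (default: empty).
#' @param use_ewc Set `FALSE` to disable the penalty and the importance
#'   bookkeeping entirely (ablation).
#' @return List with final `model`, `ewc_state`, `traces` (per task),
#'   `report` (data.frame of per-task MEF-SSIM before/after each stage) and
#'   `iterations`.
#' @export
run_curriculum <- function(tasks, config = train_config(), model = NULL,
                           ewc_state = NULL, use_ewc = TRUE) {
  if (length(tasks) < 1L) stop("need at least one task")
  if (is.null(model)) model <- init_fusion_net(seed = config$seed)
  if (is.null(ewc_state)) ewc_state <- ewc_state()
  eval_of <- function(t) t$eval_data %||% t$data
  report <- NULL
  traces <- list()
  iter <- 0L
  for (k in seq_along(tasks)) {
    task <- tasks[[k]]
    st <- if (use_ewc) ewc_state else ewc_state()
    res <- train_task(model, task, st, config, iter_offset = iter)
    model <- res$model
    iter <- iter + res$iterations
    traces[[task$name]] <- res$trace
    for (j in seq_along(tasks)) {
      sc <- evaluate_sets(model, eval_of(tasks[[j]]), config)
      report <- rbind(report, data.frame(
        stage = k, trained = task$name, evaluated = tasks[[j]]$name,
        mef_ssim = sc$mef_ssim, mae = sc$mae))
    }
    if (use_ewc) {
      omega <- task_importance(model, task, config, subset_seed = k)
      ewc_state <- ewc_accumulate(ewc_state, omega, model$params)
    }
  }
  list(model = model, ewc_state = ewc_state, traces = traces,
       report = report, iterations = iter)
}
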