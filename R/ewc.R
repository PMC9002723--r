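# Elastic Weight Consolidation.
#
# After a task is trained, the diagonal Fisher importance of each parameter
# is estimated as the mean squared per-example gradient of that task's loss
# at the trained parameters theta*. Training the next task adds the quadratic
# penalty eta * sum_i Omega_i * (theta_i - theta*_i)^2, which holds important
# parameters near their anchors while leaving unimportant ones free.
# Importances accumulate additively across tasks; the anchor is always the
# latest task's trained parameters.
#
# All functions operate on flat named lists of numeric arrays, the layout
# used by `fusenet_model$params`, but work equally for scalar toy problems
# (e.g. `list(theta = 1)`).

#' Create an empty EWC state
#'
#' @param eta Penalty factor applied inside [ewc_penalty()]. Default 1: the
#'   task-level weighting (`lambda3`, or `lambda2` for unsupervised tasks) is
#'   supplied once by the trainer, so a non-unit `eta` here would double-count.
#' @return An `ewc_state`: anchor parameters `theta*`, accumulated importance
#'   `Omega`, `eta`, and `tasks_seen` counter. Empty state yields zero penalty.
#' @export
ewc_state <- function(eta = 1) {
  structure(list(anchor = NULL, importance = NULL, eta = eta,
                 tasks_seen = 0L),
            class = "ewc_state")
}

check_layout <- function(a, b, what) {
  if (!identical(names(a), names(b))) {
    stop("parameter layout mismatch in ", what)
  }
  for (nm in names(a)) {
    if (length(a[[nm]]) != length(b[[nm]])) {
      stop("parameter layout mismatch in ", what, " at '", nm, "'")
    }
  }
  invisible(TRUE)
}

#' Diagonal Fisher importance estimate
#'
#' `Omega_i = (1/N) * sum_d grad_i(L(d, theta))^2` over the sample list:
#' the mean element-wise squared gradient of the per-example task loss at the
#' current parameters. No parameter is updated.
#'
#' @param params Flat named list of parameter arrays (`theta*`).
#' @param samples List of training examples (opaque to this function).
#' @param grad_fn `function(params, sample)` returning the gradient of the
#'   scalar per-example task loss as a list with the layout of `params`.
#' @return Importance list with the layout of `params`; all entries `>= 0`.
#' @export
estimate_importance <- function(params, samples, grad_fn) {
  if (length(samples) < 1L) stop("need at least one sample")
  acc <- lapply(params, zeros_like)
  for (s in samples) {
    g <- grad_fn(params, s)
    check_layout(params, g, "estimate_importance")
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]^2
  }
  lapply(acc, function(a) a / length(samples))
}

#' EWC quadratic penalty
#'
#' `eta * sum_i Omega_i * (theta_i - theta*_i)^2`; 0 for an empty state.
#'
#' @param params Current parameters (flat named list).
#' @param state An [ewc_state()].
#' @return Scalar penalty `>= 0`.
#' @export
ewc_penalty <- function(params, state) {
  if (state$tasks_seen == 0L) return(0)
  check_layout(params, state$anchor, "ewc_penalty")
  tot <- 0
  for (nm in names(params)) {
    d <- params[[nm]] - state$anchor[[nm]]
    tot <- tot + sum(state$importance[[nm]] * d * d)
  }
  state$eta * tot
}

# analytic gradient of the penalty: 2 * eta * Omega * (theta - theta*)
ewc_penalty_grad <- function(params, state) {
  if (state$tasks_seen == 0L) return(lapply(params, zeros_like))
  check_layout(params, state$anchor, "ewc_penalty_grad")
  g <- lapply(names(params), function(nm) {
    2 * state$eta * state$importance[[nm]] *
      (params[[nm]] - state$anchor[[nm]])
  })
  names(g) <- names(params)
  g
}

#' Accumulate a finished task into the EWC state
#'
#' Importances add element-wise; the anchor is replaced by the latest task's
#' trained parameters. Immediately after accumulation the penalty at the new
#' anchor is zero.
#'
#' @param state An [ewc_state()].
#' @param new_importance Importance list (from [estimate_importance()]).
#' @param new_anchor Trained parameters of the task just finished.
#' @return Updated `ewc_state`.
#' @export
ewc_accumulate <- function(state, new_importance, new_anchor) {
  check_layout(new_importance, new_anchor, "ewc_accumulate")
  if (state$tasks_seen == 0L) {
    state$importance <- new_importance
  } else {
    check_layout(state$importance, new_importance, "ewc_accumulate")
    state$importance <- mapply(`+`, state$importance, new_importance,
                               SIMPLIFY = FALSE)
  }
  state$anchor <- new_anchor
  state$tasks_seen <- state$tasks_seen + 1L
  state
}
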