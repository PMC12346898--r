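# Rectified Adam (RAdam): Adam with a variance-rectification term that
# switches to plain momentum updates while the second-moment estimate is
# still poorly determined (early steps), removing the need for warmup.

#' Initialize RAdam optimizer state
#'
#' @param params Named list of parameter arrays.
#' @param lr Learning rate (can be changed per step).
#' @param beta1,beta2 Exponential decay rates of the first/second moments.
#' @param eps Numerical epsilon added to the denominator.
#' @return An environment holding the optimizer state.
#' @export
radam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-6) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$rho_inf <- 2 / (1 - beta2) - 1
  st
}

#' One RAdam update step
#'
#' @param state State from [radam_init()].
#' @param params Named list of parameters.
#' @param grads Named list of gradients (same names as `params`; missing
#'   names are skipped).
#' @param lr Optional learning rate override for this step.
#' @return The updated parameter list.
#' @export
radam_step <- function(state, params, grads, lr = NULL) {
  if (!is.null(lr)) state$lr <- lr
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2
  b2t <- b2^t
  rho <- state$rho_inf - 2 * t * b2t / (1 - b2t)
  rect <- if (rho > 4) {
    sqrt(((rho - 4) * (rho - 2) * state$rho_inf) /
         ((state$rho_inf - 4) * (state$rho_inf - 2) * rho))
  } else {
    NA_real_
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^t)
    if (rho > 4) {
      vhat <- sqrt(state$v[[nm]] / (1 - b2t))
      params[[nm]] <- params[[nm]] - state$lr * rect * mhat / (vhat + state$eps)
    } else {
      params[[nm]] <- params[[nm]] - state$lr * mhat
    }
  }
  params
}
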