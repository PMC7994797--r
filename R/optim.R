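# Minimal Adam optimizer over a flat named list of numeric arrays.
# Used by both the report model and the scan model trainers.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Learning rate under a step-annealing schedule
#'
#' The schedule halves (by default) the learning rate every `anneal_every`
#' epochs: `lr(e) = lr0 * factor^floor(e / anneal_every)` with 1-based epochs,
#' so with `anneal_every = 16` the rate at epoch 16 is half the initial rate.
#'
#' @param config a training config with fields `lr`, `anneal_every`,
#'   `anneal_factor` (see [report_train_config()], [scan_train_config()]).
#' @param epoch 1-based epoch number.
#' @return the learning rate used during `epoch`.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$anneal_factor^(epoch %/% config$anneal_every)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# add a gradient array into a (possibly missing) accumulator slot
.acc <- function(acc, nm, g) {
  acc[[nm]] <- if (is.null(acc[[nm]])) g else acc[[nm]] + g
  acc
}
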