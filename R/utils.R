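# One Adam step over a named list of parameter gradients.
adam_update <- function(grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  step <- vector("list", length(grads))
  names(step) <- names(grads)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    step[[nm]] <- lr * mhat / (sqrt(vhat) + eps)
  }
  list(step = step, state = state)
}

adam_state <- function(grads) {
  list(m = lapply(grads, function(g) g * 0),
       v = lapply(grads, function(g) g * 0), t = 0L)
}

# Adam-style update normalized per keypoint (row): the first moment is the
# usual EMA of the gradient vector, but the second moment tracks the
# squared *norm* of each row's gradient, so the step direction follows the
# gradient while its size adapts to the keypoint's recent gradient scale.
# Coordinates whose gradient is at numerical-noise level therefore receive
# proportionally tiny steps instead of Adam's usual full-size ones.
adam_row_state <- function(n) {
  list(m = matrix(0, n, 3L), v = numeric(n), t = 0L)
}

adam_row_update <- function(grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * rowSums(grad^2)
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  step <- lr * mhat / (sqrt(vhat) + eps)
  list(step = step, state = state)
}
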