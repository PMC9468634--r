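# Optimizers over named parameter lists. Gradients carry the same structure
# as the parameters; weight decay enters as an L2 term added to the gradient.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_init <- function(params) {
  list(v = lapply(params, function(p) p * 0))
}

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$v[[nm]] <- momentum * state$v[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * state$v[[nm]]
  }
  list(params = params, state = state)
}

# Cosine decay over `total` epochs (epoch is 1-based; the final epoch still
# trains at a small positive rate).
cosine_lr <- function(lr, epoch, total) {
  lr * 0.5 * (1 + cos(pi * (epoch - 1) / total))
}
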