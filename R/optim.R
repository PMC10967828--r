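# AdaBound: Adam with per-parameter step sizes clipped inside bounds that
# converge to a final learning rate, implemented from its defining algorithm.
# Bounds at step t (gamma controls the convergence speed of the bounds):
#   lower = final_lr * (1 - 1/(gamma*t + 1)),  upper = final_lr * (1 + 1/(gamma*t))
# with final_lr rescaled by lr/base_lr so plateau reductions shrink the
# bounds proportionally, matching the reference implementation.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

# elementwise walk over two parallel trees; the second tree may be missing
# branches (NULL) and may hold its named elements in a different order
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
    else seq_along(a)
    for (k in keys) {
      bk <- b[[k]]
      if (!is.null(bk)) out[[k]] <- tree_map2(f, a[[k]], bk)
    }
    out
  } else f(a, b)
}

adabound_init <- function(params,
                          lr = 0.001, final_lr = 0.1, gamma = 1e-3,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- tree_map(function(x) x * 0, params)
  list(m = zeros, v = zeros, t = 0L,
       base_lr = lr, final_lr = final_lr, gamma = gamma,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adabound_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  step_size <- lr * sqrt(bc2) / bc1
  fl <- state$final_lr * lr / state$base_lr
  lb <- fl * (1 - 1 / (state$gamma * t + 1))
  ub <- fl * (1 + 1 / (state$gamma * t))
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  new_params <- step_tree(params, grads, state$m, state$v, function(p, g, m, v) {
    eta <- pmin(pmax(step_size / (sqrt(v) + state$eps), lb), ub)
    p - eta * m
  })
  list(params = new_params, state = state)
}

step_tree <- function(p, g, m, v, f) {
  if (is.list(p)) {
    out <- p
    keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
    else seq_along(p)
    for (k in keys) {
      if (is.null(g[[k]])) next
      out[[k]] <- step_tree(p[[k]], g[[k]], m[[k]], v[[k]], f)
    }
    out
  } else f(p, g, m, v)
}
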