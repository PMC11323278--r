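# Minimal neural-network primitives: explicit forward caches and hand-written
# backward passes.  Parameters live in nested named lists of matrices/vectors;
# gradients mirror that structure exactly.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x / (1 + exp(-x))

silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# fast column-wise bias add (avoids sweep)
add_bias <- function(Y, b) Y + rep(b, rep.int(nrow(Y), length(b)))

#' @keywords internal
nn_init_linear <- function(n_in, n_out, bias = TRUE) {
  sd <- sqrt(2 / (n_in + n_out))
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = if (bias) numeric(n_out) else NULL)
}

# y = X W + b
nn_linear_fwd <- function(p, X) {
  Y <- X %*% p$W
  if (!is.null(p$b)) Y <- add_bias(Y, p$b)
  list(out = Y, X = X)
}

nn_linear_bwd <- function(p, cache, dY) {
  list(dX = dY %*% t(p$W),
       grad = list(W = crossprod(cache$X, dY),
                   b = if (!is.null(p$b)) colSums(dY) else NULL))
}

#' @keywords internal
nn_init_mlp <- function(n_in, hidden, n_out, bias = TRUE) {
  dims <- c(n_in, hidden, n_out)
  lapply(seq_len(length(dims) - 1), function(i) {
    nn_init_linear(dims[i], dims[i + 1], bias = bias)
  })
}

# MLP with silu after every layer but the last.
nn_mlp_fwd <- function(layers, X) {
  caches <- vector("list", length(layers))
  pre <- vector("list", length(layers))
  h <- X
  for (i in seq_along(layers)) {
    fw <- nn_linear_fwd(layers[[i]], h)
    caches[[i]] <- fw
    pre[[i]] <- fw$out
    h <- if (i < length(layers)) silu(fw$out) else fw$out
  }
  list(out = h, caches = caches, pre = pre)
}

nn_mlp_bwd <- function(layers, cache, dY) {
  grads <- vector("list", length(layers))
  d <- dY
  for (i in rev(seq_along(layers))) {
    if (i < length(layers)) d <- d * silu_grad(cache$pre[[i]])
    bw <- nn_linear_bwd(layers[[i]], cache$caches[[i]], d)
    grads[[i]] <- bw$grad
    d <- bw$dX
  }
  list(dX = d, grad = grads)
}

# ---- parameter flattening ---------------------------------------------------

# Recursively collect numeric leaves in deterministic order.
params_flatten <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  if (is.list(p)) return(unlist(lapply(p, params_flatten), use.names = FALSE))
  if (is.null(p)) return(numeric(0))
  stop("unexpected parameter leaf of class ", class(p)[1])
}

# Rebuild the nested structure of `template` from a flat vector.
params_unflatten <- function(template, flat) {
  pos <- 0L
  rebuild <- function(p) {
    if (is.numeric(p)) {
      n <- length(p)
      out <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(p))) dim(out) <- dim(p)
      return(out)
    }
    if (is.list(p)) return(lapply(p, rebuild))
    p
  }
  out <- rebuild(template)
  stopifnot(pos == length(flat))
  out
}

# Flatten `x` following the structure and order of `template` (gradients may
# be assembled with names in a different order than the parameters).
params_flatten_like <- function(template, x) {
  if (is.numeric(template)) {
    if (is.null(x)) return(numeric(length(template)))
    stopifnot(length(x) == length(template))
    return(as.numeric(x))
  }
  if (is.list(template)) {
    nm <- names(template)
    parts <- lapply(seq_along(template), function(i) {
      xi <- if (is.null(x)) NULL
            else if (!is.null(nm) && !is.null(names(x)) && nzchar(nm[i])) x[[nm[i]]]
            else x[[i]]
      params_flatten_like(template[[i]], xi)
    })
    return(unlist(parts, use.names = FALSE))
  }
  if (is.null(template)) return(numeric(0))
  stop("unexpected template leaf")
}

# Elementwise sum of two parameter structures (used to accumulate gradients).
params_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  stopifnot(is.list(a), is.list(b), length(a) == length(b))
  out <- mapply(params_add, a, b, SIMPLIFY = FALSE)
  names(out) <- names(a)
  out
}

# Zero structure matching p.
params_zero <- function(p) {
  if (is.numeric(p)) { p[] <- 0; return(p) }
  if (is.list(p)) return(lapply(p, params_zero))
  p
}

# ---- Adam -------------------------------------------------------------------

#' @keywords internal
adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# One Adam step on flat vectors; decoupled weight decay (AdamW-style).
adam_step <- function(state, theta, grad, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(state = state, theta = theta)
}

# Group rows of `values` by integer index (1..n_groups); zero rows for empty
# groups.  The workhorse scatter-sum for message aggregation and pooling.
scatter_sum <- function(values, index, n_groups) {
  out <- matrix(0, n_groups, ncol(values))
  if (length(index)) {
    s <- rowsum(values, group = index, reorder = FALSE)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}
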