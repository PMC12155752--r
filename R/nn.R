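## Minimal deterministic neural-network primitives for 3D volumes.
## Volumes travel as N x C matrices (N = prod(grid), x-fastest layout,
## identical to an R array with dim c(grid, C)); convolutions run through
## the compiled im2col/GEMM kernels.  All layers expose explicit
## forward/backward pairs; optimisation is plain (decoupled-weight-decay)
## Adam.  Single-threaded and fully seeded, so training runs are
## bit-reproducible.

arr2mat <- function(a) {
  d <- dim(a)
  matrix(a, nrow = prod(d[1:3]), ncol = d[4])
}

mat2arr <- function(m, grid) array(m, dim = c(grid, ncol(m)))

conv3_fwd <- function(x, grid, W, b, k = 3L)
  cpp_conv3d_fwd(x, grid[1], grid[2], grid[3], W, b, k)

conv3_bwd <- function(x, grid, W, gout, k = 3L)
  cpp_conv3d_bwd(x, grid[1], grid[2], grid[3], W, gout, k)

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(x, g) g * (x > 0)

# 2x average pooling over each spatial axis
pool2_fwd <- function(m, grid) {
  a <- array(m, c(grid, ncol(m)))
  ox <- seq(1, grid[1], 2); oy <- seq(1, grid[2], 2); oz <- seq(1, grid[3], 2)
  y <- (a[ox, oy, oz, , drop = FALSE]     + a[ox + 1, oy, oz, , drop = FALSE] +
        a[ox, oy + 1, oz, , drop = FALSE] + a[ox + 1, oy + 1, oz, , drop = FALSE] +
        a[ox, oy, oz + 1, , drop = FALSE] + a[ox + 1, oy, oz + 1, , drop = FALSE] +
        a[ox, oy + 1, oz + 1, , drop = FALSE] +
        a[ox + 1, oy + 1, oz + 1, , drop = FALSE]) / 8
  list(y = arr2mat(y), grid = grid %/% 2L)
}

pool2_bwd <- function(g, grid_out, channels) {
  a <- array(g / 8, c(grid_out, channels))
  up <- a[rep(seq_len(grid_out[1]), each = 2),
          rep(seq_len(grid_out[2]), each = 2),
          rep(seq_len(grid_out[3]), each = 2), , drop = FALSE]
  arr2mat(up)
}

# nearest-neighbour 2x upsampling
up2_fwd <- function(m, grid) {
  a <- array(m, c(grid, ncol(m)))
  up <- a[rep(seq_len(grid[1]), each = 2),
          rep(seq_len(grid[2]), each = 2),
          rep(seq_len(grid[3]), each = 2), , drop = FALSE]
  list(y = arr2mat(up), grid = grid * 2L)
}

up2_bwd <- function(g, grid_in, channels) {
  grid_up <- grid_in * 2L
  a <- array(g, c(grid_up, channels))
  ox <- seq(1, grid_up[1], 2); oy <- seq(1, grid_up[2], 2)
  oz <- seq(1, grid_up[3], 2)
  y <- a[ox, oy, oz, , drop = FALSE]     + a[ox + 1, oy, oz, , drop = FALSE] +
       a[ox, oy + 1, oz, , drop = FALSE] + a[ox + 1, oy + 1, oz, , drop = FALSE] +
       a[ox, oy, oz + 1, , drop = FALSE] + a[ox + 1, oy, oz + 1, , drop = FALSE] +
       a[ox, oy + 1, oz + 1, , drop = FALSE] +
       a[ox + 1, oy + 1, oz + 1, , drop = FALSE]
  arr2mat(y)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(cout, k3cin, gain = 2) {
  matrix(rnorm(cout * k3cin, 0, sqrt(gain / k3cin)), nrow = cout)
}

# --- optimiser -------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

# One (Adam / AdamW) update.  weight_decay is decoupled (applied to the
# parameter directly, scaled by lr), matrix parameters only.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !is.null(dim(params[[nm]])))
      upd <- upd + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# cosine learning-rate decay from lr0 to lr_floor over `total` epochs
cosine_lr <- function(epoch, total, lr0, lr_floor) {
  if (total <= 1) return(lr0)
  frac <- (epoch - 1) / (total - 1)
  lr_floor + (lr0 - lr_floor) * (1 + cos(pi * frac)) / 2
}
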