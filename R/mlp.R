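# Dense action-value network ---------------------------------------------
#
# A small fully connected network implemented directly on base-R matrices:
# an input projection (3 -> width), depth_d hidden blocks (width -> width),
# rectifier activations, and a linear output head (width -> 9). Networks of
# this size train comfortably on BLAS matrix products; minibatches are the
# only batched dimension.

#' Action-value network configuration
#'
#' @param depth_d Number of width x width hidden blocks stacked after the
#'   input projection (the tunable network depth).
#' @param width Nodes per hidden layer (100 by default).
#' @param input_dim Length of the state feature vector (normalised X, Y, C).
#' @param output_dim One action value per action (9).
#' @param activation Hidden nonlinearity; only `"relu"` is implemented.
#' @param init_seed Seed for weight initialisation.
#' @return A `q_network_config` list.
#' @export
q_network_config <- function(depth_d = 2L, width = 100L, input_dim = 3L,
                             output_dim = 9L, activation = "relu",
                             init_seed = 1L) {
  stopifnot(depth_d >= 1L, width >= 1L, output_dim == 9L, input_dim >= 1L)
  activation <- match.arg(activation, "relu")
  structure(
    list(depth_d = as.integer(depth_d), width = as.integer(width),
         input_dim = as.integer(input_dim), output_dim = as.integer(output_dim),
         activation = activation, init_seed = as.integer(init_seed)),
    class = "q_network_config"
  )
}

# layer input/output sizes: input proj, depth_d hidden blocks, output head
mlp_dims <- function(config) {
  c(config$input_dim, config$width, rep(config$width, config$depth_d),
    config$output_dim)
}

# He-uniform initialisation, seeded
mlp_init <- function(config) {
  dims <- mlp_dims(config)
  n_layers <- length(dims) - 1L
  with_seed(config$init_seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      bound <- sqrt(6 / dims[l])
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -bound, bound),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    list(W = W, b = b, config = config)
  })
}

mlp_n_params <- function(net) {
  sum(vapply(net$W, length, numeric(1))) + sum(vapply(net$b, length, numeric(1)))
}

# Forward pass for a batch X (n x input_dim); returns n x 9 action values.
mlp_forward <- function(net, X) {
  n_layers <- length(net$W)
  A <- X
  for (l in seq_len(n_layers)) {
    A <- A %*% net$W[[l]]
    A <- A + rep(net$b[[l]], each = nrow(A))
    if (l < n_layers) A[A < 0] <- 0
  }
  A
}

# Forward with cached pre/post activations for backprop.
mlp_forward_cached <- function(net, X) {
  n_layers <- length(net$W)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  for (l in seq_len(n_layers)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    if (l < n_layers) Z[Z < 0] <- 0
    acts[[l + 1L]] <- Z
  }
  acts
}

# Gradient of mean squared TD error on the selected actions only.
# a_idx: integer action index per row; y: TD target per row.
mlp_grad <- function(net, acts, a_idx, y) {
  n_layers <- length(net$W)
  n <- nrow(acts[[1L]])
  Q <- acts[[n_layers + 1L]]
  G <- matrix(0, n, ncol(Q))
  sel <- cbind(seq_len(n), a_idx)
  G[sel] <- 2 * (Q[sel] - y) / n
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  for (l in n_layers:1L) {
    A_prev <- acts[[l]]
    dW[[l]] <- crossprod(A_prev, G)
    db[[l]] <- colSums(G)
    if (l > 1L) {
      G <- G %*% t(net$W[[l]])
      G[A_prev <= 0] <- 0  # ReLU gate (A_prev is the rectified activation)
    }
  }
  list(dW = dW, db = db)
}

# Adam optimiser state over the network's parameter lists.
adam_init <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros_like <- function(p) lapply(p, function(x) x * 0)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       mW = zeros_like(net$W), vW = zeros_like(net$W),
       mb = zeros_like(net$b), vb = zeros_like(net$b))
}

adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- opt$beta1 * opt$mW[[l]] + (1 - opt$beta1) * grads$dW[[l]]
    opt$vW[[l]] <- opt$beta2 * opt$vW[[l]] + (1 - opt$beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      opt$lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + opt$eps)
    opt$mb[[l]] <- opt$beta1 * opt$mb[[l]] + (1 - opt$beta1) * grads$db[[l]]
    opt$vb[[l]] <- opt$beta2 * opt$vb[[l]] + (1 - opt$beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      opt$lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + opt$eps)
  }
  list(net = net, opt = opt)
}
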