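#' Affine coupling flow (RealNVP-style density estimator)
#'
#' An invertible map f: R^d -> R^d composed of affine coupling blocks. Each
#' block applies a fixed channel permutation, splits the vector into halves
#' (u, v), and transforms v as y_v = v * exp(s(u)) + t(u), where s and t are
#' produced by a three-layer fully connected subnetwork (ReLU activations)
#' conditioned on u. The scale output is soft-clamped via
#' s = clamp * tanh(s_raw / clamp) for numerical stability. The latent space
#' is a standard multivariate Gaussian, so the exact log likelihood follows
#' from the change-of-variables formula (see [log_likelihood()]).
#'
#' Training data are z-score normalized with statistics frozen into the flow
#' (`znorm`); the normalization Jacobian is included in the likelihood.
#'
#' @param d Data dimension (even, >= 2; default 16 bands).
#' @param n_blocks Number of coupling blocks (default 20).
#' @param hidden Hidden units of each subnetwork layer (default 256).
#' @param clamp Soft-clamp bound for the log-scales.
#' @param seed Integer seed controlling permutations and initialization.
#' @param init "random" (default) or "identity" (zero subnetwork output, so
#'   the flow is an exact norm-preserving identity up to permutations).
#' @return Object of class `coupling_flow`.
#' @export
new_coupling_flow <- function(d = 16L, n_blocks = 20L, hidden = 256L,
                              clamp = 2, seed = 1L,
                              init = c("random", "identity")) {
  init <- match.arg(init)
  if (d < 2L || d %% 2L != 0L) stop("d must be an even integer >= 2")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  d1 <- d %/% 2L
  d2 <- d - d1
  blocks <- lapply(seq_len(n_blocks), function(b) {
    perm <- sample.int(d)
    he <- function(nin, nout, scale = sqrt(2 / nin)) {
      matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
    }
    w3_scale <- if (init == "identity") 0 else 0.01
    list(perm = perm, invperm = order(perm),
         W1 = he(d1, hidden), b1 = numeric(hidden),
         W2 = he(hidden, hidden), b2 = numeric(hidden),
         W3 = matrix(stats::rnorm(hidden * 2L * d2, sd = w3_scale),
                     hidden, 2L * d2),
         b3 = numeric(2L * d2))
  })
  structure(
    list(d = d, d1 = d1, d2 = d2, n_blocks = n_blocks, hidden = hidden,
         clamp = clamp, seed = seed, blocks = blocks,
         znorm = list(mean = numeric(d), sd = rep(1, d))),
    class = "coupling_flow")
}

#' Forward pass of a coupling flow
#'
#' Maps data-space rows of `X` (already z-score normalized if `normalize`
#' is FALSE, raw otherwise) to latent space, accumulating the per-row
#' log-determinant of the Jacobian.
#'
#' @param flow A `coupling_flow`.
#' @param X N x d matrix (a vector is treated as one row).
#' @param normalize Apply the frozen z-score normalization first
#'   (default TRUE); its Jacobian contribution is included in `logdet`.
#' @param cache Keep intermediate activations (for backpropagation).
#' @return List with `z` (N x d), `logdet` (length N) and optionally `cache`.
#' @export
flow_forward <- function(flow, X, normalize = TRUE, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == flow$d)
  n <- nrow(X)
  logdet <- numeric(n)
  if (normalize) {
    X <- sweep(sweep(X, 2, flow$znorm$mean), 2, flow$znorm$sd, `/`)
    logdet <- logdet - sum(log(flow$znorm$sd))
  }
  d1 <- flow$d1
  caches <- if (cache) vector("list", flow$n_blocks) else NULL
  for (b in seq_len(flow$n_blocks)) {
    bl <- flow$blocks[[b]]
    xp <- X[, bl$perm, drop = FALSE]
    u <- xp[, seq_len(d1), drop = FALSE]
    v <- xp[, (d1 + 1):flow$d, drop = FALSE]
    h1 <- pmax(u %*% bl$W1 + rep(bl$b1, each = n), 0)
    h2 <- pmax(h1 %*% bl$W2 + rep(bl$b2, each = n), 0)
    o <- h2 %*% bl$W3 + rep(bl$b3, each = n)
    sr <- o[, seq_len(flow$d2), drop = FALSE]
    s <- flow$clamp * tanh(sr / flow$clamp)
    es <- exp(s)
    yv <- v * es + o[, (flow$d2 + 1):(2 * flow$d2), drop = FALSE]
    logdet <- logdet + rowSums(s)
    X <- cbind(u, yv)
    if (cache) caches[[b]] <- list(u = u, v = v, h1 = h1, h2 = h2, s = s,
                                   es = es)
  }
  out <- list(z = X, logdet = logdet)
  if (cache) out$cache <- caches
  out
}

#' Inverse pass of a coupling flow
#'
#' @param flow A `coupling_flow`.
#' @param Z N x d latent matrix.
#' @param denormalize Undo the frozen z-score normalization (default TRUE).
#' @return N x d matrix in data space.
#' @export
flow_inverse <- function(flow, Z, denormalize = TRUE) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
  stopifnot(ncol(Z) == flow$d)
  n <- nrow(Z)
  d1 <- flow$d1
  X <- Z
  for (b in rev(seq_len(flow$n_blocks))) {
    bl <- flow$blocks[[b]]
    u <- X[, seq_len(d1), drop = FALSE]
    yv <- X[, (d1 + 1):flow$d, drop = FALSE]
    h1 <- pmax(u %*% bl$W1 + rep(bl$b1, each = n), 0)
    h2 <- pmax(h1 %*% bl$W2 + rep(bl$b2, each = n), 0)
    o <- h2 %*% bl$W3 + rep(bl$b3, each = n)
    s <- flow$clamp * tanh(o[, seq_len(flow$d2), drop = FALSE] / flow$clamp)
    v <- (yv - o[, (flow$d2 + 1):(2 * flow$d2), drop = FALSE]) * exp(-s)
    xp <- cbind(u, v)
    X <- xp[, bl$invperm, drop = FALSE]
  }
  if (denormalize) {
    X <- sweep(sweep(X, 2, flow$znorm$sd, `*`), 2, flow$znorm$mean, `+`)
  }
  X
}

#' Log likelihood from latent representation and Jacobian log-determinant
#'
#' Change-of-variables formula with a standard Gaussian latent:
#' log P(x) = -||z||^2 / 2 - (d/2) log(2 pi) + log|det Jf(x)|.
#'
#' @param z Latent vector or N x d matrix.
#' @param logdet Per-row log|det Jf| (scalar or length-N).
#' @return Log density per row.
#' @export
loglik_from_latent <- function(z, logdet = 0) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  -0.5 * rowSums(z^2) - ncol(z) / 2 * log(2 * pi) + logdet
}

#' Exact log likelihood of spectra under a coupling flow
#'
#' @param flow A `coupling_flow`.
#' @param X N x d matrix (or a single d-vector) of data-space spectra.
#' @return Length-N vector of log densities.
#' @export
log_likelihood <- function(flow, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (any(!is.finite(X))) stop("non-finite input to log_likelihood")
  fw <- flow_forward(flow, X)
  ll <- loglik_from_latent(fw$z, fw$logdet)
  if (any(!is.finite(ll))) {
    stop(sprintf("non-finite log likelihood (min |z| row norm %.3g, max %.3g)",
                 min(sqrt(rowSums(fw$z^2))), max(sqrt(rowSums(fw$z^2)))))
  }
  ll
}

# Backward pass: gradients of mean negative log likelihood wrt all block
# parameters. `fw` must come from flow_forward(..., cache = TRUE) on the
# (normalized, noise-augmented) batch.
flow_backward <- function(flow, fw) {
  n <- nrow(fw$z)
  d1 <- flow$d1
  G <- fw$z / n               # d(mean 0.5||z||^2)/dz
  glp <- -1 / n               # d(-mean logdet)/dlogdet_i
  grads <- vector("list", flow$n_blocks)
  for (b in rev(seq_len(flow$n_blocks))) {
    bl <- flow$blocks[[b]]
    ca <- fw$cache[[b]]
    gu <- G[, seq_len(d1), drop = FALSE]
    gv <- G[, (d1 + 1):flow$d, drop = FALSE]
    grad_v <- gv * ca$es
    grad_s <- gv * ca$v * ca$es + glp
    dsr <- grad_s * (1 - (ca$s / flow$clamp)^2)
    dO <- cbind(dsr, gv)
    gW3 <- crossprod(ca$h2, dO)
    gb3 <- colSums(dO)
    dh2 <- (dO %*% t(bl$W3)) * (ca$h2 > 0)
    gW2 <- crossprod(ca$h1, dh2)
    gb2 <- colSums(dh2)
    dh1 <- (dh2 %*% t(bl$W2)) * (ca$h1 > 0)
    gW1 <- crossprod(ca$u, dh1)
    gb1 <- colSums(dh1)
    du <- gu + dh1 %*% t(bl$W1)
    gx_perm <- cbind(du, grad_v)
    G <- gx_perm[, bl$invperm, drop = FALSE]
    grads[[b]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                       W3 = gW3, b3 = gb3)
  }
  grads
}

flow_param_names <- c("W1", "b1", "W2", "b2", "W3", "b3")

#' Train a coupling flow by maximum likelihood
#'
#' Minimizes the mean negative log likelihood with the Adam optimizer.
#' Training data are z-score normalized (statistics estimated from `X` and
#' frozen into the flow unless `estimate_znorm = FALSE`) and augmented with
#' additive Gaussian noise. Fully reproducible given `seed`.
#'
#' @param flow A `coupling_flow`.
#' @param X N x d training matrix (N >= 100).
#' @param epochs Number of passes over the data.
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty coefficient (default 1e-4).
#' @param noise_sd SD of the additive Gaussian noise augmentation, applied in
#'   normalized units (default 0.05).
#' @param batch_size Minibatch size (default 512).
#' @param seed Seed for shuffling and noise.
#' @param estimate_znorm Estimate and freeze z-score statistics from `X`
#'   (default TRUE); set FALSE to keep the flow's current statistics.
#' @return The trained flow, with the per-epoch mean loss in `$loss_trace`.
#' @export
train_flow <- function(flow, X, epochs = 10, lr = 1e-3, weight_decay = 1e-4,
                       noise_sd = 0.05, batch_size = 512, seed = 1L,
                       estimate_znorm = TRUE) {
  stopifnot(inherits(flow, "coupling_flow"), is.matrix(X),
            ncol(X) == flow$d)
  if (nrow(X) < 100) stop("need at least 100 training spectra")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  if (estimate_znorm) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1e-8
    flow$znorm <- list(mean = mu, sd = sdv)
  }
  Xn <- sweep(sweep(X, 2, flow$znorm$mean), 2, flow$znorm$sd, `/`)
  znorm_const <- -sum(log(flow$znorm$sd))
  n <- nrow(Xn)
  # Adam state
  mstate <- lapply(flow$blocks, function(bl)
    lapply(bl[flow_param_names], function(p) array(0, dim = dim(p) %||% length(p))))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    ep_loss <- 0
    ep_n <- 0L
    for (st in starts) {
      idx <- ord[st:min(st + batch_size - 1L, n)]
      B <- Xn[idx, , drop = FALSE]
      B <- B + matrix(stats::rnorm(length(B), sd = noise_sd), nrow(B))
      fw <- flow_forward(flow, B, normalize = FALSE, cache = TRUE)
      loss <- mean(0.5 * rowSums(fw$z^2)) + flow$d / 2 * log(2 * pi) -
        mean(fw$logdet)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss); reduce the learning rate")
      }
      grads <- flow_backward(flow, fw)
      step <- step + 1L
      corr1 <- 1 - b1^step
      corr2 <- 1 - b2^step
      for (bi in seq_len(flow$n_blocks)) {
        for (pn in flow_param_names) {
          g <- grads[[bi]][[pn]] + weight_decay * flow$blocks[[bi]][[pn]]
          mstate[[bi]][[pn]] <- b1 * mstate[[bi]][[pn]] + (1 - b1) * g
          vstate[[bi]][[pn]] <- b2 * vstate[[bi]][[pn]] + (1 - b2) * g^2
          upd <- lr * (mstate[[bi]][[pn]] / corr1) /
            (sqrt(vstate[[bi]][[pn]] / corr2) + eps)
          flow$blocks[[bi]][[pn]] <- flow$blocks[[bi]][[pn]] - upd
        }
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    trace[ep] <- ep_loss / ep_n - znorm_const
  }
  flow$loss_trace <- c(flow$loss_trace, trace)
  flow
}

`%||%` <- function(a, b) if (is.null(a)) b else a
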