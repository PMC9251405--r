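#' Initialize a variance-predicting recurrent network
#'
#' The internal model is a leaky-integrator ("continuous-time") recurrent
#' network with two output heads: a tanh-bounded mean head and a strictly
#' positive variance head (`exp(.) + var_floor`), so that every prediction
#' is a full Gaussian over the next sample.  Each shape class owns a
#' learnable initial context state; a shared learnable mean ties the
#' initial states together through a Gaussian prior.
#'
#' @param n_context Number of context neurons N.
#' @param n_dim Input/output dimensionality D (x, y, pen).
#' @param classes Character vector of shape classes the network will learn.
#' @param tau Leaky-integrator time constant (>= 1; `tau = 1` is a plain
#'   discrete-time recurrence).
#' @param seed Integer seed for the weight initialization.
#' @param var_floor Additive floor of the variance head.
#' @return An object of class `sctrnn`.
#' @export
sctrnn_init <- function(n_context = 100L, n_dim = 3L, classes = shape_classes(),
                        tau = 2, seed = 0L, var_floor = 1e-6) {
  stopifnot(n_context >= 1L, tau >= 1, var_floor > 0)
  N <- as.integer(n_context); D <- as.integer(n_dim); S <- length(classes)
  with_seed(seed, {
    net <- list(
      W_in  = matrix(rnorm(N * D, 0, 1 / sqrt(D)), N, D),
      W_rec = matrix(rnorm(N * N, 0, 1 / sqrt(N)), N, N),
      b_ctx = numeric(N),
      W_mu  = matrix(rnorm(D * N, 0, 1 / sqrt(N)), D, N),
      b_mu  = numeric(D),
      W_var = matrix(rnorm(D * N, 0, 0.1 / sqrt(N)), D, N),
      b_var = numeric(D),
      init_states = matrix(0, S, N, dimnames = list(classes, NULL)),
      init_mean   = numeric(N),
      tau = tau, var_floor = var_floor,
      n_context = N, n_dim = D, classes = classes,
      seed = as.integer(seed), trained = FALSE)
  })
  class(net) <- "sctrnn"
  net
}

#' @export
print.sctrnn <- function(x, ...) {
  cat(sprintf("<sctrnn> N = %d context neurons, D = %d, tau = %g, %d classes%s\n",
              x$n_context, x$n_dim, x$tau, length(x$classes),
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

# names of the learnable arrays
param_names <- function() {
  c("W_in", "W_rec", "b_ctx", "W_mu", "b_mu", "W_var", "b_var",
    "init_states", "init_mean")
}

check_finite_params <- function(net) {
  for (nm in param_names()) {
    if (!all(is.finite(net[[nm]])))
      stop("non-finite values in parameter '", nm, "'")
  }
  invisible(TRUE)
}

#' One forward step of the network
#'
#' Updates the context potentials by the leaky-integrator rule
#' `u' = (1 - 1/tau) u + (1/tau) (W_in input + W_rec tanh(u) + b)` and reads
#' out the Gaussian prediction of the next sample from the new context
#' activation.
#'
#' @param net An [sctrnn_init()] network.
#' @param context N-vector of context potentials `u`.
#' @param input D-vector (the current sample, or a fused posterior mean).
#' @return List with `mu` (tanh-bounded mean), `sigma2` (strictly positive
#'   variance), `context` (new activation `tanh(u')`), and `u` (new
#'   potentials).
#' @export
forward_step <- function(net, context, input) {
  check_finite_params(net)
  if (!all(is.finite(context)) || !all(is.finite(input)))
    stop("non-finite context or input")
  rho <- 1 - 1 / net$tau
  u <- rho * context + (1 / net$tau) *
    (as.numeric(net$W_in %*% input) + as.numeric(net$W_rec %*% tanh(context)) + net$b_ctx)
  c_act <- tanh(u)
  mu <- tanh(as.numeric(net$W_mu %*% c_act) + net$b_mu)
  sigma2 <- exp(as.numeric(net$W_var %*% c_act) + net$b_var) + net$var_floor
  list(mu = mu, sigma2 = sigma2, context = c_act, u = u)
}

#' Sequence negative log-likelihood
#'
#' The Gaussian sequence score minimized during training and recognition:
#' `sum_t sum_i [ ln(2 pi sigma2[t,i]) + (target[t,i] - mu[t,i])^2 / (2 sigma2[t,i]) ]`.
#' Targets are the observed samples one step ahead of the inputs.
#'
#' @param mu Matrix (T x D) of predicted means.
#' @param sigma2 Matrix (T x D) of predicted variances (all > 0).
#' @param targets Matrix (T x D) of observed samples.
#' @return The summed negative log-likelihood (a scalar).
#' @export
sequence_nll <- function(mu, sigma2, targets) {
  mu <- as.matrix(mu); sigma2 <- as.matrix(sigma2); targets <- as.matrix(targets)
  if (!all(dim(mu) == dim(sigma2)) || !all(dim(mu) == dim(targets)))
    stop("mu, sigma2 and targets must have identical dimensions")
  if (any(sigma2 <= 0)) stop("all variances must be strictly positive")
  sum(log(2 * pi * sigma2) + (targets - mu)^2 / (2 * sigma2))
}

#' Gaussian prior over the per-class initial states
#'
#' `sum_s sum_n [ ln(2 pi v_dist) + (u0[s,n] - mean[n])^2 / (2 v_dist) ]`:
#' the regularizer that pulls the per-class initial context states toward
#' their shared learnable mean during training.
#'
#' @param init_states S x N matrix of per-class initial states (or an
#'   N-vector for a single class).
#' @param mean N-vector, the shared mean of the initial states.
#' @param v_dist Predefined variance of the initial-state distribution
#'   (default 10).
#' @return The summed negative log-prior (a scalar).
#' @export
initial_state_prior_nll <- function(init_states, mean, v_dist = 10) {
  if (v_dist <= 0) stop("v_dist must be > 0")
  u <- if (is.matrix(init_states)) init_states else matrix(init_states, nrow = 1)
  if (ncol(u) != length(mean)) stop("init_states and mean have mismatched dimensions")
  dev <- sweep(u, 2, mean)
  nrow(u) * ncol(u) * log(2 * pi * v_dist) + sum(dev^2) / (2 * v_dist)
}

# run a full sequence through the compiled core
run_network <- function(net, u0, x, mode = c("teacher", "posterior", "closed"),
                        n_obs = nrow(x), cfg = precision_config(), h_loss = 1,
                        grad = FALSE, noise = NULL) {
  mode <- match.arg(mode)
  check_finite_params(net)
  x <- as.matrix(x)
  ss2 <- rep(cfg$sigma_sensor2, length.out = ncol(x))
  if (is.null(noise)) noise <- matrix(numeric(0), 0, 0)
  sctrnn_run_cpp(net, as.numeric(u0), x,
                 match(mode, c("teacher", "posterior", "closed")) - 1L,
                 as.integer(n_obs), cfg$h_prior, cfg$h_sensor, ss2,
                 h_loss, grad, noise)
}

# --- optimizer --------------------------------------------------------------

adam_init <- function(theta) {
  list(m = lapply(theta, function(a) a * 0),
       v = lapply(theta, function(a) a * 0),
       t = 0L)
}

adam_update <- function(state, theta, grads, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, theta = theta)
}

#' Training configuration
#'
#' @param max_epochs Maximum number of epochs (default 30000); one epoch is
#'   one full pass over all training trajectories with a single full-batch
#'   update.
#' @param patience_epochs Early stop when the best total loss has not
#'   improved within this many epochs (default 5000).
#' @param improvement_tolerance Minimum decrease of the best total loss that
#'   counts as an improvement.
#' @param v_dist Variance of the initial-state prior (default 10).
#' @param learning_rate Adam step size.
#' @param seed Seed for weight initialization; the whole training run is a
#'   pure function of it.
#' @param n_context Context size N of the network to initialize.
#' @param tau Leaky-integrator time constant.
#' @param optimizer `"adam"`, or `"none"` to evaluate the loss without
#'   updating (used to exercise the early-stopping contract).
#' @param stochastic_input If TRUE (default) the training input of each
#'   step is a reparameterized sample from the fused posterior rather than
#'   its mean; the sampling noise shrinks with the learned prediction
#'   variance and forces the recurrent dynamics (not the per-step sensory
#'   correction) to carry the trajectory, which is what makes closed-loop
#'   completion stable.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_epochs = 30000L, patience_epochs = 5000L,
                            improvement_tolerance = 1e-6, v_dist = 10,
                            learning_rate = 1e-3, seed = 0L,
                            n_context = 100L, tau = 2,
                            optimizer = c("adam", "none"),
                            stochastic_input = TRUE) {
  if (patience_epochs > max_epochs) stop("patience_epochs must be <= max_epochs")
  if (v_dist <= 0) stop("v_dist must be > 0")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 improvement_tolerance = improvement_tolerance,
                 v_dist = v_dist, learning_rate = learning_rate,
                 seed = as.integer(seed), n_context = as.integer(n_context),
                 tau = tau, optimizer = match.arg(optimizer),
                 stochastic_input = isTRUE(stochastic_input)),
            class = "training_config")
}

#' Train the network on a drawing dataset
#'
#' Jointly optimizes the weights, the per-class initial states and their
#' shared mean by full-batch Adam on the sequence negative log-likelihood
#' plus the initial-state prior.  At every step the network's input is the
#' precision-weighted fusion of its own prediction with the sensory sample
#' (normal reliance, `H_prior = H_sensor = 1`, unless `precision` says
#' otherwise); gradients are backpropagated through time along the
#' recurrent path with the fused inputs treated as data.  The initial
#' evaluation counts as epoch 0; training stops early when the best total
#' loss has not improved for `patience_epochs` epochs.  Best-so-far
#' parameters are returned.
#'
#' @param dataset A [build_dataset()] result (its training split is used).
#' @param config A [training_config()].
#' @param precision A [precision_config()] used for the input fusion during
#'   training.
#' @param net Optionally a pre-built [sctrnn_init()] network; by default one
#'   is initialized from `config`.
#' @param verbose Print progress every 200 epochs.
#' @return The trained `sctrnn` model; the per-epoch loss history
#'   (`epoch`, `nll`, `init_prior`, `total`) is attached as attribute
#'   `"history"`.
#' @export
train_sctrnn <- function(dataset, config = training_config(),
                         precision = precision_config(), net = NULL,
                         verbose = FALSE) {
  train <- training_trajectories(dataset)
  if (length(train) < 1L) stop("dataset has no training trajectories")
  if (is.null(net))
    net <- sctrnn_init(config$n_context, 3L, dataset$classes,
                       tau = config$tau, seed = config$seed)
  X <- lapply(train, function(tr) tr$points)
  cidx <- vapply(train, function(tr) match(tr$shape_class, net$classes), integer(1))
  if (any(is.na(cidx))) stop("dataset contains classes unknown to the network")

  theta <- net[param_names()]
  opt <- adam_init(theta)
  wnames <- setdiff(param_names(), c("init_states", "init_mean"))
  best <- list(total = Inf, epoch = -1L, theta = theta)
  hist_epoch <- integer(0); hist_nll <- numeric(0); hist_prior <- numeric(0)

  # pre-drawn posterior-sampling noise: one standard-normal matrix per
  # (epoch, trajectory), a pure function of the seed
  noise_for <- if (config$stochastic_input) {
    local({
      n_draw <- nrow(X[[1]]) * ncol(X[[1]])
      function(epoch, j) {
        s <- (as.numeric(config$seed) * 1e6 + epoch * 1000 + j) %% 2147483647
        with_seed(as.integer(s), matrix(rnorm(n_draw), nrow(X[[j]]), ncol(X[[j]])))
      }
    })
  } else function(epoch, j) NULL

  for (epoch in 0:config$max_epochs) {
    pars <- net
    pars[param_names()] <- theta
    grads <- lapply(theta, function(a) a * 0)
    nll <- 0
    for (j in seq_along(X)) {
      r <- run_network(pars, theta$init_states[cidx[j], ], X[[j]],
                       mode = "posterior", cfg = precision, h_loss = 1,
                       grad = TRUE, noise = noise_for(epoch, j))
      nll <- nll + r$nll
      for (nm in wnames) grads[[nm]] <- grads[[nm]] + r$grads[[nm]]
      grads$init_states[cidx[j], ] <- grads$init_states[cidx[j], ] + r$grads$u0
    }
    prior <- initial_state_prior_nll(theta$init_states, theta$init_mean,
                                     config$v_dist)
    dev <- sweep(theta$init_states, 2, theta$init_mean)
    grads$init_states <- grads$init_states + dev / config$v_dist
    grads$init_mean <- grads$init_mean - colSums(dev) / config$v_dist
    total <- nll + prior
    if (!is.finite(total)) stop("training diverged (non-finite loss) at epoch ", epoch)

    hist_epoch <- c(hist_epoch, epoch)
    hist_nll <- c(hist_nll, nll)
    hist_prior <- c(hist_prior, prior)
    if (total < best$total - config$improvement_tolerance)
      best <- list(total = total, epoch = epoch, theta = theta)
    if (verbose && epoch %% 200L == 0L)
      message(sprintf("epoch %6d  nll %.2f  prior %.2f", epoch, nll, prior))

    if (epoch - best$epoch >= config$patience_epochs) break
    if (epoch < config$max_epochs && config$optimizer == "adam") {
      upd <- adam_update(opt, theta, grads, config$learning_rate)
      opt <- upd$state
      theta <- upd$theta
    }
  }

  net[param_names()] <- best$theta
  net$trained <- TRUE
  net$seed <- config$seed
  attr(net, "history") <- data.frame(
    epoch = hist_epoch, nll = hist_nll, init_prior = hist_prior,
    total = hist_nll + hist_prior)
  attr(net, "config") <- config
  net
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds every weight array, the per-class initial states and
#' their mean, the architecture constants, the seed and the attached
#' training history; the round trip is exact.
#'
#' @param model A trained `sctrnn` model.
#' @param path File path (`.rds`).
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sctrnn")) stop("not an sctrnn checkpoint: ", path)
  model
}
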