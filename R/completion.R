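#' Extract the presented prefix of a trajectory
#'
#' The first third of the trajectory (30 steps for the standard 90) is what
#' the network observes during the recognition step.
#'
#' @param traj A [trajectory()].
#' @param n_steps Prefix length; defaults to one third of the trajectory.
#' @return A `pc_prefix`: the prefix samples plus the intended class.
#' @export
prefix_of <- function(traj, n_steps = NULL) {
  T_full <- nrow(traj$points)
  if (is.null(n_steps)) n_steps <- T_full %/% 3L
  stopifnot(n_steps >= 1L, n_steps <= T_full)
  structure(list(points = traj$points[seq_len(n_steps), , drop = FALSE],
                 intended_class = traj$shape_class,
                 variant_id = traj$variant_id,
                 full_length = T_full),
            class = "pc_prefix")
}

#' Recognition: infer the initial state explaining a prefix
#'
#' With the network weights frozen, the initial context state is optimized
#' for a fixed number of epochs by backpropagation through time so as to
#' minimize the prefix negative log-likelihood.  The altered precision
#' factors are active: the forward input is the precision-weighted
#' posterior under `cfg`, and the prediction variance inside the likelihood
#' is scaled by `h_prior` (so an imprecise prior weakens the data-fit term
#' of the recognition objective).  The optimization starts from the learned
#' initial-state mean plus a small seeded Gaussian perturbation; the
#' best-so-far state is returned.
#'
#' @param model A trained `sctrnn` model.
#' @param prefix A [prefix_of()] result (or a matrix of samples).
#' @param cfg A [precision_config()].
#' @param epochs Number of optimization epochs (default 100).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed Seed of the random initialization of the search.
#' @param init_sd Standard deviation of the start perturbation.
#' @return List with `u0` (best state), `nll`, `initial_nll`, and the
#'   per-epoch `history` of evaluated prefix NLLs.
#' @export
recognize_prefix <- function(model, prefix, cfg = precision_config(),
                             epochs = 100L, learning_rate = 0.01,
                             seed = 0L, init_sd = 0.01) {
  check_finite_params(model)
  stopifnot(epochs >= 1L)
  pts <- if (inherits(prefix, "pc_prefix")) prefix$points else as.matrix(prefix)
  u0 <- model$init_mean +
    with_seed(seed, rnorm(model$n_context, 0, init_sd))
  theta <- list(u0 = u0)
  opt <- adam_init(theta)
  best <- list(nll = Inf, u0 = u0)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    r <- run_network(model, theta$u0, pts, mode = "posterior", cfg = cfg,
                     h_loss = cfg$h_prior, grad = TRUE)
    history[e] <- r$nll
    if (r$nll < best$nll) best <- list(nll = r$nll, u0 = theta$u0)
    upd <- adam_update(opt, theta, list(u0 = r$grads$u0), learning_rate)
    opt <- upd$state
    theta <- upd$theta
  }
  list(u0 = best$u0, nll = best$nll, initial_nll = history[1L],
       history = history)
}

#' Generation: draw the full trajectory from an inferred initial state
#'
#' The first `n_obs` steps (the presented part) run with sensory input
#' available: the drawn output is the posterior mean of the
#' precision-weighted fusion of prediction and sample, and that posterior
#' is also fed back as the next input.  The remaining steps run closed-loop
#' without any sensory term: the network's own predicted mean is fed back
#' and drawn.
#'
#' @param model A trained `sctrnn` model.
#' @param u0 Initial context state (e.g. from [recognize_prefix()]).
#' @param prefix A [prefix_of()] result.
#' @param cfg A [precision_config()].
#' @param total_steps Full trajectory length (defaults to the prefix's
#'   parent length, i.e. 3 x 30 = 90).
#' @return A `completion_result`: the drawn 90-step trajectory with its
#'   presented (1..30) and completed (31..90) segments, the inferred
#'   initial state, and the precision cell.
#' @export
generate_completion <- function(model, u0, prefix, cfg = precision_config(),
                                total_steps = NULL) {
  stopifnot(length(u0) == model$n_context)
  pts <- prefix$points
  n_obs <- nrow(pts)
  if (is.null(total_steps))
    total_steps <- if (!is.null(prefix$full_length)) prefix$full_length else 3L * n_obs
  x_full <- rbind(pts, matrix(0, total_steps - n_obs, ncol(pts)))
  r <- run_network(model, u0, x_full, mode = "closed", n_obs = n_obs, cfg = cfg)
  drawn <- r$drawn
  colnames(drawn) <- c("x", "y", "pen")
  structure(list(drawn = drawn,
                 presented_steps = seq_len(n_obs),
                 completed_steps = seq.int(n_obs + 1L, total_steps),
                 inferred_initial_state = as.numeric(u0),
                 h_prior = cfg$h_prior, h_sensor = cfg$h_sensor,
                 intended_class = prefix$intended_class,
                 variant_id = prefix$variant_id,
                 network_id = NA_integer_, repetition = NA_integer_),
            class = "completion_result")
}

#' Complete a partial drawing (recognition + generation)
#'
#' @param model A trained `sctrnn` model.
#' @param prefix A [prefix_of()] result.
#' @param cfg A [precision_config()].
#' @param repetition_seed Seed of the recognition start perturbation; the
#'   whole completion is a pure function of
#'   `(model, prefix, cfg, repetition_seed)`.
#' @param recognition_epochs Epochs of the recognition step (default 100).
#' @param learning_rate Recognition step size.
#' @return A `completion_result` (see [generate_completion()]), with the
#'   recognition history attached as attribute `"recognition"`.
#' @export
complete_drawing <- function(model, prefix, cfg = precision_config(),
                             repetition_seed = 0L, recognition_epochs = 100L,
                             learning_rate = 0.01) {
  rec <- recognize_prefix(model, prefix, cfg, epochs = recognition_epochs,
                          learning_rate = learning_rate, seed = repetition_seed)
  res <- generate_completion(model, rec$u0, prefix, cfg)
  attr(res, "recognition") <- rec[c("nll", "initial_nll", "history")]
  res
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf("<completion_result> %s (variant %d), H_sensor = %g, H_prior = %g, %d steps\n",
              x$intended_class, x$variant_id, x$h_sensor, x$h_prior, nrow(x$drawn)))
  invisible(x)
}
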