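test_that("forward step respects symmetry and the variance floor", {
  net <- sctrnn_init(n_context = 6, classes = shape_classes()[1:2], seed = 1)
  zero <- net
  for (nm in c("W_in", "W_rec", "b_ctx", "W_mu", "b_mu", "W_var", "b_var"))
    zero[[nm]] <- zero[[nm]] * 0
  s <- forward_step(zero, numeric(6), numeric(3))
  expect_equal(s$mu, numeric(3))

  set.seed(9)
  for (k in 1:20) {
    st <- forward_step(net, rnorm(6, 0, 2), rnorm(3, 0, 2))
    expect_true(all(st$sigma2 >= net$var_floor))
    expect_true(all(is.finite(st$sigma2)))
  }

  bad <- net; bad$W_rec[2, 3] <- NaN
  expect_error(forward_step(bad, numeric(6), numeric(3)), "W_rec")
})

test_that("sequence_nll matches its closed forms and is additive", {
  # both terms vanish when mu hits the target at sigma2 = 1/(2*pi)
  expect_equal(sequence_nll(matrix(0.3), matrix(1 / (2 * pi)), matrix(0.3)), 0)
  # one term with mu = 0, x = 1, sigma2 = 1
  expect_equal(sequence_nll(matrix(0), matrix(1), matrix(1)), log(2 * pi) + 0.5,
               tolerance = 1e-12)
  set.seed(1)
  mu <- matrix(rnorm(12), 4, 3); s2 <- matrix(runif(12, 0.1, 2), 4, 3)
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(sequence_nll(rbind(mu, mu), rbind(s2, s2), rbind(x, x)),
               2 * sequence_nll(mu, s2, x))
  expect_error(sequence_nll(mu, -s2, x), "positive")
  expect_error(sequence_nll(mu, s2[1:3, ], x), "dimensions")
})

test_that("initial-state prior matches its closed forms", {
  u <- matrix(rnorm(6 * 10, 0.4, 0), 6, 10)  # all equal to 0.4
  expect_equal(initial_state_prior_nll(u, rep(0.4, 10), 10),
               6 * 10 * log(2 * pi * 10), tolerance = 1e-12)
  expect_equal(initial_state_prior_nll(matrix(0.4), 0.4, 10), log(20 * pi),
               tolerance = 1e-12)
  # doubling every deviation quadruples the quadratic part
  set.seed(2)
  u1 <- matrix(rnorm(12), 3, 4); mn <- rnorm(4)
  base <- 3 * 4 * log(2 * pi * 10)
  q1 <- initial_state_prior_nll(u1, mn, 10) - base
  u2 <- sweep(sweep(u1, 2, mn), 2, mn, FUN = function(d, m) m + 2 * d)
  expect_equal(initial_state_prior_nll(u2, mn, 10) - base, 4 * q1)
  expect_error(initial_state_prior_nll(u1, mn[1:3], 10), "mismatch")
  expect_error(initial_state_prior_nll(u1, mn, 0), "v_dist")
})

test_that("compiled sequence loss agrees with sequence_nll on its own outputs", {
  net <- sctrnn_init(n_context = 8, classes = shape_classes()[1:2], seed = 5)
  set.seed(5)
  x <- matrix(runif(30, -0.8, 0.8), 10, 3)
  r <- pcdraw:::run_network(net, rnorm(8), x, mode = "teacher")
  expect_equal(r$nll, sequence_nll(r$mu, r$sigma2, x), tolerance = 1e-10)
  # the batch likelihood decomposes into per-trajectory terms
  x2 <- matrix(runif(30, -0.8, 0.8), 10, 3)
  r2 <- pcdraw:::run_network(net, rnorm(8), x2, mode = "teacher")
  expect_equal(sequence_nll(rbind(r$mu, r2$mu), rbind(r$sigma2, r2$sigma2),
                            rbind(x, x2)),
               r$nll + r2$nll, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences in every mode", {
  net <- sctrnn_init(n_context = 4, classes = shape_classes()[1:2], seed = 3)
  set.seed(42)
  x <- matrix(runif(6 * 3, -0.5, 0.5), 6, 3)
  u0 <- rnorm(4, 0, 0.5)
  eps <- matrix(rnorm(18), 6, 3)
  cfg <- precision_config(h_prior = 2, h_sensor = 0.5)
  h <- 1e-5
  for (md in c("teacher", "posterior", "closed")) {
    nobs <- if (md == "closed") 3L else nrow(x)
    noise <- if (md == "posterior") eps else NULL
    r <- pcdraw:::run_network(net, u0, x, mode = md, n_obs = nobs, cfg = cfg,
                              h_loss = 0.5, grad = TRUE, noise = noise)
    for (nm in c("W_in", "W_rec", "b_ctx", "W_mu", "b_mu", "W_var", "b_var", "u0")) {
      g <- r$grads[[nm]]
      arr <- if (nm == "u0") u0 else net[[nm]]
      for (i in seq_along(arr)) {
        f <- function(delta) {
          np <- net; up <- u0
          if (nm == "u0") up[i] <- up[i] + delta else np[[nm]][i] <- np[[nm]][i] + delta
          pcdraw:::run_network(np, up, x, mode = md, n_obs = nobs, cfg = cfg,
                               h_loss = 0.5, noise = noise)$nll
        }
        fd <- (f(h) - f(-h)) / (2 * h)
        expect_lt(abs(g[i] - fd) / max(abs(g[i]) + abs(fd), 1e-8), 1e-4)
      }
    }
  }
})

test_that("a constant-loss run stops exactly at the patience epoch", {
  ds <- build_dataset(5, shape_classes()[1], n_per_class = 2L, n_train = 2L)
  cfg <- training_config(max_epochs = 50L, patience_epochs = 7L,
                         n_context = 8L, seed = 0L, optimizer = "none",
                         stochastic_input = FALSE)
  m <- train_sctrnn(ds, cfg)
  h <- attr(m, "history")
  expect_equal(max(h$epoch), 7)
  expect_equal(h$epoch[1], 0)
  expect_true(all(diff(h$total) == 0))
})

test_that("training improves the likelihood and keeps best-so-far monotone", {
  fit <- tiny_fit()
  h <- attr(fit$model, "history")
  expect_true(all(diff(cummin(h$total)) <= 0))
  expect_equal(h$total, h$nll + h$init_prior)
  untrained <- h$nll[1]
  expect_gt(untrained, 0)
  expect_lt(min(h$nll), untrained / 5)
})

test_that("training is bitwise reproducible and checkpoints round-trip", {
  ds <- build_dataset(5, shape_classes()[1], n_per_class = 2L, n_train = 2L)
  cfg <- training_config(max_epochs = 40L, patience_epochs = 40L,
                         n_context = 8L, seed = 9L)
  m1 <- train_sctrnn(ds, cfg)
  m2 <- train_sctrnn(ds, cfg)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(m1$W_rec, m2$W_rec)
  expect_identical(m1$init_states, m2$init_states)

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m1, path)
  back <- load_checkpoint(path)
  expect_identical(back[pcdraw:::param_names()], m1[pcdraw:::param_names()])
})

test_that("the initial-state prior pulls class states toward their mean", {
  ds <- build_dataset(0, shape_classes()[1:3], n_per_class = 2L, n_train = 2L)
  pull <- function(v_dist) {
    cfg <- training_config(max_epochs = 400L, patience_epochs = 400L,
                           n_context = 16L, seed = 2L, v_dist = v_dist)
    m <- train_sctrnn(ds, cfg)
    mean(sqrt(rowSums(sweep(m$init_states, 2, m$init_mean)^2)))
  }
  with_prior <- pull(10)
  without <- pull(1e8)  # prior term effectively removed
  expect_lt(with_prior, without)
})
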