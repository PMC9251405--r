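#' The six drawing shape classes
#'
#' Stable class order; the integer code of a class is its position minus one
#' (FACE = 0, ..., ROCKET = 5).
#'
#' @return Character vector of the six class names.
#' @export
shape_classes <- function() {
  c("FACE", "HOUSE", "CAR", "FLOWER", "HUMAN", "ROCKET")
}

#' Integer code of a shape class
#' @param shape_class Class name, one of [shape_classes()].
#' @return Integer code in 0..5.
#' @export
shape_class_code <- function(shape_class) {
  idx <- match(shape_class, shape_classes())
  if (any(is.na(idx))) {
    stop("unknown shape class: ", paste(shape_class[is.na(idx)], collapse = ", "),
         " (expected one of ", paste(shape_classes(), collapse = ", "), ")")
  }
  idx - 1L
}

#' Construct a pen trajectory object
#'
#' A trajectory is an ordered sequence of samples `(x, y, pen)` with
#' normalized coordinates in `[-1, 1]` and a binary pen state (1 = pen
#' down, 0 = pen up), labelled with its shape class.
#'
#' @param points Numeric matrix with columns `x`, `y`, `pen`.
#' @param shape_class Class name, one of [shape_classes()].
#' @param variant_id Non-negative integer identifying the instance.
#' @return An object of class `pc_trajectory`.
#' @export
trajectory <- function(points, shape_class, variant_id = 0L) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("trajectory points must have 3 columns (x, y, pen)")
  colnames(points) <- c("x", "y", "pen")
  if (!all(points[, "pen"] %in% c(0, 1)))
    stop("pen state must be 0 (up) or 1 (down)")
  if (any(abs(points[, c("x", "y")]) > 1 + 1e-12))
    stop("coordinates must lie in [-1, 1]")
  shape_class_code(shape_class)  # validates the class name
  structure(
    list(points = points, shape_class = shape_class,
         class_code = shape_class_code(shape_class),
         variant_id = as.integer(variant_id)),
    class = "pc_trajectory")
}

#' @export
print.pc_trajectory <- function(x, ...) {
  cat(sprintf("<pc_trajectory> %s variant %d, %d steps, %d strokes\n",
              x$shape_class, x$variant_id, nrow(x$points),
              length(rle(x$points[, "pen"])$lengths)))
  invisible(x)
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# --- stroke primitives ------------------------------------------------------

ellipse_pts <- function(cx, cy, rx, ry, from = 0, to = 2 * pi, n = 48) {
  th <- seq(from, to, length.out = n)
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

jit <- function(v, sd) v + rnorm(length(v), 0, sd)

# Fixed per-class stroke programs: polyline / ellipse templates whose
# control points receive Gaussian jitter (sd in normalized units).  Strokes
# are pen-down; consecutive strokes are joined by pen-up bridges.
shape_template <- function(shape_class, jitter_sd = 0.03) {
  ell <- function(cx, cy, rx, ry, from = 0, to = 2 * pi) {
    p <- jit(c(cx, cy), jitter_sd); r <- abs(jit(c(rx, ry), jitter_sd))
    ellipse_pts(p[1], p[2], r[1], r[2], from, to)
  }
  poly <- function(xy, closed = FALSE) {
    m <- matrix(jit(as.numeric(t(xy)), jitter_sd), ncol = 2, byrow = TRUE)
    if (closed) m <- rbind(m, m[1, , drop = FALSE])
    m
  }
  switch(shape_class,
    FACE = list(
      ell(0, 0, 0.7, 0.8),
      ell(-0.25, 0.25, 0.09, 0.11),
      ell(0.25, 0.25, 0.09, 0.11),
      ell(0, -0.3, 0.3, 0.18, from = pi + 0.3, to = 2 * pi - 0.3)),
    HOUSE = list(
      poly(rbind(c(-0.6, -0.7), c(0.6, -0.7), c(0.6, 0.1), c(-0.6, 0.1)), closed = TRUE),
      poly(rbind(c(-0.7, 0.1), c(0, 0.75), c(0.7, 0.1))),
      poly(rbind(c(-0.15, -0.7), c(-0.15, -0.25), c(0.15, -0.25), c(0.15, -0.7))),
      poly(rbind(c(0.25, -0.2), c(0.45, -0.2), c(0.45, -0.05), c(0.25, -0.05)), closed = TRUE)),
    CAR = list(
      poly(rbind(c(-0.8, -0.15), c(-0.8, 0.05), c(-0.45, 0.05), c(-0.3, 0.35),
                 c(0.25, 0.35), c(0.4, 0.05), c(0.8, 0.05), c(0.8, -0.15)),
           closed = TRUE),
      ell(-0.45, -0.25, 0.14, 0.14),
      ell(0.45, -0.25, 0.14, 0.14)),
    FLOWER = list(
      poly(rbind(c(0, -0.8), c(0, -0.15))),
      ell(0, 0.05, 0.16, 0.16),
      ell(0, 0.42, 0.13, 0.2),
      ell(0.35, 0.05, 0.2, 0.13),
      ell(-0.35, 0.05, 0.2, 0.13),
      ell(0.18, -0.5, 0.16, 0.08)),
    HUMAN = list(
      ell(0, 0.6, 0.18, 0.2),
      poly(rbind(c(0, 0.4), c(0, -0.1))),
      poly(rbind(c(-0.4, 0.15), c(0, 0.32), c(0.4, 0.15))),
      poly(rbind(c(-0.3, -0.75), c(0, -0.1), c(0.3, -0.75)))),
    ROCKET = list(
      poly(rbind(c(-0.25, -0.5), c(-0.25, 0.3), c(0, 0.75), c(0.25, 0.3),
                 c(0.25, -0.5)), closed = TRUE),
      ell(0, 0.2, 0.1, 0.1),
      poly(rbind(c(-0.25, -0.2), c(-0.5, -0.6), c(-0.25, -0.5))),
      poly(rbind(c(0.25, -0.2), c(0.5, -0.6), c(0.25, -0.5))),
      poly(rbind(c(-0.1, -0.5), c(0, -0.78), c(0.1, -0.5)))),
    stop("unknown shape class: ", shape_class))
}

# assemble strokes + pen-up bridges into one dense (x, y, pen) matrix
assemble_strokes <- function(strokes) {
  out <- NULL
  for (k in seq_along(strokes)) {
    s <- strokes[[k]]
    out <- rbind(out, cbind(s, 1))
    if (k < length(strokes)) {
      a <- s[nrow(s), ]
      b <- strokes[[k + 1]][1, ]
      w <- c(1 / 3, 2 / 3)
      bridge <- cbind(a[1] + w * (b[1] - a[1]), a[2] + w * (b[2] - a[2]), 0)
      out <- rbind(out, bridge)
    }
  }
  out
}

#' Generate one synthetic shape trajectory
#'
#' Produces a stylized multi-stroke instance of the requested class from a
#' fixed per-class stroke program (polylines and ellipses) whose control
#' points are perturbed by Gaussian jitter, so that variants generated with
#' different seeds differ while staying class-typical.  The result is a
#' deterministic function of `(shape_class, seed)`.
#'
#' @param shape_class One of [shape_classes()].
#' @param seed Integer seed controlling the control-point jitter.
#' @param n_points Number of samples in the returned trajectory (>= 10).
#' @param jitter_sd Standard deviation of the control-point jitter in
#'   normalized coordinate units.
#' @return A [trajectory()] of length `n_points`.
#' @export
generate_shape <- function(shape_class, seed, n_points = 200L, jitter_sd = 0.03) {
  code <- shape_class_code(shape_class)  # rejects unknown classes by name
  if (n_points < 10L) stop("n_points must be >= 10")
  dense <- with_seed(seed * 1009L + code * 101L + 1L,
                     assemble_strokes(shape_template(shape_class, jitter_sd)))
  dense[, 1:2] <- pmin(1, pmax(-1, dense[, 1:2]))
  traj <- trajectory(dense, shape_class, variant_id = 0L)
  resample_trajectory(traj, n_points)
}

# --- resampling -------------------------------------------------------------

# interpolate along a polyline at arc-length positions tq (0..L)
interp_along <- function(pts, s, tq) {
  keep <- c(TRUE, diff(s) > 0)
  s2 <- s[keep]; p2 <- pts[keep, , drop = FALSE]
  if (length(s2) == 1L) return(matrix(rep(p2[1, ], each = length(tq)), ncol = 2))
  xs <- approx(s2, p2[, 1], xout = tq, rule = 2)$y
  ys <- approx(s2, p2[, 2], xout = tq, rule = 2)$y
  cbind(xs, ys)
}

# place n points on a polyline so that consecutive output chords have equal
# length; refined by a fixed-point iteration so that an input already in
# equal-chord position is returned unchanged (to floating-point precision)
equal_chord_points <- function(pts, n) {
  m <- nrow(pts)
  if (n == 1L) return(pts[1, , drop = FALSE])
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- s[m]
  if (L <= 0) return(matrix(rep(pts[1, ], each = n), ncol = 2))
  tq <- seq(0, L, length.out = n)
  for (it in 1:400) {
    P <- interp_along(pts, s, tq)
    g <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    if (g[n] <= 0) break
    target <- seq(0, g[n], length.out = n)
    keep <- c(TRUE, diff(g) > 0)
    tq_new <- approx(g[keep], tq[keep], xout = target, rule = 2)$y
    delta <- max(abs(tq_new - tq))
    tq <- tq_new
    if (delta < 1e-15 * L) break
  }
  interp_along(pts, s, tq)
}

#' Resample a trajectory to a fixed number of time steps
#'
#' Points are redistributed within each stroke (a maximal run of constant
#' pen state) so that consecutive samples are equally spaced along the
#' stroke's path, while stroke boundaries and stroke endpoints are
#' preserved.  Steps are allocated to strokes proportionally to their arc
#' length (at least two per stroke); when the input already has exactly `T`
#' steps the per-stroke counts are kept, which makes resampling idempotent.
#'
#' @param traj A [trajectory()] (or a 3-column matrix).
#' @param T Target number of time steps (>= 2, and >= 2 per stroke).
#' @return A [trajectory()] with exactly `T` steps.
#' @export
resample_trajectory <- function(traj, T = 90L) {
  pts <- if (inherits(traj, "pc_trajectory")) traj$points else {
    m <- as.matrix(traj); colnames(m) <- c("x", "y", "pen"); m
  }
  if (nrow(pts) < 1L) stop("trajectory is empty")
  if (T < 2L) stop("T must be >= 2")
  runs <- rle(pts[, "pen"])
  K <- length(runs$lengths)
  if (T < 2L * K)
    stop(sprintf("T = %d cannot preserve stroke structure (%d strokes need >= %d steps)",
                 T, K, 2L * K))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)

  seg_len <- vapply(seq_len(K), function(k) {
    p <- pts[starts[k]:ends[k], 1:2, drop = FALSE]
    if (nrow(p) < 2L) 0 else sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))

  if (nrow(pts) == T) {
    counts <- runs$lengths
  } else {
    extra <- T - 2L * K
    share <- if (sum(seg_len) > 0) seg_len / sum(seg_len) else rep(1 / K, K)
    quota <- share * extra
    counts <- 2L + floor(quota)
    rem <- quota - floor(quota)
    short <- extra - sum(floor(quota))
    if (short > 0) {
      ord <- order(-rem, seq_len(K))  # largest remainder, stable
      counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
    }
  }

  out <- matrix(NA_real_, T, 3)
  pos <- 1L
  for (k in seq_len(K)) {
    p <- pts[starts[k]:ends[k], 1:2, drop = FALSE]
    if (nrow(p) == 1L) p <- rbind(p, p)
    newp <- equal_chord_points(p, counts[k])
    out[pos:(pos + counts[k] - 1L), 1:2] <- newp
    out[pos:(pos + counts[k] - 1L), 3] <- runs$values[k]
    pos <- pos + counts[k]
  }
  colnames(out) <- c("x", "y", "pen")
  if (inherits(traj, "pc_trajectory"))
    trajectory(out, traj$shape_class, traj$variant_id)
  else
    trajectory(out, shape_classes()[1])
}

#' Build the synthetic drawing dataset
#'
#' Generates `n_per_class` jittered variants of each class, resamples each
#' to `timesteps` steps and splits them deterministically into training and
#' test sets (variants `0..n_train-1` train, the rest test).
#'
#' @param seed Integer master seed; every variant derives its jitter seed
#'   from it, so the dataset is a pure function of `seed`.
#' @param classes Character vector of shape classes to include.
#' @param n_per_class Variants per class (default 10).
#' @param timesteps Trajectory length after resampling (default 90).
#' @param n_train Training variants per class (default 7, i.e. a 70/30 split).
#' @param n_points Dense sample count before resampling.
#' @return A `drawing_dataset`: trajectories plus split bookkeeping.
#' @export
build_dataset <- function(seed = 0L, classes = shape_classes(),
                          n_per_class = 10L, timesteps = 90L,
                          n_train = 7L, n_points = 200L) {
  stopifnot(n_train >= 1L, n_train <= n_per_class)
  trajs <- list()
  split <- NULL
  id <- 0L
  for (cls in classes) {
    for (v in seq_len(n_per_class) - 1L) {
      id <- id + 1L
      tr <- generate_shape(cls, seed = seed * 131L + shape_class_code(cls) * 17L + v,
                           n_points = n_points)
      tr <- resample_trajectory(tr, timesteps)
      tr$variant_id <- v
      trajs[[id]] <- tr
      split <- rbind(split, data.frame(
        id = id, class = cls, class_code = shape_class_code(cls),
        variant_id = v, role = if (v < n_train) "train" else "test",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(trajectories = trajs, split = split, classes = classes,
                 timesteps = as.integer(timesteps), seed = as.integer(seed)),
            class = "drawing_dataset")
}

#' @export
print.drawing_dataset <- function(x, ...) {
  cat(sprintf("<drawing_dataset> %d classes x %d variants, %d steps (%d train / %d test)\n",
              length(x$classes), nrow(x$split) / length(x$classes), x$timesteps,
              sum(x$split$role == "train"), sum(x$split$role == "test")))
  invisible(x)
}

#' Extract the training / test trajectories of a dataset
#' @param dataset A `drawing_dataset`.
#' @return List of [trajectory()] objects.
#' @export
training_trajectories <- function(dataset) {
  dataset$trajectories[dataset$split$id[dataset$split$role == "train"]]
}

#' @rdname training_trajectories
#' @export
test_trajectories <- function(dataset) {
  dataset$trajectories[dataset$split$id[dataset$split$role == "test"]]
}
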