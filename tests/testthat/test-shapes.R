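test_that("shape generation is a pure function of (class, seed) and jitter varies variants", {
  a <- generate_shape("FACE", seed = 0, n_points = 200)
  b <- generate_shape("FACE", seed = 0, n_points = 200)
  expect_identical(a$points, b$points)

  c <- generate_shape("FACE", seed = 1, n_points = 200)
  expect_gt(max(abs(a$points - c$points)), 0)
  # both variants stay multi-stroke (at least two pen-up transitions)
  expect_gte(sum(diff(a$points[, "pen"]) == -1), 2)
  expect_gte(sum(diff(c$points[, "pen"]) == -1), 2)
})

test_that("every sample of every generated shape lies in [-1, 1]", {
  for (cls in shape_classes()) {
    for (s in 0:2) {
      tr <- generate_shape(cls, seed = s, n_points = 200)
      expect_true(all(tr$points[, c("x", "y")] >= -1 & tr$points[, c("x", "y")] <= 1),
                  info = paste(cls, s))
    }
  }
})

test_that("unknown shape classes are rejected with an explicit message", {
  expect_error(generate_shape("BOAT", 0), "BOAT")
  expect_error(shape_class_code("TREE"), "unknown shape class")
})

test_that("resampling yields the requested length and preserves stroke structure", {
  tr <- generate_shape("HOUSE", 0, 200)
  r <- resample_trajectory(tr, 90)
  expect_equal(nrow(r$points), 90)

  transitions <- function(p) sum(diff(p[, "pen"]) != 0)
  two <- trajectory(rbind(cbind(seq(0, 0.5, length.out = 20), 0, 1),
                          cbind(seq(0.5, 0.9, length.out = 10), 0.2, 0)),
                    "CAR")
  r2 <- resample_trajectory(two, 90)
  expect_equal(transitions(r2$points), transitions(two$points))

  # too few steps to give every stroke its endpoints
  many <- generate_shape("FLOWER", 0, 200)   # 6 strokes + bridges
  expect_error(resample_trajectory(many, 12), "stroke structure")
})

test_that("resampling an already uniform trajectory is the identity", {
  pts <- cbind(seq(-0.5, 0.5, length.out = 90),
               seq(-0.2, 0.4, length.out = 90), 1)
  tr <- trajectory(pts, "FACE")
  r <- resample_trajectory(tr, 90)
  expect_lt(max(abs(r$points - tr$points)), 1e-9)
})

test_that("resampling is idempotent within 1e-9", {
  for (cls in shape_classes()) {
    tr <- generate_shape(cls, seed = 7, n_points = 200)
    r1 <- resample_trajectory(tr, 90)
    r2 <- resample_trajectory(r1, 90)
    expect_lt(max(abs(r1$points - r2$points)), 1e-9)
  }
})

test_that("the dataset has 10 variants per class split 7/3, deterministically", {
  ds <- build_dataset(0)
  expect_equal(length(ds$trajectories), 60)
  expect_equal(sum(ds$split$role == "train"), 42)
  expect_equal(sum(ds$split$role == "test"), 18)
  for (cls in shape_classes()) {
    sub <- ds$split[ds$split$class == cls, ]
    expect_equal(sum(sub$role == "train"), 7)
    expect_equal(sum(sub$role == "test"), 3)
    expect_length(intersect(sub$variant_id[sub$role == "train"],
                            sub$variant_id[sub$role == "test"]), 0)
    expect_setequal(sub$variant_id, 0:9)
  }
  ds2 <- build_dataset(0)
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$trajectories[[13]]$points, ds2$trajectories[[13]]$points)
  expect_equal(nrow(ds$trajectories[[1]]$points), 90)
})

test_that("variants of the same class are mutually closer than across classes", {
  ds <- build_dataset(0)
  trajs <- ds$trajectories
  mse <- function(a, b) mean(rowSums((a$points[, 1:2] - b$points[, 1:2])^2))
  same <- c(); other <- c()
  for (i in 1:(length(trajs) - 1)) {
    for (j in (i + 1):length(trajs)) {
      v <- mse(trajs[[i]], trajs[[j]])
      if (trajs[[i]]$shape_class == trajs[[j]]$shape_class) same <- c(same, v)
      else other <- c(other, v)
    }
  }
  expect_lt(mean(same), mean(other))
})

test_that("trajectory files round-trip and malformed files are rejected", {
  ds <- build_dataset(2, shape_classes()[1:2], n_per_class = 3L, n_train = 2L)
  dir <- withr::local_tempdir()
  write_trajectories(ds, dir)
  back <- read_trajectories(dir)
  expect_equal(length(back$trajectories), length(ds$trajectories))
  for (i in seq_along(ds$trajectories)) {
    expect_lt(max(abs(back$trajectories[[i]]$points - ds$trajectories[[i]]$points)), 1e-9)
    expect_identical(back$trajectories[[i]]$shape_class, ds$trajectories[[i]]$shape_class)
    expect_identical(back$trajectories[[i]]$points[, "pen"],
                     ds$trajectories[[i]]$points[, "pen"])
  }
  expect_identical(back$split$role, ds$split$role)

  # pen value outside {0, 1} names the offending row
  csv <- file.path(dir, "trajectories.csv")
  rows <- read.csv(csv)
  rows$pen[5] <- 2
  write.csv(rows, csv, row.names = FALSE, quote = FALSE)
  expect_error(read_trajectories(dir), "row 5")

  # an empty file has zero classes
  writeLines("trajectory_id,class,t,x,y,pen", csv)
  expect_error(read_trajectories(dir), "zero classes")
})
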