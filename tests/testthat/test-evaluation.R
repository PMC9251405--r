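make_traj <- function(xy, cls, variant = 0L, pen = 1) {
  trajectory(cbind(xy, pen), cls, variant)
}

test_that("distance to the closest training trajectory is an exact pointwise MSE", {
  # toy case with a 6-step trajectory: presented = first 2 steps
  drawing <- cbind(x = c(0, 1, 0, 0, 0, 0), y = numeric(6), pen = 1)
  cand <- make_traj(matrix(0, 6, 2), "FACE")
  d <- distance_to_closest(drawing, list(cand), segment = "presented")
  expect_equal(d$error, (0 + 1) / 2)

  # identity: zero error and the matching class wins
  ds <- build_dataset(1, shape_classes()[1:2], n_per_class = 2L, n_train = 2L)
  train <- training_trajectories(ds)
  self <- distance_to_closest(train[[3]]$points, train, segment = "completed")
  expect_equal(self$error, 0)
  expect_identical(self$closest_class, train[[3]]$shape_class)

  # the presented segment ignores everything after step T/3
  base <- train[[1]]$points
  mod <- base
  mod[40:90, 1:2] <- 0.9
  d1 <- distance_to_closest(base, train, segment = "presented")
  d2 <- distance_to_closest(mod, train, segment = "presented")
  expect_equal(d1$error, d2$error)

  expect_error(distance_to_closest(base, list(), "presented"), "empty")
})

make_distance_df <- function(errors, mis, h_sensor = 1, h_prior = 1,
                             segment = "completed", class = "FACE",
                             variant = seq_along(errors)) {
  data.frame(h_sensor = h_sensor, h_prior = h_prior, network_id = 0L,
             intended_class = class, variant_id = variant,
             repetition = 0L, segment = segment, error = errors,
             closest_class = ifelse(mis, "HOUSE", class),
             misinterpreted = mis, stringsAsFactors = FALSE)
}

test_that("misinterpretation percentages and scribble masking follow the rules", {
  # 4 results, exactly 1 mismatch -> 25 %
  df <- make_distance_df(c(0.1, 0.1, 0.1, 0.1), c(TRUE, FALSE, FALSE, FALSE))
  m <- misinterpretation_rate(df)
  expect_equal(cell_value(m, "pct", 1, 1, "completed"), 25)
  expect_false(cell_value(m, "mask", 1, 1, "completed"))

  # all matching -> 0 % in the (unmasked) cell
  m0 <- misinterpretation_rate(make_distance_df(rep(0.05, 6), rep(FALSE, 6)))
  expect_equal(cell_value(m0, "pct", 1, 1, "completed"), 0)

  # a cell with mean error 0.31 is masked and emits no percentage
  mm <- misinterpretation_rate(make_distance_df(c(0.31, 0.31), c(FALSE, TRUE)))
  expect_true(cell_value(mm, "mask", 1, 1, "completed"))
  expect_true(is.na(cell_value(mm, "pct", 1, 1, "completed")))

  # relabeling variant ids within a class changes nothing
  df2 <- make_distance_df(runif(6, 0, 0.2), rep(c(TRUE, FALSE), 3))
  df3 <- df2; df3$variant_id <- rev(df3$variant_id)
  expect_equal(misinterpretation_rate(df2)$pct, misinterpretation_rate(df3)$pct)
})

test_that("mean errors per cell average exactly and ignore duplicates' weight", {
  df <- make_distance_df(c(0.1, 0.3), c(FALSE, FALSE))
  m <- summarize_errors(df)
  expect_equal(cell_value(m, "error", 1, 1, "completed"), 0.2)

  one <- summarize_errors(make_distance_df(0.17, FALSE))
  expect_equal(cell_value(one, "error", 1, 1, "completed"), 0.17)

  dup <- summarize_errors(make_distance_df(c(0.1, 0.3, 0.2), logical(3)))
  expect_equal(cell_value(dup, "error", 1, 1, "completed"), 0.2)
})

test_that("sweep matrices survive the JSON round trip", {
  df <- rbind(
    make_distance_df(c(0.1, 0.5), c(FALSE, TRUE), h_sensor = 0.001, h_prior = 1000),
    make_distance_df(c(0.05, 0.08), c(FALSE, FALSE), h_sensor = 1, h_prior = 1),
    make_distance_df(c(0.35, 0.4), c(TRUE, FALSE), h_sensor = 1000, h_prior = 1000,
                     segment = "presented"))
  m <- misinterpretation_rate(df)
  path <- withr::local_tempfile(fileext = ".json")
  write_sweep_matrix(m, path)
  back <- read_sweep_matrix(path)
  expect_equal(back$h_values, m$h_values)
  expect_equal(back$error, m$error)
  expect_equal(back$pct, m$pct)
  expect_equal(back$mask, m$mask)
  expect_equal(back$n, m$n)
})

test_that("rendering produces nine panels, heatmaps and a matrix file", {
  st <- study_fixture()
  dir <- withr::local_tempdir()
  plots <- render_outputs(st$misinterpretation, st$sweep, dir)
  built <- ggplot2::ggplot_build(plots$grid)
  expect_equal(nrow(built$layout$layout), 9)
  expect_true(file.exists(file.path(dir, "grid.png")))
  expect_true(file.exists(file.path(dir, "error_completed.png")))
  expect_true(file.exists(file.path(dir, "pct_completed.png")))
  back <- read_sweep_matrix(file.path(dir, "matrix.json"))
  expect_equal(back$error, st$misinterpretation$error)

  # masked cells render in the sentinel gray, distinct from a genuine 0 %
  df <- rbind(
    make_distance_df(c(0.35, 0.41), c(FALSE, TRUE), h_sensor = 0.001, h_prior = 0.001),
    make_distance_df(c(0.05, 0.08), c(FALSE, FALSE), h_sensor = 1, h_prior = 1),
    make_distance_df(c(0.01, 0.02), c(FALSE, FALSE), h_sensor = 1000, h_prior = 1000))
  mm <- misinterpretation_rate(df)
  pm <- plot_sweep_matrix(mm, "pct", "completed")
  dat <- ggplot2::ggplot_build(pm)$data[[1]]
  expect_true("gray60" %in% dat$fill)
  expect_true(any(dat$fill != "gray60" & !is.na(dat$fill)))
})
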