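#' Distance of a drawing to its closest training trajectory
#'
#' Pointwise (same time index) squared Euclidean distance on (x, y),
#' averaged over the steps of the chosen segment and minimized over all
#' training trajectories.  Ties break toward the lowest class code, then
#' the lowest variant id.  The pen channel is excluded by default so that
#' stroke-break encoding does not dominate the spatial error; set
#' `use_pen = TRUE` to include it.
#'
#' @param drawing A `completion_result` or a T x 3 matrix.
#' @param training_set List of training [trajectory()] objects aligned to
#'   the same length.
#' @param segment `"presented"` (steps 1..T/3) or `"completed"` (the rest).
#' @param use_pen Include the pen channel in the distance.
#' @return List with `error`, `closest_class`, `closest_variant`.
#' @export
distance_to_closest <- function(drawing, training_set,
                                segment = c("presented", "completed"),
                                use_pen = FALSE) {
  segment <- match.arg(segment)
  if (length(training_set) == 0L) stop("empty training set")
  drawn <- if (inherits(drawing, "completion_result")) drawing$drawn else as.matrix(drawing)
  T_full <- nrow(drawn)
  idx <- if (inherits(drawing, "completion_result")) {
    if (segment == "presented") drawing$presented_steps else drawing$completed_steps
  } else {
    if (segment == "presented") seq_len(T_full %/% 3L)
    else seq.int(T_full %/% 3L + 1L, T_full)
  }
  dims <- if (use_pen) 1:3 else 1:2

  errs <- vapply(training_set, function(tr) {
    if (nrow(tr$points) != T_full)
      stop("training trajectory length does not match the drawing")
    mean(rowSums((drawn[idx, dims, drop = FALSE] -
                  tr$points[idx, dims, drop = FALSE])^2))
  }, numeric(1))
  codes <- vapply(training_set, function(tr) tr$class_code, numeric(1))
  vars <- vapply(training_set, function(tr) as.numeric(tr$variant_id), numeric(1))
  k <- order(errs, codes, vars)[1L]
  list(error = errs[k],
       closest_class = training_set[[k]]$shape_class,
       closest_variant = training_set[[k]]$variant_id)
}

#' Score every sweep record against the training set
#'
#' @param sweep A [run_sweep()] result (or a plain list of
#'   `completion_result` records).
#' @param dataset The dataset whose training split is the reference.
#' @param use_pen Include the pen channel in distances.
#' @return A data frame with one row per (record, segment): precision cell,
#'   provenance, `error`, `closest_class` and `misinterpreted`.
#' @export
evaluate_sweep <- function(sweep, dataset, use_pen = FALSE) {
  records <- if (inherits(sweep, "sweep_results")) sweep$records else sweep
  train <- training_trajectories(dataset)
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(c("presented", "completed"), function(seg) {
      d <- distance_to_closest(rec, train, segment = seg, use_pen = use_pen)
      data.frame(h_sensor = rec$h_sensor, h_prior = rec$h_prior,
                 network_id = rec$network_id,
                 intended_class = rec$intended_class,
                 variant_id = rec$variant_id, repetition = rec$repetition,
                 segment = seg, error = d$error,
                 closest_class = d$closest_class,
                 misinterpreted = !identical(d$closest_class, rec$intended_class),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

new_sweep_matrix <- function(h_values, segments = c("presented", "completed")) {
  hv <- as.character(h_values)
  arr <- array(NA_real_, dim = c(length(hv), length(hv), length(segments)),
               dimnames = list(h_prior = hv, h_sensor = hv, segment = segments))
  structure(list(h_values = h_values, error = arr, pct = arr,
                 mask = array(FALSE, dim = dim(arr), dimnames = dimnames(arr)),
                 n = arr), class = "sweep_matrix")
}

#' Mean completion error per precision cell
#'
#' The machine twin of the error heatmaps: the mean of the
#' closest-training-trajectory error over all records of each cell,
#' separately for the presented and completed segments.
#'
#' @param distances A data frame from [evaluate_sweep()].
#' @return A `sweep_matrix` with the `error` and `n` fields filled; rows
#'   are `H_prior` values, columns `H_sensor`, in ascending numeric order
#'   (plotting reverses the axes so low precision sits bottom-left).
#' @export
summarize_errors <- function(distances) {
  hv <- sort(unique(c(distances$h_prior, distances$h_sensor)))
  m <- new_sweep_matrix(hv)
  for (seg in c("presented", "completed")) {
    for (hp in hv) for (hs in hv) {
      sub <- distances[distances$segment == seg & distances$h_prior == hp &
                         distances$h_sensor == hs, ]
      m$n[as.character(hp), as.character(hs), seg] <- nrow(sub)
      if (nrow(sub) > 0L)
        m$error[as.character(hp), as.character(hs), seg] <- mean(sub$error)
    }
  }
  m$pct <- NULL
  m
}

#' Misinterpretation percentage per precision cell, with scribble masking
#'
#' A completion is misinterpreted when its closest training shape is not
#' the intended shape.  Cells whose mean error reaches the scribble
#' threshold are masked: the drawing is not similar to any training shape
#' there, so no misinterpretation percentage is meaningful.  Empty cells
#' are masked with reason "no data".
#'
#' @param distances A data frame from [evaluate_sweep()].
#' @param scribble_threshold Mean error at or above which a cell counts as
#'   scribbling (default 0.3).
#' @return A `sweep_matrix` with `error`, `pct` (percentage, NA where
#'   masked), `mask` and `n` filled.
#' @export
misinterpretation_rate <- function(distances, scribble_threshold = 0.3) {
  hv <- sort(unique(c(distances$h_prior, distances$h_sensor)))
  m <- new_sweep_matrix(hv)
  for (seg in c("presented", "completed")) {
    for (hp in hv) for (hs in hv) {
      i <- as.character(hp); j <- as.character(hs)
      sub <- distances[distances$segment == seg & distances$h_prior == hp &
                         distances$h_sensor == hs, ]
      m$n[i, j, seg] <- nrow(sub)
      if (nrow(sub) == 0L) {
        m$mask[i, j, seg] <- TRUE  # no data
        next
      }
      m$error[i, j, seg] <- mean(sub$error)
      if (m$error[i, j, seg] >= scribble_threshold) {
        m$mask[i, j, seg] <- TRUE
      } else {
        m$pct[i, j, seg] <- 100 * mean(sub$misinterpreted)
      }
    }
  }
  m
}

#' Look up one cell of a sweep matrix
#'
#' @param m A `sweep_matrix`.
#' @param stat `"error"`, `"pct"`, `"mask"` or `"n"`.
#' @param h_sensor,h_prior Cell coordinates (precision factors).
#' @param segment `"presented"` or `"completed"`.
#' @return The scalar cell value.
#' @export
cell_value <- function(m, stat, h_sensor, h_prior,
                       segment = c("completed", "presented")) {
  segment <- match.arg(segment)
  m[[stat]][as.character(h_prior), as.character(h_sensor), segment]
}

#' @export
print.sweep_matrix <- function(x, ...) {
  for (seg in dimnames(x$error)$segment) {
    cat(sprintf("mean error (%s part), rows H_prior / cols H_sensor:\n", seg))
    print(round(x$error[, , seg], 4))
    if (!is.null(x$pct)) {
      cat(sprintf("misinterpretation %% (%s part), masked cells NA:\n", seg))
      print(round(x$pct[, , seg], 1))
    }
  }
  invisible(x)
}

#' Write / read a sweep matrix as JSON
#'
#' Axes ordering in the file: `h_values` ascending; `error`, `pct`, `mask`
#' and `n` are row-major lists of rows, rows indexed by `H_prior` and
#' columns by `H_sensor`, one matrix per segment.
#'
#' @param m A `sweep_matrix`.
#' @param path JSON file path.
#' @return `read_sweep_matrix` returns the reconstructed `sweep_matrix`.
#' @export
write_sweep_matrix <- function(m, path) {
  obj <- list(h_values = m$h_values,
              segments = dimnames(m$error)$segment,
              axes = "rows: h_prior ascending; cols: h_sensor ascending")
  nh <- length(m$h_values)
  for (f in c("error", "pct", "mask", "n")) {
    if (is.null(m[[f]])) next
    obj[[f]] <- lapply(dimnames(m$error)$segment, function(seg)
      lapply(seq_len(nh), function(i)
        lapply(seq_len(nh), function(j) {
          v <- m[[f]][i, j, seg]
          if (is.na(v)) NULL else v
        })))
    names(obj[[f]]) <- dimnames(m$error)$segment
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep_matrix
#' @export
read_sweep_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  hv <- unlist(obj$h_values)
  segs <- unlist(obj$segments)
  m <- new_sweep_matrix(hv, segs)
  for (f in c("error", "pct", "mask", "n")) {
    if (is.null(obj[[f]])) { m[f] <- list(NULL); next }
    for (seg in segs) {
      rows <- obj[[f]][[seg]]
      for (i in seq_along(rows)) for (j in seq_along(rows[[i]])) {
        v <- rows[[i]][[j]]
        m[[f]][i, j, seg] <- if (is.null(v)) NA else
          if (f == "mask") as.logical(v) else as.numeric(v)
      }
    }
  }
  m
}

#' Fraction of completions whose closest shape is the intended one
#'
#' @param distances A data frame from [evaluate_sweep()].
#' @param h_sensor,h_prior Precision cell to evaluate.
#' @param segment Which segment to score (default `"completed"`).
#' @return Proportion in `[0, 1]`.
#' @export
completion_accuracy <- function(distances, h_sensor = 1, h_prior = 1,
                                segment = "completed") {
  sub <- distances[distances$segment == segment &
                     distances$h_sensor == h_sensor &
                     distances$h_prior == h_prior, ]
  if (nrow(sub) == 0L) return(NA_real_)
  mean(!sub$misinterpreted)
}
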