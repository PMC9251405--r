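#' Write / read a drawing dataset
#'
#' Trajectories are stored as delimited text, one sample per row
#' (`trajectory_id, class, t, x, y, pen`), next to a JSON manifest holding
#' the generation seed, the class codes and the train/test split.  The
#' round trip is lossless on pen states and labels and exact on
#' coordinates to the stored precision (17 significant digits).
#'
#' @param dataset A [build_dataset()] result.
#' @param path Directory to write `trajectories.csv` and `manifest.json` to
#'   (created if missing).
#' @return `read_trajectories` returns the reconstructed `drawing_dataset`.
#' @export
write_trajectories <- function(dataset, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  rows <- do.call(rbind, lapply(seq_along(dataset$trajectories), function(i) {
    tr <- dataset$trajectories[[i]]
    data.frame(trajectory_id = i, class = tr$shape_class,
               t = seq_len(nrow(tr$points)),
               x = sprintf("%.17g", tr$points[, "x"]),
               y = sprintf("%.17g", tr$points[, "y"]),
               pen = as.integer(tr$points[, "pen"]),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, file.path(path, "trajectories.csv"), row.names = FALSE,
            quote = FALSE)
  manifest <- list(
    seed = dataset$seed, timesteps = dataset$timesteps,
    classes = dataset$classes,
    class_codes = setNames(as.list(shape_class_code(dataset$classes)),
                           dataset$classes),
    split = dataset$split)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  csv <- file.path(path, "trajectories.csv")
  mf <- file.path(path, "manifest.json")
  if (!file.exists(csv)) stop("no trajectory file at ", csv)
  rows <- read.csv(csv, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) stop("trajectory file has zero classes: ", csv)
  need <- c("trajectory_id", "class", "t", "x", "y", "pen")
  if (!all(need %in% names(rows)))
    stop("malformed trajectory file (missing columns): ", csv)
  bad <- which(!(rows$pen %in% c(0L, 1L)))
  if (length(bad) > 0L)
    stop(sprintf("parse error in %s: row %d has pen value %s (expected 0 or 1)",
                 csv, bad[1L], rows$pen[bad[1L]]))
  bad_xy <- which(!is.finite(rows$x) | !is.finite(rows$y))
  if (length(bad_xy) > 0L)
    stop(sprintf("parse error in %s: row %d has non-numeric coordinates",
                 csv, bad_xy[1L]))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  split <- as.data.frame(manifest$split, stringsAsFactors = FALSE)

  trajs <- lapply(sort(unique(rows$trajectory_id)), function(id) {
    sub <- rows[rows$trajectory_id == id, ]
    sub <- sub[order(sub$t), ]
    vid <- split$variant_id[split$id == id]
    trajectory(cbind(x = sub$x, y = sub$y, pen = sub$pen),
               sub$class[1L], if (length(vid)) vid else 0L)
  })
  structure(list(trajectories = trajs, split = split,
                 classes = manifest$classes,
                 timesteps = as.integer(manifest$timesteps),
                 seed = as.integer(manifest$seed)),
            class = "drawing_dataset")
}
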