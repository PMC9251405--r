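axis_levels <- function(h_values) {
  # low precision (large H) bottom-left, high precision top-right
  as.character(sort(h_values, decreasing = TRUE))
}

#' Grid of drawn completions, one panel per precision cell
#'
#' Presented steps are drawn in black (solid pen-down, dashed pen-up),
#' completed steps in green, for one network and one repetition.
#'
#' @param sweep A [run_sweep()] result.
#' @param network_id Which network to display (0-based; default the first).
#' @param repetition Which repetition (default 0).
#' @return A ggplot object with a 3 x 3 facet grid (rows `H_prior` from
#'   low precision at the bottom, columns `H_sensor` likewise).
#' @export
plot_completion_grid <- function(sweep, network_id = 0L, repetition = 0L) {
  recs <- Filter(function(r) r$network_id == network_id &&
                   r$repetition == repetition, sweep$records)
  if (length(recs) == 0L) stop("no records for this network/repetition")
  df <- do.call(rbind, lapply(recs, function(r) {
    n <- nrow(r$drawn)
    pen <- ifelse(r$drawn[, "pen"] >= 0.5, "down", "up")
    part <- ifelse(seq_len(n) %in% r$presented_steps, "presented", "completed")
    run <- cumsum(c(TRUE, pen[-1] != pen[-n] | part[-1] != part[-n]))
    data.frame(x = r$drawn[, "x"], y = r$drawn[, "y"], pen = pen, part = part,
               piece = paste(r$intended_class, r$variant_id, run),
               h_sensor = as.character(r$h_sensor),
               h_prior = as.character(r$h_prior),
               stringsAsFactors = FALSE)
  }))
  lv <- axis_levels(sweep$plan$h_values)
  df$h_sensor <- factor(df$h_sensor, levels = rev(lv))   # left -> right: low precision first
  df$h_prior <- factor(df$h_prior, levels = lv)          # facet rows top -> bottom
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, group = piece,
                                   colour = part, linetype = pen)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::facet_grid(h_prior ~ h_sensor,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(presented = "black",
                                            completed = "forestgreen")) +
    ggplot2::scale_linetype_manual(values = c(down = "solid", up = "dashed")) +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a sweep-matrix statistic
#'
#' @param m A `sweep_matrix`.
#' @param stat `"error"` or `"pct"`.
#' @param segment `"presented"` or `"completed"`.
#' @return A ggplot tile map; masked cells (scribbling or no data) are
#'   drawn gray without a value label.
#' @export
plot_sweep_matrix <- function(m, stat = c("error", "pct"),
                              segment = c("completed", "presented")) {
  stat <- match.arg(stat); segment <- match.arg(segment)
  hv <- as.character(m$h_values)
  df <- expand.grid(h_prior = hv, h_sensor = hv, stringsAsFactors = FALSE)
  df$value <- mapply(function(i, j) m[[stat]][i, j, segment],
                     df$h_prior, df$h_sensor)
  df$masked <- mapply(function(i, j) isTRUE(m$mask[i, j, segment]),
                      df$h_prior, df$h_sensor)
  df$value[df$masked] <- NA_real_
  lv <- axis_levels(m$h_values)
  df$h_sensor <- factor(df$h_sensor, levels = rev(lv))
  df$h_prior <- factor(df$h_prior, levels = rev(lv))    # y axis bottom -> top
  lab <- ifelse(df$masked, "", ifelse(is.na(df$value), "",
                                      sprintf("%.2f", df$value)))
  ggplot2::ggplot(df, ggplot2::aes(x = h_sensor, y = h_prior, fill = value)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(label = lab, size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "gray60") +
    ggplot2::labs(x = "H_sensor (variance factor)",
                  y = "H_prior (variance factor)",
                  fill = stat,
                  title = sprintf("%s (%s part)",
                                  if (stat == "error") "mean error"
                                  else "misinterpretation %", segment)) +
    ggplot2::theme_minimal()
}

#' Render all sweep outputs to a directory
#'
#' Writes the per-cell completion grid, the error heatmaps for both
#' segments, the misinterpretation heatmaps (masked cells gray), and a
#' machine-readable `matrix.json`.
#'
#' @param matrix A `sweep_matrix` from [misinterpretation_rate()].
#' @param sweep The [run_sweep()] result the matrix was computed from.
#' @param out_dir Output directory (created if missing).
#' @param network_id Network shown in the trajectory grid.
#' @return Invisibly, the list of ggplot objects that were written.
#' @export
render_outputs <- function(matrix, sweep, out_dir, network_id = 0L) {
  if (length(sweep$records) == 0L) stop("no sweep records to render")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  plots <- list(grid = plot_completion_grid(sweep, network_id))
  for (seg in c("presented", "completed")) {
    plots[[paste0("error_", seg)]] <- plot_sweep_matrix(matrix, "error", seg)
    if (!is.null(matrix$pct))
      plots[[paste0("pct_", seg)]] <- plot_sweep_matrix(matrix, "pct", seg)
  }
  for (nm in names(plots)) {
    ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), plots[[nm]],
                    width = 7, height = 6, dpi = 120)
  }
  write_sweep_matrix(matrix, file.path(out_dir, "matrix.json"))
  invisible(plots)
}

utils::globalVariables(c("x", "y", "piece", "part", "pen", "h_sensor", "h_prior", "value"))
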