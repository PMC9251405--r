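#' Plan of the factorial precision sweep
#'
#' The Cartesian product of the `H_sensor` and `H_prior` axes (3 x 3 = 9
#' cells by default), the set of independently trained networks, and the
#' number of completion repetitions per (network, test prefix).
#'
#' @param h_values Precision scaling factors for both axes
#'   (default `c(0.001, 1, 1000)`).
#' @param n_networks Number of independently trained networks (default 10).
#' @param n_repetitions Completions per (network, prefix, cell) (default 3).
#' @param network_seeds One seed per network; repetition seeds derive as
#'   `network_seed * 1000 + repetition_index`, so the same prefixes and
#'   recognition starts are used in every cell (paired design).
#' @return A list of class `sweep_plan`.
#' @export
sweep_plan <- function(h_values = c(0.001, 1, 1000), n_networks = 10L,
                       n_repetitions = 3L,
                       network_seeds = seq_len(n_networks) - 1L) {
  if (length(network_seeds) != n_networks)
    stop("need exactly one seed per network")
  structure(list(h_values = sort(h_values), n_networks = as.integer(n_networks),
                 n_repetitions = as.integer(n_repetitions),
                 network_seeds = as.integer(network_seeds)),
            class = "sweep_plan")
}

#' Expected number of completion records for a plan
#' @param plan A [sweep_plan()].
#' @param dataset The dataset the sweep runs on.
#' @return Integer: cells x networks x test prefixes x repetitions.
#' @export
sweep_expected_count <- function(plan, dataset) {
  length(plan$h_values)^2 * plan$n_networks *
    length(test_trajectories(dataset)) * plan$n_repetitions
}

#' Train a set of independently seeded networks
#'
#' @param dataset A [build_dataset()] result.
#' @param config A [training_config()]; its `seed` is replaced per network.
#' @param seeds One integer seed per network.
#' @param precision [precision_config()] used during training (normal
#'   reliance by default).
#' @param dir Optional directory: each model is checkpointed to
#'   `model_<seed>.rds`.
#' @param verbose Forwarded to [train_sctrnn()].
#' @return List of trained models; networks whose training diverged are
#'   dropped with a warning naming the seed and reason.
#' @export
train_model_set <- function(dataset, config = training_config(), seeds,
                            precision = precision_config(), dir = NULL,
                            verbose = FALSE) {
  models <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    m <- tryCatch(train_sctrnn(dataset, cfg, precision, verbose = verbose),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warning("network with seed ", s, " excluded: ", conditionMessage(m))
      next
    }
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      save_checkpoint(m, file.path(dir, sprintf("model_%d.rds", s)))
    }
    models[[length(models) + 1L]] <- m
  }
  models
}

record_key <- function(rec) {
  paste(rec$h_sensor, rec$h_prior, rec$network_id, rec$intended_class,
        rec$variant_id, rec$repetition, sep = "|")
}

record_to_json <- function(rec) {
  jsonlite::toJSON(list(
    h_sensor = rec$h_sensor, h_prior = rec$h_prior,
    network_id = rec$network_id, class = rec$intended_class,
    variant_id = rec$variant_id, repetition = rec$repetition,
    inferred_initial_state = rec$inferred_initial_state,
    drawn = unname(rec$drawn)), auto_unbox = TRUE, digits = NA)
}

json_to_record <- function(line) {
  obj <- jsonlite::fromJSON(line)
  drawn <- matrix(unlist(obj$drawn), ncol = 3,
                  byrow = !is.matrix(obj$drawn))
  if (is.matrix(obj$drawn)) drawn <- obj$drawn
  colnames(drawn) <- c("x", "y", "pen")
  n <- nrow(drawn)
  structure(list(drawn = drawn,
                 presented_steps = seq_len(n %/% 3L),
                 completed_steps = seq.int(n %/% 3L + 1L, n),
                 inferred_initial_state = as.numeric(obj$inferred_initial_state),
                 h_prior = obj$h_prior, h_sensor = obj$h_sensor,
                 intended_class = obj$class, variant_id = obj$variant_id,
                 network_id = obj$network_id, repetition = obj$repetition),
            class = "completion_result")
}

#' Read a JSON-lines sweep record file
#' @param path JSON-lines file written by [run_sweep()].
#' @return Named list of `completion_result` records.
#' @export
read_sweep_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, json_to_record)
  names(recs) <- vapply(recs, record_key, character(1))
  recs
}

#' Run the full factorial precision sweep
#'
#' Every (cell, network, test prefix, repetition) combination is completed
#' with identical prefixes and repetition seeds across cells, so the
#' precision configuration is the only variable between cells.  Records can
#' be streamed to a JSON-lines file and the run resumed: combinations
#' already present in `out_file` are loaded instead of recomputed, and the
#' final record set equals an uninterrupted run.
#'
#' @param models List of trained models (see [train_model_set()]).
#' @param dataset The dataset whose test prefixes are completed.
#' @param plan A [sweep_plan()]; `plan$n_networks` must match `models`.
#' @param cfg_base [precision_config()] supplying the base sensory variance.
#' @param out_file Optional JSON-lines path for streaming/resuming.
#' @param recognition_epochs Epochs of each recognition step.
#' @param verbose Print one line per cell.
#' @return A `sweep_results` object: all completion records plus the plan.
#' @export
run_sweep <- function(models, dataset, plan, cfg_base = precision_config(),
                      out_file = NULL, recognition_epochs = 100L,
                      verbose = FALSE) {
  if (length(models) != plan$n_networks)
    stop("missing checkpoints: plan expects ", plan$n_networks,
         " networks, got ", length(models))
  tests <- test_trajectories(dataset)
  if (length(tests) == 0L) stop("dataset has no test trajectories")
  prefixes <- lapply(tests, prefix_of)

  existing <- if (!is.null(out_file) && file.exists(out_file))
    read_sweep_records(out_file) else list()

  records <- list()
  con <- if (!is.null(out_file)) file(out_file, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con))

  for (hs in plan$h_values) for (hp in plan$h_values) {
    if (verbose) message(sprintf("cell H_sensor = %g, H_prior = %g", hs, hp))
    cfg <- precision_config(h_prior = hp, h_sensor = hs,
                            sigma_sensor2 = cfg_base$sigma_sensor2)
    for (ni in seq_along(models)) {
      for (pf in prefixes) {
        for (rep_i in seq_len(plan$n_repetitions) - 1L) {
          stub <- list(h_sensor = hs, h_prior = hp, network_id = ni - 1L,
                       intended_class = pf$intended_class,
                       variant_id = pf$variant_id, repetition = rep_i)
          key <- record_key(stub)
          if (key %in% names(existing)) {
            records[[key]] <- existing[[key]]
            next
          }
          res <- complete_drawing(models[[ni]], pf, cfg,
                                  repetition_seed = plan$network_seeds[ni] * 1000L + rep_i,
                                  recognition_epochs = recognition_epochs)
          res$network_id <- ni - 1L
          res$repetition <- rep_i
          attr(res, "recognition") <- NULL
          records[[key]] <- res
          if (!is.null(con)) writeLines(record_to_json(res), con)
        }
      }
    }
  }
  structure(list(records = records, plan = plan,
                 sigma_sensor2 = cfg_base$sigma_sensor2),
            class = "sweep_results")
}

#' @export
print.sweep_results <- function(x, ...) {
  cat(sprintf("<sweep_results> %d completion records over %d cells\n",
              length(x$records), length(x$plan$h_values)^2))
  invisible(x)
}
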