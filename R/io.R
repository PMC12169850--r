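#' Read and write spike rasters as CSV event lists
#'
#' Rasters are stored as plain CSV with header
#' `neuron_id,time_ms,population` (population is `"net"` for the
#' single-population models, `"exc"`/`"inh"` for the Dale's-law model,
#' `"input"` for afferent spikes).
#'
#' @param raster data frame with columns `neuron` and `time_ms` (as
#'   returned in a `phase_recording`).
#' @param file path.
#' @param population population label.
#' @return `write_raster_csv()` returns `file` invisibly;
#'   `read_raster_csv()` returns the raster data frame.
#' @export
write_raster_csv <- function(raster, file, population = "net") {
  df <- data.frame(neuron_id = raster$neuron, time_ms = raster$time_ms,
                   population = population)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("neuron_id", "time_ms", "population") %in% names(df)))
  df
}

#' Read and write stimulus schedules as CSV
#'
#' Event lists serialize as `pattern_id,onset_ms,offset_ms`; the group
#' membership and protocol parameters travel in a JSON side-car written by
#' [write_schedule_csv()] when `json` is not `NULL`.
#'
#' @param schedule a `stimulus_schedule`.
#' @param file CSV path.
#' @param json optional path for the JSON membership/parameter block.
#' @return `write_schedule_csv()` returns `file` invisibly;
#'   `read_schedule_csv()` returns a data frame of events.
#' @export
write_schedule_csv <- function(schedule, file, json = NULL) {
  ev <- schedule$events
  utils::write.csv(
    data.frame(pattern_id = ev$pattern_id, onset_ms = ev$onset_ms,
               offset_ms = ev$offset_ms),
    file, row.names = FALSE, quote = FALSE)
  if (!is.null(json)) {
    spec <- schedule$spec
    meta <- list(n_patterns = spec$n_patterns, n_inputs = spec$n_inputs,
                 total_ms = schedule$total_ms,
                 probabilities = spec$probabilities,
                 membership = apply(spec$membership, 2, which))
    jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(file) {
  df <- utils::read.csv(file)
  stopifnot(all(c("pattern_id", "onset_ms", "offset_ms") %in% names(df)))
  df
}

#' Weight snapshots as CSV matrices with JSON metadata
#'
#' Writes every weight matrix of the network to `<dir>/<name>.csv`
#' (plain numeric CSV, no headers) together with a `meta.json` block
#' recording the variant, dimensions, simulation time and matrix names.
#' `read_weights_snapshot()` restores a `network_weights` object.
#'
#' @param weights a [network_weights()] object.
#' @param dir snapshot directory (created if missing).
#' @param step,seed optional provenance fields stored in the metadata.
#' @return the directory, invisibly; or the restored `network_weights`.
#' @export
write_weights_snapshot <- function(weights, dir, step = NA, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- weight_matrix_names(weights)
  if (weights$kind == "signed")
    nms <- c(nms, "mask_exc", "mask_inh", "mask_g")
  for (nm in nms) {
    w <- weights[[nm]]
    # %.17g round-trips IEEE doubles exactly through text
    utils::write.table(matrix(sprintf("%.17g", w), nrow(w)),
                       file.path(dir, paste0(nm, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  meta <- list(kind = weights$kind, n_neurons = weights$n_neurons,
               n_inputs = weights$n_inputs, n_inh = weights$n_inh,
               matrices = nms, step = step, seed = seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Crash-safe simulation checkpoints
#'
#' A checkpoint stores everything needed to resume a run and reproduce
#' the original trajectory exactly: the weight matrices (CSV + JSON, see
#' [write_weights_snapshot()]), the full network state, the neuron
#' parameters, and the RNG state of the session. All files are plain
#' text.
#'
#' @param net a network triple (`weights`, `state`, `params`), e.g. the
#'   `net` returned by [run_phase()] or a fitted [replaynet()].
#' @param dir checkpoint directory.
#' @return `write_checkpoint()`: `dir`, invisibly. `read_checkpoint()`:
#'   the restored network triple; the session RNG state is reset to the
#'   stored one, so continuing the simulation reproduces the original
#'   run bit for bit.
#' @export
write_checkpoint <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_weights_snapshot(net$weights, file.path(dir, "weights"))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  st <- net$state
  state <- list(x = st$x, y = st$y, h = st$h, t = st$t,
                params = as_params_list(net$params),
                rng = get(".Random.seed", envir = globalenv()))
  jsonlite::write_json(state, file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(dir) {
  weights <- read_weights_snapshot(file.path(dir, "weights"))
  js <- jsonlite::read_json(file.path(dir, "state.json"),
                            simplifyVector = TRUE)
  params <- do.call(neuron_params, as.list(js$params))
  state <- network_state(weights, params)
  if (weights$kind == "DL") {
    state$x <- as.numeric(js$x)
    state$y <- list(E = as.numeric(js$y$E), I = as.numeric(js$y$I))
    state$h <- list(E = as.numeric(js$h$E), I = as.numeric(js$h$I))
  } else {
    state$x <- as.numeric(js$x)
    state$y <- as.numeric(js$y)
    state$h <- as.numeric(js$h)
  }
  state$t <- js$t
  assign(".Random.seed", as.integer(js$rng), envir = globalenv())
  list(weights = weights, state = state, params = params)
}

#' @rdname write_weights_snapshot
#' @export
read_weights_snapshot <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  w <- list(kind = meta$kind, n_neurons = as.integer(meta$n_neurons),
            n_inputs = as.integer(meta$n_inputs),
            n_inh = if (is.null(meta$n_inh) || is.na(meta$n_inh))
              NA_integer_ else as.integer(meta$n_inh),
            w_mask = NULL)
  for (nm in meta$matrices) {
    w[[nm]] <- as.matrix(utils::read.table(
      file.path(dir, paste0(nm, ".csv")), sep = ","))
    dimnames(w[[nm]]) <- NULL
  }
  structure(w, class = "network_weights")
}
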