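# CSV + JSON serialisation. Matrices are written rows = dimensions,
# columns = samples (tasks) or plain row/column layout (weights), with a JSON
# sidecar carrying dimensions and provenance so files round-trip losslessly.

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write / read a task as delimited text
#'
#' Writes `<prefix>_X.csv`, `<prefix>_Y.csv` (rows = dimensions, columns =
#' samples) and `<prefix>.json` recording the dimensions and any generator
#' metadata.
#'
#' @param task a [linear_task()].
#' @param prefix file path prefix (directories must exist).
#' @param meta optional named list of generator metadata stored in the
#'   sidecar (seed, generator name, parameters).
#' @return `write_task()` returns `prefix` invisibly; `read_task()` returns
#'   the [linear_task()] with the sidecar attached as attribute `"meta"`.
#' @export
write_task <- function(task, prefix, meta = list()) {
  stopifnot(inherits(task, "linear_task"))
  write_matrix_csv(task$X, paste0(prefix, "_X.csv"))
  write_matrix_csv(task$Y, paste0(prefix, "_Y.csv"))
  sidecar <- c(list(ni = task$ni, no = task$no, p = task$p), meta)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_task
#' @export
read_task <- function(prefix) {
  x <- read_matrix_csv(paste0(prefix, "_X.csv"))
  y <- read_matrix_csv(paste0(prefix, "_Y.csv"))
  task <- linear_task(unname(x), unname(y))
  side <- paste0(prefix, ".json")
  if (file.exists(side)) {
    attr(task, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  task
}

#' Write / read a network state as delimited text
#'
#' Writes `<prefix>_W1.csv`, `<prefix>_W2.csv` and a JSON sidecar with the
#' dimensions and optional metadata.
#'
#' @param state a [network_state()].
#' @inheritParams write_task
#' @return `write_state()` returns `prefix` invisibly; `read_state()`
#'   returns the [network_state()].
#' @export
write_state <- function(state, prefix, meta = list()) {
  stopifnot(inherits(state, "network_state"))
  write_matrix_csv(state$W1, paste0(prefix, "_W1.csv"))
  write_matrix_csv(state$W2, paste0(prefix, "_W2.csv"))
  sidecar <- c(list(ni = state$ni, nh = state$nh, no = state$no), meta)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_state
#' @export
read_state <- function(prefix) {
  w1 <- read_matrix_csv(paste0(prefix, "_W1.csv"))
  w2 <- read_matrix_csv(paste0(prefix, "_W2.csv"))
  network_state(unname(w1), unname(w2))
}

#' Export a trajectory as CSV files plus a JSON manifest
#'
#' Writes `times.csv`, `losses.csv` (when a task correlation is supplied or
#' losses were recorded), one `qq_<k>.csv` per recorded time, and
#' `manifest.json` tying them together (block layout, tau, source).
#'
#' @param traj a `trajectory`.
#' @param dir output directory (created if missing).
#' @param corr optional [compute_correlations()] to evaluate losses with.
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir, corr = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(matrix(traj$times, ncol = 1), file.path(dir, "times.csv"))
  losses <- if (!is.null(corr)) loss_trajectory(traj, corr) else traj$losses
  if (!is.null(losses)) {
    write_matrix_csv(matrix(losses, ncol = 1), file.path(dir, "losses.csv"))
  }
  for (k in seq_along(traj$qq)) {
    write_matrix_csv(traj$qq[[k]]$m, file.path(dir, sprintf("qq_%04d.csv", k)))
  }
  manifest <- list(
    source = traj$source, tau = traj$tau, n_times = length(traj$times),
    ni = traj$qq[[1]]$ni, no = traj$qq[[1]]$no,
    block_layout = "top-left Ni x Ni = W1'W1; bottom-right No x No = W2W2'; bottom-left No x Ni = W2W1",
    files = c("times.csv", if (!is.null(losses)) "losses.csv",
              sprintf("qq_%04d.csv", seq_along(traj$qq)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
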