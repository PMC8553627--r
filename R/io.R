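#' Electrode layout
#'
#' Describes the electrode grid: unique integer IDs and coordinates in
#' micrometres. [mea_layout_60()] builds the standard 60-electrode grid
#' (8 x 8 minus the four corners, 200-um pitch, 12-um electrode diameter)
#' used for organoid slice recordings.
#'
#' @param electrode_id Integer electrode IDs (0-based), unique, at least 2.
#' @param x_um,y_um Coordinates in micrometres.
#' @param z_um Optional third coordinate (defaults to 0 for planar arrays).
#' @param diameter_um Electrode diameter in micrometres.
#' @param pitch_um Nominal inter-electrode spacing in micrometres.
#' @return An object of class `mea_layout`: a data frame of electrodes with
#'   `diameter_um` and `pitch_um` attributes.
#' @examples
#' lay <- mea_layout_60()
#' nrow(lay) # 60
#' @export
mea_layout <- function(electrode_id, x_um, y_um, z_um = NULL,
                       diameter_um = 12, pitch_um = 200) {
  electrode_id <- as.integer(electrode_id)
  n <- length(electrode_id)
  if (n < 2L) stop_validation("layout needs at least 2 electrodes")
  if (anyDuplicated(electrode_id)) stop_validation("electrode IDs must be unique")
  coords <- cbind(x_um, y_um, z_um %||% rep(0, n))
  if (nrow(coords) != n || any(!is.finite(coords))) {
    stop_validation("coordinates must be finite, one per electrode")
  }
  if (!is_scalar_num(diameter_um) || diameter_um <= 0) {
    stop_validation("`diameter_um` must be positive")
  }
  out <- data.frame(electrode_id = electrode_id,
                    x_um = as.numeric(coords[, 1]),
                    y_um = as.numeric(coords[, 2]),
                    z_um = as.numeric(coords[, 3]))
  attr(out, "diameter_um") <- diameter_um
  attr(out, "pitch_um") <- pitch_um
  class(out) <- c("mea_layout", "data.frame")
  out
}

#' @rdname mea_layout
#' @export
mea_layout_60 <- function(pitch_um = 200, diameter_um = 12) {
  grid <- expand.grid(col = 0:7, row = 0:7)
  corner <- (grid$col %in% c(0, 7)) & (grid$row %in% c(0, 7))
  grid <- grid[!corner, , drop = FALSE]
  mea_layout(electrode_id = seq_len(nrow(grid)) - 1L,
             x_um = grid$col * pitch_um, y_um = grid$row * pitch_um,
             diameter_um = diameter_um, pitch_um = pitch_um)
}

#' Read or write an electrode layout
#'
#' CSV files carry the header `electrode_id,x_um,y_um` with an optional
#' `z_um` column; extra columns (vendor labels) are preserved on read but
#' ignored by computation. JSON files carry the same keys.
#'
#' @param path File path (`.csv` or `.json`).
#' @param layout An `mea_layout` (for writing).
#' @return `read_layout()` returns an `mea_layout`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop_format("layout file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
    d <- as.data.frame(d)
  } else {
    d <- utils::read.csv(path)
  }
  need <- c("electrode_id", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    stop_format("layout must have columns ", paste(need, collapse = ", "))
  }
  mea_layout(d$electrode_id, d$x_um, d$y_um, d$z_um,
             diameter_um = attr(d, "diameter_um") %||% 12,
             pitch_um = attr(d, "pitch_um") %||% 200)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "mea_layout"))
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

#' Raw multichannel recording
#'
#' A channels x samples voltage matrix with its sampling rate. Amplitude
#' units are arbitrary but must be consistent across channels; all
#' downstream thresholds are noise-relative, so absolute calibration is not
#' required.
#'
#' @param signal Numeric matrix, channels x samples, all finite.
#' @param sampling_rate_hz Positive sampling rate.
#' @return An object of class `mea_recording` with a `duration_s` field.
#' @examples
#' rec <- mea_recording(matrix(rnorm(2000), nrow = 2), 25000)
#' rec$duration_s # 0.04
#' @export
mea_recording <- function(signal, sampling_rate_hz) {
  if (!is.matrix(signal)) stop_validation("`signal` must be a channels x samples matrix")
  if (any(!is.finite(signal))) stop_validation("signal contains non-finite samples")
  if (!is_scalar_num(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop_validation("`sampling_rate_hz` must be positive")
  }
  structure(list(signal = signal,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 duration_s = ncol(signal) / sampling_rate_hz),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz, x$duration_s))
  invisible(x)
}

#' Read and write raw recordings
#'
#' The on-disk container is a flat little-endian binary file of
#' channel-contiguous samples plus a JSON sidecar (`<path>.json`) holding
#' `sampling_rate_hz`, `n_channels`, `n_samples`, `dtype` (`"float64"`,
#' `"float32"` or `"int16"`) and, for `int16`, the scale attribute `lsb_uV`
#' (microvolts per least significant bit). `float64` (the default) round
#' trips samples bit-exactly. Proprietary vendor formats are not parsed;
#' convert to this container first.
#'
#' @param recording An `mea_recording`.
#' @param path Path of the binary data file; the sidecar is `<path>.json`.
#' @param dtype Storage type.
#' @param lsb_uV Scale for `int16` storage (stored value x `lsb_uV` =
#'   amplitude).
#' @return `read_recording()` returns an `mea_recording`.
#' @examples
#' rec <- mea_recording(matrix(rnorm(200), nrow = 2), 25000)
#' p <- tempfile(fileext = ".bin")
#' write_recording(rec, p)
#' rec2 <- read_recording(p)
#' identical(rec$signal, rec2$signal)
#' @export
write_recording <- function(recording, path, dtype = c("float64", "float32", "int16"),
                            lsb_uV = 1) {
  stopifnot(inherits(recording, "mea_recording"))
  dtype <- match.arg(dtype)
  sig <- recording$signal
  meta <- list(sampling_rate_hz = recording$sampling_rate_hz,
               n_channels = nrow(sig), n_samples = ncol(sig),
               dtype = dtype, byte_order = "little")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  vec <- as.vector(t(sig)) # channel-contiguous
  if (dtype == "float64") {
    writeBin(vec, con, size = 8, endian = "little")
  } else if (dtype == "float32") {
    writeBin(vec, con, size = 4, endian = "little")
  } else {
    meta$lsb_uV <- lsb_uV
    writeBin(as.integer(round(vec / lsb_uV)), con, size = 2, endian = "little")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop_format("recording file not found: ", path)
  if (!file.exists(sidecar)) stop_format("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$sampling_rate_hz)) {
    stop_format("sidecar lacks required `sampling_rate_hz` attribute")
  }
  if (is.null(meta$n_channels) || is.null(meta$n_samples)) {
    stop_format("sidecar must state `n_channels` and `n_samples`")
  }
  n <- meta$n_channels * meta$n_samples
  dtype <- meta$dtype %||% "float64"
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vec <- switch(dtype,
    float64 = readBin(con, "double", n = n, size = 8, endian = "little"),
    float32 = readBin(con, "double", n = n, size = 4, endian = "little"),
    int16 = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                    endian = "little") * (meta$lsb_uV %||% 1),
    stop_format("unknown dtype: ", dtype)
  )
  if (length(vec) != n) {
    stop_format("recording is ragged: expected ", n, " values, read ", length(vec))
  }
  sig <- t(matrix(vec, nrow = meta$n_samples, ncol = meta$n_channels))
  mea_recording(sig, meta$sampling_rate_hz)
}

#' Read and write spike tables
#'
#' A spike table is a CSV with header `electrode_id,time_s`, one row per
#' spike. On read, electrodes listed in `layout` (or in `electrode_ids`)
#' but absent from the table receive empty trains, so silent electrodes are
#' not dropped from the array.
#'
#' @param path CSV path.
#' @param duration_s Recording window length; all times must lie in
#'   `[0, duration_s)`.
#' @param layout Optional `mea_layout` fixing the electrode set.
#' @param electrode_ids Optional integer IDs fixing the electrode set
#'   (ignored if `layout` is given).
#' @param spikes A `spike_matrix` (for writing).
#' @return `read_spike_table()` returns a `spike_matrix`.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_spike_table(spike_matrix(list(c(0.5, 1), 2), 10), p)
#' read_spike_table(p, duration_s = 10)
#' @export
read_spike_table <- function(path, duration_s, layout = NULL, electrode_ids = NULL) {
  if (!file.exists(path)) stop_format("spike table not found: ", path)
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stop_validation("`duration_s` must be positive")
  }
  d <- utils::read.csv(path, colClasses = c(NA, NA))
  if (!all(c("electrode_id", "time_s") %in% names(d))) {
    stop_format("spike table must have columns electrode_id,time_s")
  }
  if (nrow(d) && (!is.numeric(d$time_s) || anyNA(d$time_s))) {
    stop_format("non-numeric spike time in table")
  }
  if (nrow(d) && (any(d$time_s < 0) || any(d$time_s >= duration_s))) {
    stop_validation("spike time outside [0, duration_s)")
  }
  ids <- if (!is.null(layout)) layout$electrode_id else electrode_ids
  ids <- sort(unique(as.integer(c(ids, d$electrode_id))))
  if (!length(ids)) ids <- 0L
  trains <- lapply(ids, function(id) sort(d$time_s[d$electrode_id == id]))
  spike_matrix(trains, duration_s, electrode_ids = ids)
}

#' @rdname read_spike_table
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_matrix"))
  d <- data.frame(
    electrode_id = rep(spikes$electrode_ids, lengths(spikes$trains)),
    time_s = unlist(spikes$trains, use.names = FALSE)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write the result files of an analysis
#'
#' Emits the standard report set into `dir`: `sttc_matrix.csv` (square,
#' header = electrode IDs), `edges.csv` (`source,target,sttc`), `nodes.csv`
#' (`electrode_id,degree,firing_rate_hz,n_spikes`) and `summary.json`
#' (configuration echo, global metrics, surrogate comparison). No
#' timestamps or hostnames are written, so identical inputs and seed give
#' byte-identical reports.
#'
#' @param results A fitted [mea_network()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!inherits(results, "mea_network")) {
    stop_validation("`results` must be an mea_network object")
  }
  if (is.null(results$sttc)) stop_validation("results lack the STTC matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.access(dir, mode = 2) == 0
  if (!ok) stop("cannot write to directory: ", dir)

  m <- as.data.frame(results$sttc$values)
  names(m) <- as.character(results$spikes$electrode_ids)
  p_mat <- file.path(dir, "sttc_matrix.csv")
  utils::write.csv(m, p_mat, row.names = FALSE)

  p_edges <- file.path(dir, "edges.csv")
  utils::write.csv(results$graph$edges, p_edges, row.names = FALSE)

  p_nodes <- file.path(dir, "nodes.csv")
  utils::write.csv(results$graph$nodes, p_nodes, row.names = FALSE)

  summ <- list(
    config = unclass(results$config),
    global_metrics = results$metrics,
    surrogate = if (!is.null(results$surrogates)) {
      c(results$surrogates$comparison,
        list(n_surrogates = results$surrogates$n_surrogates,
             surrogate_mean_degree_mean =
               mean(results$surrogates$per_surrogate$mean_degree)))
    }
  )
  p_sum <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(p_mat, p_edges, p_nodes, p_sum))
}
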