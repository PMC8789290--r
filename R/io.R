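#' Read and write event tables as TSV with a YAML config sidecar
#'
#' The table is written as tab-separated values (`train_id`,
#' `departure_time_s`, `velocity_um_s`, `is_open`, `copies_<cargo>` per
#' cargo); the generating configuration is echoed to `<path>.yaml`.
#'
#' @param et An `event_table`.
#' @param path Output TSV path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(et, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  utils::write.table(as.data.frame(et), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- attr(et, "config")
  if (!is.null(cfg))
    yaml::write_yaml(config_as_list(cfg), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("train_id", "departure_time_s", "velocity_um_s", "is_open")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("event table is missing columns: ", paste(miss, collapse = ", "))
  side <- paste0(path, ".yaml")
  cfg <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  structure(df, config_echo = cfg, class = c("event_table", "data.frame"))
}

#' Read and write cotransport count tables
#'
#' TSV schema: `label`, `cargo_a`, `cargo_b`, `n_a`, `n_b`, `n_co`,
#' `duration_s`, and optional `n_flagella`, `train_rate`. Each row is
#' validated through [count_record()]; malformed rows are rejected with
#' their line numbers.
#'
#' @param path TSV path.
#' @return `read_counts`: a list of `count_record`s. `write_counts`: `path`,
#'   invisibly.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "n_a", "n_b", "n_co", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("count table schema error: missing columns ",
         paste(miss, collapse = ", "))
  if (!"train_rate" %in% names(df)) df$train_rate <- 1.0
  if (!"n_flagella" %in% names(df)) df$n_flagella <- NA_integer_
  if (!"cargo_a" %in% names(df)) df$cargo_a <- "cargoA"
  if (!"cargo_b" %in% names(df)) df$cargo_b <- "cargoB"
  lapply(seq_len(nrow(df)), function(i) {
    rec <- try(count_record(df$label[i], df$n_a[i], df$n_b[i], df$n_co[i],
                            df$duration_s[i], df$n_flagella[i],
                            df$train_rate[i], df$cargo_a[i], df$cargo_b[i]),
               silent = TRUE)
    if (inherits(rec, "try-error"))
      stop("invalid count record on line ", i + 1L, " of '", path, "': ",
           attr(rec, "condition")$message)
    rec
  })
}

#' @rdname read_counts
#' @param records A `count_record` or list of them.
#' @param overwrite Allow replacing an existing file.
#' @export
write_counts <- function(records, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  if (inherits(records, "count_record")) records <- list(records)
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(label = r$label, cargo_a = r$cargo_a, cargo_b = r$cargo_b,
               n_a = r$n_a, n_b = r$n_b, n_co = r$n_co,
               duration_s = r$duration, n_flagella = r$n_flagella,
               train_rate = r$train_rate)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read two-channel kymographs as 16-bit TIFF + JSON calibration
#'
#' The two channels are stored as two pages of a 16-bit TIFF (counts are
#' clipped to the 16-bit range); frame rate, pixel size, flagellum length,
#' padding offset and duration go to a `<path>.json` sidecar.
#'
#' @param kymo A `kymograph`.
#' @param path Output TIFF path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  pages <- lapply(kymo$channels, function(m)
    pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  cal <- list(frame_rate = kymo$frame_rate, pixel_size = kymo$pixel_size,
              origin_px = kymo$origin_px, length_um = kymo$length_um,
              duration = kymo$duration, provenance = kymo$provenance,
              intensity_scale = 65535)
  jsonlite::write_json(cal, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("kymograph is uncalibrated: sidecar '", side, "' not found")
  cal <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(m) m * cal$intensity_scale)
  structure(
    list(channels = channels, frame_rate = cal$frame_rate,
         pixel_size = cal$pixel_size, origin_px = cal$origin_px,
         length_um = cal$length_um, duration = cal$duration,
         imaging = NULL, bleach_times = NULL,
         provenance = if (is.null(cal$provenance)) "measured" else cal$provenance),
    class = "kymograph"
  )
}

#' Write extracted tracks as TSV
#'
#' One row per tracked point: `track_id`, `channel`, `frame`, `x_px`,
#' `label`.
#'
#' @param tracks A `track_set`.
#' @param path Output TSV path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE to replace it")
  rows <- lapply(tracks$tracks, function(tr)
    data.frame(track_id = attr(tr, "id"), channel = attr(tr, "channel"),
               frame = tr$frame, x_px = tr$x, label = tr$label))
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(track_id = integer(0), channel = integer(0),
               frame = integer(0), x_px = numeric(0), label = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
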