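#' Render cargo trajectories into a synthetic two-channel kymograph
#'
#' Each unbleached fluorophore copy contributes a pixel-integrated Gaussian
#' line profile at its position in every frame. Exposure is integrated over
#' `substeps` sub-frame position samples, so fast-moving (diffusing) cargo is
#' motion blurred exactly as in real finite-exposure TIRF recordings. Each
#' copy photobleaches in a single step at an exponentially distributed time
#' (per-channel rate) counted from its first appearance. Poisson shot noise
#' and Gaussian read noise are then applied.
#'
#' The image is padded by `img$pad_px` columns on each side of the flagellum
#' so point-spread tails at the base and tip remain inside the frame; the
#' calibration records the offset. Row 1 is the first frame; position
#' increases from base to tip with increasing column.
#'
#' @param trajectories List of [build_trajectory()] objects.
#' @param img An [imaging_config()].
#' @param duration Recording duration (s).
#' @param length Flagellar length (um).
#' @param seed Integer seed or `NULL`.
#' @param noise If `FALSE`, return the noise-free expected image (no shot or
#'   read noise, bleach times still drawn); used by the linearity and photon
#'   conservation checks.
#' @return An object of class `kymograph`: a list with per-channel intensity
#'   matrices (`channels`, rows = frames, columns = positions), calibration
#'   (`frame_rate`, `pixel_size`, `origin_px`, `length_um`, `duration`), and
#'   provenance.
#' @export
render_kymograph <- function(trajectories, img, duration, length,
                             seed = NULL, noise = TRUE) {
  stopifnot(inherits(img, "imaging_config"))
  if (duration <= 0) stop("duration must be > 0")
  if (length <= 0) stop("flagellum length must be > 0")
  if (!is.null(seed)) set.seed(seed)
  fps <- img$frame_rate
  px <- img$pixel_size
  nframes <- max(1L, round(duration * fps))
  ncore <- ceiling(length / px)
  npix <- ncore + 2L * img$pad_px
  origin <- img$pad_px           # column j covers [(j-1-origin)*px, (j-origin)*px)
  S <- img$substeps
  sigma <- img$psf_sigma_px
  w <- ceiling(4 * sigma)

  channels <- list(matrix(0, nframes, npix), matrix(0, nframes, npix))
  t_sub <- (rep(seq_len(nframes), each = S) - 1 + (seq_len(S) - 0.5) / S) / fps
  rows_sub <- rep(seq_len(nframes), each = S)

  idx_all <- vector("list", 0L)
  val_all <- vector("list", 0L)
  ch_all <- integer(0)
  bleach_times <- vector("list", length(trajectories))

  for (ti in seq_along(trajectories)) {
    traj <- trajectories[[ti]]
    ch <- traj$channel
    if (is.na(ch) || ch < 1L || ch > 2L)
      stop("trajectory channel must be 1 or 2")
    t_on <- traj$segments$t0[1L]
    rate <- img$bleach_rate[ch]
    b <- if (rate > 0) t_on + stats::rexp(traj$copies, rate) else
      rep(Inf, traj$copies)
    if (!is.na(traj$bleach_time)) b <- pmin(b, traj$bleach_time)
    bleach_times[[ti]] <- b
    xx <- trajectory_position(traj, t_sub)
    vis <- which(!is.na(xx))
    if (length(vis) == 0L) next
    alive <- vapply(t_sub[vis], function(t) sum(b > t), numeric(1))
    keep <- which(alive > 0)
    if (length(keep) == 0L) next
    vis <- vis[keep]
    flux <- img$photons_per_particle * alive[keep] / S
    u <- xx[vis] / px + origin + 0.5   # continuous column coordinate
    j0 <- round(u)
    rows <- rows_sub[vis]
    for (k in -w:w) {
      j <- j0 + k
      ok <- which(j >= 1L & j <= npix)
      if (length(ok) == 0L) next
      wt <- stats::pnorm((j[ok] + 0.5 - u[ok]) / sigma) -
        stats::pnorm((j[ok] - 0.5 - u[ok]) / sigma)
      idx_all[[length(idx_all) + 1L]] <- rows[ok] + (j[ok] - 1L) * nframes
      val_all[[length(val_all) + 1L]] <- flux[ok] * wt
      ch_all[length(ch_all) + 1L] <- ch
    }
  }
  if (length(idx_all) > 0L) {
    for (ch in 1:2) {
      sel <- which(ch_all == ch)
      if (length(sel) == 0L) next
      idx <- unlist(idx_all[sel], use.names = FALSE)
      val <- unlist(val_all[sel], use.names = FALSE)
      agg <- rowsum(val, idx)
      channels[[ch]][as.integer(rownames(agg))] <-
        channels[[ch]][as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  in_flag <- seq_len(npix) > origin & seq_len(npix) <= origin + ncore
  for (ch in 1:2) {
    E <- channels[[ch]] + img$background
    if (img$static_axoneme_intensity > 0)
      E[, in_flag] <- E[, in_flag] + img$static_axoneme_intensity
    if (noise) {
      K <- matrix(stats::rpois(nframes * npix, E), nframes, npix)
      if (img$read_noise_sd > 0)
        K <- K + matrix(stats::rnorm(nframes * npix, 0, img$read_noise_sd),
                        nframes, npix)
      channels[[ch]] <- pmax(K, 0)
    } else {
      channels[[ch]] <- E
    }
  }
  structure(
    list(channels = channels,
         frame_rate = fps, pixel_size = px, origin_px = origin,
         length_um = length, duration = duration,
         imaging = img, bleach_times = bleach_times,
         provenance = "rendered"),
    class = "kymograph"
  )
}

#' Photobleach a region of the flagellum at a given time
#'
#' All fluorophores located inside the region at `time` are set permanently
#' dark (emulating a focused bleaching laser pointed at, e.g., the flagellar
#' tip before acquisition). Trajectories outside the region, or passing
#' through it at other times, are unaffected.
#'
#' @param trajectories List of `cargo_trajectory` objects.
#' @param region Numeric `c(x0, x1)` interval (um from the base).
#' @param time Bleach time (s).
#' @return The trajectory list with `bleach_time` set on affected entries.
#' @export
bleach_region <- function(trajectories, region, time) {
  stopifnot(length(region) == 2L, region[1L] <= region[2L])
  lapply(trajectories, function(traj) {
    x <- trajectory_position(traj, time)
    if (!is.na(x) && x >= region[1L] && x <= region[2L])
      traj$bleach_time <- min(traj$bleach_time, time, na.rm = TRUE)
    traj
  })
}

# Continuous column coordinate of a physical position (um) in a kymograph.
kymo_col <- function(kymo, x_um) x_um / kymo$pixel_size + kymo$origin_px + 0.5

# Physical position (um) of a continuous column coordinate.
kymo_um <- function(kymo, col) (col - 0.5 - kymo$origin_px) * kymo$pixel_size

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d px, 2 channels (%.3g fps, %.3g um/px)\n",
              nrow(x$channels[[1L]]), ncol(x$channels[[1L]]),
              x$frame_rate, x$pixel_size))
  cat(sprintf("  flagellum %.3g um (columns %d..%d), %.4g s, provenance: %s\n",
              x$length_um, x$origin_px + 1L,
              x$origin_px + ceiling(x$length_um / x$pixel_size),
              x$duration, x$provenance))
  invisible(x)
}

#' Display a kymograph
#'
#' @param x A `kymograph`.
#' @param channel 1, 2, or `"merge"` for a red/green overlay.
#' @param ... Passed to [graphics::image()] (single-channel display only).
#' @export
plot.kymograph <- function(x, channel = "merge", ...) {
  m1 <- x$channels[[1L]]; m2 <- x$channels[[2L]]
  tt <- (seq_len(nrow(m1)) - 0.5) / x$frame_rate
  xx <- kymo_um(x, seq_len(ncol(m1)))
  norm <- function(m) {
    r <- stats::quantile(m, c(0.02, 0.999))
    pmin(pmax((m - r[1L]) / max(r[2L] - r[1L], 1e-9), 0), 1)
  }
  if (identical(channel, "merge")) {
    r <- norm(m1); g <- norm(m2)
    col <- grDevices::rgb(r, g, 0)
    dim(col) <- dim(r)
    graphics::plot(NA, xlim = range(xx), ylim = rev(range(tt)),
                   xlab = "position (um)", ylab = "time (s)",
                   main = "kymograph (ch1 red / ch2 green)")
    graphics::rasterImage(col, min(xx), max(tt), max(xx), min(tt))
  } else {
    m <- x$channels[[as.integer(channel)]]
    graphics::image(xx, tt, t(m), ylim = rev(range(tt)),
                    xlab = "position (um)", ylab = "time (s)",
                    col = grDevices::gray.colors(256, 0, 1), ...)
  }
  invisible(x)
}
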