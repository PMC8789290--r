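#' Track-extraction parameters
#'
#' @param k_mad Detection threshold: a pixel is a candidate peak if it
#'   exceeds the frame median by `k_mad` median absolute deviations.
#' @param gate_px Association gate (pixels) between a track's predicted and
#'   a peak's observed position.
#' @param gap_frames Frames a track may go undetected before it is closed.
#' @param min_frames Minimum track (and minimum anterograde-run) length in
#'   frames; shorter tracks are discarded.
#' @param v_min Minimum absolute slope (um/s) for a point to be labeled
#'   anterograde or retrograde.
#' @param d_tip_px Width of the tip zone (pixels): an anterograde run ending
#'   within `d_tip_px` of the distal end starts a tip dwell.
#' @param move_px Displacement (pixels) from the arrival position that ends
#'   a tip dwell.
#' @param slope_window Centered window (frames) for the local-slope motion
#'   classification.
#' @param min_run_um Minimum displacement (um) of an anterograde run for the
#'   track to count as a transport event. Processive runs traverse most of
#'   the flagellum, whereas apparent short "runs" assembled from the
#'   diffusive background rarely persist over several micrometers, so this
#'   is the main guard against clutter tracks. Runs truncated by the
#'   recording window (starting in the first or ending in the last frames)
#'   are counted down to `boundary_run_um`.
#' @param boundary_run_um Displacement (um) required of a run that touches
#'   the start or end of the recording.
#' @param v_max Maximum plausible anterograde velocity (um/s) for a run to
#'   count as a transport event.
#' @param run_resid_px Maximum trimmed residual SD (pixels; best 80% of
#'   points) of the straight-line fit to an anterograde run. Processive IFT runs are linear to within the
#'   localization noise, whereas a diffusing particle that happens to drift
#'   tipward scatters around any line by several pixels; this is the main
#'   guard against counting diffusive returns as transport events.
#' @return An object of class `extract_params`.
#' @export
extract_params <- function(k_mad = 5, gate_px = 3, gap_frames = 2,
                           min_frames = 5, v_min = 0.5, d_tip_px = 3,
                           move_px = 2, slope_window = 7, min_run_um = 3.0,
                           boundary_run_um = 1.0, v_max = 3.0,
                           run_resid_px = 0.6) {
  structure(list(k_mad = k_mad, gate_px = gate_px, gap_frames = gap_frames,
                 min_frames = as.integer(min_frames), v_min = v_min,
                 d_tip_px = d_tip_px, move_px = move_px,
                 slope_window = as.integer(slope_window),
                 min_run_um = min_run_um, boundary_run_um = boundary_run_um,
                 v_max = v_max, run_resid_px = run_resid_px),
            class = "extract_params")
}

# Background level and noise scale for a channel. The padding columns on
# the base side of the image carry no particle signal (beyond faint
# point-spread tails), so they give a robust estimate even when the
# flagellum itself is crowded with signal; without padding information the
# whole image median/MAD is used.
channel_background <- function(mat, origin_px) {
  if (!is.null(origin_px) && origin_px >= 3L) {
    ref <- mat[, 1:(origin_px - 2L), drop = FALSE]
  } else {
    ref <- mat
  }
  bg <- stats::median(ref)
  s <- stats::mad(ref)
  if (s <= 0) s <- max(stats::sd(ref), 1e-9)
  c(bg = bg, noise = s)
}

# Peak detection in one kymograph row: local maxima above bg + k * noise,
# with subpixel centroid refinement. Returns positions (continuous column
# coordinates) and background-subtracted amplitudes.
detect_peaks <- function(row, k_mad, bg = NULL, noise = NULL) {
  n <- length(row)
  if (is.null(bg)) bg <- stats::median(row)
  if (is.null(noise)) {
    noise <- stats::mad(row)
    if (noise <= 0) noise <- max(stats::sd(row), 1e-9)
  }
  thr <- bg + k_mad * noise
  if (n < 3L) return(list(x = numeric(0), amp = numeric(0), flux = numeric(0)))
  mid <- 2:(n - 1L)
  is_peak <- row[mid] > thr & row[mid] >= row[mid - 1L] & row[mid] > row[mid + 1L]
  j <- mid[is_peak]
  if (length(j) == 0L)
    return(list(x = numeric(0), amp = numeric(0), flux = numeric(0)))
  # non-maximum suppression: a noisy point-spread profile can carry two
  # local maxima a pixel or two apart; keep only the brighter one
  if (length(j) > 1L) {
    ord <- order(row[j], decreasing = TRUE)
    keep <- logical(length(j))
    for (o in ord) {
      if (any(keep & abs(j - j[o]) < 3L)) next
      keep[o] <- TRUE
    }
    j <- sort(j[keep])
  }
  x <- numeric(length(j))
  flux <- numeric(length(j))
  amp <- numeric(length(j))
  for (i in seq_along(j)) {
    # local pedestal: diffusing cargo spreads a slowly varying background
    # over the flagellum that the global estimate does not see
    ann <- c(max(1L, j[i] - 8L):max(1L, j[i] - 4L),
             min(n, j[i] + 4L):min(n, j[i] + 8L))
    local_bg <- max(bg, stats::median(row[ann]))
    win <- max(1L, j[i] - 2L):min(n, j[i] + 2L)
    wgt <- pmax(row[win] - local_bg, 0)
    x[i] <- if (sum(wgt) > 0) sum(win * wgt) / sum(wgt) else j[i]
    fwin <- max(1L, j[i] - 3L):min(n, j[i] + 3L)
    flux[i] <- sum(row[fwin] - local_bg)
    amp[i] <- row[j[i]] - local_bg
  }
  list(x = x, amp = amp, flux = flux)
}

# Online velocity estimate (columns/frame) from the last few track points.
tail_velocity <- function(frames, xs, m = 5L) {
  n <- length(frames)
  if (n < 2L) return(0)
  i <- max(1L, n - m + 1L):n
  f <- frames[i]; x <- xs[i]
  vf <- stats::var(f)
  if (vf == 0) return(0)
  stats::cov(f, x) / vf
}

#' Extract particle tracks from a kymograph
#'
#' Per-frame one-dimensional peak detection above a noise-adaptive threshold
#' (background and noise estimated from the off-flagellum padding columns),
#' followed by velocity-gated nearest-neighbor linking across frames (greedy
#' one-to-one assignment by ascending prediction error, with a gap
#' tolerance), fragment stitching and line growing to heal runs broken by
#' crossings and the crowded tip cluster, duplicate-line removal, and
#' local-slope segmentation of each track into anterograde, retrograde,
#' stationary and diffusive motion. Tracks shorter than `min_frames` are
#' discarded; see `extract_params` for the rules that qualify an anterograde
#' run as a transport event.
#'
#' @param kymo A calibrated [render_kymograph()] object (or one read back by
#'   [read_kymograph()]).
#' @param params An [extract_params()] object.
#' @param channels Channels to process (default both).
#' @return An object of class `track_set`: a list of per-track data frames
#'   (`frame`, `x`, `amp`, `label`) with track attributes, plus the
#'   calibration needed to interpret them.
#' @export
extract_tracks <- function(kymo, params = extract_params(), channels = 1:2) {
  if (!inherits(kymo, "kymograph"))
    stop("input must be a calibrated kymograph")
  if (is.null(kymo$frame_rate) || is.null(kymo$pixel_size))
    stop("kymograph is missing calibration")
  tracks <- list()
  for (ch in channels) {
    mat <- kymo$channels[[ch]]
    bgn <- channel_background(mat, kymo$origin_px)
    peaks <- lapply(seq_len(nrow(mat)), function(f)
      detect_peaks(mat[f, ], params$k_mad, bgn["bg"], bgn["noise"]))
    raw <- link_peaks(peaks, params)
    raw <- stitch_tracks(raw, params)
    raw <- grow_lines(raw, peaks, params, ncol(mat))
    raw <- dedupe_tracks(raw, params)
    for (tr in raw) {
      if (nrow(tr) < params$min_frames) next
      tr <- classify_track(tr, kymo, params)
      attr(tr, "channel") <- ch
      tracks[[length(tracks) + 1L]] <- tr
    }
  }
  tracks <- suppress_duplicate_events(tracks)
  for (i in seq_along(tracks)) attr(tracks[[i]], "id") <- i
  structure(list(tracks = tracks,
                 frame_rate = kymo$frame_rate, pixel_size = kymo$pixel_size,
                 origin_px = kymo$origin_px, length_um = kymo$length_um,
                 duration = kymo$duration, params = params),
            class = "track_set")
}

# Frame-by-frame linking of detected peaks into tracks for one channel.
link_peaks <- function(peaks, params) {
  nframes <- length(peaks)
  open <- list()    # each: list(frame=, x=, amp=, last=, v=)
  done <- list()
  for (f in seq_len(nframes)) {
    pk <- peaks[[f]]
    npk <- length(pk$x)
    # predictions for open tracks
    if (length(open) > 0L && npk > 0L) {
      pred <- vapply(open, function(tr) {
        tr$x[length(tr$x)] + tr$v * (f - tr$last)
      }, numeric(1))
      cost <- abs(outer(pred, pk$x, "-"))
      cost[cost > params$gate_px] <- NA
      assigned_tr <- integer(0); assigned_pk <- integer(0)
      ord <- order(cost, na.last = NA)
      for (o in ord) {
        i <- (o - 1L) %% length(open) + 1L
        j <- (o - 1L) %/% length(open) + 1L
        if (i %in% assigned_tr || j %in% assigned_pk) next
        assigned_tr <- c(assigned_tr, i); assigned_pk <- c(assigned_pk, j)
        tr <- open[[i]]
        tr$frame <- c(tr$frame, f); tr$x <- c(tr$x, pk$x[j])
        tr$amp <- c(tr$amp, pk$amp[j]); tr$flux <- c(tr$flux, pk$flux[j])
        tr$last <- f
        tr$v <- tail_velocity(tr$frame, tr$x)
        open[[i]] <- tr
      }
      new_pk <- setdiff(seq_len(npk), assigned_pk)
    } else {
      new_pk <- seq_len(npk)
    }
    for (j in new_pk)
      open[[length(open) + 1L]] <- list(frame = f, x = pk$x[j],
                                        amp = pk$amp[j], flux = pk$flux[j],
                                        last = f, v = 0)
    # close stale tracks
    stale <- vapply(open, function(tr) f - tr$last > params$gap_frames,
                    logical(1))
    if (any(stale)) {
      done <- c(done, open[stale])
      open <- open[!stale]
    }
  }
  done <- c(done, open)
  lapply(done, function(tr)
    data.frame(frame = tr$frame, x = tr$x, amp = tr$amp, flux = tr$flux))
}

# Merge track fragments split by occlusions (crossing particles, the tip
# cluster). Fragment B continues fragment A when it starts shortly after A
# ends, its first points lie on the straight line extrapolated from A's last
# points, and the two local velocities agree. Candidate merges are applied
# best-first (smallest extrapolation error) until none remain.
stitch_tracks <- function(raw, params, max_gap = NULL) {
  if (length(raw) < 2L) return(raw)
  if (is.null(max_gap)) max_gap <- max(params$gap_frames + 2L, 8L)
  line_fit <- function(f, x) {
    m <- min(length(f), 8L)
    i <- (length(f) - m + 1L):length(f)
    if (m < 2L || stats::var(f[i]) == 0) return(c(v = 0, x0 = x[length(x)],
                                                  f0 = f[length(f)]))
    v <- stats::cov(f[i], x[i]) / stats::var(f[i])
    c(v = v, x0 = mean(x[i]) , f0 = mean(f[i]))
  }
  for (pass in 1:3) {
    starts <- vapply(raw, function(tr) tr$frame[1L], numeric(1))
    ends <- vapply(raw, function(tr) tr$frame[nrow(tr)], numeric(1))
    cand <- list()
    for (i in seq_along(raw)) {
      js <- which(starts - ends[i] >= 1 & starts - ends[i] <= max_gap)
      if (length(js) == 0L) next
      a <- raw[[i]]
      fa <- line_fit(a$frame, a$x)
      for (j in js) {
        b <- raw[[j]]
        m <- min(nrow(b), 5L)
        pred <- fa["x0"] + fa["v"] * (b$frame[1:m] - fa["f0"])
        err <- mean(abs(b$x[1:m] - pred))
        if (err > params$gate_px) next
        if (nrow(a) >= 4L && nrow(b) >= 4L) {
          fb <- line_fit(b$frame[1:min(nrow(b), 8L)], b$x[1:min(nrow(b), 8L)])
          if (abs(fb["v"] - fa["v"]) > 1.0) next
        }
        cand[[length(cand) + 1L]] <- c(i = i, j = j, err = err)
      }
    }
    if (length(cand) == 0L) break
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, "err"]), , drop = FALSE]
    used <- logical(length(raw))
    target <- seq_along(raw)   # where each original index now lives
    merged_any <- FALSE
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (used[i] || used[j]) next
      raw[[i]] <- rbind(raw[[i]], raw[[j]])
      used[i] <- TRUE; used[j] <- TRUE
      raw[[j]] <- data.frame(frame = numeric(0), x = numeric(0),
                             amp = numeric(0), flux = numeric(0))
      merged_any <- TRUE
    }
    raw <- raw[vapply(raw, nrow, integer(1)) > 0L]
    if (!merged_any) break
  }
  raw
}

# Extend tracks whose endpoints are still in directed motion along their
# fitted line through the detected peak field (the automated analogue of
# following a faint kymograph line by eye). Fragments of a processive run
# that the frame-by-frame linker lost in clutter are recovered this way;
# the resulting near-duplicate tracks are collapsed by dedupe_tracks().
grow_lines <- function(raw, peaks, params, npix) {
  nframes <- length(peaks)
  end_slope <- function(f, x, head = FALSE) {
    m <- min(length(f), 10L)
    i <- if (head) seq_len(m) else (length(f) - m + 1L):length(f)
    if (m < 5L || stats::var(f[i]) == 0)
      return(c(v = 0, x0 = NA, f0 = NA, resid = Inf))
    v <- stats::cov(f[i], x[i]) / stats::var(f[i])
    res <- x[i] - mean(x[i]) - v * (f[i] - mean(f[i]))
    c(v = v, x0 = mean(x[i]), f0 = mean(f[i]), resid = stats::mad(res))
  }
  for (k in seq_along(raw)) {
    tr <- raw[[k]]
    if (nrow(tr) < 6L) next
    for (dir in c(1L, -1L)) {
      fit <- end_slope(tr$frame, tr$x, head = dir == -1L)
      # only endpoints still in clean directed motion (in pixels/frame) are
      # worth extending; diffusive tails fail the linearity test
      if (!is.finite(fit["v"]) || abs(fit["v"]) < 0.5 ||
          abs(fit["v"]) > 3 || fit["resid"] > 0.8) next
      f_start <- if (dir == 1L) tr$frame[nrow(tr)] else tr$frame[1L]
      f_cur <- f_start
      misses <- 0L
      tr_before <- tr
      added <- 0L
      repeat {
        f_cur <- f_cur + dir
        if (f_cur < 1L || f_cur > nframes || misses > 2L) break
        pred <- fit["x0"] + fit["v"] * (f_cur - fit["f0"])
        if (pred < 1 || pred > npix) break
        pk <- peaks[[f_cur]]
        if (length(pk$x) == 0L) { misses <- misses + 1L; next }
        d <- abs(pk$x - pred)
        j <- which.min(d)
        if (d[j] > 1.1) { misses <- misses + 1L; next }
        misses <- 0L
        added <- added + 1L
        tr <- rbind(tr, data.frame(frame = f_cur, x = pk$x[j],
                                   amp = pk$amp[j], flux = pk$flux[j]))
        tr <- tr[order(tr$frame), ]
        fit <- end_slope(tr$frame, tr$x, head = dir == -1L)
      }
      # extension must be well supported, otherwise it was clutter
      span <- abs(f_cur - f_start)
      if (span > 0L && added / span < 0.6) tr <- tr_before
    }
    raw[[k]] <- tr[!duplicated(tr$frame), ]
  }
  raw
}

# Drop tracks that duplicate a longer track (same line within ~1 pixel over
# most of their shared support), as produced by line growing over fragments.
dedupe_tracks <- function(raw, params) {
  if (length(raw) < 2L) return(raw)
  n <- vapply(raw, nrow, integer(1))
  ord <- order(n, decreasing = TRUE)
  keep <- rep(TRUE, length(raw))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (!keep[j]) next
      shared <- intersect(raw[[i]]$frame, raw[[j]]$frame)
      if (length(shared) < max(5L, 0.5 * nrow(raw[[j]]))) next
      d <- mean(abs(raw[[i]]$x[match(shared, raw[[i]]$frame)] -
                      raw[[j]]$x[match(shared, raw[[j]]$frame)]))
      if (d <= 1.2) keep[j] <- FALSE
    }
  }
  raw[keep]
}

# Demote duplicate transport events: two event tracks in one channel whose
# anterograde runs lie on the same line (same slope AND same intercept, i.e.
# the same train) are complementary fragments of one run that the linker
# split across an occlusion; only the longer fragment keeps event status.
# Distinct trains on parallel paths have different intercepts and are kept.
suppress_duplicate_events <- function(tracks) {
  ev <- which(vapply(tracks, function(tr)
    isTRUE(attr(tr, "is_anterograde_event")), logical(1)))
  if (length(ev) < 2L) return(tracks)
  line_of <- function(tr) {
    rr <- attr(tr, "run_range")
    sel <- tr$frame >= rr[1L] & tr$frame <= rr[2L]
    f <- tr$frame[sel]; x <- tr$x[sel]
    v <- stats::cov(f, x) / stats::var(f)
    list(v = v, f0 = mean(f), x0 = mean(x), frames = f, x = x,
         n = length(f), channel = attr(tr, "channel"))
  }
  lines <- lapply(tracks[ev], line_of)
  ord <- order(vapply(lines, `[[`, numeric(1), "n"), decreasing = TRUE)
  for (a in seq_along(ord)) {
    la <- lines[[ord[a]]]
    if (is.null(la)) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      lb <- lines[[ord[b]]]
      if (is.null(lb) || lb$channel != la$channel) next
      pred <- la$x0 + la$v * (lb$frames - la$f0)
      if (mean(abs(pred - lb$x)) > 2.0) next
      attr(tracks[[ev[ord[b]]]], "is_anterograde_event") <- FALSE
      lines[ord[b]] <- list(NULL)
    }
  }
  tracks
}

# Local-slope motion classification and track-level summaries.
classify_track <- function(tr, kymo, params) {
  fps <- kymo$frame_rate; px <- kymo$pixel_size
  n <- nrow(tr)
  half <- (params$slope_window - 1L) %/% 2L
  v_loc <- numeric(n)
  spread <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(abs(tr$frame - tr$frame[i]) <= half)
    if (length(w) >= 2L && stats::var(tr$frame[w]) > 0) {
      v_loc[i] <- stats::cov(tr$frame[w], tr$x[w]) / stats::var(tr$frame[w])
    } else v_loc[i] <- 0
    spread[i] <- if (length(w) >= 2L)
      max(tr$x[w]) - min(tr$x[w]) else 0
  }
  v_umps <- v_loc * px * fps
  label <- ifelse(v_umps >= params$v_min, "anterograde",
           ifelse(v_umps <= -params$v_min, "retrograde",
           ifelse(spread <= 2 * params$move_px, "stationary", "diffusive")))
  tr$label <- label

  # longest anterograde run, tolerating brief interruptions (a crossing
  # particle perturbs the centroid for a frame or two without ending the run)
  is_antero <- label == "anterograde"
  gaps <- rle(is_antero)
  if (length(gaps$lengths) > 2L) {
    ge <- cumsum(gaps$lengths)
    for (g in which(!gaps$values & gaps$lengths <= 3L)) {
      if (g == 1L || g == length(gaps$lengths)) next
      is_antero[(ge[g] - gaps$lengths[g] + 1L):ge[g]] <- TRUE
    }
  }
  runs <- rle(is_antero)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  antero_runs <- which(runs$values)
  run_idx <- NULL
  if (length(antero_runs) > 0L) {
    best <- antero_runs[which.max(runs$lengths[antero_runs])]
    run_idx <- starts[best]:ends[best]
  }
  velocity <- NA_real_
  run_disp_um <- 0
  run_frames <- 0L
  run_resid <- NA_real_
  if (!is.null(run_idx) && length(run_idx) >= 2L) {
    f <- tr$frame[run_idx]; x <- tr$x[run_idx]
    slope <- stats::cov(f, x) / stats::var(f)
    velocity <- slope * px * fps
    run_disp_um <- (max(x) - min(x)) * px
    run_frames <- length(run_idx)
    res <- x - (mean(x) + slope * (f - mean(f)))
    # trimmed spread: a crossing particle may perturb a few frames without
    # disqualifying the run, but most points must sit on the line -- a
    # diffusive track scatters everywhere and fails
    run_resid <- if (length(run_idx) > 2L) {
      r2 <- sort(res^2)
      sqrt(mean(r2[seq_len(max(3L, floor(0.8 * length(r2))))]))
    } else 0
  }
  nframes_total <- nrow(kymo$channels[[1L]])
  at_boundary <- !is.null(run_idx) &&
    (tr$frame[run_idx[1L]] <= params$gap_frames + 1L ||
       tr$frame[run_idx[length(run_idx)]] >= nframes_total - params$gap_frames)
  disp_needed <- if (at_boundary) params$boundary_run_um else params$min_run_um
  # Two ways to qualify as a transport event: a long run covering most of
  # the flagellum tolerates centroid wobble from crossings and the tip
  # cluster, while a short run must be clean enough that the diffusive
  # background cannot mimic it.
  run_density <- if (!is.null(run_idx) && length(run_idx) >= 2L)
    run_frames / (tr$frame[run_idx[length(run_idx)]] -
                    tr$frame[run_idx[1L]] + 1L) else 0
  is_long_run <- run_frames >= 20L && run_disp_um >= 4.5 &&
    run_density >= 0.75 && is.finite(run_resid) && run_resid <= 2.5
  is_clean_run <- run_disp_um >= disp_needed &&
    is.finite(run_resid) && run_resid <= params$run_resid_px
  # densely detected, highly linear medium runs at plausible transport speed:
  # fragments of real runs broken by the tip cluster look like this, while
  # diffusive clutter essentially never sustains such a clean line
  is_medium_run <- run_frames >= 10L && run_density >= 0.8 &&
    run_disp_um >= 1.6 && is.finite(run_resid) && run_resid <= 0.5 &&
    is.finite(velocity) && velocity >= 2 * params$v_min
  is_event <- !is.null(run_idx) &&
    run_frames >= params$min_frames &&
    is.finite(velocity) && velocity <= params$v_max &&
    (is_long_run || is_clean_run || is_medium_run)

  retro <- rle(label == "retrograde")
  is_retro <- any(retro$values & retro$lengths >= params$min_frames)

  # tip dwell: arrival = first point at/after the anterograde run within
  # d_tip of the distal end; end = first later point displaced by > move_px.
  tip_col <- kymo_col(kymo, kymo$length_um)
  dwell <- NA_real_
  censored <- NA
  if (!is.null(run_idx)) {
    # arrival = end of the anterograde run, provided it reaches the tip zone
    run_end <- run_idx[length(run_idx)]
    arr <- if (tr$x[run_end] >= tip_col - params$d_tip_px) run_end else NA
    if (!is.na(arr)) {
      later <- which(seq_len(n) > arr & abs(tr$x - tr$x[arr]) > params$move_px)
      if (length(later) > 0L) {
        dwell <- (tr$frame[later[1L]] - tr$frame[arr]) / fps
        censored <- FALSE
      } else {
        dwell <- (tr$frame[n] - tr$frame[arr]) / fps
        censored <- TRUE
      }
    }
  }
  run_flux <- if (!is.null(run_idx))
    stats::median(tr$flux[run_idx]) else NA_real_
  attr(tr, "run_flux") <- run_flux
  attr(tr, "velocity") <- velocity
  attr(tr, "is_anterograde_event") <- is_event
  attr(tr, "is_retrograde_event") <- is_retro
  attr(tr, "run_frames") <- run_frames
  attr(tr, "run_range") <- if (!is.null(run_idx))
    c(tr$frame[run_idx[1L]], tr$frame[run_idx[length(run_idx)]]) else c(NA, NA)
  attr(tr, "tip_dwell") <- dwell
  attr(tr, "dwell_censored") <- censored
  tr
}

track_attr <- function(ts, what) {
  vapply(ts$tracks, function(tr) {
    a <- attr(tr, what)
    if (is.null(a)) NA_real_ else as.numeric(a[1L])
  }, numeric(1))
}

track_channel <- function(ts) {
  vapply(ts$tracks, function(tr) as.integer(attr(tr, "channel")), integer(1))
}

#' @export
print.track_set <- function(x, ...) {
  ch <- track_channel(x)
  ev <- track_attr(x, "is_anterograde_event") > 0
  cat(sprintf("track set: %d tracks (%d anterograde events) over %.4g s\n",
              length(x$tracks), sum(ev, na.rm = TRUE), x$duration))
  for (c in sort(unique(ch)))
    cat(sprintf("  channel %d: %d tracks, %d anterograde events\n",
                c, sum(ch == c), sum(ev & ch == c, na.rm = TRUE)))
  invisible(x)
}
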