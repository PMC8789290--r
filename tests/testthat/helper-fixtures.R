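# Shared fixtures: small configurations used across test files.

two_cargo_config <- function(duration, p_a, p_b, seed = NULL, ...) {
  sim_config(duration = duration,
             cargoes = list(
               cargo_spec("cargoA", p_load = p_a, two_copy_prob = 0,
                          channel = 1L),
               cargo_spec("cargoB", p_load = p_b, two_copy_prob = 0,
                          channel = 2L)),
             seed = seed, ...)
}

# a minimal event_table built by hand (bypassing the simulator)
manual_event_table <- function(times, copies, duration,
                               velocity = 1.71, cargo = "cargoA") {
  cfg <- sim_config(duration = duration,
                    cargoes = list(cargo_spec(cargo, channel = 1L)))
  et <- data.frame(train_id = seq_along(times), departure_time_s = times,
                   velocity_um_s = velocity, is_open = TRUE)
  et[[paste0("copies_", cargo)]] <- as.integer(copies)
  structure(et, config = cfg, class = c("event_table", "data.frame"))
}

# a track_set built by hand for measurement unit tests
manual_track_set <- function(n_events, duration, frame_rate = 10,
                             pixel_size = 0.16, length_um = 7.3) {
  params <- extract_params()
  tracks <- lapply(seq_len(n_events), function(i) {
    tr <- data.frame(frame = 1:20, x = 6 + (1:20), amp = 50, flux = 150,
                     label = "anterograde")
    attr(tr, "channel") <- 1L
    attr(tr, "id") <- i
    attr(tr, "velocity") <- 1.71
    attr(tr, "is_anterograde_event") <- TRUE
    attr(tr, "is_retrograde_event") <- FALSE
    attr(tr, "run_frames") <- 20L
    attr(tr, "run_range") <- c(1L, 20L)
    attr(tr, "run_flux") <- 150
    attr(tr, "tip_dwell") <- NA_real_
    attr(tr, "dwell_censored") <- NA
    tr
  })
  structure(list(tracks = tracks, frame_rate = frame_rate,
                 pixel_size = pixel_size, origin_px = 5L,
                 length_um = length_um, duration = duration,
                 params = params),
            class = "track_set")
}
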