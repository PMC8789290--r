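#' Cargo specification
#'
#' Describes one fluorescently tagged cargo species: how often it loads onto
#' an anterograde IFT train, how many copies a train may carry, and what the
#' cargo does once released at the flagellar tip.
#'
#' @param name Cargo label, used for the `copies_<name>` column of event
#'   tables and in error messages.
#' @param p_load Probability that an anterograde train carries this cargo
#'   (before any length response is applied). Under the subclass loading
#'   model this is the target marginal probability; the conditional
#'   probability given an open train is `p_load / open_fraction`.
#' @param max_copies Maximum number of copies per train (default 2; trains
#'   carrying two copies of a tagged protein are observed as two-step
#'   photobleaching).
#' @param two_copy_prob Conditional probability that a carrying train holds a
#'   second copy. The source data report two-copy trains only qualitatively;
#'   0.1 is a configurable default, not a measured value.
#' @param release Named numeric vector of probabilities for the fate of the
#'   cargo after its tip dwell: `diffuse` (return to the base by diffusion),
#'   `dock` (remain stationary at a subdistal site, as axonemal building
#'   blocks do), `retrograde` (return by retrograde IFT). Must sum to 1.
#' @param channel Imaging channel (1 or 2) the cargo is rendered into.
#' @return An object of class `cargo_spec`.
#' @seealso [cargo_adapter()], [cargo_axonemal()] for presets matching the
#'   behavior of an IFT cargo adapter and of an axonemal cargo.
#' @export
cargo_spec <- function(name,
                       p_load = 0.5,
                       max_copies = 2,
                       two_copy_prob = 0.1,
                       release = c(diffuse = 14 / 15, dock = 0, retrograde = 1 / 15),
                       channel = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(p_load) || length(p_load) != 1L || p_load < 0 || p_load > 1)
    stop("cargo '", name, "': p_load must be a probability in [0, 1]")
  if (two_copy_prob < 0 || two_copy_prob > 1)
    stop("cargo '", name, "': two_copy_prob must be in [0, 1]")
  if (max_copies < 1) stop("cargo '", name, "': max_copies must be >= 1")
  rel <- c(diffuse = 0, dock = 0, retrograde = 0)
  if (is.null(names(release)) || !all(names(release) %in% names(rel)))
    stop("release probabilities must be named among 'diffuse', 'dock', 'retrograde'")
  rel[names(release)] <- release
  if (any(rel < 0) || abs(sum(rel) - 1) > 1e-8)
    stop("cargo '", name, "': release probabilities must be non-negative and sum to 1")
  structure(
    list(name = name, p_load = p_load, max_copies = as.integer(max_copies),
         two_copy_prob = two_copy_prob, release = rel,
         channel = as.integer(channel)),
    class = "cargo_spec"
  )
}

#' @rdname cargo_spec
#' @details `cargo_adapter()` is the preset for an adapter-like cargo
#'   (released cargo mostly diffuses back, retrograde return is rare, about
#'   1 event in 15); `cargo_axonemal()` is the preset for an axonemal cargo
#'   that mostly docks subdistally after release (12 of 15 events), with
#'   occasional deeper diffusion (2 of 15) or retrograde return (1 of 15).
#' @export
cargo_adapter <- function(name = "adapter", p_load = 44 / 60, channel = 1L, ...) {
  cargo_spec(name, p_load = p_load,
             release = c(diffuse = 14 / 15, dock = 0, retrograde = 1 / 15),
             channel = channel, ...)
}

#' @rdname cargo_spec
#' @param ... Further arguments passed to [cargo_spec()].
#' @export
cargo_axonemal <- function(name = "cargo", p_load = 0.08, channel = 2L, ...) {
  cargo_spec(name, p_load = p_load,
             release = c(dock = 12 / 15, diffuse = 2 / 15, retrograde = 1 / 15),
             channel = channel, ...)
}

#' Length-response presets
#'
#' A length response maps flagellar length (um) to a multiplier on the cargo
#' loading probability. `length_response_identity` is the default (loading
#' does not depend on length). `length_response_logistic` returns a logistic
#' decline calibrated so that transport frequency falls from `f_short`
#' events/min in short regenerating flagella to `f_full` events/min in
#' full-length flagella; the functional form is a modeling choice, the two
#' anchor frequencies are measured values (44 and 0.9 events/min/flagellum).
#' The multiplier is normalized to 1 at `ref_length`.
#'
#' @param f_short,f_full Frequencies (events/min) anchoring the decline.
#' @param midpoint,scale Logistic midpoint and scale (um).
#' @param ref_length Length (um) at which the multiplier equals 1.
#' @return A function of length (um) returning a non-negative multiplier.
#' @export
length_response_identity <- function() function(length_um) rep(1, length(length_um))

#' @rdname length_response_identity
#' @export
length_response_logistic <- function(f_short = 44, f_full = 0.9,
                                     midpoint = 8, scale = 1.5,
                                     ref_length = 7.3) {
  freq <- function(L) f_full + (f_short - f_full) / (1 + exp((L - midpoint) / scale))
  at_ref <- freq(ref_length)
  function(length_um) freq(length_um) / at_ref
}

#' Simulation configuration
#'
#' Bundles all kinematic, loading-model and timing parameters of the train
#' traffic simulator. Defaults are the measured values for the ARMC2 cargo
#' adapter in regenerating Chlamydomonas flagella: anterograde trains at
#' ~1/s, anterograde runs at 1.71 um/s (SD 0.24), a tip dwell of 2.3 s
#' (SD 1.8), rare retrograde return, and a basal-pool dwell of ~19 s
#' (SD 7.7).
#'
#' @param duration Observation window (s).
#' @param flagellum_length Flagellar length (um); default 7.3 um, the mean
#'   length of the regenerating cilia analyzed in the cotransport data set.
#' @param train_rate Anterograde train frequency (trains/s).
#' @param arrival `"poisson"` (homogeneous Poisson arrivals, default) or
#'   `"regular"` (evenly spaced trains, the idealization under which T
#'   seconds of recording correspond to exactly T trains at 1/s).
#' @param antero_velocity_mean,antero_velocity_sd Anterograde velocity
#'   (um/s), drawn per train from a normal truncated at zero.
#' @param retro_velocity Retrograde velocity (um/s) for cargoes returning by
#'   retrograde IFT. Not reported in the source data; 3.0 um/s is typical of
#'   Chlamydomonas retrograde IFT.
#' @param tip_dwell_mean,tip_dwell_sd Tip dwell (s), drawn per trajectory
#'   from a normal truncated at zero.
#' @param diffusion_coeff Diffusion coefficient (um^2/s) for cargo returning
#'   to the base by diffusion. Not reported; default 2.0.
#' @param diffusion_dt Time step (s) for simulating the reflected Brownian
#'   return path.
#' @param pool_dwell_mean,pool_dwell_sd Dwell time (s) of cargo in the
#'   basal-body-associated pool, i.e. the expected traffic gap after the pool
#'   is photobleached.
#' @param cargoes List of [cargo_spec()] objects (at most one per channel).
#' @param loading_model `"stochastic"` (every train can bind cargo
#'   independently) or `"subclass"` (only an `open_fraction` of trains can
#'   bind cargo).
#' @param open_fraction Fraction f of open trains under the subclass model
#'   (0 < f <= 1). Marginal loading probabilities are preserved by loading
#'   open trains with probability `p_load / f`.
#' @param subclass_saturation What to do when `p_load / f > 1` under the
#'   subclass model: `"error"` (default; the marginal cannot be preserved and
#'   the configuration is rejected, naming the offending cargo) or `"cap"`
#'   (load every open train with that cargo, so its marginal shrinks to f).
#' @param length_response Function mapping flagellar length (um) to a loading
#'   multiplier, or `NULL` for the identity. See
#'   [length_response_logistic()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 60,
                       flagellum_length = 7.3,
                       train_rate = 1.0,
                       arrival = c("poisson", "regular"),
                       antero_velocity_mean = 1.71,
                       antero_velocity_sd = 0.24,
                       retro_velocity = 3.0,
                       tip_dwell_mean = 2.3,
                       tip_dwell_sd = 1.8,
                       diffusion_coeff = 2.0,
                       diffusion_dt = 0.02,
                       pool_dwell_mean = 19,
                       pool_dwell_sd = 7.7,
                       cargoes = list(cargo_adapter("cargoA", channel = 1L),
                                      cargo_axonemal("cargoB", channel = 2L)),
                       loading_model = c("stochastic", "subclass"),
                       open_fraction = 1.0,
                       subclass_saturation = c("error", "cap"),
                       length_response = NULL,
                       seed = NULL) {
  arrival <- match.arg(arrival)
  loading_model <- match.arg(loading_model)
  subclass_saturation <- match.arg(subclass_saturation)
  if (inherits(cargoes, "cargo_spec")) cargoes <- list(cargoes)
  stopifnot(is.list(cargoes), length(cargoes) >= 1L)
  for (cg in cargoes)
    if (!inherits(cg, "cargo_spec")) stop("cargoes must be cargo_spec objects")
  nm <- vapply(cargoes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("cargo names must be unique")
  names(cargoes) <- nm
  if (is.null(length_response)) length_response <- length_response_identity()
  cfg <- structure(
    list(duration = duration, flagellum_length = flagellum_length,
         train_rate = train_rate, arrival = arrival,
         antero_velocity_mean = antero_velocity_mean,
         antero_velocity_sd = antero_velocity_sd,
         retro_velocity = retro_velocity,
         tip_dwell_mean = tip_dwell_mean, tip_dwell_sd = tip_dwell_sd,
         diffusion_coeff = diffusion_coeff, diffusion_dt = diffusion_dt,
         pool_dwell_mean = pool_dwell_mean, pool_dwell_sd = pool_dwell_sd,
         cargoes = cargoes, loading_model = loading_model,
         open_fraction = open_fraction,
         subclass_saturation = subclass_saturation,
         length_response = length_response,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()]: positive rates and
#' durations, probabilities in range, non-negative spreads, and — under the
#' subclass loading model with `subclass_saturation = "error"` — that every
#' cargo's marginal loading probability can be preserved (`p_load /
#' open_fraction <= 1`). The error names the offending cargo.
#'
#' @param config A `sim_config` object.
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (!is.numeric(train_rate) || train_rate <= 0)
      stop("train_rate must be > 0")
    if (duration < 0) stop("duration must be >= 0")
    if (flagellum_length <= 0) stop("flagellum_length must be > 0")
    if (antero_velocity_sd < 0 || tip_dwell_sd < 0 || pool_dwell_sd < 0)
      stop("standard deviations must be >= 0")
    if (antero_velocity_mean <= 0) stop("antero_velocity_mean must be > 0")
    if (diffusion_coeff <= 0) stop("diffusion_coeff must be > 0")
    if (open_fraction <= 0 || open_fraction > 1)
      stop("open_fraction must be in (0, 1]")
  })
  if (config$loading_model == "subclass" &&
      config$subclass_saturation == "error") {
    mult <- config$length_response(config$flagellum_length)
    for (cg in config$cargoes) {
      p_eff <- min(1, cg$p_load * mult)
      if (p_eff / config$open_fraction > 1 + 1e-12)
        stop("invalid subclass configuration for cargo '", cg$name,
             "': p_load/open_fraction = ",
             signif(p_eff / config$open_fraction, 3),
             " > 1; the marginal loading probability cannot be preserved ",
             "(use subclass_saturation = \"cap\" to saturate open trains)")
    }
  }
  invisible(config)
}

#' Imaging configuration for the kymograph renderer
#'
#' @param frame_rate Acquisition rate (frames/s); recordings in the source
#'   data set were taken at 10 fps.
#' @param pixel_size Pixel size (um/pixel); 0.16 um is typical for the
#'   60x/NA 1.49 TIRF setup described.
#' @param psf_sigma_px Gaussian point-spread sigma (pixels).
#' @param photons_per_particle Mean integrated counts contributed by one
#'   unbleached fluorophore per frame.
#' @param background Mean background (counts/pixel/frame).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param bleach_rate Per-channel single-step photobleaching rate (1/s);
#'   channel 2 defaults higher than channel 1 to emulate the lower
#'   photostability difference between the two tags (mScarlet bleaches
#'   faster than NeonGreen under comparable excitation; here channel 1
#'   carries the sparser adapter signal and is given the slower rate so both
#'   conventions are configurable).
#' @param substeps Sub-frame exposure samples per frame; positions are
#'   averaged over the exposure, so fast-diffusing particles are motion
#'   blurred as they are in real 10 fps TIRF recordings.
#' @param pad_px Columns of padding on each side of the flagellum so that
#'   point-spread tails at the base and tip stay inside the image.
#' @param static_axoneme_intensity Constant counts/pixel added along the
#'   flagellum (residual unbleached signal incorporated in the axoneme).
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(frame_rate = 10,
                           pixel_size = 0.16,
                           psf_sigma_px = 1.0,
                           photons_per_particle = 150,
                           background = 10,
                           read_noise_sd = 2,
                           bleach_rate = c(0.02, 0.04),
                           substeps = 10,
                           pad_px = 5,
                           static_axoneme_intensity = 0) {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  if (photons_per_particle < 0 || background < 0 ||
      static_axoneme_intensity < 0)
    stop("intensities must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (length(bleach_rate) == 1L) bleach_rate <- rep(bleach_rate, 2L)
  if (any(bleach_rate < 0)) stop("bleach_rate must be >= 0")
  structure(
    list(frame_rate = frame_rate, pixel_size = pixel_size,
         psf_sigma_px = psf_sigma_px,
         photons_per_particle = photons_per_particle,
         background = background, read_noise_sd = read_noise_sd,
         bleach_rate = bleach_rate, substeps = as.integer(substeps),
         pad_px = as.integer(pad_px),
         static_axoneme_intensity = static_axoneme_intensity),
    class = "imaging_config"
  )
}

# Echo a sim_config as a plain list suitable for YAML serialization.
config_as_list <- function(config) {
  x <- unclass(config)
  x$length_response <- NULL
  x$cargoes <- lapply(config$cargoes, function(cg) {
    y <- unclass(cg)
    y$release <- as.list(y$release)
    y
  })
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat("IFT traffic simulation configuration\n")
  cat(sprintf("  trains: %.3g/s (%s arrivals), duration %.4g s, flagellum %.3g um\n",
              x$train_rate, x$arrival, x$duration, x$flagellum_length))
  cat(sprintf("  anterograde %.3g +/- %.3g um/s, tip dwell %.3g +/- %.3g s\n",
              x$antero_velocity_mean, x$antero_velocity_sd,
              x$tip_dwell_mean, x$tip_dwell_sd))
  cat(sprintf("  loading model: %s%s\n", x$loading_model,
              if (x$loading_model == "subclass")
                sprintf(" (open fraction %.3g)", x$open_fraction) else ""))
  for (cg in x$cargoes)
    cat(sprintf("  cargo %-10s p_load %.3g, channel %d\n",
                cg$name, cg$p_load, cg$channel))
  invisible(x)
}
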