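#' Simulate anterograde IFT train traffic and cargo loading
#'
#' Draws train departures over the observation window and loads each cargo
#' onto trains under the configured model. Under the `"stochastic"` model
#' every train carries cargo c independently with probability
#' `p_c * length_response(L)`. Under the `"subclass"` model a train is open
#' with probability `open_fraction` and an open train carries cargo c with
#' probability `p_c * length_response(L) / open_fraction`, which preserves
#' the marginal carrying probability while concentrating cargo on the open
#' subset; the two models therefore differ only in cargo co-occurrence.
#'
#' @param config A [sim_config()].
#' @return An object of class `event_table`: a data frame with one row per
#'   train (`train_id`, `departure_time_s`, `velocity_um_s`, `is_open`, and
#'   one `copies_<name>` column per cargo), with the configuration attached
#'   as attribute `config`. Summaries are available via [cotransport_counts()].
#' @examples
#' cfg <- sim_config(duration = 100, seed = 1)
#' et <- simulate_traffic(cfg)
#' cotransport_counts(et)
#' @export
simulate_traffic <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- config$train_rate
  T <- config$duration
  if (config$arrival == "poisson") {
    n <- stats::rpois(1L, r * T)
    times <- sort(stats::runif(n, 0, T))
  } else {
    n <- floor(r * T)
    times <- if (n > 0) (seq_len(n) - 0.5) / r else numeric(0)
  }
  vel <- truncated_normal(n, config$antero_velocity_mean,
                          config$antero_velocity_sd,
                          lower = 0.05 * config$antero_velocity_mean)
  mult <- config$length_response(config$flagellum_length)
  f <- config$open_fraction
  subclass <- config$loading_model == "subclass"
  is_open <- if (subclass) stats::runif(n) < f else rep(TRUE, n)

  et <- data.frame(train_id = seq_len(n),
                   departure_time_s = times,
                   velocity_um_s = vel,
                   is_open = is_open)
  for (cg in config$cargoes) {
    p_eff <- min(1, cg$p_load * mult)
    if (subclass) {
      q <- p_eff / f
      if (q > 1) {
        if (config$subclass_saturation == "error")
          stop("invalid subclass configuration for cargo '", cg$name, "'")
        q <- 1
      }
      carried <- is_open & (stats::runif(n) < q)
    } else {
      carried <- stats::runif(n) < p_eff
    }
    copies <- integer(n)
    copies[carried] <- 1L
    if (cg$max_copies >= 2L && cg$two_copy_prob > 0 && any(carried)) {
      second <- stats::runif(sum(carried)) < cg$two_copy_prob
      copies[carried] <- copies[carried] + as.integer(second)
    }
    copies <- pmin(copies, cg$max_copies)
    et[[paste0("copies_", cg$name)]] <- copies
  }
  structure(et, config = config, class = c("event_table", "data.frame"))
}

# Normal draws truncated below at `lower` (rejection sampling).
truncated_normal <- function(n, mean, sd, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

cargo_names <- function(et) {
  sub("^copies_", "", grep("^copies_", names(et), value = TRUE))
}

#' Count transports and cotransports in an event table
#'
#' A train counts once toward a cargo's total if it carries at least one copy
#' of that cargo, and once toward the cotransport total if it carries at
#' least one copy of each of the two cargoes.
#'
#' @param et An `event_table` from [simulate_traffic()].
#' @param cargo_a,cargo_b Cargo names (default: the first two cargoes).
#' @param label Label for the resulting record.
#' @return A [count_record()] with the observed counts, the observation
#'   duration and the configured train rate.
#' @export
cotransport_counts <- function(et, cargo_a = NULL, cargo_b = NULL,
                               label = "simulated") {
  cn <- cargo_names(et)
  if (length(cn) < 1L) stop("event table has no cargo columns")
  if (is.null(cargo_a)) cargo_a <- cn[1L]
  if (is.null(cargo_b)) cargo_b <- if (length(cn) >= 2L) cn[2L] else cn[1L]
  a <- et[[paste0("copies_", cargo_a)]] > 0
  b <- et[[paste0("copies_", cargo_b)]] > 0
  cfg <- attr(et, "config")
  count_record(label = label,
               n_a = sum(a), n_b = sum(b), n_co = sum(a & b),
               duration = cfg$duration,
               train_rate = cfg$train_rate,
               cargo_a = cargo_a, cargo_b = cargo_b,
               n_trains_observed = nrow(et))
}

#' Expected cotransport probability under a loading model
#'
#' Under stochastic (independent) loading the probability that a train
#' carries both cargoes is the product of the marginals, `pA * pB`. Under
#' the subclass model both cargoes ride only on the open fraction `f` of
#' trains, so the co-occurrence probability is enriched to `pA * pB / f`,
#' bounded above by `min(pA, pB)` (a cotransport requires both cargoes).
#'
#' @param p_a,p_b Marginal carrying probabilities.
#' @param model `"stochastic"` or `"subclass"`.
#' @param f Open-train fraction (subclass model only), in (0, 1].
#' @return The expected probability that a train carries both cargoes.
#' @examples
#' expected_cotransport_probability(0.268, 0.117)        # 0.0314
#' expected_cotransport_probability(0.1, 0.1, "subclass", f = 0.2)  # 0.05
#' @export
expected_cotransport_probability <- function(p_a, p_b,
                                             model = c("stochastic", "subclass"),
                                             f = 1) {
  model <- match.arg(model)
  stopifnot(p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  if (model == "subclass") {
    if (f <= 0 || f > 1) stop("open fraction f must be in (0, 1]")
    min(p_a * p_b / f, min(p_a, p_b))
  } else {
    p_a * p_b
  }
}

#' Simulate a basal-pool photobleaching (FRAP) experiment
#'
#' After the basal-body-associated cargo pool is photobleached, trains keep
#' departing but the cargo they pick up from the pool is dark until the pool
#' has turned over. The pool dwell is drawn once per experiment from
#' `(pool_dwell_mean, pool_dwell_sd)` truncated at zero; trains departing
#' within that window after `bleach_time` carry only bleached cargo. After
#' the window, carriage of fluorescent cargo resumes, thinned by
#' `recovery_fraction` (1 = full recovery; recovery of the tagged adapter
#' was observed to be incomplete).
#'
#' @param config A [sim_config()].
#' @param bleach_time Time (s) at which the pool is bleached; must be less
#'   than `config$duration`.
#' @param cargo Name of the pool-fed cargo (default: first cargo).
#' @param recovery_fraction Probability that a post-gap copy is fluorescent.
#' @return An `event_table` with an additional `fluor_<cargo>` column giving
#'   the number of fluorescent copies per train, and attributes
#'   `bleach_time` and `pool_dwell` (the realized dwell).
#' @seealso [detect_traffic_gap()]
#' @export
simulate_pool_bleach <- function(config, bleach_time, cargo = NULL,
                                 recovery_fraction = 1.0) {
  if (bleach_time >= config$duration)
    stop("bleach_time must be earlier than the observation window end")
  if (recovery_fraction < 0 || recovery_fraction > 1)
    stop("recovery_fraction must be in [0, 1]")
  et <- simulate_traffic(config)
  cn <- cargo_names(et)
  if (is.null(cargo)) cargo <- cn[1L]
  if (!cargo %in% cn) stop("unknown cargo '", cargo, "'")
  dwell <- rgamma_ms(1L, config$pool_dwell_mean, config$pool_dwell_sd)
  copies <- et[[paste0("copies_", cargo)]]
  fluor <- copies
  dark <- et$departure_time_s > bleach_time &
    et$departure_time_s <= bleach_time + dwell
  fluor[dark] <- 0L
  if (recovery_fraction < 1) {
    post <- which(et$departure_time_s > bleach_time + dwell & copies > 0)
    if (length(post) > 0)
      fluor[post] <- stats::rbinom(length(post), copies[post], recovery_fraction)
  }
  et[[paste0("fluor_", cargo)]] <- fluor
  attr(et, "bleach_time") <- bleach_time
  attr(et, "pool_dwell") <- dwell
  attr(et, "bleached_cargo") <- cargo
  et
}

#' @export
print.event_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("IFT event table: %d trains over %.4g s (%s model)\n",
              nrow(x), cfg$duration, cfg$loading_model))
  cn <- cargo_names(x)
  for (nm in cn)
    cat(sprintf("  %-10s %d transports\n", nm, sum(x[[paste0("copies_", nm)]] > 0)))
  if (length(cn) >= 2L) {
    co <- sum(x[[paste0("copies_", cn[1L])]] > 0 & x[[paste0("copies_", cn[2L])]] > 0)
    cat(sprintf("  cotransports (%s & %s): %d\n", cn[1L], cn[2L], co))
  }
  invisible(x)
}
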