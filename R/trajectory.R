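# Gamma draws parameterized by mean and SD: a non-negative waiting-time
# distribution whose realized mean equals the configured (measured) mean
# exactly, unlike a zero-truncated normal. Zero spread returns the mean.
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0) return(rep(max(mean, 0), n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Build the position-versus-time path of one transported cargo
#'
#' A cargo trajectory starts with a processive anterograde run from the base
#' (position 0) to the tip at the train's velocity, followed by a tip dwell
#' drawn from a gamma distribution with the configured mean and SD (dwell
#' times are non-negative waiting times; the gamma reproduces the measured
#' mean exactly, which a zero-truncated normal does not). The
#' release branch is then drawn from the cargo's release partition: diffusive
#' return (reflected one-dimensional Brownian motion with the configured
#' diffusion coefficient until exit at the base), stationary docking at a
#' subdistal site, or retrograde IFT back to the base.
#'
#' @param event One-row slice of an `event_table` (or a list with
#'   `departure_time_s` and `velocity_um_s`).
#' @param cargo Cargo name; must be carried by the event.
#' @param config The [sim_config()] used to generate the event.
#' @return An object of class `cargo_trajectory`: a list with the cargo
#'   label, channel, copy count, a `segments` data frame (`kind`, `t0`,
#'   `t1`, `x0`, `x1`), and for diffusive returns the sampled path.
#' @export
build_trajectory <- function(event, cargo, config) {
  cg <- config$cargoes[[cargo]]
  if (is.null(cg)) stop("unknown cargo '", cargo, "'")
  copies <- event[[paste0("copies_", cargo)]]
  if (is.null(copies) || length(copies) != 1L || copies < 1L)
    stop("event does not carry cargo '", cargo, "'")
  L <- config$flagellum_length
  v <- event$velocity_um_s
  t0 <- event$departure_time_s
  t_tip <- t0 + L / v

  dwell <- rgamma_ms(1L, config$tip_dwell_mean, config$tip_dwell_sd)
  t_rel <- t_tip + dwell
  fate <- sample(names(cg$release), 1L, prob = cg$release)

  seg <- data.frame(kind = c("run", "tip_dwell"),
                    t0 = c(t0, t_tip), t1 = c(t_tip, t_rel),
                    x0 = c(0, L), x1 = c(L, L),
                    stringsAsFactors = FALSE)
  diff_path <- NULL
  horizon <- config$duration + 1 / max(config$train_rate, 1e-6)
  if (fate == "retrograde") {
    t_base <- t_rel + L / config$retro_velocity
    seg <- rbind(seg, data.frame(kind = "retrograde", t0 = t_rel, t1 = t_base,
                                 x0 = L, x1 = 0))
  } else if (fate == "dock") {
    dock_x <- L - stats::runif(1L, 0.3, 1.0)
    dock_x <- max(0, dock_x)
    # brief repositioning to the subdistal site, then stationary
    t_move <- t_rel + (L - dock_x) / config$retro_velocity
    seg <- rbind(seg,
                 data.frame(kind = "retrograde", t0 = t_rel, t1 = t_move,
                            x0 = L, x1 = dock_x),
                 data.frame(kind = "docked", t0 = t_move, t1 = horizon,
                            x0 = dock_x, x1 = dock_x))
  } else { # diffuse
    if (t_rel < horizon) {
      diff_path <- reflected_brownian_exit(L, config$diffusion_coeff,
                                           config$diffusion_dt, L,
                                           horizon - t_rel)
      seg <- rbind(seg,
                   data.frame(kind = "diffusion", t0 = t_rel,
                              t1 = t_rel + diff_path$t[length(diff_path$t)],
                              x0 = L, x1 = diff_path$x[length(diff_path$x)]))
      diff_path$t <- diff_path$t + t_rel
    } else {
      seg <- rbind(seg, data.frame(kind = "diffusion", t0 = t_rel, t1 = t_rel,
                                   x0 = L, x1 = L))
    }
  }
  structure(
    list(label = cargo, channel = cg$channel,
         train_id = event$train_id, copies = as.integer(copies),
         segments = seg, diff_path = diff_path, bleach_time = NA_real_),
    class = "cargo_trajectory"
  )
}

# Reflected Brownian motion on [0, L] started at x0, absorbed at 0 (exit at
# the flagellar base); returns the sampled path up to exit or max_t.
reflected_brownian_exit <- function(L, D, dt, x0, max_t) {
  nmax <- max(1L, ceiling(max_t / dt))
  sd_step <- sqrt(2 * D * dt)
  x <- numeric(nmax + 1L)
  x[1L] <- x0
  n_end <- nmax + 1L
  steps <- stats::rnorm(nmax, 0, sd_step)
  for (i in seq_len(nmax)) {
    xi <- x[i] + steps[i]
    if (xi > L) xi <- 2 * L - xi      # reflect at the tip
    if (xi <= 0) {                    # exit at the base
      x[i + 1L] <- 0
      n_end <- i + 1L
      break
    }
    x[i + 1L] <- xi
  }
  list(t = (seq_len(n_end) - 1L) * dt, x = x[seq_len(n_end)])
}

#' Build trajectories for every carried cargo in an event table
#'
#' @param et An `event_table`.
#' @param config The generating [sim_config()]; defaults to the table's
#'   `config` attribute.
#' @param cargoes Cargo names to include (default: all).
#' @param fluorescent_only If `TRUE` and the table carries `fluor_<cargo>`
#'   columns (from [simulate_pool_bleach()]), copies are restricted to the
#'   fluorescent ones and trains with no fluorescent copy are skipped.
#' @return A list of `cargo_trajectory` objects.
#' @export
build_trajectories <- function(et, config = attr(et, "config"),
                               cargoes = NULL, fluorescent_only = FALSE) {
  cn <- cargo_names(et)
  if (!is.null(cargoes)) cn <- intersect(cn, cargoes)
  out <- list()
  for (nm in cn) {
    copies <- et[[paste0("copies_", nm)]]
    fcol <- paste0("fluor_", nm)
    if (fluorescent_only && fcol %in% names(et)) copies <- et[[fcol]]
    idx <- which(copies > 0)
    for (i in idx) {
      ev <- et[i, , drop = FALSE]
      ev[[paste0("copies_", nm)]] <- copies[i]
      tr <- build_trajectory(ev, nm, config)
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}

#' Evaluate a trajectory's position at given times
#'
#' @param traj A `cargo_trajectory`.
#' @param t Numeric vector of times (s).
#' @return Positions (um from the base) at each time; `NA` before the run
#'   starts or after the cargo has left the flagellum.
#' @export
trajectory_position <- function(traj, t) {
  seg <- traj$segments
  out <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(seg))) {
    k <- seg$kind[i]
    inside <- t >= seg$t0[i] & (if (i == nrow(seg)) t <= seg$t1[i] else t < seg$t1[i])
    if (!any(inside)) next
    if (k == "diffusion" && !is.null(traj$diff_path)) {
      out[inside] <- stats::approx(traj$diff_path$t, traj$diff_path$x,
                                   xout = t[inside], rule = 2)$y
    } else if (seg$t1[i] > seg$t0[i]) {
      frac <- (t[inside] - seg$t0[i]) / (seg$t1[i] - seg$t0[i])
      out[inside] <- seg$x0[i] + frac * (seg$x1[i] - seg$x0[i])
    } else {
      out[inside] <- seg$x0[i]
    }
  }
  # once a diffusing or retrograde cargo reaches the base it leaves the field
  last <- seg[nrow(seg), ]
  if (last$kind %in% c("diffusion", "retrograde"))
    out[t >= last$t1] <- NA_real_
  out
}

#' @export
print.cargo_trajectory <- function(x, ...) {
  cat(sprintf("cargo trajectory: %s (channel %d, %d cop%s)\n",
              x$label, x$channel, x$copies, if (x$copies == 1L) "y" else "ies"))
  print(x$segments, ...)
  invisible(x)
}
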