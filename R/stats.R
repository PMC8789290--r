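#' Observed transport counts for one cargo pair
#'
#' The unit of observation is the anterograde IFT train: at a train
#' frequency of `train_rate` (1/s by convention), `duration` seconds of
#' recording correspond to `duration * train_rate` trains, and every
#' transport occupies one train.
#'
#' @param label Row label (e.g. strain and regeneration state).
#' @param n_a,n_b Anterograde transports of cargo A and cargo B.
#' @param n_co Cotransports (trains carrying both cargoes; each counts once
#'   toward `n_a` and once toward `n_b`).
#' @param duration Total observation time (s), summed over flagella.
#' @param n_flagella Number of flagella analyzed (annotation only).
#' @param train_rate Assumed anterograde train frequency (trains/s).
#' @param cargo_a,cargo_b Cargo names (annotation only).
#' @param n_trains_observed Realized train count for simulated records
#'   (annotation only; probabilities always use the `duration * train_rate`
#'   convention).
#' @return An object of class `count_record`.
#' @export
count_record <- function(label, n_a, n_b, n_co, duration,
                         n_flagella = NA_integer_, train_rate = 1.0,
                         cargo_a = "cargoA", cargo_b = "cargoB",
                         n_trains_observed = NA_integer_) {
  if (duration <= 0) stop("duration must be > 0")
  if (train_rate <= 0) stop("train_rate must be > 0")
  n_a <- as.integer(n_a); n_b <- as.integer(n_b); n_co <- as.integer(n_co)
  if (any(c(n_a, n_b, n_co) < 0)) stop("counts must be non-negative")
  if (n_co > min(n_a, n_b))
    stop("invalid record '", label, "': n_co (", n_co,
         ") exceeds min(n_a, n_b) = ", min(n_a, n_b))
  n_trains <- round(duration * train_rate)
  if (n_a > n_trains || n_b > n_trains)
    stop("invalid record '", label, "': a cargo count exceeds the train count ",
         n_trains, " (at most one transport per train)")
  structure(list(label = label, n_a = n_a, n_b = n_b, n_co = n_co,
                 duration = duration, n_flagella = n_flagella,
                 train_rate = train_rate, n_trains = n_trains,
                 cargo_a = cargo_a, cargo_b = cargo_b,
                 n_trains_observed = n_trains_observed),
            class = "count_record")
}

#' @export
print.count_record <- function(x, ...) {
  cat(sprintf("count record '%s': nA = %d, nB = %d, nCo = %d over %.4g s (%d trains at %.3g/s)\n",
              x$label, x$n_a, x$n_b, x$n_co, x$duration, x$n_trains,
              x$train_rate))
  invisible(x)
}

#' Marginal probability that a train carries a cargo
#'
#' `n / (duration * train_rate)`, at full precision; display rounding is a
#' separate concern (see [round_like_paper()]).
#'
#' @param n Number of transports observed.
#' @param duration Observation time (s).
#' @param train_rate Train frequency (trains/s), default 1.
#' @return The carrying probability.
#' @examples
#' marginal_probability(243, 905)  # 0.26851
#' @export
marginal_probability <- function(n, duration, train_rate = 1.0) {
  if (any(duration <= 0)) stop("duration must be > 0")
  n_trains <- duration * train_rate
  if (any(n > round(n_trains)))
    stop("n exceeds the train count (at most one transport per train)")
  n / n_trains
}

#' Round probabilities for display
#'
#' Probabilities in the source tables are printed at two significant figures
#' (e.g. 0.0286 prints as 0.029); the worked example in the accompanying
#' methods text prints marginals at three figures using truncation
#' (243/905 = 0.26851 prints as 0.268, not 0.269).
#'
#' @param x Numeric vector of probabilities.
#' @param sig Significant figures (default 2).
#' @param method `"round"` (round half up, default) or `"truncate"`.
#' @return `x` rounded for display.
#' @examples
#' round_like_paper(0.02856)              # 0.029
#' round_like_paper(0.26851, sig = 3, method = "truncate")  # 0.268
#' @export
round_like_paper <- function(x, sig = 2, method = c("round", "truncate")) {
  method <- match.arg(method)
  out <- x
  nz <- which(is.finite(x) & x != 0)
  if (length(nz) > 0L) {
    k <- sig - 1 - floor(log10(abs(x[nz])))
    scaled <- x[nz] * 10^k
    out[nz] <- switch(method,
                      round = floor(scaled + 0.5) * 10^(-k),
                      truncate = trunc(scaled) * 10^(-k))
  }
  out
}

# Does a full-precision value reproduce a printed decimal string at the
# string's own precision? Printed tables of this kind mix round-half-up and
# truncation, so either convention is accepted.
matches_printed <- function(x, printed) {
  printed <- as.character(printed)
  dec <- ifelse(grepl("\\.", printed),
                nchar(sub("^[^.]*\\.", "", printed)), 0L)
  target <- as.numeric(printed)
  mapply(function(xi, d, tg) {
    isTRUE(all.equal(floor(xi * 10^d + 0.5) / 10^d, tg)) ||
      isTRUE(all.equal(trunc(xi * 10^d) / 10^d, tg))
  }, x, dec, target)
}

#' Test independence of two cargoes' loading onto IFT trains
#'
#' Classifies the `duration * train_rate` trains of a [count_record()] into
#' the 2x2 table (both cargoes; A only; B only; neither) and tests whether
#' cotransports occur more (or less) often than expected if the cargoes
#' attach to trains independently of each other.
#'
#' @param rec A `count_record`.
#' @param method `"fisher"` (exact test conditioning on both margins,
#'   default), `"permutation"` (cargo-A labels shuffled over trains, which
#'   conditions on the margins as well; two-sided p from the distance of
#'   `n_co` to its expectation), or `"binomial"` (`n_co` against
#'   Binomial(n_trains, pA*pB) with estimated marginals; mirrors the
#'   product-of-probabilities calculation most directly but is
#'   anti-conservative because the marginals are estimated).
#' @param n_perm Permutations for `method = "permutation"`.
#' @param alternative Alternative hypothesis for the Fisher test.
#' @param midp Use the mid-p variant of the exact test (half weight on the
#'   observed outcome's probability). The exact test is conservative on
#'   discrete data; mid-p values are approximately uniform under the null
#'   and are the right choice for calibration studies.
#' @param use_observed_trains For simulated records that carry the realized
#'   train count, condition on it instead of the `duration * train_rate`
#'   convention (exact conditional inference needs the actual number of
#'   trials; published count tables only support the convention).
#' @return The p-value, with attribute `method`.
#' @examples
#' rec <- count_record("example", 2, 2, 2, duration = 4)
#' independence_test(rec, alternative = "greater")  # 1/6
#' @export
independence_test <- function(rec,
                              method = c("fisher", "permutation", "binomial"),
                              n_perm = 10000L,
                              alternative = "two.sided",
                              midp = FALSE,
                              use_observed_trains = FALSE) {
  stopifnot(inherits(rec, "count_record"))
  method <- match.arg(method)
  N <- rec$n_trains
  if (use_observed_trains && !is.na(rec$n_trains_observed))
    N <- rec$n_trains_observed
  co <- rec$n_co
  a_only <- rec$n_a - co
  b_only <- rec$n_b - co
  neither <- N - rec$n_a - rec$n_b + co
  if (neither < 0)
    stop("inconsistent record: nA + nB - nCo exceeds the train count")
  if (rec$n_a == 0L || rec$n_b == 0L)
    return(structure(1, method = method))
  p <- switch(method,
    fisher = if (midp && alternative == "two.sided") {
      k <- 0:min(rec$n_a, rec$n_b)
      pr <- stats::dhyper(k, rec$n_a, N - rec$n_a, rec$n_b)
      po <- stats::dhyper(co, rec$n_a, N - rec$n_a, rec$n_b)
      sum(pr[pr < po * (1 - 1e-7)]) +
        0.5 * sum(pr[abs(pr - po) <= po * 1e-7])
    } else {
      stats::fisher.test(matrix(c(co, b_only, a_only, neither), 2L),
                         alternative = alternative)$p.value
    },
    permutation = {
      draws <- stats::rhyper(n_perm, rec$n_a, N - rec$n_a, rec$n_b)
      expct <- rec$n_a * rec$n_b / N
      (1 + sum(abs(draws - expct) >= abs(co - expct))) / (n_perm + 1)
    },
    binomial = {
      pp <- (rec$n_a / N) * (rec$n_b / N)
      stats::binom.test(co, N, pp, alternative = alternative)$p.value
    })
  structure(min(p, 1), method = method)
}

#' Cotransport analysis of a count record
#'
#' The central statistic: from the observed counts it computes the marginal
#' carrying probabilities `pA = nA / (T * rate)` and `pB = nB / (T * rate)`,
#' the observed cotransport probability `p_obs = nCo / (T * rate)`, and the
#' probability expected if the two cargoes load independently,
#' `p_calc = pA * pB`. An observed probability close to `p_calc` supports
#' stochastic loading of the cargoes onto any train; an observed probability
#' exceeding it by a factor 1/f supports loading restricted to an open
#' fraction f of trains. The independence hypothesis is tested with
#' [independence_test()].
#'
#' @param rec A [count_record()].
#' @param method Test method (see [independence_test()]), or `"none"`.
#' @param n_perm Permutations for the permutation test.
#' @param seed Optional seed (permutation test only).
#' @return An object of class `cotransport_test` with components `p_a`,
#'   `p_b`, `p_obs`, `p_calc`, `frac_b_with_a` (share of B transports
#'   accompanied by A; `NA` when `n_b` is 0), `frac_a_solo` (share of A
#'   transports without B), `enrichment` (`p_obs / p_calc`), `p_value` and
#'   `record`. Methods: [print()], [summary()], [coef()], [simulate()].
#' @examples
#' rec <- count_record("regenerating", 578, 130, 104, 1622)
#' fit <- cotransport_test(rec)
#' coef(fit)
#' @export
cotransport_test <- function(rec,
                             method = c("fisher", "permutation", "binomial",
                                        "none"),
                             n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(rec, "count_record"))
  method <- match.arg(method)
  denom <- rec$duration * rec$train_rate
  p_a <- rec$n_a / denom
  p_b <- rec$n_b / denom
  p_obs <- rec$n_co / denom
  p_calc <- p_a * p_b
  p_value <- NA_real_
  if (method != "none") {
    if (!is.null(seed)) set.seed(seed)
    p_value <- as.numeric(independence_test(rec, method, n_perm))
  }
  structure(
    list(p_a = p_a, p_b = p_b, p_obs = p_obs, p_calc = p_calc,
         frac_b_with_a = if (rec$n_b > 0L) rec$n_co / rec$n_b else NA_real_,
         frac_a_solo = if (rec$n_a > 0L) (rec$n_a - rec$n_co) / rec$n_a else NA_real_,
         enrichment = if (p_calc > 0) p_obs / p_calc else NA_real_,
         p_value = p_value, method = method, record = rec),
    class = "cotransport_test"
  )
}

#' @export
print.cotransport_test <- function(x, digits = 3, ...) {
  r <- x$record
  cat("\n\tIFT cargo cotransport analysis\n\n")
  cat(sprintf("data: %s (nA = %d, nB = %d, nCo = %d, %d trains)\n",
              r$label, r$n_a, r$n_b, r$n_co, r$n_trains))
  cat(sprintf("P(%s) = %.*g, P(%s) = %.*g\n",
              r$cargo_a, digits, x$p_a, r$cargo_b, digits, x$p_b))
  cat(sprintf("P(cotransport observed)   = %.*g\n", digits, x$p_obs))
  cat(sprintf("P(cotransport calculated) = %.*g  (= pA x pB, independence)\n",
              digits, x$p_calc))
  if (is.finite(x$enrichment))
    cat(sprintf("enrichment (obs/calc) = %.*g\n", digits, x$enrichment))
  if (!is.na(x$p_value))
    cat(sprintf("independence test (%s): p = %.3g\n", x$method, x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
coef.cotransport_test <- function(object, ...) {
  c(p_a = object$p_a, p_b = object$p_b, p_obs = object$p_obs,
    p_calc = object$p_calc)
}

#' @export
summary.cotransport_test <- function(object, ...) {
  r <- object$record
  out <- list(fit = object,
              expected_n_co = r$n_trains * object$p_calc,
              display = c(p_a = round_like_paper(object$p_a),
                          p_b = round_like_paper(object$p_b),
                          p_obs = round_like_paper(object$p_obs),
                          p_calc = round_like_paper(object$p_calc)))
  class(out) <- "summary.cotransport_test"
  out
}

#' @export
print.summary.cotransport_test <- function(x, ...) {
  print(x$fit)
  cat(sprintf("expected cotransports under independence: %.3g (observed %d)\n",
              x$expected_n_co, x$fit$record$n_co))
  cat("display-rounded (two significant figures): ",
      paste(names(x$display), format(x$display, trim = TRUE), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate count records under the fitted independence model
#'
#' Parametric resampling: each of the `n_trains` trains carries cargo A and
#' cargo B independently with the fitted marginal probabilities.
#'
#' @param object A [cotransport_test()] fit.
#' @param nsim Number of simulated records.
#' @param seed Optional integer seed.
#' @param ... Ignored.
#' @return A list of `count_record`s.
#' @export
simulate.cotransport_test <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- object$record
  probs <- c(object$p_a * object$p_b,
             object$p_a * (1 - object$p_b),
             (1 - object$p_a) * object$p_b,
             (1 - object$p_a) * (1 - object$p_b))
  draws <- stats::rmultinom(nsim, r$n_trains, probs)
  lapply(seq_len(nsim), function(i) {
    co <- draws[1L, i]; ao <- draws[2L, i]; bo <- draws[3L, i]
    count_record(paste0(r$label, "_sim", i), n_a = co + ao, n_b = co + bo,
                 n_co = co, duration = r$duration, train_rate = r$train_rate,
                 cargo_a = r$cargo_a, cargo_b = r$cargo_b)
  })
}

#' Power to discriminate the two loading models
#'
#' Simulates complete experiments with [simulate_traffic()] under a given
#' loading model, applies [independence_test()] to each simulated count
#' record, and reports the fraction rejecting independence at level `alpha`.
#' Under the stochastic model this fraction is the type-I error and should
#' match `alpha`; under the subclass model it is the power to detect the
#' open-train fraction `f`.
#'
#' @param p_a,p_b Marginal loading probabilities handed to the simulator.
#' @param duration Observation time per simulated experiment (s).
#' @param loading_model `"stochastic"` or `"subclass"`.
#' @param f Open-train fraction (subclass model).
#' @param alpha Test level.
#' @param n_sim Number of simulated experiments (must be >= 1).
#' @param method Test method.
#' @param train_rate Trains per second.
#' @param seed Optional integer seed.
#' @return An object of class `power_analysis`: a one-row data frame with
#'   the rejection rate and the mean observed/calculated probabilities.
#' @export
power_analysis <- function(p_a, p_b, duration, loading_model = "stochastic",
                           f = 1.0, alpha = 0.05, n_sim = 200L,
                           method = "fisher", train_rate = 1.0, seed = NULL) {
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(duration = duration, train_rate = train_rate,
                    cargoes = list(
                      cargo_spec("cargoA", p_load = p_a, two_copy_prob = 0,
                                 channel = 1L),
                      cargo_spec("cargoB", p_load = p_b, two_copy_prob = 0,
                                 channel = 2L)),
                    loading_model = loading_model, open_fraction = f,
                    subclass_saturation = "cap")
  reject <- logical(n_sim)
  p_obs <- p_calc <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    rec <- cotransport_counts(simulate_traffic(cfg))
    fit <- cotransport_test(rec, method = method)
    reject[i] <- is.finite(fit$p_value) && fit$p_value < alpha
    p_obs[i] <- fit$p_obs; p_calc[i] <- fit$p_calc
  }
  structure(data.frame(model = loading_model, f = f, p_a = p_a, p_b = p_b,
                       duration = duration, alpha = alpha, n_sim = n_sim,
                       power = mean(reject), mean_p_obs = mean(p_obs),
                       mean_p_calc = mean(p_calc)),
            class = c("power_analysis", "data.frame"))
}

#' The packaged cotransport count table
#'
#' The four published count rows (cargo pair, transports of each cargo,
#' cotransports, total observation time and number of cilia) together with
#' the probabilities as printed, shipped as a plain-text fixture.
#'
#' @param path Path to the fixture (default: the packaged copy).
#' @return A data frame with one row per strain/condition.
#' @export
table1_counts <- function(path = system.file("extdata", "table1_counts.tsv",
                                             package = "iftcargo")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("count table fixture not found")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(p_a_printed = "character",
                                   p_b_printed = "character",
                                   p_obs_printed = "character",
                                   p_calc_printed = "character"))
}

#' Recompute the published cotransport probability table
#'
#' Recomputes all derived probability columns from the packaged counts at
#' full precision and verifies that each reproduces the printed value at the
#' printed value's own precision. Marginals enter the calculated probability
#' unrounded (rounding first fails for the pair with the lowest counts).
#'
#' @param fixture Data frame from [table1_counts()], or a path to one.
#' @param strict If `TRUE` (default), any mismatching cell is an error.
#' @return A data frame with computed values, printed values and match
#'   flags; attribute `ok` is `TRUE` when all cells match.
#' @export
reproduce_table1 <- function(fixture = table1_counts(), strict = TRUE) {
  if (is.character(fixture)) fixture <- table1_counts(fixture)
  need <- c("label", "n_a", "n_b", "n_co", "duration_s",
            "p_a_printed", "p_b_printed", "p_obs_printed", "p_calc_printed")
  if (!all(need %in% names(fixture)))
    stop("fixture is missing columns: ",
         paste(setdiff(need, names(fixture)), collapse = ", "))
  rows <- lapply(seq_len(nrow(fixture)), function(i) {
    fx <- fixture[i, ]
    rec <- count_record(fx$label, fx$n_a, fx$n_b, fx$n_co, fx$duration_s)
    fit <- cotransport_test(rec, method = "none")
    data.frame(label = fx$label,
               p_a = fit$p_a, p_b = fit$p_b,
               p_obs = fit$p_obs, p_calc = fit$p_calc,
               p_a_printed = fx$p_a_printed,
               p_b_printed = fx$p_b_printed,
               p_obs_printed = fx$p_obs_printed,
               p_calc_printed = fx$p_calc_printed,
               match_p_a = matches_printed(fit$p_a, fx$p_a_printed),
               match_p_b = matches_printed(fit$p_b, fx$p_b_printed),
               match_p_obs = matches_printed(fit$p_obs, fx$p_obs_printed),
               match_p_calc = matches_printed(fit$p_calc, fx$p_calc_printed))
  })
  out <- do.call(rbind, rows)
  ok <- all(out$match_p_a & out$match_p_b & out$match_p_obs & out$match_p_calc)
  attr(out, "ok") <- ok
  if (strict && !ok)
    stop("computed probabilities do not reproduce the printed table")
  out
}
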