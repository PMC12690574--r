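# GaMD boost-potential mathematics: the harmonic boost applied below a
# potential-energy threshold, running potential statistics, and a Langevin
# double-well demonstrator of the enhanced barrier crossing the boost buys.

#' GaMD harmonic force constant
#'
#' `k = k0 / (U_max - U_min)` where `k0` in `[0, 1]` scales the boost
#' (`k0 = 1` gives the maximum boost) and `U_max`, `U_min` are the maximum
#' and minimum potential energies sampled.
#'
#' @param k0 unitless scaling in `[0, 1]`.
#' @param U_max,U_min sampled potential extrema (kcal/mol), `U_max > U_min`.
#' @return force constant in 1/(kcal/mol).
#' @export
force_constant <- function(k0, U_max, U_min) {
  if (!is.finite(k0) || k0 < 0 || k0 > 1)
    stop("k0 must lie in [0, 1]")
  if (!is.finite(U_max) || !is.finite(U_min) || U_max <= U_min)
    stop("U_max must exceed U_min")
  k0 / (U_max - U_min)
}

#' GaMD boost energy
#'
#' The harmonic boost `dU = 0.5 * k * (E - U)^2` applied only when the
#' system potential `U` lies below the threshold `E`; zero otherwise.
#'
#' @param U potential energy (kcal/mol); vectorised.
#' @param E boost threshold (kcal/mol).
#' @param k harmonic force constant, 1/(kcal/mol), `k >= 0`.
#' @return boost energy (kcal/mol), non-negative.
#' @export
boost_energy <- function(U, E, k) {
  if (!all(is.finite(U)) || !is.finite(E) || !is.finite(k))
    stop("boost_energy requires finite inputs")
  if (k < 0) stop("k must be >= 0")
  ifelse(U < E, 0.5 * k * (E - U)^2, 0)
}

#' Modified (smoothed) potential
#'
#' `U' = U + dU(U)`: the boost fills energy wells below the threshold `E`,
#' smoothing the landscape while leaving the region `U >= E` untouched.
#' Continuous (with continuous first derivative) at `U = E`.
#'
#' @inheritParams boost_energy
#' @return modified potential (kcal/mol), `U' >= U`.
#' @export
modified_potential <- function(U, E, k) {
  U + boost_energy(U, E, k)
}

#' Initialise running potential statistics
#'
#' Online (Welford) accumulator for the running maximum, minimum, mean and
#' standard deviation of the potential energy, updated once per sample as a
#' GaMD preparation phase would.
#'
#' @param window nominal averaging window in steps (`ntave`); bookkeeping
#'   only.
#' @return list of class `fd_potential_stats`.
#' @export
potential_stats <- function(window = NA_integer_) {
  structure(list(window = window, n_samples = 0L, U_mean = NA_real_,
                 m2 = 0, U_min = Inf, U_max = -Inf, U_sd = NA_real_),
            class = "fd_potential_stats")
}

#' Update running potential statistics with one sample
#'
#' @param stats an [potential_stats()] accumulator.
#' @param U_sample potential-energy sample (kcal/mol).
#' @return the updated accumulator; `U_sd` is `NA` until two samples exist.
#' @export
update_stats <- function(stats, U_sample) {
  if (!is.finite(U_sample)) stop("sample must be finite")
  n <- stats$n_samples + 1L
  if (n == 1L) {
    stats$U_mean <- U_sample
    stats$m2 <- 0
  } else {
    delta <- U_sample - stats$U_mean
    stats$U_mean <- stats$U_mean + delta / n
    stats$m2 <- stats$m2 + delta * (U_sample - stats$U_mean)
  }
  stats$n_samples <- n
  stats$U_min <- min(stats$U_min, U_sample)
  stats$U_max <- max(stats$U_max, U_sample)
  stats$U_sd <- if (n >= 2L) sqrt(stats$m2 / (n - 1L)) else NA_real_
  stats
}

# double-well potential and force
dw_potential <- function(x, h) h * (x^2 - 1)^2
dw_force <- function(x, h) -4 * h * x * (x^2 - 1)

# hysteresis-band crossing counter: a crossing is counted each time x moves
# from beyond -band to beyond +band or vice versa
count_crossings <- function(x, band = 0.25) {
  state <- 0L   # -1 left, +1 right, 0 unset
  n <- 0L
  sides <- ifelse(x <= -band, -1L, ifelse(x >= band, 1L, 0L))
  sides <- sides[sides != 0L]
  if (!length(sides)) return(0L)
  state <- sides[1]
  flips <- sides[c(TRUE, diff(sides) != 0L)]
  length(flips) - 1L
}

#' Langevin double-well demonstrator of GaMD barrier-crossing enhancement
#'
#' Overdamped Euler-Maruyama dynamics on the quartic double well
#' `U(x) = h (x^2 - 1)^2` (barrier height `h` at `x = 0`, minima at
#' `x = +/-1`). A preparation phase runs without boost while collecting
#' running potential statistics; the production phase then applies the GaMD
#' modified-potential force with `E = U_max` (lower-bound threshold rule)
#' and `k` from [force_constant()]. An unboosted production run with the
#' identical random stream is produced for comparison; with `k0 = 0` the two
#' runs are identical step for step.
#'
#' @param barrier_height barrier `h` in kcal/mol.
#' @param k0 boost scaling in `[0, 1]`.
#' @param n_steps production steps.
#' @param temperature thermal energy kT (kcal/mol).
#' @param seed RNG seed; the run is fully reproducible.
#' @param dt time step (friction and mass absorbed); default `0.08 / h`,
#'   which keeps the Euler scheme stable against the quartic's curvature.
#' @param n_prep preparation steps (default `max(2000, n_steps / 5)`).
#' @param band hysteresis half-width for crossing counting.
#' @param x0 initial position.
#' @param keep_traj store the position series.
#' @return list with crossing counts for the boosted and unboosted
#'   production phases, the boost parameters used (`E`, `k`, `U_max`,
#'   `U_min`), and (optionally) the `x` series of both runs.
#' @export
langevin_double_well_demo <- function(barrier_height, k0 = 1, n_steps = 2e5,
                                      temperature = 0.6, seed = 1,
                                      dt = NULL, n_prep = NULL, band = 0.25,
                                      x0 = -1, keep_traj = FALSE) {
  if (!is.finite(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (temperature <= 0) stop("temperature must be > 0")
  if (k0 < 0 || k0 > 1) stop("k0 must lie in [0, 1]")
  h <- barrier_height
  if (is.null(dt)) dt <- 0.08 / h
  if (is.null(n_prep)) n_prep <- max(2000L, as.integer(n_steps %/% 5))
  sig <- sqrt(2 * temperature * dt)

  run <- function(apply_boost) {
    set.seed(seed)
    noise_prep <- stats::rnorm(n_prep)
    noise_prod <- stats::rnorm(n_steps)
    x <- x0
    st <- potential_stats(window = n_prep)
    for (i in seq_len(n_prep)) {
      st <- update_stats(st, dw_potential(x, h))
      x <- x + dt * dw_force(x, h) + sig * noise_prep[i]
    }
    k <- if (apply_boost && k0 > 0)
      force_constant(k0, st$U_max, st$U_min) else 0
    E <- st$U_max
    xs <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      f <- dw_force(x, h)
      if (k > 0) {
        U <- dw_potential(x, h)
        if (U < E) f <- f * (1 - k * (E - U))
      }
      x <- x + dt * f + sig * noise_prod[i]
      xs[i] <- x
    }
    list(x = xs, k = k, E = E, stats = st)
  }

  boosted <- run(TRUE)
  plain <- run(FALSE)
  out <- list(
    crossings_boosted = count_crossings(boosted$x, band),
    crossings_unboosted = count_crossings(plain$x, band),
    k = boosted$k, E = boosted$E,
    U_max = boosted$stats$U_max, U_min = boosted$stats$U_min,
    dt = dt, n_prep = n_prep
  )
  if (keep_traj) {
    out$x_boosted <- boosted$x
    out$x_unboosted <- plain$x
  }
  out
}
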