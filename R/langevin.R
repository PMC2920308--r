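#' Chemical-Langevin drift and noise amplitudes
#'
#' Continuum (diffusion) approximation of the network: each reaction
#' channel with mass-action rate `r` contributes drift `-r` to the inactive
#' abundance of its substrate and an independent Gaussian noise term of
#' amplitude `sqrt(r)`. With rates
#' `r_A = k_a * x0 * y3`, `r_B1 = k_b1 * x0 * y1`,
#' `r_B2 = k_b2 * (x1_total - y1) * y2`, `r_B3 = k_b3 * (x2_total - y2) * y3`,
#' the inactive abundances `(y1, y2, y3)` obey
#' `dy1 = -r_B1 dt + sqrt(r_B1) dW_B1`, `dy2 = -r_B2 dt + sqrt(r_B2) dW_B2`,
#' `dy3 = -(r_A + r_B3) dt + sqrt(r_A) dW_A + sqrt(r_B3) dW_B3`
#' (Ito interpretation, one independent Brownian motion per channel).
#' Active abundances are `total - inactive` by conservation.
#'
#' The relative noise on a channel is `1/sqrt(r)`, so a small rate constant
#' keeps the noise term at order one even when copy numbers are large —
#' stochasticity here is generated by slow kinetics, not by small numbers.
#'
#' Negative rates arising from out-of-bounds states are clamped to zero
#' before evaluation.
#'
#' @param state A list with inactive abundances `y1`, `y2`, `y3`.
#' @param params A [network_params()] object with finite `x0`.
#' @return A list with `drift` (named length-3 vector over `y1, y2, y3`)
#'   and `diffusion`, a 3 x 4 matrix of noise amplitudes (rows `y1, y2,
#'   y3`; columns channels `A, B1, B2, B3`).
#' @export
drift_diffusion <- function(state, params) {
  if (is.na(params$x0)) stop("x0 is unset", call. = FALSE)
  y1 <- max(state$y1, 0); y2 <- max(state$y2, 0); y3 <- max(state$y3, 0)
  r <- c(A  = params$k_a  * params$x0 * y3,
         B1 = params$k_b1 * params$x0 * y1,
         B2 = params$k_b2 * max(params$x1_total - y1, 0) * y2,
         B3 = params$k_b3 * max(params$x2_total - y2, 0) * y3)
  r <- pmax(r, 0)
  drift <- c(y1 = -r[["B1"]], y2 = -r[["B2"]], y3 = -(r[["A"]] + r[["B3"]]))
  diffusion <- matrix(0, nrow = 3, ncol = 4,
                      dimnames = list(c("y1", "y2", "y3"),
                                      c("A", "B1", "B2", "B3")))
  diffusion["y1", "B1"] <- sqrt(r[["B1"]])
  diffusion["y2", "B2"] <- sqrt(r[["B2"]])
  diffusion["y3", "A"]  <- sqrt(r[["A"]])
  diffusion["y3", "B3"] <- sqrt(r[["B3"]])
  list(drift = drift, diffusion = diffusion)
}

#' Integrator configuration for the chemical-Langevin engine
#'
#' @param t_max Integration horizon.
#' @param dt Euler-Maruyama step size; `NULL` chooses
#'   `0.01 / (k_b3 * max(totals))`, well below the fast final-step
#'   timescale at full activation.
#' @param record_times Output grid (default `n_records` evenly spaced
#'   points on `[0, t_max]`).
#' @param n_records Number of evenly spaced records when `record_times` is
#'   `NULL`.
#' @param seed Integer seed (`NULL` = continue the current stream).
#' @param noise If `FALSE`, the diffusion terms are switched off and the
#'   integrator reduces to deterministic Euler (mean-field dynamics).
#' @return A list of class `integrator_config`.
#' @export
integrator_config <- function(t_max, dt = NULL, record_times = NULL,
                              n_records = 101, seed = NULL, noise = TRUE) {
  if (!is.numeric(t_max) || length(t_max) != 1 || t_max <= 0) {
    stop("t_max must be a positive number", call. = FALSE)
  }
  if (!is.null(dt) && (!is.numeric(dt) || length(dt) != 1 || dt <= 0)) {
    stop("dt must be a positive number", call. = FALSE)
  }
  if (is.null(record_times)) {
    record_times <- seq(0, t_max, length.out = n_records)
  }
  check_record_times(record_times, t_max)
  structure(list(t_max = t_max, dt = dt,
                 record_times = as.numeric(record_times),
                 seed = seed, noise = isTRUE(noise)),
            class = "integrator_config")
}

default_dt <- function(params) {
  h <- params$k_b3 * max(params$x1_total, params$x2_total, params$x3_total)
  if (h <= 0) {
    h <- max(params$k_a * params$x0, params$k_b2 * params$x1_total, 1e-8,
             na.rm = TRUE)
  }
  0.01 / h
}

# Vectorized Euler-Maruyama over n_paths independent realizations.
# Clamps each inactive abundance to [0, total] after every step (reflecting
# boundary; conservation then holds by construction). The very fast entry
# channel B1 may overshoot within one step under strong stimuli; the clamp
# pins y1 to its absorbing limit 0, which is also the exact limit behavior.
em_core <- function(params, n_paths, dt, t_max, record_times, noise) {
  y1 <- rep(params$x1_total, n_paths)
  y2 <- rep(params$x2_total, n_paths)
  y3 <- rep(params$x3_total, n_paths)
  n_rec <- length(record_times)
  Y1 <- matrix(NA_real_, n_paths, n_rec)
  Y2 <- matrix(NA_real_, n_paths, n_rec)
  Y3 <- matrix(NA_real_, n_paths, n_rec)
  gi <- 1
  while (gi <= n_rec && record_times[gi] <= 0) {
    Y1[, gi] <- y1; Y2[, gi] <- y2; Y3[, gi] <- y3
    gi <- gi + 1
  }
  n_steps <- ceiling(t_max / dt - 1e-9)
  sq_dt <- sqrt(dt)
  x0 <- params$x0
  for (s in seq_len(n_steps)) {
    rA  <- pmax(params$k_a  * x0 * y3, 0)
    rB1 <- pmax(params$k_b1 * x0 * y1, 0)
    rB2 <- pmax(params$k_b2 * (params$x1_total - y1) * y2, 0)
    rB3 <- pmax(params$k_b3 * (params$x2_total - y2) * y3, 0)
    if (noise) {
      y1 <- y1 - rB1 * dt + sqrt(rB1) * stats::rnorm(n_paths, sd = sq_dt)
      y2 <- y2 - rB2 * dt + sqrt(rB2) * stats::rnorm(n_paths, sd = sq_dt)
      y3 <- y3 - (rA + rB3) * dt +
        sqrt(rA) * stats::rnorm(n_paths, sd = sq_dt) +
        sqrt(rB3) * stats::rnorm(n_paths, sd = sq_dt)
    } else {
      y1 <- y1 - rB1 * dt
      y2 <- y2 - rB2 * dt
      y3 <- y3 - (rA + rB3) * dt
    }
    y1 <- pmin(pmax(y1, 0), params$x1_total)
    y2 <- pmin(pmax(y2, 0), params$x2_total)
    y3 <- pmin(pmax(y3, 0), params$x3_total)
    t_now <- s * dt
    while (gi <= n_rec && record_times[gi] <= t_now + 1e-12) {
      Y1[, gi] <- y1; Y2[, gi] <- y2; Y3[, gi] <- y3
      gi <- gi + 1
    }
  }
  while (gi <= n_rec) {  # grid points beyond the last full step
    Y1[, gi] <- y1; Y2[, gi] <- y2; Y3[, gi] <- y3
    gi <- gi + 1
  }
  list(y1 = Y1, y2 = Y2, y3 = Y3)
}

cle_states_df <- function(params, record_times, y1, y2, y3) {
  data.frame(time = record_times,
             x1 = y1, x1a = params$x1_total - y1,
             x2 = y2, x2a = params$x2_total - y2,
             x3 = y3, x3a = params$x3_total - y3,
             fireA = NA_real_, fireB1 = NA_real_,
             fireB2 = NA_real_, fireB3 = NA_real_)
}

#' Integrate the chemical-Langevin equations (Euler-Maruyama)
#'
#' Explicit Euler-Maruyama integration of the coupled Langevin equations of
#' [drift_diffusion()], with independent Gaussian increments per reaction
#' channel and reflecting clamps to `[0, total]` after each step. The same
#' seed reproduces the identical path.
#'
#' @param params A [network_params()] object with finite `x0`.
#' @param config An [integrator_config()].
#' @param cell_id Identifier stored with the trajectory.
#' @return A `trajectory` object with `engine = "cle"`; the `states` data
#'   frame uses the same columns as the SSA engine (continuous abundances;
#'   the firing counters are `NA`, since a diffusion path has no discrete
#'   events to attribute).
#' @examples
#' p <- network_preset("weak")
#' cfg <- integrator_config(t_max = 200, dt = 0.01, seed = 1)
#' tr <- euler_maruyama_simulate(p, cfg)
#' @export
euler_maruyama_simulate <- function(params, config, cell_id = 0L) {
  ens <- cle_population(params, n_cells = 1L, config = config)
  tr <- ens$trajectories[[1]]
  tr$cell_id <- cell_id
  tr
}

#' Population of chemical-Langevin paths
#'
#' Vectorized Euler-Maruyama integration of `n_cells` independent
#' realizations (one shared RNG stream seeded by `config$seed`).
#'
#' @inheritParams euler_maruyama_simulate
#' @param n_cells Number of independent paths.
#' @return An `ensemble` object with `engine = "cle"`, interchangeable with
#'   SSA ensembles in the analysis functions (except pathway attribution,
#'   which needs discrete firing counters).
#' @export
cle_population <- function(params, n_cells, config) {
  rep_ <- validate_parameters(params)
  if (length(rep_$errors) > 0) {
    stop("invalid parameters: ", paste(rep_$errors, collapse = "; "),
         call. = FALSE)
  }
  if (is.na(params$x0)) stop("x0 is unset", call. = FALSE)
  if (!inherits(config, "integrator_config")) {
    stop("config must be an integrator_config", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  dt <- if (is.null(config$dt)) default_dt(params) else config$dt
  h_slowest <- max(params$k_a * params$x0, params$k_b2 * params$x1_total,
                   params$k_b3 * params$x2_total)
  if (is.finite(h_slowest) && h_slowest > 0 && dt * h_slowest > 0.1) {
    warning(sprintf(
      "dt = %g is not small against the fastest deterministic timescale %g",
      dt, 1 / h_slowest), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  paths <- em_core(params, n_cells, dt, config$t_max, config$record_times,
                   config$noise)
  trajectories <- lapply(seq_len(n_cells) - 1L, function(i) {
    structure(list(cell_id = i,
                   seed = NA_integer_,
                   engine = "cle",
                   params = params,
                   states = cle_states_df(params, config$record_times,
                                          paths$y1[i + 1, ], paths$y2[i + 1, ],
                                          paths$y3[i + 1, ])),
              class = "trajectory")
  })
  structure(list(params = params,
                 master_seed = if (is.null(config$seed)) NA_integer_
                               else as.integer(config$seed),
                 engine = "cle",
                 record_times = config$record_times,
                 trajectories = trajectories),
            class = "ensemble")
}

#' Analytic one-step Langevin paths via the square-root transformation
#'
#' The isolated one-step reaction obeys
#' `dx = -k_eff x dt + sqrt(k_eff x) dW` with `k_eff = k * x0` for the
#' inactive abundance `x`. The substitution `u = sqrt(x)` linearizes the
#' noise: dropping the small Ito correction (`k_eff / (8 u)`, relatively
#' `1/(4x)` of the drift), `u` follows the Ornstein-Uhlenbeck equation
#' `du = -(k_eff / 2) u dt + (sqrt(k_eff) / 2) dW`, whose transition over a
#' grid increment `d` is exactly Gaussian with mean `u exp(-k_eff d / 2)`
#' and variance `(1 - exp(-k_eff d)) / 4`. Paths are sampled exactly on the
#' grid from that transition; `u` is absorbed at 0 (the reaction has
#' completed) and the inactive abundance returned is `u^2`. Agreement with
#' the full nonlinear Euler-Maruyama integration is monitored in the test
#' suite rather than assumed.
#'
#' @param k Rate constant of the one-step reaction.
#' @param x0 Stimulus copy number (`k_eff = k * x0`).
#' @param x_init Initial inactive abundance (> 0).
#' @param t_grid Nondecreasing, nonnegative, nonempty time grid.
#' @param seed Integer seed (`NULL` = continue the current stream).
#' @param n_paths Number of independent paths.
#' @return Numeric matrix of inactive abundances, `n_paths` rows and one
#'   column per grid time. Activated abundance is `x_init - value`.
#' @examples
#' x <- one_step_analytic_path(0.1, 1, 100, t_grid = c(0, 5, 10),
#'                             seed = 1, n_paths = 3)
#' @export
one_step_analytic_path <- function(k, x0, x_init, t_grid, seed = NULL,
                                   n_paths = 1L) {
  stopifnot(k >= 0, x0 >= 0)
  if (!is.numeric(x_init) || length(x_init) != 1 || x_init <= 0) {
    stop("x_init must be positive", call. = FALSE)
  }
  if (length(t_grid) == 0) stop("t_grid must be nonempty", call. = FALSE)
  if (anyNA(t_grid) || any(t_grid < 0) || is.unsorted(t_grid)) {
    stop("t_grid must be nondecreasing and nonnegative", call. = FALSE)
  }
  n_paths <- as.integer(n_paths)
  if (!is.null(seed)) set.seed(seed)
  k_eff <- k * x0
  out <- matrix(NA_real_, n_paths, length(t_grid))
  if (k_eff == 0) {
    out[] <- x_init
    return(out)
  }
  u <- rep(sqrt(x_init), n_paths)
  absorbed <- rep(FALSE, n_paths)
  t_prev <- 0
  for (g in seq_along(t_grid)) {
    d <- t_grid[g] - t_prev
    if (d > 0) {
      sd_g <- sqrt((1 - exp(-k_eff * d)) / 4)
      u <- u * exp(-k_eff * d / 2) + stats::rnorm(n_paths, sd = sd_g)
      absorbed <- absorbed | u <= 0
      u[absorbed] <- 0
    }
    out[, g] <- u^2
    t_prev <- t_grid[g]
  }
  out
}

#' Deterministic mean-field activation of the pure type A network
#'
#' Ignoring the type B channels and all noise, the inactive X3 pool decays
#' exponentially at per-copy hazard `k_a * x0`, so
#' `x3a(t) = x3_total * (1 - exp(-k_a * x0 * t))` with half-activation time
#' `log(2) / (k_a * x0)`.
#'
#' @param params A [network_params()] object with finite `x0`.
#' @param t_grid Numeric vector of times.
#' @return A data.frame with columns `time` and `x3a`.
#' @export
mean_field_solution <- function(params, t_grid) {
  if (is.na(params$x0)) stop("x0 is unset", call. = FALSE)
  data.frame(time = as.numeric(t_grid),
             x3a = params$x3_total *
               (1 - exp(-params$k_a * params$x0 * as.numeric(t_grid))))
}
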