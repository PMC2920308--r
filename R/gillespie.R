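#' Initial system state
#'
#' All species start fully inactive and all channel firing counters at zero.
#'
#' @param params A [network_params()] object.
#' @param t Starting time (default 0).
#' @return A named list of class `system_state` with fields `t`, `x1`,
#'   `x1a`, `x2`, `x2a`, `x3`, `x3a`, `fireA`, `fireB1`, `fireB2`,
#'   `fireB3`.
#' @export
initial_state <- function(params, t = 0) {
  structure(list(t = t,
                 x1 = params$x1_total, x1a = 0,
                 x2 = params$x2_total, x2a = 0,
                 x3 = params$x3_total, x3a = 0,
                 fireA = 0, fireB1 = 0, fireB2 = 0, fireB3 = 0),
            class = "system_state")
}

#' Reaction propensities
#'
#' Mass-action firing rates of the four channels at a given state, in the
#' fixed order A, B1, B2, B3:
#' `a_A = k_a * x0 * x3`, `a_B1 = k_b1 * x0 * x1`,
#' `a_B2 = k_b2 * x1a * x2`, `a_B3 = k_b3 * x2a * x3`.
#' Zero counts give zero propensity; no propensity is ever negative.
#'
#' @param state A `system_state` (or any list with the count fields).
#' @param params A [network_params()] object with finite `x0`.
#' @return Named numeric vector `c(A=, B1=, B2=, B3=)`.
#' @examples
#' p <- network_params(x0 = 100)
#' propensities(initial_state(p), p)  # A = 1e-5*100*100 = 0.1
#' @export
propensities <- function(state, params) {
  if (is.na(params$x0)) stop("x0 is unset", call. = FALSE)
  c(A  = params$k_a  * params$x0  * state$x3,
    B1 = params$k_b1 * params$x0  * state$x1,
    B2 = params$k_b2 * state$x1a * state$x2,
    B3 = params$k_b3 * state$x2a * state$x3)
}

#' One exact Gillespie step
#'
#' Draws the waiting time to the next reaction (exponential with rate equal
#' to the total propensity) and the identity of the firing channel
#' (probability proportional to its propensity), then applies the channel's
#' update. Uses R's global RNG stream; wrap with [set.seed()] for
#' reproducibility.
#'
#' @param state Current `system_state`.
#' @param params A [network_params()] object.
#' @return A list `(tau, channel, state)`. In an absorbing state (total
#'   propensity zero) `tau` is `Inf`, `channel` is `NA` and the state is
#'   returned unchanged.
#' @export
ssa_step <- function(state, params) {
  a <- propensities(state, params)
  a0 <- sum(a)
  if (a0 <= 0) {
    return(list(tau = Inf, channel = NA_character_, state = state))
  }
  tau <- stats::rexp(1, rate = a0)
  u <- stats::runif(1) * a0
  ch <- if (u < a[["A"]]) "A"
        else if (u < a[["A"]] + a[["B1"]]) "B1"
        else if (u < a[["A"]] + a[["B1"]] + a[["B2"]]) "B2"
        else "B3"
  s <- state
  s$t <- state$t + tau
  if (ch == "A")  { s$x3 <- s$x3 - 1; s$x3a <- s$x3a + 1; s$fireA  <- s$fireA  + 1 }
  if (ch == "B1") { s$x1 <- s$x1 - 1; s$x1a <- s$x1a + 1; s$fireB1 <- s$fireB1 + 1 }
  if (ch == "B2") { s$x2 <- s$x2 - 1; s$x2a <- s$x2a + 1; s$fireB2 <- s$fireB2 + 1 }
  if (ch == "B3") { s$x3 <- s$x3 - 1; s$x3a <- s$x3a + 1; s$fireB3 <- s$fireB3 + 1 }
  list(tau = tau, channel = ch, state = s)
}

# Per-cell seed derived from the master seed by a fixed affine mixing map,
# so cell i is reproducible in isolation and independent of simulation order.
#' Derive the RNG seed for one cell of a population
#'
#' @param master_seed Integer master seed of the ensemble.
#' @param cell_id Zero-based cell index.
#' @return An integer seed: `(master_seed + 1000003 * (cell_id + 1)) mod
#'   (2^31 - 1)`.
#' @export
cell_seed <- function(master_seed, cell_id) {
  as.integer((as.numeric(master_seed) + 1000003 * (as.numeric(cell_id) + 1)) %%
               2147483647)
}

check_record_times <- function(record_times, t_max) {
  if (!is.numeric(record_times) || length(record_times) < 1 ||
      anyNA(record_times)) {
    stop("record_times must be a numeric vector without NAs", call. = FALSE)
  }
  if (is.unsorted(record_times, strictly = TRUE)) {
    stop("record_times must be strictly increasing", call. = FALSE)
  }
  if (min(record_times) < 0 || max(record_times) > t_max) {
    stop("record_times must lie within [0, t_max]", call. = FALSE)
  }
  record_times
}

#' Simulate a single cell with the exact Gillespie algorithm
#'
#' Runs the direct-method SSA from the fully inactive initial state to
#' `t_max` and samples the jump process piecewise-constantly onto
#' `record_times`: the state reported at grid time `tau` is the state just
#' after the last event with event time `<= tau`. Once all substrates are
#' exhausted (total propensity 0) the absorbing state is copied to the
#' remaining grid points. The same seed always reproduces the identical
#' trajectory.
#'
#' @param params A [network_params()] object with finite `x0`.
#' @param t_max Simulation horizon.
#' @param record_times Strictly increasing grid within `[0, t_max]`;
#'   default 101 evenly spaced points.
#' @param seed Integer seed for this cell (`NULL` = continue the current
#'   RNG stream).
#' @param cell_id Identifier stored with the trajectory.
#' @return A `trajectory` object: list with `cell_id`, `seed`, `engine`
#'   (`"ssa"`), `params`, and `states`, a data.frame with columns
#'   `time, x1, x1a, x2, x2a, x3, x3a, fireA, fireB1, fireB2, fireB3`.
#' @examples
#' p <- network_preset("weak")
#' tr <- simulate_cell(p, t_max = 500, seed = 1)
#' tail(tr$states[, c("time", "x3a")])
#' @export
simulate_cell <- function(params, t_max, record_times = NULL, seed = NULL,
                          cell_id = 0L) {
  rep_ <- validate_parameters(params)
  if (length(rep_$errors) > 0) {
    stop("invalid parameters: ", paste(rep_$errors, collapse = "; "),
         call. = FALSE)
  }
  if (is.na(params$x0)) stop("x0 is unset", call. = FALSE)
  if (!is.numeric(t_max) || length(t_max) != 1 || !is.finite(t_max) ||
      t_max <= 0) {
    stop("t_max must be a positive number", call. = FALSE)
  }
  if (is.null(record_times)) {
    record_times <- seq(0, t_max, length.out = 101)
  }
  check_record_times(record_times, t_max)
  if (!is.null(seed)) set.seed(seed)
  m <- ssa_core(params$x0,
                params$x1_total, params$x2_total, params$x3_total,
                params$k_a, params$k_b1, params$k_b2, params$k_b3,
                as.numeric(record_times), t_max)
  states <- as.data.frame(m)
  names(states) <- state_cols
  structure(list(cell_id = cell_id,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 engine = "ssa",
                 params = params,
                 states = states),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> cell %s, engine %s, %d records on [%g, %g], final x3a = %g\n",
              format(x$cell_id), x$engine, nrow(x$states),
              min(x$states$time), max(x$states$time),
              x$states$x3a[nrow(x$states)]))
  invisible(x)
}

#' Simulate an in-silico cell population
#'
#' Simulates `n_cells` statistically independent cells sharing one
#' parameter set and record grid. Cell `i` (zero-based) uses the seed
#' [cell_seed()]`(master_seed, i)`, so any single cell can be re-simulated
#' in isolation and the ensemble does not depend on simulation order.
#'
#' @inheritParams simulate_cell
#' @param n_cells Number of cells (>= 1).
#' @param master_seed Integer seed of the whole population.
#' @return An `ensemble` object: list with `params`, `master_seed`,
#'   `engine`, `record_times`, and `trajectories` (a list of `trajectory`
#'   objects with `cell_id` 0..n-1).
#' @examples
#' ens <- simulate_population(network_preset("weak"), n_cells = 20,
#'                            t_max = 1000, master_seed = 1)
#' ens
#' @export
simulate_population <- function(params, n_cells, t_max, record_times = NULL,
                                master_seed = 1L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
    stop("n_cells must be a positive integer", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (is.null(record_times)) {
    record_times <- seq(0, t_max, length.out = 101)
  }
  trajectories <- lapply(seq_len(n_cells) - 1L, function(i) {
    simulate_cell(params, t_max, record_times,
                  seed = cell_seed(master_seed, i), cell_id = i)
  })
  structure(list(params = params,
                 master_seed = as.integer(master_seed),
                 engine = "ssa",
                 record_times = as.numeric(record_times),
                 trajectories = trajectories),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d cells, engine %s, %d records on [%g, %g], master seed %s\n",
              length(x$trajectories), x$engine, length(x$record_times),
              min(x$record_times), max(x$record_times),
              format(x$master_seed)))
  invisible(x)
}

#' Exact activated-count distribution for the one-step subnetwork
#'
#' For the isolated one-step reaction (a single substrate pool activated by
#' the constant catalytic stimulus at per-copy hazard `k * x0`), the master
#' equation solves in closed form: each copy converts independently, so the
#' number activated by time `t` is Binomial(`n_total`,
#' `1 - exp(-k * x0 * t)`). This is the exact oracle used to validate the
#' stochastic simulator.
#'
#' @param k Rate constant of the one-step reaction.
#' @param x0 Stimulus copy number.
#' @param n_total Substrate pool size.
#' @param t Time.
#' @return Numeric probability vector over activated counts `0..n_total`
#'   (sums to 1).
#' @examples
#' one_step_exact_distribution(0.1, 1, 3, log(2) / 0.1)
#' # 0.125 0.375 0.375 0.125
#' @export
one_step_exact_distribution <- function(k, x0, n_total, t) {
  stopifnot(k >= 0, x0 >= 0, t >= 0, n_total >= 0)
  p <- 1 - exp(-k * x0 * t)
  stats::dbinom(0:n_total, size = n_total, prob = p)
}
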