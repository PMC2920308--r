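#' Parameter set for the minimal two-pathway signaling network
#'
#' The network couples two activation routes for a shared downstream species
#' X3. The *type A* pathway activates X3 directly from the stimulus in one
#' step (rate constant `k_a`). The *type B* pathway is a fast-slow-fast
#' cascade: the stimulus rapidly activates X1 (`k_b1`), activated X1 slowly
#' activates X2 (`k_b2`), and activated X2 rapidly activates X3 (`k_b3`).
#' All reactions are irreversible, mass-action, and catalytic in the
#' activator (the activator is never consumed); the stimulus copy number
#' `x0` is constant in time. Per species, inactive + active copies are
#' conserved.
#'
#' Units are dimensionless: copy numbers are counts, rate constants are per
#' activator-copy per substrate-copy per unit simulation time.
#'
#' @param x0 Stimulus copy number (real, >= 0). May be `NA` for a parameter
#'   set whose stimulus is to be supplied later (the engines require a
#'   finite value).
#' @param x1_total,x2_total,x3_total Initial inactive copy numbers of
#'   species X1, X2, X3 (nonnegative integers). All active counts start
#'   at zero.
#' @param k_a Rate constant of the one-step (type A) pathway.
#' @param k_b1 Rate constant of the first, fast step of the type B pathway
#'   (stimulus activates X1). Intended to exceed `k_a` so that the
#'   stochastic pathway engages preferentially under weak stimuli.
#' @param k_b2 Rate constant of the slow intermediate step (activated X1
#'   activates X2). This is the rate-limiting step that generates slow,
#'   noisy activation; it should be far below `k_b3`.
#' @param k_b3 Rate constant of the final, fast step (activated X2
#'   activates X3).
#'
#' @return An object of class `network_params`: a named list with the eight
#'   fields above.
#'
#' @seealso [validate_parameters()] for the full validation report,
#'   [network_preset()] for ready-made parameter sets,
#'   [classify_regime_analytic()] for the signaling-regime classifier.
#'
#' @examples
#' p <- network_params(x0 = 50)
#' p
#' classify_regime_analytic(p)
#' @export
network_params <- function(x0 = NA_real_,
                           x1_total = 100, x2_total = 100, x3_total = 100,
                           k_a = 1e-5, k_b1 = 1.0, k_b2 = 1e-4, k_b3 = 1.0) {
  p <- structure(
    list(x0 = as.numeric(x0),
         x1_total = as.numeric(x1_total),
         x2_total = as.numeric(x2_total),
         x3_total = as.numeric(x3_total),
         k_a = as.numeric(k_a), k_b1 = as.numeric(k_b1),
         k_b2 = as.numeric(k_b2), k_b3 = as.numeric(k_b3)),
    class = "network_params")
  rep_ <- validate_parameters(p)
  if (length(rep_$errors) > 0) {
    stop("invalid network parameters:\n  ",
         paste(rep_$errors, collapse = "\n  "), call. = FALSE)
  }
  p
}

#' @export
print.network_params <- function(x, ...) {
  cat("Minimal signaling network parameters\n")
  cat(sprintf("  stimulus x0       : %s\n",
              if (is.na(x$x0)) "(unset)" else format(x$x0)))
  cat(sprintf("  totals x1/x2/x3   : %g / %g / %g\n",
              x$x1_total, x$x2_total, x$x3_total))
  cat(sprintf("  type A    k_a     : %g\n", x$k_a))
  cat(sprintf("  type B    k_b1    : %g (fast)\n", x$k_b1))
  cat(sprintf("            k_b2    : %g (slow)\n", x$k_b2))
  cat(sprintf("            k_b3    : %g (fast)\n", x$k_b3))
  if (!is.na(x$x0)) {
    cl <- classify_regime_analytic(x)
    cat(sprintf("  analytic regime   : %s\n", cl$label))
  }
  invisible(x)
}

#' Validate a network parameter set
#'
#' Checks hard constraints (errors) and the structural rate-constant
#' ordering of the minimal network (warnings). Errors: any negative field,
#' non-integer copy-number totals, non-finite rate constants. Warnings flag
#' parameter sets that are numerically legal but break the fast-slow-fast
#' design: the slow intermediate constant should be well below the final
#' fast constant (`k_b2 < k_b3 / 10`), and the type B entry step should be
#' faster than the type A step (`k_b1 > k_a`).
#'
#' Nothing is thrown; findings are returned for the caller to act on.
#'
#' @param params A [network_params()] object (or a bare named list with the
#'   same fields).
#' @return A list of class `param_validation` with character vectors
#'   `errors` and `warnings`, each entry naming the violated relation.
#' @examples
#' validate_parameters(network_params(x0 = 50))           # clean
#' validate_parameters(list(x0 = 50, x1_total = 100, x2_total = 100,
#'   x3_total = 100, k_a = 1e-5, k_b1 = 1, k_b2 = 1, k_b3 = 1))
#' @export
validate_parameters <- function(params) {
  errors <- character()
  warnings <- character()
  num_fields <- c("x0", "x1_total", "x2_total", "x3_total",
                  "k_a", "k_b1", "k_b2", "k_b3")
  missing <- setdiff(num_fields, names(params))
  if (length(missing) > 0) {
    errors <- c(errors, paste0("missing field(s): ",
                               paste(missing, collapse = ", ")))
    return(structure(list(errors = errors, warnings = warnings),
                     class = "param_validation"))
  }
  for (f in num_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1) {
      errors <- c(errors, paste0(f, " must be a numeric scalar"))
      next
    }
    if (f == "x0" && is.na(v)) next  # stimulus may be deferred
    if (!is.finite(v)) {
      errors <- c(errors, paste0(f, " must be finite"))
    } else if (v < 0) {
      errors <- c(errors, paste0("negative ",
                                 if (grepl("^k", f)) "rate constant " else "count ",
                                 f, " = ", format(v)))
    }
  }
  for (f in c("x1_total", "x2_total", "x3_total")) {
    v <- params[[f]]
    if (is.numeric(v) && length(v) == 1 && is.finite(v) &&
        abs(v - round(v)) > 1e-8) {
      errors <- c(errors, paste0(f, " must be a nonnegative integer, got ",
                                 format(v)))
    }
  }
  if (length(errors) == 0) {
    if (params$k_b2 >= params$k_b3 / 10) {
      warnings <- c(warnings, sprintf(
        "slow-fast ordering violated: k_b2 = %g is not well below k_b3 = %g (want k_b2 < k_b3/10)",
        params$k_b2, params$k_b3))
    }
    if (params$k_b1 <= params$k_a) {
      warnings <- c(warnings, sprintf(
        "type B entry step not faster than type A: k_b1 = %g <= k_a = %g",
        params$k_b1, params$k_a))
    }
  }
  structure(list(errors = errors, warnings = warnings),
            class = "param_validation")
}

#' @export
print.param_validation <- function(x, ...) {
  if (length(x$errors) == 0 && length(x$warnings) == 0) {
    cat("parameters OK (no errors, no warnings)\n")
  }
  for (e in x$errors) cat("error  :", e, "\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Reaction channels of the minimal network
#'
#' Expands a parameter set into the four mass-action channels. Each channel
#' is catalytic in its activator: firing converts one substrate copy from
#' inactive to active and leaves the activator count unchanged. Channels A
#' and B3 both produce activated X3, joining the two pathways in a loop.
#'
#' @param params A validated [network_params()] object.
#' @return A list of four `reaction_channel` objects (names `A`, `B1`,
#'   `B2`, `B3`), each a list with `name`, `activator`, `substrate`,
#'   `rate_constant` (the parameter-field name), and `delta`, the integer
#'   state-update vector over all trajectory state fields.
#' @examples
#' ch <- build_reaction_channels(network_params(x0 = 50))
#' ch$B2$delta
#' @export
build_reaction_channels <- function(params) {
  rep_ <- validate_parameters(params)
  if (length(rep_$errors) > 0) {
    stop("invalid parameters: ", paste(rep_$errors, collapse = "; "),
         call. = FALSE)
  }
  fields <- c("x1", "x1a", "x2", "x2a", "x3", "x3a",
              "fireA", "fireB1", "fireB2", "fireB3")
  zero <- stats::setNames(integer(length(fields)), fields)
  mk <- function(name, activator, substrate, rate_constant, d) {
    delta <- zero
    delta[names(d)] <- d
    structure(list(name = name, activator = activator,
                   substrate = substrate, rate_constant = rate_constant,
                   delta = delta),
              class = "reaction_channel")
  }
  list(
    A  = mk("A",  "x0",  "x3", "k_a",
            c(x3 = -1L, x3a = 1L, fireA = 1L)),
    B1 = mk("B1", "x0",  "x1", "k_b1",
            c(x1 = -1L, x1a = 1L, fireB1 = 1L)),
    B2 = mk("B2", "x1a", "x2", "k_b2",
            c(x2 = -1L, x2a = 1L, fireB2 = 1L)),
    B3 = mk("B3", "x2a", "x3", "k_b3",
            c(x3 = -1L, x3a = 1L, fireB3 = 1L))
  )
}

#' Analytic classification of the signaling regime
#'
#' Decides from the parameters alone which pathway dominates activation of
#' X3 as a function of the stimulus, by comparing the effective activation
#' coefficients of the two pathways:
#'
#' * type A dominates at all times when
#'   `x0 > k_b3 * sqrt(k_b2 * x1_total * x2_total) / k_a`
#'   (threshold `threshold_type_a`);
#' * type B dominates from the beginning when
#'   `x0 < k_b2 * x1_total * x2_total / (k_a * x3_total)`
#'   (threshold `threshold_type_b`);
#' * otherwise the response is mixed.
#'
#' Both relations are order-of-magnitude estimates: empirical pathway
#' attribution (see [channel_attribution()]) matches the labels reliably
#' only well beyond the thresholds.
#'
#' With `k_a = 0` the type A pathway is absent: both thresholds are
#' reported as `Inf` and the label is `TYPE_B`.
#'
#' @param params A [network_params()] object with finite `x0`.
#' @return A list of class `regime_classification`: `label` (one of
#'   `"TYPE_A"`, `"MIXED"`, `"TYPE_B"`), `threshold_type_a`,
#'   `threshold_type_b`.
#' @examples
#' p <- network_params(x0 = 2e5)  # thresholds 1e5 and 1e3
#' classify_regime_analytic(p)$label           # "TYPE_A"
#' classify_regime_analytic(network_params(x0 = 50))$label  # "TYPE_B"
#' @export
classify_regime_analytic <- function(params) {
  rep_ <- validate_parameters(params)
  if (length(rep_$errors) > 0) {
    stop("invalid parameters: ", paste(rep_$errors, collapse = "; "),
         call. = FALSE)
  }
  if (is.na(params$x0)) {
    stop("x0 is unset; the regime depends on the stimulus", call. = FALSE)
  }
  if (params$k_a == 0) {
    return(structure(list(label = "TYPE_B",
                          threshold_type_a = Inf,
                          threshold_type_b = Inf),
                     class = "regime_classification"))
  }
  thr_a <- params$k_b3 *
    sqrt(params$k_b2 * params$x1_total * params$x2_total) / params$k_a
  thr_b <- params$k_b2 * params$x1_total * params$x2_total /
    (params$k_a * params$x3_total)
  label <- if (params$x0 > thr_a) {
    "TYPE_A"
  } else if (params$x0 < thr_b) {
    "TYPE_B"
  } else {
    "MIXED"
  }
  structure(list(label = label,
                 threshold_type_a = thr_a,
                 threshold_type_b = thr_b),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("regime: %s  (type A above x0 = %g; type B below x0 = %g)\n",
              x$label, x$threshold_type_a, x$threshold_type_b))
  invisible(x)
}

#' Named parameter presets
#'
#' `figS1_base` is the reference parameter set: copy-number totals
#' 100/100/100, `k_a = 1e-5`, `k_b3 = 1.0`, plus the package's documented
#' choices `k_b1 = 1.0` and `k_b2 = 1e-4`, with the stimulus left unset.
#' At these values the analytic thresholds are `1e5` (type A) and `1e3`
#' (type B).
#'
#' The three stimulus presets place the network in each regime:
#'
#' * `strong`: `figS1_base` with `x0 = 1e6`, ten times the type A
#'   threshold — rapid, near-deterministic activation through channel A.
#' * `intermediate`: `figS1_base` with `x0 = 1e4`, the geometric mean of
#'   the two thresholds — mixed response.
#' * `weak`: `k_b2 = 1e-6` and `x0 = 5`, half the type B threshold at that
#'   `k_b2`. The smaller slow-step constant puts the aggregate slow rate
#'   `k_b2 * x1_total * x2_total = 0.01` far below `k_b3`, which is what
#'   produces the hallmark type B phenomenology: activation onsets spread
#'   over hundreds of time units with an abrupt per-cell rise, hence
#'   all-or-none activation, a bimodal snapshot distribution and Fano
#'   factors far above one. (At `k_b2 = 1e-4` the aggregate slow rate
#'   equals `k_b3` and the all-or-none character is lost even though type B
#'   still dominates.)
#'
#' @param name One of `"figS1_base"`, `"weak"`, `"intermediate"`,
#'   `"strong"`.
#' @return A [network_params()] object.
#' @examples
#' network_preset("weak")
#' @export
network_preset <- function(name) {
  base <- network_params(x0 = NA_real_,
                         x1_total = 100, x2_total = 100, x3_total = 100,
                         k_a = 1e-5, k_b1 = 1.0, k_b2 = 1e-4, k_b3 = 1.0)
  switch(name,
    figS1_base = base,
    strong = { base$x0 <- 1e6; base },
    intermediate = { base$x0 <- 1e4; base },
    weak = { base$k_b2 <- 1e-6; base$x0 <- 5; base },
    stop("unknown preset '", name,
         "'; valid names: figS1_base, weak, intermediate, strong",
         call. = FALSE)
  )
}
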