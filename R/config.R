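#' Swarm simulation configuration
#'
#' Builds and validates the full parameter set for one simulation run.
#' Defaults follow the published study conditions: neighborhood radius
#' `r = 20`, speed `v = 5` length units per step.
#'
#' @param model `"SPP"` (velocity matching only, offset symbol d fixed at 0),
#'   `"BO"` (Bayesian inference chooses d each step, likelihood table frozen),
#'   or `"BIB"` (Bayesian plus inverse Bayesian inference: one likelihood row
#'   is overwritten per step by the windowed data frequency).
#' @param n number of agents.
#' @param steps total number of recorded time steps `T` (the swarm moves
#'   `steps - 1` times).
#' @param epsilon maximum heading perturbation (radian); each step every agent
#'   receives an angular noise term drawn uniformly from `[-epsilon, epsilon]`
#'   (a fair sign times `Uniform[0, epsilon]`).
#' @param r neighborhood radius.
#' @param v speed per time step; every displacement has magnitude `v`.
#' @param boundary `"open"` (free space) or `"periodic"` (square box of side
#'   `L` with minimum-image distances).
#' @param L box side for the periodic boundary; must exceed `2 r`.
#' @param m data-window size for inverse Bayesian inference (BIB only).
#' @param init initial placement: `"central"` puts agents uniformly in a
#'   central square of side `central_side`; `"uniform"` scatters them over
#'   the box (`[0, L]^2`; under an open boundary `L` is still used as the
#'   initial scatter extent).
#' @param central_side side of the central starting square.
#' @param seed integer seed; `(config, seed)` determines the trajectory
#'   exactly.
#' @param likelihood_floor lower bound imposed on likelihood entries when
#'   normalizing a Bayes update (0 disables; see [bayes_posterior()] for the
#'   degenerate-normalizer rule).
#' @param prior_leak belief relaxation rate: after each Bayes update the
#'   posterior is mixed with the uniform distribution,
#'   `(1 - prior_leak) * posterior + prior_leak / 4`. Keeps every
#'   hypothesis recoverable (the posterior can never degenerate to a point
#'   mass, so the inverse Bayesian replacement keeps reaching every
#'   likelihood row). 0 disables.
#' @param response_floor minimum per-symbol probability enforced when the
#'   next data symbol is sampled from a likelihood row (the row is floored
#'   and renormalized for sampling only; the stored table is untouched).
#'   Keeps the symbol dynamics ergodic: pure rows would otherwise be
#'   absorbing. 0 disables.
#'
#' @return An object of class `swarm_config` (a validated named list).
#' @seealso [swarm_preset()] for the two study scenarios.
#' @examples
#' cfg <- swarm_config("BIB", n = 50, steps = 200, epsilon = 0.1, seed = 1)
#' cfg
#' @export
swarm_config <- function(model = c("BIB", "BO", "SPP"),
                         n = 1000,
                         steps = 10000,
                         epsilon = 0.1,
                         r = 20,
                         v = 5,
                         boundary = c("open", "periodic"),
                         L = 500,
                         m = 10,
                         init = c("central", "uniform"),
                         central_side = 50,
                         seed = 1,
                         likelihood_floor = 0,
                         prior_leak = 0.01,
                         response_floor = 0.01) {
  model <- match.arg(toupper(model[1]), c("BIB", "BO", "SPP"))
  boundary <- match.arg(boundary)
  init <- match.arg(init)
  cfg <- structure(list(
    model = model, n = as.integer(n), steps = as.integer(steps),
    epsilon = epsilon, r = r, v = v,
    boundary = boundary, L = L, m = as.integer(m),
    init = init, central_side = central_side,
    seed = as.integer(seed), likelihood_floor = likelihood_floor,
    prior_leak = prior_leak, response_floor = response_floor
  ), class = "swarm_config")
  validate_swarm_config(cfg)
  cfg
}

validate_swarm_config <- function(cfg) {
  stopifnot(
    cfg$n >= 1, cfg$steps >= 1,
    cfg$r > 0, cfg$v > 0, cfg$epsilon >= 0,
    cfg$m >= 1, cfg$likelihood_floor >= 0,
    cfg$prior_leak >= 0, cfg$prior_leak < 1,
    cfg$response_floor >= 0, cfg$response_floor <= 0.25
  )
  if (cfg$boundary == "periodic" && cfg$L <= 2 * cfg$r)
    stop("periodic boundary requires L > 2 * r", call. = FALSE)
  if (cfg$init == "central" && cfg$central_side <= 0)
    stop("central_side must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Study-scenario presets
#'
#' Two canonical scenarios. `"indexes"` is the behavior-index setting:
#' periodic box, agents scattered uniformly, so the swarm cannot disperse and
#' tornado/splash/translation counts are meaningful. `"levy"` is the
#' step-length setting: open space with all agents started in a small central
#' square, so freely moving agents can be tracked over long distances.
#'
#' @param scenario `"indexes"` or `"levy"`.
#' @param model,epsilon,n,steps,seed passed to [swarm_config()].
#' @param ... further overrides for [swarm_config()].
#' @return A `swarm_config`.
#' @examples
#' swarm_preset("levy", "BIB", epsilon = 0.1, n = 100, steps = 500)
#' @export
swarm_preset <- function(scenario = c("levy", "indexes"), model = "BIB",
                         epsilon = 0.1, n = 1000,
                         steps = if (scenario == "levy") 10000 else 5000,
                         seed = 1, ...) {
  scenario <- match.arg(scenario)
  base <- if (scenario == "levy") {
    list(boundary = "open", init = "central", central_side = 50)
  } else {
    list(boundary = "periodic", init = "uniform", L = 500)
  }
  do.call(swarm_config, c(list(model = model, n = n, steps = steps,
                               epsilon = epsilon, seed = seed),
                          modifyList(base, list(...))))
}

#' @export
print.swarm_config <- function(x, ...) {
  cat(sprintf("Swarm configuration: %s model\n", x$model))
  cat(sprintf("  agents N = %d, steps T = %d\n", x$n, x$steps))
  cat(sprintf("  R = %g, V = %g, epsilon = %g rad\n", x$r, x$v, x$epsilon))
  if (x$boundary == "periodic")
    cat(sprintf("  boundary: periodic, L = %g\n", x$L))
  else
    cat("  boundary: open\n")
  cat(sprintf("  init: %s%s, seed = %d\n", x$init,
              if (x$init == "central")
                sprintf(" (side %g)", x$central_side) else "",
              x$seed))
  if (x$model == "BIB") cat(sprintf("  window m = %d\n", x$m))
  invisible(x)
}
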