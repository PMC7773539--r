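# Per-agent decision machinery: Bayesian posterior update, roulette
# selection of hypothesis and data symbols, windowed empirical data
# probability, and the inverse Bayesian likelihood replacement.
#
# Symbols d (data) and h (hypothesis) live in {0, 1, 2, 3} throughout; all
# selection functions speak that 0-based symbol alphabet, matching the
# geometric meaning d * pi/2 of the data symbol.

#' Construct an agent belief
#'
#' A belief holds a prior over the four hypotheses and a 4 x 4
#' row-stochastic likelihood table `P(d | h)` (rows indexed by `h`, columns
#' by `d`). Defaults are the study's initial condition: uniform prior and
#' `P(d | h) = 0.7` when `d == h`, `0.1` otherwise.
#'
#' @param prior probability 4-vector over hypotheses.
#' @param likelihood 4 x 4 row-stochastic matrix `P(d | h)`.
#' @return A list of class `belief` with elements `prior` and `likelihood`.
#' @examples
#' b <- new_belief()
#' rowSums(b$likelihood)
#' @export
new_belief <- function(prior = rep(0.25, 4),
                       likelihood = default_likelihood()) {
  stopifnot(length(prior) == 4, all(prior >= 0),
            abs(sum(prior) - 1) < 1e-9,
            all(dim(likelihood) == c(4, 4)), all(likelihood >= 0),
            all(abs(rowSums(likelihood) - 1) < 1e-9))
  structure(list(prior = as.numeric(prior),
                 likelihood = unname(as.matrix(likelihood))),
            class = "belief")
}

#' @rdname new_belief
#' @export
default_likelihood <- function() {
  lik <- matrix(0.1, 4, 4)
  diag(lik) <- 0.7
  lik
}

#' Bayesian posterior over hypotheses
#'
#' `P(h | d) = P(d | h) P(h) / sum_h' P(d | h') P(h')`. When the normalizer
#' is zero (possible once inverse Bayesian replacement has introduced zero
#' likelihood entries) the prior is returned unchanged: an impossible
#' observation carries no information. A positive `floor` instead clamps
#' the likelihood column from below before normalizing.
#'
#' @param belief a [new_belief()] object.
#' @param d observed data symbol in `0:3`.
#' @param floor optional lower bound on likelihood entries (default 0).
#' @return Probability 4-vector `P(h | d)` summing to 1.
#' @examples
#' b <- new_belief()
#' bayes_posterior(b, d = 0)
#' @export
bayes_posterior <- function(belief, d, floor = 0) {
  stopifnot(d %in% 0:3)
  lik_col <- belief$likelihood[, d + 1]
  if (floor > 0) lik_col <- pmax(lik_col, floor)
  num <- lik_col * belief$prior
  z <- sum(num)
  if (z <= 0) return(belief$prior)
  num / z
}

#' Roulette-wheel selection by cumulative weight
#'
#' Returns the smallest symbol `i` whose cumulative weight reaches the draw
#' `r`; over `r ~ Uniform[0, sum(weights)]` symbol `i` is selected with
#' probability `weights[i + 1] / sum(weights)`.
#'
#' @param weights nonnegative weight vector (not all zero), ordered by
#'   symbol `0, 1, ...`.
#' @param r draw in `[0, sum(weights)]`; defaults to a fresh uniform draw.
#' @return Selected symbol in `0:(length(weights) - 1)`.
#' @examples
#' roulette_select(c(0.2, 0.1, 0.4, 0.3), r = 0.5)  # cumulative 0.2 0.3 0.7 1
#' @export
roulette_select <- function(weights, r = runif(1, 0, sum(weights))) {
  stopifnot(all(weights >= 0))
  tot <- sum(weights)
  if (tot <= 0) stop("all-zero weights")
  cw <- cumsum(weights)
  i <- which(r <= cw + 1e-12)
  if (length(i) == 0) length(weights) - 1L else i[1] - 1L
}

#' Inverse-probability selection of the replacement target
#'
#' Picks the hypothesis `f` whose likelihood row will be overwritten by
#' inverse Bayesian inference, favoring low-probability hypotheses: the
#' cumulative score is `EP(h) = sum_{h' <= h} (1 - P(h'))` and
#' `f = min{h : r <= EP(h)}` for `r ~ Uniform[0, 3]`, so hypothesis `h` is
#' chosen with probability `(1 - P(h)) / 3`.
#'
#' @param posterior probability 4-vector over hypotheses.
#' @param r draw in `[0, 3]`; defaults to a fresh uniform draw.
#' @return Selected hypothesis symbol in `0:3`.
#' @examples
#' # posterior (0.2, 0.1, 0.4, 0.3) gives EP = (0.8, 1.7, 2.3, 3.0);
#' # r = 1.0 lands in (0.8, 1.7] so f = 1
#' select_inverse_target(c(0.2, 0.1, 0.4, 0.3), r = 1.0)
#' @export
select_inverse_target <- function(posterior, r = runif(1, 0, 3)) {
  stopifnot(abs(sum(posterior) - 1) < 1e-6)
  roulette_select(1 - posterior, r)
}

#' Windowed empirical data probability
#'
#' Normalized frequency of each data symbol in the FIFO window of recent
#' data: `P(d) = #(window == d) / length(window)`. During warm-up, before
#' `m` symbols have accumulated, the current buffer length is the
#' denominator.
#'
#' @param window integer vector of recent data symbols (values in `0:3`),
#'   oldest first; must be nonempty.
#' @return Probability 4-vector over `d = 0:3`.
#' @examples
#' window_probability(c(0, 0, 2, 1))  # 0.5 0.25 0.25 0
#' @export
window_probability <- function(window) {
  if (length(window) == 0) stop("empty data window")
  stopifnot(all(window %in% 0:3))
  tabulate(window + 1L, nbins = 4L) / length(window)
}

#' Inverse Bayesian likelihood replacement
#'
#' Overwrites likelihood row `f` wholesale with the windowed data
#' probability `wp`: `P(d | f) <- P_window(d)`. This is the symmetric
#' counterpart of the Bayesian replacement `P(h) <- P(h | d)` — Bayes
#' contracts the hypothesis side, inverse Bayes extends the data side. All
#' other rows and the prior are untouched; row-stochasticity is preserved.
#'
#' @param belief a [new_belief()] object.
#' @param f hypothesis symbol in `0:3` whose row is replaced.
#' @param wp probability 4-vector (sums to 1).
#' @return The updated belief.
#' @export
apply_inverse_bayes <- function(belief, f, wp) {
  stopifnot(f %in% 0:3, abs(sum(wp) - 1) < 1e-9, all(wp >= 0))
  belief$likelihood[f + 1, ] <- wp
  belief
}

#' One inference step for a single agent
#'
#' The per-step decision update, in order: (1) Bayes — the prior is replaced
#' by the posterior given the current data symbol; (2) inverse Bayes (BIB
#' only) — the current datum is pushed into the window, and the likelihood
#' row of an inverse-roulette-selected hypothesis is replaced by the
#' windowed data frequency; (3) a new hypothesis is roulette-sampled from
#' the posterior; (4) a new data symbol is roulette-sampled from that
#' hypothesis's likelihood row. In `BO` mode the likelihood table is never
#' modified.
#'
#' @param agent list with elements `belief` ([new_belief()]), `d` (current
#'   data symbol), `h` (current hypothesis), and for BIB a `window` integer
#'   vector (oldest first).
#' @param mode `"BO"` or `"BIB"`.
#' @param m window size (BIB).
#' @param floor likelihood floor passed to [bayes_posterior()].
#' @param prior_leak,response_floor stabilization parameters as in
#'   [swarm_config()]: posterior relaxation toward uniform, and the minimum
#'   per-symbol probability used when sampling the new data symbol.
#' @return The updated agent list (new `belief`, `h`, `d`, and window).
#' @export
inference_step <- function(agent, mode = c("BIB", "BO"), m = 10, floor = 0,
                           prior_leak = 0.01, response_floor = 0.01) {
  mode <- match.arg(mode)
  post <- bayes_posterior(agent$belief, agent$d, floor)
  if (prior_leak > 0)
    post <- (1 - prior_leak) * post + prior_leak / 4
  agent$belief$prior <- post
  if (mode == "BIB") {
    agent$window <- c(agent$window, agent$d)
    if (length(agent$window) > m)
      agent$window <- agent$window[seq.int(length(agent$window) - m + 1,
                                           length(agent$window))]
    wp <- window_probability(agent$window)
    f <- select_inverse_target(post)
    agent$belief <- apply_inverse_bayes(agent$belief, f, wp)
  }
  agent$h <- roulette_select(post, r = runif(1))
  row <- agent$belief$likelihood[agent$h + 1, ]
  if (response_floor > 0) {
    row <- pmax(row, response_floor)
    row <- row / sum(row)
  }
  agent$d <- roulette_select(row, r = runif(1))
  agent
}
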