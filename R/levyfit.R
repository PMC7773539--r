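# Levy-walk detection: maximum-likelihood fit of a hard-truncated power law
# density (mu - 1) / (xmin^(1-mu) - xmax^(1-mu)) * x^-mu on [xmin, xmax]
# against a shifted exponential lambda * exp(-lambda (x - xmin)), with the
# lower cutoff xmin selected by the Kolmogorov-Smirnov distance and the two
# models compared through AIC / Akaike weights.

#' Truncated power-law distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the hard-truncated power law with exponent `mu > 1` on
#' `[xmin, xmax]`.
#'
#' @param x,q,p,n usual distribution-function arguments.
#' @param mu exponent (> 1).
#' @param xmin,xmax support bounds, `0 < xmin < xmax`.
#' @return `dtruncpl` the density, `ptruncpl` the CDF, `qtruncpl` the
#'   quantile function, `rtruncpl` random deviates (inverse-CDF sampling).
#' @examples
#' integrate(dtruncpl, 1, 100, mu = 2.5, xmin = 1, xmax = 100)
#' @export
dtruncpl <- function(x, mu, xmin, xmax) {
  stopifnot(mu > 1, xmin > 0, xmax > xmin)
  c0 <- (mu - 1) / (xmin^(1 - mu) - xmax^(1 - mu))
  out <- c0 * x^(-mu)
  out[x < xmin | x > xmax] <- 0
  out
}

#' @rdname dtruncpl
#' @export
ptruncpl <- function(q, mu, xmin, xmax) {
  stopifnot(mu > 1, xmin > 0, xmax > xmin)
  denom <- xmin^(1 - mu) - xmax^(1 - mu)
  out <- (xmin^(1 - mu) - q^(1 - mu)) / denom
  pmin(1, pmax(0, out))
}

#' @rdname dtruncpl
#' @export
qtruncpl <- function(p, mu, xmin, xmax) {
  stopifnot(all(p >= 0 & p <= 1), mu > 1, xmin > 0, xmax > xmin)
  (xmin^(1 - mu) - p * (xmin^(1 - mu) - xmax^(1 - mu)))^(1 / (1 - mu))
}

#' @rdname dtruncpl
#' @export
rtruncpl <- function(n, mu, xmin, xmax) {
  qtruncpl(runif(n), mu, xmin, xmax)
}

#' Log-likelihood of the truncated power law
#'
#' `n log((mu-1)/(xmin^(1-mu) - xmax^(1-mu))) - mu sum(log x)` for data in
#' `[xmin, xmax]`.
#'
#' @param x data vector, all in `[xmin, xmax]`.
#' @param mu exponent (> 1).
#' @param xmin,xmax support bounds.
#' @return Log-likelihood (finite for valid inputs).
#' @export
truncated_pl_loglik <- function(x, mu, xmin, xmax) {
  stopifnot(mu > 1, all(x >= xmin - 1e-9), all(x <= xmax + 1e-9))
  length(x) * log((mu - 1) / (xmin^(1 - mu) - xmax^(1 - mu))) -
    mu * sum(log(x))
}

# maximize a scalar log-likelihood over a bounded mu interval; endpoints
# are checked explicitly so boundary solutions come back as the exact bound
.maximize_mu <- function(ll, mu_range) {
  opt <- optimize(ll, interval = mu_range, maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, mu_range)
  vals <- vapply(cand, ll, numeric(1))
  i <- which.max(vals)
  list(mu = cand[i], loglik = vals[i])
}

#' Fit the truncated power law by bounded maximum likelihood
#'
#' Maximizes the truncated power-law likelihood over
#' `mu` in `mu_range` (default `[1 + 1e-6, 3]`, the Levy-walk exponent
#' range); when the likelihood is monotone over the interval the exact
#' bound is returned, so misspecified data report `mu = 1` or `mu = 3`.
#'
#' @param x tail data, all in `[xmin, xmax]`, at least 10 values.
#' @param xmin,xmax support bounds.
#' @param mu_range search interval for the exponent.
#' @return List with `mu_hat` and `loglik`.
#' @export
fit_truncated_pl <- function(x, xmin, xmax, mu_range = c(1 + 1e-6, 3)) {
  if (length(x) < 10) stop("need at least 10 tail data points")
  stopifnot(all(x >= xmin - 1e-9), all(x <= xmax + 1e-9), xmax > xmin)
  s <- sum(log(x))
  n <- length(x)
  ll <- function(mu) n * log((mu - 1) / (xmin^(1 - mu) - xmax^(1 - mu))) -
    mu * s
  m <- .maximize_mu(ll, mu_range)
  list(mu_hat = m$mu, loglik = m$loglik)
}

#' Fit the shifted exponential by maximum likelihood
#'
#' Closed form: `lambda_hat = 1 / (mean(x) - xmin)` for the density
#' `lambda exp(-lambda (x - xmin))`.
#'
#' @param x tail data, all `>= xmin`, at least 2 values.
#' @param xmin shift (lower cutoff).
#' @return List with `lambda_hat` and `loglik`.
#' @examples
#' fit_exponential(c(2, 3, 4), xmin = 1)$lambda_hat  # 0.5
#' @export
fit_exponential <- function(x, xmin) {
  if (length(x) < 2) stop("need at least 2 tail data points")
  excess <- mean(x) - xmin
  if (excess <= 0) stop("all data at xmin: exponential rate undefined")
  lambda <- 1 / excess
  list(lambda_hat = lambda,
       loglik = length(x) * log(lambda) - lambda * sum(x - xmin))
}

#' Select the lower cutoff by Kolmogorov-Smirnov distance
#'
#' Candidate cutoffs are unique data values up to the `prob_cap` quantile
#' (thinned to at most `max_candidates` quantile-spaced values when the
#' data are large). For each candidate the truncated power law is fitted to
#' the tail `x >= xmin` (with `xmax` the overall maximum) and the KS
#' distance between the empirical tail CDF and the fitted CDF is computed;
#' the candidate minimizing the distance wins, ties going to the smallest
#' cutoff.
#'
#' @param x data vector (>= 50 values).
#' @param max_candidates cap on the number of candidate cutoffs.
#' @param prob_cap highest quantile considered as a cutoff.
#' @param mu_range exponent search interval, as in [fit_truncated_pl()].
#' @return The selected `xmin` (a data value), with attribute `"ks"` giving
#'   its KS distance.
#' @export
select_xmin <- function(x, max_candidates = 200, prob_cap = 0.99,
                        mu_range = c(1 + 1e-6, 3)) {
  x <- sort(x[is.finite(x) & x > 0])
  n <- length(x)
  if (n < 50) stop("need at least 50 data points to select xmin")
  xmax <- x[n]
  cand <- unique(x[x <= quantile(x, prob_cap, names = FALSE)])
  cand <- cand[cand < xmax]
  if (length(cand) == 0) cand <- x[1]
  if (length(cand) > max_candidates)
    cand <- unique(quantile(cand, seq(0, 1, length.out = max_candidates),
                            names = FALSE, type = 1))
  slog <- rev(cumsum(rev(log(x))))   # suffix sums of log(x)
  best_ks <- Inf
  best_xmin <- cand[1]
  for (xm in cand) {
    i <- which.max(x >= xm)
    nt <- n - i + 1
    if (nt < 10) next
    s <- slog[i]
    ll <- function(mu)
      nt * log((mu - 1) / (xm^(1 - mu) - xmax^(1 - mu))) - mu * s
    mu <- .maximize_mu(ll, mu_range)$mu
    xt <- x[i:n]
    Fhat <- ptruncpl(xt, mu, xm, xmax)
    emp <- seq_len(nt) / nt
    ks <- max(abs(Fhat - emp), abs(Fhat - (emp - 1 / nt)))
    if (ks < best_ks - 1e-15) {   # strict: ties keep the smaller xmin
      best_ks <- ks
      best_xmin <- xm
    }
  }
  structure(best_xmin, ks = best_ks)
}

#' AIC and Akaike weights for the two candidate models
#'
#' Each model carries one free parameter (`mu` or `lambda`; the shared,
#' data-determined `xmin` and `xmax` are not counted), so
#' `AIC = 2 - 2 loglik`. The Akaike weight of the truncated power law is
#' `exp(-(AIC_pl - AIC_min)/2)` normalized over both models.
#'
#' @param loglik_pl,loglik_exp log-likelihoods of the truncated power law
#'   and the exponential on the same tail.
#' @return List with `w_pl`, `aic_pl`, `aic_exp`.
#' @export
akaike_weights <- function(loglik_pl, loglik_exp) {
  stopifnot(is.finite(loglik_pl), is.finite(loglik_exp))
  aic <- c(pl = 2 - 2 * loglik_pl, exp = 2 - 2 * loglik_exp)
  rel <- exp(-(aic - min(aic)) / 2)
  list(w_pl = unname(rel["pl"] / sum(rel)),
       aic_pl = unname(aic["pl"]), aic_exp = unname(aic["exp"]))
}

#' Fit the step-length distribution
#'
#' The full model-selection protocol on a pooled step-length sample:
#' `xmax` is the sample maximum, `xmin` is selected by [select_xmin()],
#' both the truncated power law and the shifted exponential are fitted to
#' the common tail `x >= xmin`, and the models are compared by Akaike
#' weight. A weight near 1 for the truncated power law with exponent
#' `1 <= mu <= 3` is the Levy-walk signature.
#'
#' @param x a `step_table` from [pool_steps()], or a numeric vector of step
#'   lengths (>= 50 values).
#' @param xmin optional fixed lower cutoff (skips KS selection).
#' @param mu_range exponent search interval.
#' @param max_candidates,prob_cap passed to [select_xmin()].
#' @return An object of class `levy_fit` with components `mu_hat`,
#'   `lambda_hat`, `xmin`, `xmax`, `loglik_pl`, `loglik_exp`, `aic_pl`,
#'   `aic_exp`, `w_pl`, `n_tail`, `n_total`, and the sorted tail sample.
#' @examples
#' set.seed(1)
#' fit <- levy_fit(rtruncpl(2000, mu = 2.5, xmin = 5, xmax = 500))
#' fit
#' coef(fit)
#' @export
levy_fit <- function(x, xmin = NULL, mu_range = c(1 + 1e-6, 3),
                     max_candidates = 200, prob_cap = 0.99) {
  if (inherits(x, "step_table") || is.data.frame(x)) x <- x$length
  x <- as.numeric(x[is.finite(x) & x > 0])
  if (length(x) < 50) stop("need at least 50 positive step lengths")
  xmax <- max(x)
  ks <- NA_real_
  if (is.null(xmin)) {
    xmin <- select_xmin(x, max_candidates, prob_cap, mu_range)
    ks <- attr(xmin, "ks")
    xmin <- as.numeric(xmin)
  }
  tail_x <- sort(x[x >= xmin])
  pl <- fit_truncated_pl(tail_x, xmin, xmax, mu_range)
  ex <- fit_exponential(tail_x, xmin)
  aw <- akaike_weights(pl$loglik, ex$loglik)
  structure(list(
    mu_hat = pl$mu_hat, lambda_hat = ex$lambda_hat,
    xmin = xmin, xmax = xmax, ks = ks,
    loglik_pl = pl$loglik, loglik_exp = ex$loglik,
    aic_pl = aw$aic_pl, aic_exp = aw$aic_exp, w_pl = aw$w_pl,
    n_tail = length(tail_x), n_total = length(x),
    mu_range = mu_range, tail = tail_x
  ), class = "levy_fit")
}

#' @export
print.levy_fit <- function(x, ...) {
  cat("Step-length model selection (truncated power law vs exponential)\n")
  cat(sprintf("  n = %d (tail n = %d), xmin = %.4g, xmax = %.4g\n",
              x$n_total, x$n_tail, x$xmin, x$xmax))
  cat(sprintf("  truncated power law: mu = %.3f, logLik = %.2f, AIC = %.2f\n",
              x$mu_hat, x$loglik_pl, x$aic_pl))
  cat(sprintf("  exponential:     lambda = %.4f, logLik = %.2f, AIC = %.2f\n",
              x$lambda_hat, x$loglik_exp, x$aic_exp))
  cat(sprintf("  Akaike weight of the power law: w_pl = %.4f -> %s\n",
              x$w_pl,
              if (x$w_pl >= 0.5) "Levy-walk-like (power-law preferred)"
              else "exponential preferred"))
  invisible(x)
}

#' @export
summary.levy_fit <- function(object, ...) {
  out <- unclass(object)
  out$tail <- NULL
  out$preferred <- if (object$w_pl >= 0.5) "truncated_power_law"
  else "exponential"
  class(out) <- "summary.levy_fit"
  out
}

#' @export
print.summary.levy_fit <- function(x, ...) {
  print.levy_fit(structure(unclass(x), class = "levy_fit"))
  cat(sprintf("  preferred model: %s\n", x$preferred))
  invisible(x)
}

#' @export
coef.levy_fit <- function(object, ...) {
  c(mu = object$mu_hat, lambda = object$lambda_hat)
}

#' @export
logLik.levy_fit <- function(object, ...) {
  better <- object$w_pl >= 0.5
  structure(if (better) object$loglik_pl else object$loglik_exp,
            df = 1L, nobs = object$n_tail, class = "logLik")
}

#' Empirical and fitted tail CCDF table
#'
#' Complementary CDF `P(X >= x)` of the fitted tail together with both
#' fitted model CCDFs, suitable for log-log cumulative plots or CSV export.
#'
#' @param fit a [levy_fit()] object.
#' @return Data frame with columns `x`, `empirical`, `truncated_pl`,
#'   `exponential`.
#' @export
ccdf_table <- function(fit) {
  stopifnot(inherits(fit, "levy_fit"))
  xs <- fit$tail
  n <- length(xs)
  data.frame(
    x = xs,
    empirical = (n - seq_len(n) + 1) / n,
    truncated_pl = 1 - ptruncpl(xs, fit$mu_hat, fit$xmin, fit$xmax),
    exponential = exp(-fit$lambda_hat * (xs - fit$xmin)))
}

#' @export
plot.levy_fit <- function(x, ...) {
  tab <- ccdf_table(x)
  plot(tab$x, tab$empirical, log = "xy", pch = 0, col = "purple",
       xlab = "step length", ylab = "P(X >= x)",
       main = sprintf("mu = %.2f, lambda = %.3f, w_pl = %.2f",
                      x$mu_hat, x$lambda_hat, x$w_pl), ...)
  lines(tab$x, pmax(tab$truncated_pl, .Machine$double.xmin),
        col = "darkgreen", lwd = 2)
  lines(tab$x, pmax(tab$exponential, .Machine$double.xmin),
        col = "steelblue", lwd = 2)
  legend("bottomleft", bty = "n",
         legend = c("empirical", "truncated power law", "exponential"),
         col = c("purple", "darkgreen", "steelblue"),
         pch = c(0, NA, NA), lty = c(NA, 1, 1), lwd = c(NA, 2, 2))
  invisible(x)
}
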