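#' Build the behavioral comparison trial list
#'
#' Full factorial list of two-interval comparison trials for the acuity
#' pre-test: test/reference ratio x average item area x total field area x
#' presentation order x session. With the default factors (6 ratios, 6 item
#' areas, 2 field areas, 2 orders, 3 sessions) this yields 432 comparisons
#' per task. Test values are \code{reference * ratio}.
#'
#' @param task \code{"number"} or \code{"size"}; determines the units of the
#'   reference (dot count vs vd^2) but not the trial structure.
#' @param reference reference value (10 dots, or 0.1 vd^2 for the size task).
#' @param ratios test/reference ratios.
#' @param item_areas distractor average item-area levels (vd^2).
#' @param field_areas virtual-circle field areas (vd^2).
#' @param orders presentation orders.
#' @param sessions number of sessions.
#' @return data frame of \code{ComparisonTrial}s with columns \code{task},
#'   \code{reference_value}, \code{test_value}, \code{test_ratio},
#'   \code{log_ratio}, \code{item_area}, \code{tfa_level}, \code{order},
#'   \code{session}.
#' @export
comparison_trials <- function(task = c("number", "size"),
                              reference = if (match.arg(task) == "number") 10 else 0.1,
                              ratios = c(0.5, 0.7, 0.9, 1.1, 1.5, 2),
                              item_areas = c(0.05, 0.06, 0.08, 0.11, 0.15, 0.2),
                              field_areas = c(26.42, 45.36),
                              orders = c("test-first", "test-second"),
                              sessions = 3L) {
  task <- match.arg(task)
  stopifnot(length(ratios) >= 1, all(ratios > 0), reference > 0,
            length(item_areas) >= 1, length(field_areas) >= 1,
            length(orders) >= 1, sessions >= 1)
  g <- expand.grid(session = seq_len(sessions),
                   order = orders,
                   tfa_level = seq_along(field_areas),
                   item_area = item_areas,
                   test_ratio = ratios,
                   stringsAsFactors = FALSE)
  data.frame(task = task,
             reference_value = reference,
             test_value = reference * g$test_ratio,
             test_ratio = g$test_ratio,
             log_ratio = log(g$test_ratio),
             item_area = g$item_area,
             tfa_level = g$tfa_level,
             order = g$order,
             session = g$session,
             stringsAsFactors = FALSE)
}

#' Simulate a psychophysical observer
#'
#' Generates binary "test greater than reference" responses from a
#' cumulative-Gaussian observer on the log-ratio axis:
#' \deqn{P(\mathrm{greater} \mid x) = \lambda/2 + (1-\lambda)\,
#'   \Phi((x - \mu)/\sigma)}
#' with \code{x = log(test/reference)}. \code{sigma_true = 0} gives the
#' deterministic step-function limit.
#'
#' @param trials a trial data frame from \code{\link{comparison_trials}}, or
#'   any data frame with a \code{log_ratio} column.
#' @param sigma_true observer spread in log-ratio units (>= 0).
#' @param mu_true point of subjective equality in log-ratio units.
#' @param lapse lapse rate \code{lambda} in \code{[0, 0.5)}.
#' @param seed integer seed.
#' @return integer vector of responses (1 = "test greater").
#' @export
simulate_observer <- function(trials, sigma_true, mu_true = 0, lapse = 0,
                              seed = 1L) {
  stopifnot(sigma_true >= 0, lapse >= 0, lapse < 0.5)
  x <- trials$log_ratio
  if (is.null(x)) stop("'trials' must have a 'log_ratio' column", call. = FALSE)
  base <- if (sigma_true == 0) as.numeric(x > mu_true)
          else stats::pnorm((x - mu_true) / sigma_true)
  p <- lapse / 2 + (1 - lapse) * base
  with_seed(seed, stats::rbinom(length(x), 1L, p))
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood binomial fit of \eqn{\Phi((x - \mu)/\sigma)} to the
#' proportion of "test greater" responses as a function of the log
#' test/reference ratio. The default model has two parameters (\eqn{\mu},
#' \eqn{\sigma}); a fixed lapse rate can be supplied, in which case the
#' fitted probability is \eqn{\lambda/2 + (1-\lambda)\Phi}. Optimisation is
#' bounded quasi-Newton (L-BFGS-B) with three starts and a 1e-8
#' log-likelihood tolerance.
#'
#' Responses may be given per trial (\code{response} of 0/1 with one
#' \code{log_ratio} per trial) or pre-aggregated (\code{n_greater} and
#' \code{n_total} per level); aggregated counts need not be integers, so
#' expected-count (noiseless) input is supported.
#'
#' @param log_ratio stimulus levels in log-ratio units.
#' @param response per-trial 0/1 responses (alternative to counts).
#' @param n_greater,n_total per-level counts of "greater" responses and
#'   trials.
#' @param lapse fixed lapse rate (not estimated); default 0.
#' @return object of class \code{"psychometric_fit"} with components
#'   \code{mu}, \code{sigma}, \code{lapse}, \code{log_likelihood},
#'   \code{converged}, \code{data} (per-level table) and
#'   \code{n_trials_per_level}.
#' @seealso \code{\link{jnd}}, \code{\link{weber_fraction}},
#'   \code{\link{match_value}}
#' @export
fit_psychometric <- function(log_ratio, response = NULL, n_greater = NULL,
                             n_total = NULL, lapse = 0) {
  stopifnot(lapse >= 0, lapse < 0.5)
  if (!is.null(response)) {
    stopifnot(length(response) == length(log_ratio),
              all(response %in% c(0, 1)))
    agg <- stats::aggregate(cbind(k = response, n = rep(1, length(response))),
                            by = list(x = log_ratio), FUN = sum)
  } else {
    stopifnot(!is.null(n_greater), !is.null(n_total),
              length(n_greater) == length(log_ratio),
              length(n_total) == length(log_ratio),
              all(n_total > 0), all(n_greater >= 0),
              all(n_greater <= n_total))
    agg <- data.frame(x = log_ratio, k = n_greater, n = n_total)
    agg <- agg[order(agg$x), ]
  }
  if (nrow(agg) < 2L)
    stop("need responses at >= 2 distinct stimulus levels", call. = FALSE)
  prop <- agg$k / agg$n
  if (all(prop <= 0.5) || all(prop >= 0.5))
    stop("responses must bracket 50% for the psychometric fit to be identified",
         call. = FALSE)

  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((agg$x - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  rng <- range(agg$x)
  # quantile-based initial guesses plus dispersed alternatives
  mu0 <- stats::approx(prop, agg$x, xout = 0.5, ties = mean, rule = 2)$y
  starts <- list(c(mu0, log(diff(rng) / 4)),
                 c(mean(rng), log(diff(rng))),
                 c(mu0, log(diff(rng) / 20)))
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, nll, method = "L-BFGS-B",
                            lower = c(rng[1] - 2 * diff(rng), log(1e-5)),
                            upper = c(rng[2] + 2 * diff(rng), log(10 * diff(rng))),
                            control = list(factr = 100, pgtol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best))
    stop("psychometric fit failed to converge from all starts", call. = FALSE)
  structure(list(mu = best$par[1],
                 sigma = exp(best$par[2]),
                 lapse = lapse,
                 log_likelihood = -best$value,
                 converged = best$convergence == 0,
                 data = agg,
                 n_trials_per_level = agg$n),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Cumulative-Gaussian psychometric fit\n")
  cat(sprintf("  mu    = %.5f (log-ratio units, PSE)\n", x$mu))
  cat(sprintf("  sigma = %.5f (log-ratio units)\n", x$sigma))
  if (x$lapse > 0) cat(sprintf("  lapse = %.3f (fixed)\n", x$lapse))
  cat(sprintf("  JND   = %.5f   Weber fraction = %.4f\n",
              jnd(x), weber_fraction(x)))
  cat(sprintf("  logLik = %.3f over %d levels (%d trials), converged: %s\n",
              x$log_likelihood, nrow(x$data), sum(x$data$n), x$converged))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
logLik.psychometric_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 2L, class = "logLik")
}

#' Predicted probability of a "greater" response
#'
#' @param object a \code{psychometric_fit}.
#' @param newdata log-ratio values (defaults to the fitted levels).
#' @param ... unused.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  object$lapse / 2 +
    (1 - object$lapse) * stats::pnorm((x - object$mu) / object$sigma)
}

#' Simulate responses from a fitted psychometric function
#'
#' @param object a \code{psychometric_fit}.
#' @param nsim number of replicate response sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a matrix of per-level "greater" counts, one column per replicate.
#' @export
simulate.psychometric_fit <- function(object, nsim = 1, seed = 1L, ...) {
  p <- predict(object)
  n <- object$data$n
  with_seed(seed, {
    matrix(stats::rbinom(length(p) * nsim, rep(n, nsim), rep(p, nsim)),
           ncol = nsim)
  })
}

#' Plot a psychometric fit
#'
#' Observed proportions against the log ratio with the fitted cumulative
#' Gaussian overlaid.
#' @param x a \code{psychometric_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.psychometric_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$k / d$n, ylim = c(0, 1), pch = 19,
                 xlab = "log(test / reference)",
                 ylab = "P(judged greater)", ...)
  xx <- seq(min(d$x), max(d$x), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(h = c(0.5, 0.75), lty = 3)
  invisible(x)
}

#' Just-noticeable difference of a psychometric fit
#'
#' Distance on the log-ratio axis between the 50% and 75% points of the
#' fitted cumulative Gaussian: \eqn{\Phi^{-1}(0.75)\,\sigma \approx
#' 0.6745\,\sigma}.
#'
#' @param fit a \code{psychometric_fit}, or a numeric \code{sigma}.
#' @return JND in log-ratio units.
#' @export
jnd <- function(fit) {
  sigma <- if (inherits(fit, "psychometric_fit")) fit$sigma else fit
  stopifnot(sigma > 0)
  stats::qnorm(0.75) * sigma
}

#' Weber fraction implied by a psychometric fit
#'
#' The fractional stimulus change supporting 75% discrimination:
#' \code{exp(jnd) - 1}.
#'
#' @param fit a \code{psychometric_fit} or numeric \code{sigma}.
#' @export
weber_fraction <- function(fit) {
  exp(jnd(fit)) - 1
}

#' Construct a match stimulus ~2 JNDs from a sample
#'
#' Match values sit two just-noticeable differences above or below the
#' sample on the logarithmic stimulus axis:
#' \code{sample * exp(+/- 2 jnd)}. For integer-valued dimensions (dot
#' counts) set \code{round_integer = TRUE}: the result is rounded to the
#' nearest integer and bumped one step away from the sample if rounding
#' collides with it.
#'
#' @param sample_value sample stimulus value (> 0).
#' @param jnd just-noticeable difference in log units (>= 0).
#' @param direction \code{"larger"} or \code{"smaller"}.
#' @param n_jnd number of JNDs separating match from sample (default 2).
#' @param round_integer round to integer dot counts.
#' @export
match_value <- function(sample_value, jnd, direction = c("larger", "smaller"),
                        n_jnd = 2, round_integer = FALSE) {
  direction <- match.arg(direction)
  stopifnot(sample_value > 0, jnd >= 0, n_jnd > 0)
  sgn <- if (direction == "larger") 1 else -1
  v <- sample_value * exp(sgn * n_jnd * jnd)
  if (round_integer) {
    v <- round(v)
    if (v == round(sample_value)) v <- v + sgn
  }
  v
}

#' Serialise a psychometric fit summary as JSON
#'
#' Writes \code{\{mu, sigma, jnd, weber_fraction\}}.
#' @param fit a \code{psychometric_fit}.
#' @param path file path.
#' @export
write_psychometric_fit <- function(fit, path) {
  stopifnot(inherits(fit, "psychometric_fit"))
  jsonlite::write_json(list(mu = fit$mu, sigma = fit$sigma, jnd = jnd(fit),
                            weber_fraction = weber_fraction(fit)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
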