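## centered running mean (width in samples, made odd)
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Percentile-based membrane state thresholds
#'
#' From the membrane-potential histogram of a segment (normally the 2 s
#' window around one light event), defines the down-state level as the 20th
#' percentile, the up-state level as the 80th percentile, and the transition
#' level as the mean of these two potentials.
#'
#' @param vm numeric membrane-potential segment (mV).
#' @param probs percentile pair defining the down and up levels.
#' @return object of class `state_thresholds`: `down_level_mv`,
#'   `up_level_mv`, `transition_level_mv`.
#' @export
estimate_thresholds <- function(vm, probs = c(0.2, 0.8)) {
  if (!all(is.finite(vm))) stop("estimate_thresholds: vm must be finite")
  if (diff(range(vm)) < 1e-9)
    stop("estimate_thresholds: degenerate (constant) segment")
  q <- stats::quantile(vm, probs, names = FALSE, type = 7)
  structure(list(down_level_mv = q[1], up_level_mv = q[2],
                 transition_level_mv = mean(q)),
            class = "state_thresholds")
}

#' @export
print.state_thresholds <- function(x, ...) {
  cat(sprintf("state_thresholds: down %.2f / transition %.2f / up %.2f mV\n",
              x$down_level_mv, x$transition_level_mv, x$up_level_mv))
  invisible(x)
}

#' Extract light-evoked and random-control up-state latencies
#'
#' For each annotated light event, thresholds are estimated from the 2 s
#' window around that event. Only light events arriving in the down state are
#' used (roughly half at the default duty cycle); the latency is the time to
#' the first upward crossing of the transition level. For every valid light
#' latency, a control time point is drawn uniformly (seeded) within the same
#' down state up to the light onset, and its latency to the next crossing
#' recorded. Pairs in which either latency has no crossing within
#' `max_latency_s` are dropped from both lists.
#'
#' State membership and crossings are evaluated on a lightly smoothed trace
#' (centered running mean, `smooth_ms`) so that membrane noise does not
#' fragment the down state; the percentile thresholds themselves come from
#' the raw segment. Membership in the down state is judged against the
#' transition level (see the methods vignette for why the 20th-percentile
#' level is not usable as a membership cutoff).
#'
#' @param rec a `membrane_recording` with annotated `light` events.
#' @param max_latency_s drop latencies exceeding this cap (default 1 s).
#' @param window_s width of the per-event threshold window (default 2 s).
#' @param smooth_ms running-mean width for state tracking (ms).
#' @param seed RNG seed for the random control points.
#' @return a `latency_dataset` (paired) with attributes `n_light_total` and
#'   `n_in_down`. No qualifying events gives an empty dataset, not an error.
#' @export
extract_latencies <- function(rec, max_latency_s = 1, window_s = 2,
                              smooth_ms = 25, seed = NULL) {
  stopifnot(inherits(rec, "membrane_recording"))
  if (!is.null(seed)) set.seed(seed)
  fs <- rec$sampling_rate_hz
  lights <- sort(rec$events$time_s[rec$events$kind == "light"])
  sm <- running_mean(rec$vm, smooth_ms / 1000 * fs)
  n <- length(sm)
  light_lat <- numeric(); rand_lat <- numeric(); n_down <- 0L

  for (tl in lights) {
    i <- round(tl * fs) + 1
    if (i < 1 || i > n) next
    w0 <- max(1, i - round(window_s / 2 * fs))
    w1 <- min(n, i + round(window_s / 2 * fs))
    thr <- tryCatch(estimate_thresholds(rec$vm[w0:w1]), error = function(e) NULL)
    if (is.null(thr)) next
    lev <- thr$transition_level_mv
    if (sm[i] >= lev) next                      # light arrived in the up state
    n_down <- n_down + 1L
    cross <- first_crossing(sm, i, lev)
    if (is.na(cross)) next
    lat_l <- (cross - i) / fs
    ## preceding down state: contiguous sub-transition-level run containing
    ## the light onset, truncated at the onset itself
    j0 <- i
    while (j0 > 1 && sm[j0 - 1] < lev) j0 <- j0 - 1
    jr <- j0 + floor(stats::runif(1) * (i - j0 + 1))
    jr <- min(max(jr, 1L), i)
    cross_r <- first_crossing(sm, jr, lev)
    if (is.na(cross_r)) next
    lat_r <- (cross_r - jr) / fs
    ## the cap applies to the light latency (no valid light latency drops the
    ## pair); the control latency only needs an eventual crossing
    if (lat_l <= max_latency_s && lat_l > 0 && lat_r > 0) {
      light_lat <- c(light_lat, lat_l)
      rand_lat <- c(rand_lat, lat_r)
    }
  }
  out <- new_latency_dataset(light_lat, rand_lat, paired = TRUE)
  attr(out, "n_light_total") <- length(lights)
  attr(out, "n_in_down") <- n_down
  out
}

## first index > i at which x rises to >= level (NA if none)
first_crossing <- function(x, i, level) {
  idx <- which(x[(i + 1):length(x)] >= level)
  if (!length(idx)) NA_integer_ else i + idx[1]
}

#' Maximum-likelihood fit of a positive-support latency distribution
#'
#' Fits one of the candidate families (log-logistic, Weibull, lognormal,
#' gamma, exponential) by maximum likelihood and reports the Bayesian
#' information criterion `BIC = k log(n) - 2 logLik` with `k` free
#' parameters. Non-convergence is flagged, not thrown.
#'
#' @param x positive latencies (s), `n >= 5`.
#' @param family one of `"llogis"`, `"weibull"`, `"lnorm"`, `"gamma"`, `"exp"`.
#' @return object of class `dist_fit`: `family`, `params`, `loglik`, `bic`,
#'   `n`, `converged`.
#' @export
fit_distribution <- function(x, family) {
  family <- match.arg(family, c("llogis", "weibull", "lnorm", "gamma", "exp"))
  if (length(x) < 5) stop("fit_distribution: need at least 5 observations")
  if (any(x <= 0)) stop("fit_distribution: latencies must be positive")
  f <- tryCatch({
    if (family == "llogis") fit_llogis_mle(x) else fitdistrplus::fitdist(x, family)
  }, error = function(e) e)
  if (inherits(f, "error") || any(!is.finite(f$estimate)) ||
      !is.finite(f$loglik)) {
    return(structure(list(family = family, params = NULL, loglik = NA_real_,
                          bic = NA_real_, n = length(x), converged = FALSE,
                          diagnostics = if (inherits(f, "error"))
                            conditionMessage(f) else "non-finite estimate"),
                     class = "dist_fit"))
  }
  k <- length(f$estimate)
  structure(list(family = family, params = as.list(f$estimate),
                 loglik = f$loglik, bic = k * log(length(x)) - 2 * f$loglik,
                 n = length(x), converged = TRUE),
            class = "dist_fit")
}

## Direct log-logistic MLE. If X ~ log-logistic(shape b, scale s) then
## log X is logistic with location log(s) and scale 1/b, which gives robust
## moment starts; the likelihood is maximized on the unconstrained log scale.
fit_llogis_mle <- function(x) {
  start <- c(log_scale = stats::median(log(x)),
             log_shape = log(pi / (sqrt(3) * stats::sd(log(x)))))
  nll <- function(p)
    -sum(flexsurv::dllogis(x, shape = exp(p[2]), scale = exp(p[1]), log = TRUE))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0) stop("log-logistic MLE did not converge")
  list(estimate = c(shape = exp(opt$par[[2]]), scale = exp(opt$par[[1]])),
       loglik = -opt$value)
}

#' @export
print.dist_fit <- function(x, ...) {
  if (!x$converged) {
    cat("dist_fit:", x$family, "(did not converge)\n")
  } else {
    cat(sprintf("dist_fit: %s (%s)  logLik %.2f  BIC %.2f  n %d\n", x$family,
                paste(names(x$params), signif(unlist(x$params), 4),
                      sep = "=", collapse = ", "),
                x$loglik, x$bic, x$n))
  }
  invisible(x)
}

#' Convert a fitted distribution to a latency_dist
#'
#' @param fit a converged `dist_fit`.
#' @return the corresponding [latency_dist()].
#' @export
as_latency_dist <- function(fit) {
  if (inherits(fit, "latency_dist")) return(fit)
  stopifnot(inherits(fit, "dist_fit"))
  if (!fit$converged) stop("as_latency_dist: fit did not converge")
  do.call(latency_dist, c(list(fit$family), fit$params))
}

#' Rank candidate latency distributions by BIC
#'
#' Fits every candidate family and ranks the converged fits by ascending
#' BIC; ties are broken by fewer free parameters, then by the fixed family
#' order given in `families`.
#'
#' @param x positive latencies.
#' @param families candidate family names, in tie-break order.
#' @return list of `dist_fit` objects sorted best-first, with attribute
#'   `failed` listing non-converged families.
#' @export
select_distribution <- function(x, families = c("llogis", "weibull", "lnorm",
                                                "gamma", "exp")) {
  fits <- lapply(families, function(f) fit_distribution(x, f))
  ok <- vapply(fits, function(f) f$converged, TRUE)
  good <- fits[ok]
  if (!length(good)) stop("select_distribution: no family converged")
  bic <- vapply(good, function(f) f$bic, 0)
  npar <- vapply(good, function(f) length(f$params), 0L)
  ord <- order(bic, npar, match(vapply(good, `[[`, "", "family"), families))
  structure(good[ord],
            failed = vapply(fits[!ok], `[[`, "", "family"))
}

#' Kuiper's one-sample test
#'
#' Tests whether a sample was drawn from a reference continuous distribution
#' using Kuiper's statistic `V = D+ + D-`, the sum of the maximal excursions
#' of the empirical CDF above and below the reference CDF. Unlike
#' Kolmogorov--Smirnov, `V` is invariant under cyclic shifts and equally
#' sensitive in the distribution tails. The p-value uses the asymptotic
#' Kuiper series with Stephens' finite-n scaling
#' `lambda = (sqrt(n) + 0.155 + 0.24/sqrt(n)) V`; a Monte Carlo option
#' (`method = "mc"`) is recommended for very small samples (n < 30).
#'
#' @param x sample (n >= 5).
#' @param reference reference distribution: a CDF function, a
#'   [latency_dist()], or a converged `dist_fit`.
#' @param method `"asymptotic"` (default) or `"mc"`.
#' @param n_mc Monte Carlo replicates for `method = "mc"`.
#' @param seed RNG seed for the Monte Carlo null.
#' @return object of class `kuiper_result`: `statistic`, `p_value`, `n`,
#'   `method`.
#' @export
kuiper_test <- function(x, reference, method = c("asymptotic", "mc"),
                        n_mc = 2000, seed = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 5) stop("kuiper_test: need at least 5 observations")
  cdf <- if (is.function(reference)) reference else as_latency_dist(reference)$p
  u <- cdf(sort(x))
  if (any(!is.finite(u)) || any(u < -1e-12) || any(u > 1 + 1e-12))
    stop("kuiper_test: reference CDF must map the sample into [0, 1]")
  if (any(diff(u) < -1e-12))
    stop("kuiper_test: reference CDF is not monotone on the sample support")
  V <- kuiper_statistic_u(u)
  p <- switch(method,
    asymptotic = kuiper_pvalue(V, n),
    mc = {
      if (!is.null(seed)) set.seed(seed)
      null_V <- replicate(n_mc, kuiper_statistic_u(sort(stats::runif(n))))
      (1 + sum(null_V >= V)) / (n_mc + 1)
    })
  structure(list(statistic = V, p_value = p, n = n, method = method),
            class = "kuiper_result")
}

## V from sorted probability-integral-transformed sample
kuiper_statistic_u <- function(u) {
  n <- length(u)
  dplus <- max(seq_len(n) / n - u)
  dminus <- max(u - (seq_len(n) - 1) / n)
  dplus + dminus
}

## asymptotic Kuiper tail probability with Stephens' finite-n scaling
kuiper_pvalue <- function(V, n) {
  lambda <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  if (lambda < 0.4) return(1)    # series numerically 1 in this regime
  j <- 1:120
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.kuiper_result <- function(x, ...) {
  cat(sprintf("Kuiper's test: V = %.4f, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' Excess up-state probability in an expected-latency window
#'
#' The probability that an up state begins inside the expected-interval
#' window (default 60--140 ms) following a light event, over and above the
#' probability of one starting there by chance:
#' `[F_light(b) - F_light(a)] - [F_random(b) - F_random(a)]`.
#'
#' @param light_fit,random_fit fitted distributions (`dist_fit` or
#'   [latency_dist()]) of the light-evoked and random-control latencies.
#' @param window length-2 numeric window (s), default `c(0.060, 0.140)`.
#' @return scalar in `[-1, 1]`; antisymmetric under swapping the two fits.
#' @export
excess_probability <- function(light_fit, random_fit,
                               window = c(0.060, 0.140)) {
  if (length(window) != 2 || window[1] < 0 || window[2] <= window[1])
    stop("excess_probability: window must be an increasing pair within the support")
  Fl <- as_latency_dist(light_fit)$p
  Fr <- as_latency_dist(random_fit)$p
  vals <- c(Fl(window), Fr(window))
  if (any(!is.finite(vals)))
    stop("excess_probability: window outside distribution support")
  (Fl(window[2]) - Fl(window[1])) - (Fr(window[2]) - Fr(window[1]))
}
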