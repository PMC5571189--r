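#' Named positive-support latency distributions
#'
#' Builds a distribution object used throughout the latency machinery: by the
#' synthetic generator to draw light-evoked latencies, and by the fitting and
#' Kuiper-test stages as reference models. Only families with strictly
#' positive support are admitted, because latencies to an up-state transition
#' are positive by construction.
#'
#' Supported families and their parameters:
#' \describe{
#'   \item{`llogis`}{log-logistic; `shape`, `scale` (as in [flexsurv::dllogis]).}
#'   \item{`weibull`}{`shape`, `scale`.}
#'   \item{`lnorm`}{`meanlog`, `sdlog`.}
#'   \item{`gamma`}{`shape`, `rate`.}
#'   \item{`exp`}{`rate`.}
#'   \item{`point`}{degenerate point mass at `value` (> 0); useful for
#'     noiseless limiting tests.}
#' }
#'
#' @param name family name, one of the above.
#' @param ... named family parameters.
#' @return object of class `latency_dist`: a list with `name`, `params`, and
#'   vectorized `d`, `p`, `q`, `r` functions.
#' @examples
#' ld <- latency_dist("llogis", shape = 3, scale = 0.12)
#' ld$p(0.12)  # median of a log-logistic is its scale
#' @export
latency_dist <- function(name, ...) {
  params <- list(...)
  fams <- c("llogis", "weibull", "lnorm", "gamma", "exp", "point")
  name <- match.arg(name, fams)
  need <- switch(name,
    llogis  = c("shape", "scale"),
    weibull = c("shape", "scale"),
    lnorm   = c("meanlog", "sdlog"),
    gamma   = c("shape", "rate"),
    exp     = "rate",
    point   = "value")
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("latency_dist('", name, "'): missing parameter(s) ", paste(missing, collapse = ", "))
  params <- params[need]
  if (!all(vapply(params, function(p) is.numeric(p) && length(p) == 1 && is.finite(p), TRUE)))
    stop("latency_dist: all parameters must be finite scalars")
  if (name == "point" && params$value <= 0)
    stop("latency_dist('point'): point mass must sit on positive support")
  if (name != "point" && any(unlist(params) <= 0))
    stop("latency_dist('", name, "'): parameters must be positive")

  fn <- switch(name,
    llogis = list(d = flexsurv::dllogis, p = flexsurv::pllogis,
                  q = flexsurv::qllogis, r = flexsurv::rllogis),
    weibull = list(d = stats::dweibull, p = stats::pweibull,
                   q = stats::qweibull, r = stats::rweibull),
    lnorm = list(d = stats::dlnorm, p = stats::plnorm,
                 q = stats::qlnorm, r = stats::rlnorm),
    gamma = list(d = stats::dgamma, p = stats::pgamma,
                 q = stats::qgamma, r = stats::rgamma),
    exp = list(d = stats::dexp, p = stats::pexp,
               q = stats::qexp, r = stats::rexp),
    point = NULL)

  if (name == "point") {
    v <- params$value
    obj <- list(
      name = name, params = params,
      d = function(x) as.numeric(x == v),
      p = function(q) as.numeric(q >= v),
      q = function(p) rep(v, length(p)),
      r = function(n) rep(v, n))
  } else {
    obj <- list(
      name = name, params = params,
      d = function(x) do.call(fn$d, c(list(x), params)),
      p = function(q) do.call(fn$p, c(list(q), params)),
      q = function(p) do.call(fn$q, c(list(p), params)),
      r = function(n) do.call(fn$r, c(list(n), params)))
  }
  structure(obj, class = "latency_dist")
}

#' @export
print.latency_dist <- function(x, ...) {
  cat("latency_dist:", x$name, "(",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

is_latency_dist <- function(x) inherits(x, "latency_dist")
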