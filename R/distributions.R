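#' Specify a sampling distribution for simulation parameters
#'
#' Generator configurations describe random quantities (exit durations,
#' nucleolus radii, counts per nucleus, ...) as small declarative specs so
#' that every fixture states its distribution explicitly and tests can ask
#' for closed-form summaries.
#'
#' @param dist One of `"point"`, `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"poisson"`.
#' @param ... Parameters of the distribution: `value` (point), `mean`/`sd`
#'   (normal), `meanlog`/`sdlog` (lognormal), `min`/`max` (uniform),
#'   `lambda` (poisson).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", meanlog = log(21), sdlog = 0.25)
#' dist_spec("point", value = 12)
#' @export
dist_spec <- function(dist = c("point", "normal", "lognormal", "uniform", "poisson"),
                      ...) {
  dist <- match.arg(dist)
  pars <- list(...)
  required <- switch(dist,
    point = "value", normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"), uniform = c("min", "max"),
    poisson = "lambda")
  missing <- setdiff(required, names(pars))
  if (length(missing))
    stop("dist_spec('", dist, "') needs parameter(s): ",
         paste(missing, collapse = ", "))
  structure(list(dist = dist, pars = pars[required]), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$dist, "(",
      paste(names(x$pars), unlist(x$pars), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Draw samples from a distribution spec
#'
#' Sampling uses the current RNG stream; seed control lives in the calling
#' generator. `positive = TRUE` resamples non-positive draws (relevant for
#' normal specs used as radii or durations).
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param positive Enforce strictly positive samples by resampling.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, positive = FALSE) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  p <- spec$pars
  draw <- function(m) switch(spec$dist,
    point     = rep(p$value, m),
    normal    = stats::rnorm(m, p$mean, p$sd),
    lognormal = stats::rlnorm(m, p$meanlog, p$sdlog),
    uniform   = stats::runif(m, p$min, p$max),
    poisson   = stats::rpois(m, p$lambda))
  x <- draw(n)
  if (positive) {
    for (i in 1:100) {
      bad <- which(x <= 0)
      if (!length(bad)) break
      x[bad] <- draw(length(bad))
    }
    if (any(x <= 0)) stop("could not draw positive samples from spec")
  }
  x
}

#' Closed-form median of a distribution spec
#'
#' Used by tests as the analytic reference for Monte-Carlo recovery checks.
#'
#' @param spec A [dist_spec()].
#' @return The distribution median.
#' @export
dist_median <- function(spec) {
  p <- spec$pars
  switch(spec$dist,
    point     = p$value,
    normal    = p$mean,
    lognormal = exp(p$meanlog),
    uniform   = (p$min + p$max) / 2,
    poisson   = stats::qpois(0.5, p$lambda))
}

# internal: coerce EBImage results back to plain matrices
as_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}
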