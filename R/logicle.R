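#' Logicle transformation
#'
#' The logicle (biexponential) transform is the standard display/analysis
#' scale for cytometry intensities: asymptotically logarithmic for large
#' values, linear through zero, so the zero-inflated low end of mass
#' cytometry data is representable without discarding exact zeros.
#'
#' Parameterization follows the standard (Parks/Moore) definition: `t` is
#' the top of scale, `m` the total display width in asymptotic decades, `w`
#' the linearization width in decades, and `a` additional negative decades.
#' The transform maps raw intensity `x` to `y` in decade units: `y = m` at
#' `x = t`, and `y = w` at `x = 0` (with `a = 0`). The forward transform
#' inverts the closed-form biexponential numerically (grid interpolation
#' refined by Newton steps to machine precision); the inverse is closed
#' form.
#'
#' The defaults are the parameters conventionally used for HELIOS mass
#' cytometry data (w = 0.25, t = 16409, m = 4.5, a = 0).
#'
#' @param w linearization width in asymptotic decades (>= 0).
#' @param t top of scale (> 0).
#' @param m total display width in asymptotic decades (> 0).
#' @param a additional negative decades (>= 0).
#' @return `logicle_params()` returns an object of class `logicle_params`
#'   holding the biexponential coefficients.
#' @export
logicle_params <- function(w = 0.25, t = 16409, m = 4.5, a = 0) {
  if (!(t > 0)) stop("invalid logicle parameters: t must be > 0")
  if (!(m > 0)) stop("invalid logicle parameters: m must be > 0")
  if (w < 0) stop("invalid logicle parameters: w must be >= 0")
  if (a < 0) stop("invalid logicle parameters: a must be >= 0")
  if (2 * w + a > m)
    stop("invalid logicle parameters: need 2w + a <= m")
  wn <- w / (m + a)              # normalized linearization width
  x2 <- a / (m + a)
  x1 <- x2 + wn
  x0 <- x2 + 2 * wn
  b <- (m + a) * log(10)
  d <- if (wn == 0) b else {
    # root of 2(ln d - ln b) + w(b + d) = 0 on (0, b)
    g <- function(dd) 2 * (log(dd) - log(b)) + wn * (b + dd)
    stats::uniroot(g, lower = .Machine$double.xmin^0.25, upper = b,
                   tol = .Machine$double.eps^0.75)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a_coef <- t / (exp(b) - mf_a - c_a / exp(d))
  obj <- structure(
    list(w = w, t = t, m = m, a = a,
         b = b, d = d,
         A = a_coef, C = c_a * a_coef, F = -mf_a * a_coef),
    class = "logicle_params")
  # interpolation grid for fast forward transforms (refined by Newton)
  yg <- seq(-0.6, 1.1, length.out = 4096)
  obj$grid_y <- yg
  obj$grid_x <- .biexp(yg, obj)
  obj
}

# biexponential B(y) on the normalized scale y in [0, 1] and its derivative
.biexp <- function(y, p) p$A * exp(p$b * y) - p$C * exp(-p$d * y) + p$F
.biexp_d1 <- function(y, p) p$A * p$b * exp(p$b * y) + p$C * p$d * exp(-p$d * y)

#' @param x raw intensities (any real values; exact zeros map to `w`).
#' @param params a `logicle_params` object.
#' @rdname logicle_params
#' @export
logicle <- function(x, params = logicle_params()) {
  p <- params
  y <- stats::approx(p$grid_x, p$grid_y, xout = x, rule = 2)$y
  for (i in 1:20) {
    e1 <- exp(p$b * y); e2 <- exp(-p$d * y)
    f <- p$A * e1 - p$C * e2 + p$F - x
    y <- y - f / (p$A * p$b * e1 + p$C * p$d * e2)
    if (i >= 2 && max(abs(f) / (1 + abs(x))) < 1e-10) break
  }
  y * (p$m + p$a) - p$a
}

#' @param y transformed values in decade units.
#' @rdname logicle_params
#' @export
inv_logicle <- function(y, params = logicle_params()) {
  p <- params
  .biexp((y + p$a) / (p$m + p$a), p)
}

#' @export
print.logicle_params <- function(x, ...) {
  cat(sprintf("<logicle_params> w=%g t=%g m=%g a=%g\n", x$w, x$t, x$m, x$a))
  invisible(x)
}

#' Logicle-transform every channel of an event table
#'
#' Applies the logicle transform to all measurement channels. The
#' transformation state and parameters are recorded in the table metadata;
#' transforming twice is an error.
#'
#' @param table an [event_table()].
#' @param params a [logicle_params()] object.
#' @return the transformed `event_table`.
#' @export
logicle_transform <- function(table, params = logicle_params()) {
  stopifnot(inherits(table, "event_table"))
  if (isTRUE(table$meta$transformed))
    stop("event table is already logicle-transformed")
  ex <- table$exprs
  v <- as.vector(ex)
  nz <- which(v != 0)
  out <- rep(logicle(0, params), length(v))
  if (length(nz)) out[nz] <- logicle(v[nz], params)
  ex[] <- out
  table$exprs <- ex
  table$meta$transformed <- TRUE
  table$meta$logicle <- params[c("w", "t", "m", "a")]
  table
}

#' Randomize exact zeros for display
#'
#' Metal-conjugated antibodies not detected on a cell are measured as exact
#' zero; for compressed two-dimensional dot plots these zeros are
#' conventionally randomized into values strictly between -1 and 0. This is
#' a display-only convenience: all downstream statistics consume the
#' un-randomized table.
#'
#' @param values numeric vector of raw intensities.
#' @param seed integer seed; replacement values are reproducible.
#' @return `values` with every exact zero replaced by a uniform draw in
#'   (-1, 0); non-zero values are untouched.
#' @export
randomize_zeros <- function(values, seed) {
  z <- which(values == 0)
  if (!length(z)) return(values)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  repeat {
    u <- stats::runif(length(z), -1, 0)
    if (all(u > -1 & u < 0)) break
  }
  values[z] <- u
  values
}
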