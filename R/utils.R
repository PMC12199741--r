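# Shared helpers: coordinate conventions, rounding, RNG substreams.

# Meters per degree of latitude on the working sphere; longitude scales by
# cos(latitude). All meter<->degree conversions in the package go through
# these two helpers so the metric is identical in the integrator, the
# diffusion kicks and the synthetic fields.
M_PER_DEG <- 111195

deg2rad <- function(x) x * pi / 180

#' Wrap longitudes into [0, 360)
#'
#' The package works in degrees east on [0, 360) everywhere, so that domains
#' spanning the antimeridian stay contiguous.
#'
#' @param lon numeric vector of longitudes in degrees (any convention).
#' @return numeric vector in [0, 360).
#' @export
wrap_lon <- function(lon) {
  out <- lon %% 360
  # -1e-15 %% 360 can return 360 exactly; fold it back
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up to a fixed number of decimals
#' (so 7.55 -> 7.6), unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Derive a 32-bit-safe substream seed from a master seed and a stream key.
# A fixed linear congruential mix keeps streams decorrelated and makes every
# per-particle (or per-replicate) stream a pure function of (seed, key), so
# results do not depend on execution order.
substream_seed <- function(seed, key) {
  m <- 2147483647
  as.integer((as.numeric(seed) * 48271 + as.numeric(key) * 16807 + 12345) %% m)
}

# Run fn() with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = "UTC"))
  if (is.character(x)) {
    out <- suppressWarnings(as.POSIXct(x, tz = "UTC"))
    if (anyNA(out)) out <- as.POSIXct(as.Date(x), tz = "UTC")
    return(out)
  }
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  stop("cannot interpret time value", call. = FALSE)
}
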