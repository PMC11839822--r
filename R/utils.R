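#' Geometric mean
#'
#' Exponential of the mean of log-transformed values; the standard summary
#' for log-normally distributed pharmacokinetic parameters.
#'
#' @param x numeric vector of positive values. `NA`s are dropped.
#' @return the geometric mean as a length-one numeric.
#' @examples
#' geometric_mean(c(1, 100)) # 10
#' @export
geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires positive values")
  exp(mean(log(x)))
}

#' Time-unit conversions
#'
#' Concentration-time profiles are handled in days (egg collection is daily)
#' while pharmacokinetic parameters are conventionally reported in hours;
#' these helpers make the conversion explicit so the two unit systems never
#' mix silently.
#'
#' @param hours,days numeric vector of times.
#' @return numeric vector in the other unit.
#' @examples
#' hours_to_days(228.1) # 9.50 days
#' days_to_hours(6.625) # 159 hours
#' @export
hours_to_days <- function(hours) hours / 24

#' @rdname hours_to_days
#' @export
days_to_hours <- function(days) days * 24

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}
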