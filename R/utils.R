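# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Hours elapsed between two time points
#' @noRd
hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

#' Strict trailing rolling mean
#'
#' Mean over the trailing window of length `w` ending at each position; a
#' window containing any NA is itself NA (missing hours invalidate a window,
#' they never count as zero).
#' @noRd
roll_mean_strict <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cn <- cumsum(is.na(x))
  idx <- w:n
  lo_cs <- c(0, cs)[idx - w + 1]
  lo_cn <- c(0, cn)[idx - w + 1]
  ok <- (cn[idx] - lo_cn) == 0
  vals <- (cs[idx] - lo_cs) / w
  out[idx] <- ifelse(ok, vals, NA_real_)
  out
}

#' Last-observation-carried-forward lookup of a step function
#'
#' Value of the step function defined by (times, values) at each query time;
#' `default` before the first point.
#' @noRd
locf_at <- function(times, values, at, default = NA) {
  idx <- findInterval(as.numeric(at), as.numeric(times))
  out <- rep(default, length(at))
  hit <- idx > 0
  out[hit] <- values[idx[hit]]
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
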