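#' Strict local extrema of a discrete profile
#'
#' Finds strict local minima and maxima over a three-sample neighbourhood.
#' Runs of equal values (plateaus) are collapsed to a single extremum at the
#' depth-wise midpoint of the run, so positions may be half-integers. Runs
#' touching the first or last sample are never extrema.
#'
#' @param v numeric vector, all values finite.
#' @return data frame with columns `pos` (1-based, possibly fractional
#'   sample position), `value`, and `type` (`"min"` or `"max"`), ordered by
#'   position.
#' @export
local_extrema <- function(v) {
  if (!is.numeric(v) || anyNA(v) || !all(is.finite(v))) {
    stop_param("`v` must be a finite numeric vector")
  }
  ex <- extrema_core(v)
  data.frame(pos = ex$pos, value = ex$value,
             type = ifelse(ex$is_min, "min", "max"),
             stringsAsFactors = FALSE)
}

# Allocation-light workhorse shared by the per-column detection loop.
extrema_core <- function(v) {
  r <- rle(as.numeric(v))
  nr <- length(r$values)
  if (nr < 3L) {
    return(list(pos = numeric(0), value = numeric(0), is_min = logical(0)))
  }
  ends <- cumsum(r$lengths)
  mid <- ends - (r$lengths - 1) / 2
  i <- 2:(nr - 1L)
  lo <- r$values[i] < r$values[i - 1L] & r$values[i] < r$values[i + 1L]
  hi <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  keep <- lo | hi
  list(pos = mid[i][keep], value = r$values[i][keep], is_min = lo[keep])
}
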