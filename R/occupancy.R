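# Amplitude-occupancy measure and generalized (Renyi) dimensions.
#
# The amplitude range is cut into m equal-width intervals; r_j is the
# fraction of recording time the signal spends in interval j (occupancy
# time t_j over total duration T).  The generalized dimension of order c
# is D_c = H_c / ln(1/eps) with eps = 1/m, the interval width on the
# normalized amplitude axis.

#' Occupancy-time histogram of a recording
#'
#' @param record a [ts_record()] or numeric vector (then `fs = 1`).
#' @param m number of equal-width amplitude intervals (>= 1).  Intervals
#'   are half-open with the top interval closed.  A constant signal has
#'   zero amplitude range; its histogram is built on a unit-width window
#'   centered on the value, so all mass falls in one interval.
#' @return object of class `occupancy_histogram`: list with `edges`
#'   (length m + 1), `r` (probabilities), `t` (occupancy seconds), `T`
#'   (total duration), `m`.
#' @export
occupancy_histogram <- function(record, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("m must be a positive interval count")
  }
  m <- as.integer(m)
  if (inherits(record, "ts_record")) {
    x <- record$samples; fs <- record$fs
  } else {
    x <- as.numeric(record); fs <- 1
  }
  n <- length(x)
  if (n == 0L) stop("record is empty")
  lo <- min(x); hi <- max(x)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  w <- (hi - lo) / m
  idx <- pmin(1L + floor((x - lo) / w), m)   # top interval closed
  counts <- tabulate(idx, nbins = m)
  t_j <- counts / fs
  structure(list(edges = lo + w * (0:m), r = counts / n, t = t_j,
                 T = n / fs, m = m),
            class = "occupancy_histogram")
}

#' Renyi entropy of an occupancy distribution
#'
#' `H_c = ln(sum r_j^c) / (1 - c)` over the nonzero probabilities, in nats;
#' the limit at `c = 1` is the Shannon entropy `-sum r_j ln r_j`.
#'
#' @param hist an [occupancy_histogram()], or a numeric probability vector.
#' @param c entropy order, `c >= 0`.
#' @return entropy in nats (nonnegative scalar).
#' @export
renyi_entropy <- function(hist, c) {
  if (!is.numeric(c) || length(c) != 1L || c < 0) stop("order c must be >= 0")
  r <- if (inherits(hist, "occupancy_histogram")) hist$r else as.numeric(hist)
  if (any(r < 0)) stop("probabilities must be nonnegative")
  s <- sum(r)
  if (abs(s - 1) > 1e-9) stop("probabilities must sum to 1")
  r <- r[r > 0]
  if (abs(c - 1) < 1e-12) {
    -sum(r * log(r))
  } else {
    log(sum(r^c)) / (1 - c)
  }
}

#' Generalized (Renyi) dimension of a recording
#'
#' `D_c = H_c / ln(m)` where `H_c` is the Renyi entropy of the
#' amplitude-occupancy distribution over `m` intervals of width
#' `eps = 1/m` on the normalized amplitude axis.  `D_c` is non-increasing
#' in `c`; `D_0 = 1` for fully uniform occupancy and 0 for a degenerate
#' one.
#'
#' @param record a [ts_record()] or numeric vector.
#' @param c a single order (returns a scalar) or a vector of orders
#'   (returns a [generalized_spectrum()]).
#' @param m number of amplitude intervals (>= 2; at `m = 1` the
#'   normalizer `ln(1/eps)` vanishes). Default 100.
#' @return scalar `D_c`, or a `generalized_spectrum` for vector `c`.
#' @export
generalized_dimension <- function(record, c = 0, m = 100L) {
  if (m < 2) stop("m must be >= 2 (ln(1/eps) = 0 at m = 1)")
  h <- occupancy_histogram(record, m)
  if (length(c) > 1L) return(generalized_spectrum(h, orders = c))
  renyi_entropy(h, c) / log(m)
}

#' Generalized-dimension spectrum from a histogram
#'
#' @param hist an [occupancy_histogram()].
#' @param orders numeric vector of orders `c >= 0`.
#' @return object of class `generalized_spectrum`: data frame with columns
#'   `order`, `H` (nats), `D`; attribute `epsilon = 1/m`.
#' @export
generalized_spectrum <- function(hist, orders = c(0, 1, 2)) {
  stopifnot(inherits(hist, "occupancy_histogram"))
  if (hist$m < 2) stop("m must be >= 2 for a dimension spectrum")
  H <- vapply(orders, function(cc) renyi_entropy(hist, cc), numeric(1))
  out <- data.frame(order = orders, H = H, D = H / log(hist$m))
  attr(out, "epsilon") <- 1 / hist$m
  class(out) <- c("generalized_spectrum", "data.frame")
  out
}
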