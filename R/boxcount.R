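# Box-counting dimension of a signal graph.
#
# Grid convention (shared by the fast counter and the exhaustive reference
# scan, so the two agree exactly): the unit square is divided into cells
# [i*eps, (i+1)*eps) x [j*eps, (j+1)*eps), half-open, with the top and
# right edges of the square closed (points at x = 1 or y = 1 belong to the
# last cell).  A segment occupies every cell it passes through; a cell
# merely touched at a single corner point belongs to the cell the segment
# enters, except that polyline vertices always occupy their own cell.

#' Normalize a signal to a polyline in the unit square
#'
#' Time is mapped affinely to \[0, 1\]; amplitude is min-max scaled to
#' \[0, 1\].  A constant signal maps to the horizontal line y = 0.5.  The
#' box-counting dimension of the resulting graph is therefore invariant
#' under positive affine transforms of the raw amplitude.
#'
#' @param record a [ts_record()] or a numeric vector of samples.
#' @return an `n x 2` matrix (columns `x`, `y`) of polyline vertices.
#' @export
normalize_graph <- function(record) {
  y <- if (inherits(record, "ts_record")) record$samples else as.numeric(record)
  n <- length(y)
  if (n < 2L) stop("need at least 2 samples to form a graph")
  r <- range(y)
  yy <- if (r[1] == r[2]) rep(0.5, n) else (y - r[1]) / (r[2] - r[1])
  cbind(x = seq(0, 1, length.out = n), y = yy)
}

check_eps <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps > 1) {
    stop("eps must be a scalar in (0, 1]")
  }
  m <- round(1 / eps)
  if (abs(m * eps - 1) > 1e-9) {
    stop(sprintf("eps = %g does not divide the unit interval evenly", eps))
  }
  as.integer(m)
}

cell_of <- function(v, eps, m) pmin(floor(v / eps), m - 1)

#' Count grid cells occupied by a polyline
#'
#' Returns the number of cells of side `eps` intersected by the polyline.
#' Signals (strictly increasing x) take a fast per-column path: within each
#' grid column the curve is continuous, so its occupied cells are the
#' contiguous rows between the running minimum and maximum, boundary
#' crossings included.  General polylines are traversed segment by segment
#' via grid-crossing parameters.
#'
#' @param poly `n x 2` matrix of vertices inside the closed unit square.
#' @param eps box side; `1/eps` must be an integer.
#' @return integer count of occupied cells.
#' @seealso [box_count_naive()] for the exhaustive reference scan.
#' @export
box_count <- function(poly, eps) {
  m <- check_eps(eps)
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) stop("poly must have two columns (x, y)")
  if (any(poly < -1e-12) || any(poly > 1 + 1e-12)) {
    stop("polyline must lie inside the closed unit square")
  }
  n <- nrow(poly)
  if (n == 1L) return(1L)
  x <- poly[, 1]; y <- poly[, 2]
  if (all(diff(x) > 0)) {
    box_count_columns(x, y, eps, m)
  } else {
    box_count_traverse(x, y, eps, m)
  }
}

# Fast path for graphs: per grid column, rows touched = contiguous range of
# the curve's values over the half-open column.  The value at the column's
# right edge is approached but not attained (the edge point belongs to the
# next column), so when that limit value sits exactly on a row gridline it
# counts toward the row below -- matching the entered-cell corner rule of
# the segment traversal and the reference scan.
box_count_columns <- function(x, y, eps, m) {
  if (m == 1L) return(1L)
  n <- length(x)
  xb <- (1:(m - 1)) * eps
  keep <- xb > x[1] & xb <= x[n]     # boundaries the curve actually reaches
  xb <- xb[keep]
  yb <- if (length(xb)) stats::approx(x, y, xout = xb)$y else numeric(0)
  o <- order(c(x, xb))
  ya <- c(y, yb)[o]
  col <- cell_of(c(x, xb)[o], eps, m)   # nondecreasing after the sort
  ends <- c(which(diff(col) > 0L), length(col))
  starts <- c(1L, ends[-length(ends)] + 1L)
  cols <- col[starts]                   # non-empty columns, ascending
  nr <- length(starts)
  vmin <- numeric(nr); vmax <- numeric(nr)
  for (k in seq_len(nr)) {              # attained extremes per column
    rg <- range(ya[starts[k]:ends[k]])
    vmin[k] <- rg[1]; vmax[k] <- rg[2]
  }
  rmin <- cell_of(vmin, eps, m)
  rmax <- cell_of(vmax, eps, m)
  if (length(xb)) {
    # boundary at x = i*eps is the (unattained) right-edge limit of column
    # i-1; a limit value exactly on a row gridline counts toward the row
    # below (the edge point itself belongs to the next column)
    k <- match(round(xb / eps) - 1, cols)
    lim_min <- cell_of(yb, eps, m)
    on_grid <- abs(yb / eps - round(yb / eps)) < 1e-9
    lim_max <- ifelse(on_grid, pmax(round(yb / eps) - 1, 0), lim_min)
    rmin[k] <- pmin(rmin[k], lim_min)
    rmax[k] <- pmax(rmax[k], lim_max)
  }
  as.integer(sum(rmax - rmin + 1L))
}

# General path: for each segment, split [0,1] at every crossing of a grid
# line; each open sub-interval lies in one cell, identified by its midpoint.
# Vertices are added separately so endpoint-only touches count.
box_count_traverse <- function(x, y, eps, m) {
  n <- length(x)
  keys <- cell_of(x, eps, m) * m + cell_of(y, eps, m)   # vertex cells
  for (s in seq_len(n - 1L)) {
    x0 <- x[s]; y0 <- y[s]; dx <- x[s + 1L] - x0; dy <- y[s + 1L] - y0
    ts <- c(0, 1)
    if (dx != 0) {
      kr <- sort(c(x0, x0 + dx))
      lo <- ceiling(kr[1] / eps); hi <- floor(kr[2] / eps)
      if (lo <= hi) ts <- c(ts, ((lo:hi) * eps - x0) / dx)
    }
    if (dy != 0) {
      kr <- sort(c(y0, y0 + dy))
      lo <- ceiling(kr[1] / eps); hi <- floor(kr[2] / eps)
      if (lo <= hi) ts <- c(ts, ((lo:hi) * eps - y0) / dy)
    }
    ts <- sort(ts[ts > -1e-12 & ts < 1 + 1e-12])
    ts <- ts[c(TRUE, diff(ts) > 1e-12)]
    if (length(ts) > 1L) {
      tm <- (ts[-1] + ts[-length(ts)]) / 2
      keys <- c(keys, cell_of(x0 + tm * dx, eps, m) * m +
                      cell_of(y0 + tm * dy, eps, m))
    }
  }
  length(unique(keys))
}

#' Exhaustive reference box count
#'
#' Scans every grid cell and tests it against every polyline segment with a
#' direct geometric predicate (Liang-Barsky clipping plus the half-open
#' edge rules).  Quadratic in `1/eps` and meant as an independent oracle
#' for [box_count()]; both use the same grid convention and agree exactly.
#'
#' @inheritParams box_count
#' @return integer count of occupied cells.
#' @export
box_count_naive <- function(poly, eps) {
  m <- check_eps(eps)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  vi <- cell_of(x, eps, m); vj <- cell_of(y, eps, m)
  occupied <- 0L
  x0 <- x[-n]; y0 <- y[-n]; x1 <- x[-1]; y1 <- y[-1]
  dx <- x1 - x0; dy <- y1 - y0
  if (n == 1L) { x0 <- numeric(0) }
  for (i in 0:(m - 1)) {
    for (j in 0:(m - 1)) {
      if (any(vi == i & vj == j)) { occupied <- occupied + 1L; next }
      if (length(x0) == 0L) next
      lx <- i * eps; rx <- (i + 1) * eps
      ly <- j * eps; ry <- (j + 1) * eps
      # Liang-Barsky clip of each segment to the closed cell
      t0 <- rep(0, length(x0)); t1 <- rep(1, length(x0))
      clip <- function(p, q, t0, t1) {
        # p*t <= q ; update the feasible t-interval
        hit <- p != 0
        r <- ifelse(hit, q / ifelse(p == 0, 1, p), 0)
        t0n <- ifelse(hit & p < 0, pmax(t0, r), t0)
        t1n <- ifelse(hit & p > 0, pmin(t1, r), t1)
        dead <- !hit & q < 0
        t0n[dead] <- 1; t1n[dead] <- 0
        list(t0 = t0n, t1 = t1n)
      }
      cl <- clip(-dx, x0 - lx, t0, t1)
      cl <- clip(dx, rx - x0, cl$t0, cl$t1)
      cl <- clip(-dy, y0 - ly, cl$t0, cl$t1)
      cl <- clip(dy, ry - y0, cl$t0, cl$t1)
      pos <- cl$t1 - cl$t0 > 1e-12    # positive-length overlap only
      if (!any(pos)) next
      # half-open rules: a segment running exactly along the cell's right or
      # top edge belongs to the neighboring cell (unless that edge is the
      # square's boundary, which is closed)
      ok <- pos
      if (i < m - 1) ok <- ok & !(dx == 0 & x0 == rx)
      if (j < m - 1) ok <- ok & !(dy == 0 & y0 == ry)
      if (any(ok)) occupied <- occupied + 1L
    }
  }
  occupied
}

#' Dyadic scale set for box counting
#'
#' Box sides 1/2, 1/4, ..., 2^-k_max with
#' `k_max = min(floor(log2(n / 2)), cap)`: the depth is capped so that each
#' grid column still averages at least two samples, keeping counts
#' meaningful at the finest scale.
#'
#' @param n number of samples in the signal.
#' @param cap maximum dyadic depth (default 8, i.e. finest box 1/256).
#' @return numeric vector of scales, decreasing.
#' @export
dyadic_scales <- function(n, cap = 8L) {
  k_max <- min(floor(log2(n / 2)), cap)
  if (k_max < 1L) stop("signal too short for any dyadic scale")
  2^-(seq_len(k_max))
}

#' Box-count curve over a set of scales
#'
#' @param poly polyline matrix as from [normalize_graph()].
#' @param scales numeric vector of box sides (each `1/eps` an integer),
#'   e.g. [dyadic_scales()].
#' @return object of class `box_count_curve`: data frame with columns
#'   `eps` and `N`.
#' @export
box_count_curve <- function(poly, scales) {
  if (length(scales) == 0L) stop("scales must be nonempty")
  scales <- sort(unique(as.numeric(scales)), decreasing = TRUE)
  poly <- as.matrix(poly)
  ks <- -log2(scales)
  dyadic <- all(abs(ks - round(ks)) < 1e-9)
  full_graph <- nrow(poly) > 1L && all(diff(poly[, 1]) > 0) &&
    poly[1, 1] == 0 && poly[nrow(poly), 1] == 1
  N <- if (dyadic && full_graph && max(ks) >= 1) {
    box_count_pyramid(poly[, 1], poly[, 2], as.integer(round(ks)))
  } else {
    vapply(scales, function(e) as.integer(box_count(poly, e)), integer(1))
  }
  structure(data.frame(eps = scales, N = N),
            class = c("box_count_curve", "data.frame"))
}

# All dyadic levels at once for a full-span graph: per-column attained
# extremes are computed once at the finest level, then coarsened by
# pairwise min/max (the attained set of a parent column is the union of
# its children's).  Right-edge limits at every level are interpolated
# boundary values of the finest grid.  Counts agree exactly with
# box_count called per scale.
box_count_pyramid <- function(x, y, ks) {
  K <- max(ks)
  M <- 2^K
  eps_K <- 2^-K
  xb <- (1:(M - 1)) * eps_K
  yb <- stats::approx(x, y, xout = xb)$y
  o <- order(c(x, xb))
  ya <- c(y, yb)[o]
  col <- cell_of(c(x, xb)[o], eps_K, M)
  ends <- c(which(diff(col) > 0L), length(col))
  starts <- c(1L, ends[-length(ends)] + 1L)
  vmin <- numeric(M); vmax <- numeric(M)
  for (k in seq_along(starts)) {
    rg <- range(ya[starts[k]:ends[k]])
    vmin[k] <- rg[1]; vmax[k] <- rg[2]
  }
  counts <- integer(K)
  for (k in K:1) {
    m <- 2^k; eps <- 2^-k
    rmin <- cell_of(vmin, eps, m)
    rmax <- cell_of(vmax, eps, m)
    if (m > 1) {
      ybk <- yb[(1:(m - 1)) * 2^(K - k)]   # this level's right-edge limits
      i <- 1:(m - 1)
      lim_min <- cell_of(ybk, eps, m)
      on_grid <- abs(ybk / eps - round(ybk / eps)) < 1e-9
      lim_max <- ifelse(on_grid, pmax(round(ybk / eps) - 1, 0), lim_min)
      rmin[i] <- pmin(rmin[i], lim_min)
      rmax[i] <- pmax(rmax[i], lim_max)
    }
    counts[k] <- as.integer(sum(rmax - rmin + 1L))
    if (k > 1) {
      odd <- seq(1L, m, by = 2L)
      vmin <- pmin(vmin[odd], vmin[odd + 1L])
      vmax <- pmax(vmax[odd], vmax[odd + 1L])
    }
  }
  counts[ks]
}

#' Box-counting fractal dimension from a count curve
#'
#' Ordinary least-squares slope of `ln N(eps)` against `ln(1/eps)`, over
#' all scales in the curve, unweighted.  For a signal graph embedded in
#' the unit square, 1 <= D <= 2 up to estimator tolerance.
#'
#' @param curve a [box_count_curve()] (or data frame with `eps`, `N`),
#'   at least 3 scale points.
#' @return object of class `fd_estimate`: list with `D`, `slope`,
#'   `intercept`, `r_squared`, `scales_used`.
#' @export
estimate_fd <- function(curve) {
  eps <- curve$eps; N <- curve$N
  if (length(eps) < 3L) stop("need at least 3 scale points to fit a slope")
  if (any(N < 1)) stop("all box counts must be >= 1")
  lx <- log(1 / eps)
  if (stats::var(lx) == 0) stop("zero variance in log(1/eps)")
  fit <- stats::lm.fit(cbind(1, lx), log(N))
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ssr <- sum(fit$residuals^2)
  sst <- sum((log(N) - mean(log(N)))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(D = slope, slope = slope, intercept = intercept,
                 r_squared = r2, scales_used = eps),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> D = %.4f (R^2 = %.4f, %d scales)\n",
              x$D, x$r_squared, length(x$scales_used)))
  invisible(x)
}

#' Box-counting dimension of a recording in one call
#'
#' Convenience wrapper: [normalize_graph()] then [box_count_curve()] then
#' [estimate_fd()].
#'
#' @param record a [ts_record()] or numeric vector.
#' @param scales box sides; default [dyadic_scales()] for the record length.
#' @return an `fd_estimate`.
#' @export
record_fd <- function(record, scales = NULL) {
  poly <- normalize_graph(record)
  if (is.null(scales)) scales <- dyadic_scales(nrow(poly))
  estimate_fd(box_count_curve(poly, scales))
}
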