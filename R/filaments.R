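# Filament morphometry: fixed-spacing resampling, arc length, orientation
# against a reference axis, per-region summaries.

#' Resample a filament trace into fixed-spacing segments
#'
#' Places points at arc-length multiples of `spacing` along the polyline by
#' linear interpolation. A trailing remainder shorter than `spacing / 2` is
#' dropped; a remainder of at least `spacing / 2` is kept as a final short
#' segment. A trace shorter than `spacing` yields an empty segment set with
#' `short = TRUE` (the filament is still counted for length summaries).
#'
#' @param trace a [filament_trace].
#' @param spacing segment spacing in nm (default 10).
#' @return An object of class `segment_set`: list with `filament_id`,
#'   `segments` (data.frame of start/end coordinates, unit direction and
#'   length), `spacing`, and the `short` flag.
#' @export
resample <- function(trace, spacing = 10) {
  stopifnot(inherits(trace, "filament_trace"), spacing > 0)
  pts <- trace$points
  seg <- pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  L <- cum[length(cum)]
  empty <- data.frame(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                      x1 = numeric(), y1 = numeric(), z1 = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      length = numeric())
  if (L < spacing) {
    return(structure(list(filament_id = trace$id, segments = empty,
                          spacing = spacing, short = TRUE),
                     class = "segment_set"))
  }
  n_full <- floor(L / spacing)
  pos <- seq(0, n_full * spacing, by = spacing)
  rem <- L - n_full * spacing
  if (rem >= spacing / 2) pos <- c(pos, L)
  # linear interpolation of the polyline at arc positions pos
  idx <- findInterval(pos, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seglen))
  frac <- (pos - cum[idx]) / seglen[idx]
  rp <- pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  a <- rp[-nrow(rp), , drop = FALSE]
  b <- rp[-1L, , drop = FALSE]
  d <- b - a
  len <- sqrt(rowSums(d^2))
  d <- d / len
  segments <- data.frame(x0 = a[, 1], y0 = a[, 2], z0 = a[, 3],
                         x1 = b[, 1], y1 = b[, 2], z1 = b[, 3],
                         dx = d[, 1], dy = d[, 2], dz = d[, 3],
                         length = len)
  structure(list(filament_id = trace$id, segments = segments,
                 spacing = spacing, short = FALSE),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set %s> %d segments at %.1f nm spacing%s\n",
              x$filament_id, nrow(x$segments), x$spacing,
              if (x$short) " (trace shorter than spacing)" else ""))
  invisible(x)
}

#' Filament length from the resampled polyline
#'
#' Sum of consecutive-vertex Euclidean distances of the resampled polyline
#' (including a kept trailing remainder). Traces shorter than the resampling
#' spacing fall back to the raw polyline arc length so every filament is
#' counted.
#'
#' @param trace a [filament_trace].
#' @param spacing resampling spacing in nm (default 10).
#' @return length in nm.
#' @export
filament_length <- function(trace, spacing = 10) {
  ss <- resample(trace, spacing)
  if (ss$short) return(polyline_length(trace$points))
  sum(ss$segments$length)
}

#' Angles of resampled segments to a reference axis
#'
#' `angle = acos(|d . r|)` in degrees, folded to \[0, 90\] because traced
#' filaments carry no polarity. Invariant under reflection of the filament
#' and under negation of the reference axis.
#'
#' @param segs a `segment_set` from [resample()].
#' @param reference_axis non-zero 3-vector (need not be unit length).
#' @return numeric vector of angles in degrees, one per segment.
#' @export
segment_angles <- function(segs, reference_axis = c(1, 0, 0)) {
  stopifnot(inherits(segs, "segment_set"))
  nr <- sqrt(sum(reference_axis^2))
  if (!is.finite(nr) || nr == 0) stop("reference axis must be non-zero")
  r <- reference_axis / nr
  s <- segs$segments
  if (!nrow(s)) return(numeric(0))
  dotp <- abs(s$dx * r[1] + s$dy * r[2] + s$dz * r[3])
  acos(pmin(1, dotp)) * 180 / pi
}

#' Estimate a reference axis as the principal axis of a point cloud
#'
#' Convenience helper for choosing the neuron's longitudinal axis from
#' supplied landmark points (e.g. microtubule picks): the leading
#' eigenvector of the coordinate covariance.
#'
#' @param points n x 3 matrix of points.
#' @return unit 3-vector.
#' @export
estimate_reference_axis <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L)
  ev <- eigen(stats::cov(points), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  v / sqrt(sum(v^2))
}

#' Per-region filament statistics
#'
#' Median and interquartile range of filament lengths per region (linear
#' interpolation between order statistics, R's type-7 quantile rule) and an
#' angle histogram of all resampled segments against the reference axis.
#'
#' @param traces list of [filament_trace] objects (>= 1).
#' @param reference_axis reference axis for segment angles.
#' @param spacing resampling spacing in nm.
#' @param bin_width angle histogram bin width in degrees (default 10).
#' @return An object of class `filament_stats`: list with `stats`
#'   (per-region data.frame: n, median, q1, q3, iqr, n_segments, n_short),
#'   `lengths` (per-filament data.frame), and `angle_hist` (per-region
#'   data.frame of bin edges and counts).
#' @export
summarize_filaments <- function(traces, reference_axis = c(1, 0, 0),
                                spacing = 10, bin_width = 10) {
  stopifnot(length(traces) >= 1L)
  lengths_df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(id = tr$id, region = tr$region,
               length = filament_length(tr, spacing),
               stringsAsFactors = FALSE)
  }))
  breaks <- seq(0, 90, by = bin_width)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  regions <- unique(lengths_df$region)
  stats_rows <- list(); hist_rows <- list()
  for (rg in regions) {
    sel <- which(lengths_df$region == rg)
    vals <- lengths_df$length[sel]
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    angs <- unlist(lapply(traces[sel], function(tr) {
      segment_angles(resample(tr, spacing), reference_axis)
    }))
    n_short <- sum(vapply(traces[sel],
                          function(tr) resample(tr, spacing)$short, logical(1)))
    # left-closed bins; include.lowest keeps exact-90 angles in the last bin
    h <- if (length(angs))
      hist(angs, breaks = breaks, plot = FALSE, include.lowest = TRUE,
           right = FALSE)$counts
    else integer(length(breaks) - 1L)
    stats_rows[[rg]] <- data.frame(region = rg, n = length(vals),
                                   median_length = q[2], q1 = q[1], q3 = q[3],
                                   iqr = q[3] - q[1],
                                   n_segments = length(angs),
                                   n_short = n_short,
                                   stringsAsFactors = FALSE)
    hist_rows[[rg]] <- data.frame(region = rg,
                                  bin_lo = breaks[-length(breaks)],
                                  bin_hi = breaks[-1L],
                                  count = h, stringsAsFactors = FALSE)
  }
  structure(list(stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
                 lengths = lengths_df,
                 angle_hist = do.call(rbind, c(hist_rows,
                                               make.row.names = FALSE))),
            class = "filament_stats")
}

#' @export
print.filament_stats <- function(x, ...) {
  cat("<filament_stats>\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}
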