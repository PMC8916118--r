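#' Read an ASCII point file of traced contours
#'
#' Parses the 5-column ASCII dialect produced by converting annotation model
#' files to points (`object contour x y z`, whitespace-separated, coordinates
#' in pixels). Records of one contour must be consecutive and ordered.
#' Pixel coordinates are converted to nm via `voxel_size / 10`; contours with
#' two or more points become filament traces and single-point contours are
#' collected into a particle set.
#'
#' @param path path to the point file.
#' @param voxel_size pixel size in Angstrom (> 0) of the coordinate frame the
#'   points were picked in (binned or unbinned -- the caller decides).
#' @param region region label attached to the resulting objects.
#' @return A list with elements `traces` (list of [filament_trace] objects)
#'   and `particles` (a [particle_set] or `NULL` if there were no
#'   single-point contours).
#' @export
read_point_file <- function(path, voxel_size, region = "mature_branch") {
  if (!file.exists(path)) stop("point file not found: ", path)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (Angstrom)")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- matrix(NA_real_, nrow = sum(keep), ncol = 5L)
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 5L || anyNA(vals))
      stop(sprintf("malformed point-file line %d: '%s' (expected 5 numeric fields)",
                   i, lines[i]))
    j <- j + 1L
    rows[j, ] <- vals
  }
  if (j == 0L) return(list(traces = list(), particles = NULL))
  obj <- as.integer(rows[, 1]); ctr <- as.integer(rows[, 2])
  if (any(obj < 1L) || any(ctr < 1L))
    stop("object and contour ids must be >= 1")
  xyz_nm <- rows[, 3:5, drop = FALSE] * (voxel_size / 10)
  key <- paste(obj, ctr, sep = "_")
  groups <- split(seq_len(j), factor(key, levels = unique(key)))
  traces <- list()
  pts_single <- NULL
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) >= 2L) {
      traces[[length(traces) + 1L]] <-
        filament_trace(xyz_nm[idx, , drop = FALSE], region = region, id = g)
    } else {
      pts_single <- rbind(pts_single, xyz_nm[idx, , drop = FALSE])
    }
  }
  particles <- if (!is.null(pts_single))
    particle_set(pts_single, region = region) else NULL
  list(traces = traces, particles = particles)
}

#' Write traces and particles to an ASCII point file
#'
#' Inverse of [read_point_file()]: nm coordinates are converted back to pixel
#' units via `10 / voxel_size` and written as the 5-column
#' `object contour x y z` dialect, one contour per trace (particles are
#' single-point contours of a final extra object).
#'
#' @param traces list of [filament_trace] objects (may be empty).
#' @param path output path.
#' @param voxel_size pixel size in Angstrom used for the nm -> pixel
#'   conversion.
#' @param particles optional [particle_set] appended as single-point contours.
#' @export
write_point_file <- function(traces, path, voxel_size, particles = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  scale <- 10 / voxel_size
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(o, c, m) {
    sprintf("%d %d %.9g %.9g %.9g", o, c, m[, 1], m[, 2], m[, 3])
  }
  out <- character(0)
  for (i in seq_along(traces)) {
    out <- c(out, fmt(1L, i, traces[[i]]$points * scale))
  }
  if (!is.null(particles)) {
    px <- particles$coords * scale
    for (k in seq_len(nrow(px)))
      out <- c(out, fmt(2L, k, px[k, , drop = FALSE]))
  }
  writeLines(out, con)
  invisible(path)
}

# --- MRC2014 (mode 2) volumes ------------------------------------------------

#' Read an MRC2014 volume (mode 2)
#'
#' Minimal reader for the MRC2014 container restricted to mode 2 (32-bit
#' IEEE float), little-endian. The voxel size is taken as the ratio of the
#' cell dimension to the grid sampling (`cella / mx`).
#'
#' @param path path to the MRC file.
#' @return A [tomo_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  mode <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float, is supported)")
  readBin(con, "integer", 3L, size = 4L, endian = "little")      # nxstart..
  mxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")      # cellb
  readBin(con, "integer", 3L, size = 4L, endian = "little")      # mapc/mapr/maps
  readBin(con, "numeric", 3L, size = 4L, endian = "little")      # dmin/dmax/dmean
  readBin(con, "integer", 1L, size = 4L, endian = "little")      # ispg
  nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 25L, size = 4L, endian = "little")     # extra
  origin <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  seek(con, 1024 + max(0L, nsymbt))
  n <- prod(nxyz)
  data <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(data) < n)
    stop("truncated MRC file: expected ", n, " voxels, got ", length(data))
  vs <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  tomo_volume(array(data, dim = nxyz), voxel_size = vs, origin = origin)
}

#' Write a volume as MRC2014 mode 2
#'
#' @param volume a [tomo_volume].
#' @param path output path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "tomo_volume"))
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2
  wi(c(0L, 0L, 0L))           # nxstart
  wi(d)                       # mx my mz
  wf(d * volume$voxel_size)   # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(volume$data), max(volume$data), mean(volume$data)))
  wi(0L)                      # ispg
  wi(0L)                      # nsymbt
  wi(integer(25L))            # extra
  wf(volume$origin)           # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(volume$data))  # rms
  wi(0L)                      # nlabl
  writeBin(raw(800L), con)    # labels
  # mode-2 data: stored as float32 (round-trip is exact for float32 payloads)
  writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  invisible(path)
}

# --- measurement CSV ---------------------------------------------------------

#' Read a measurement table from CSV
#'
#' Expects a header with columns `structure, region, value` (a `source`
#' column is optional). Vocabulary and positivity are validated; an empty
#' data section yields an empty table.
#'
#' @param path path to a comma-separated, UTF-8, "."-decimal CSV file.
#' @return A [measurement_table].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("structure", "region", "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("measurement CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(df$source)) df$source <- ""
  validate_measurement_table(df[, c("structure", "region", "value", "source")])
}

#' Write a measurement table to CSV
#'
#' @param table a [measurement_table].
#' @param path output path.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
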