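#' @useDynLib tomomorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft pnorm rnorm runif rlnorm sd median quantile var
#' @importFrom utils read.csv write.csv head combn
#' @importFrom graphics hist
NULL

#' Closed vocabulary of anatomical regions
#'
#' Region labels used throughout: mature branches (microtubule-invaded),
#' premature branches (actin-filopodial, no microtubules), axon shafts,
#' growth cones and dendrites.
#' @export
REGIONS <- c("mature_branch", "premature_branch", "shaft",
             "growth_cone", "dendrite")

#' Closed vocabulary of measured structures
#' @export
STRUCTURES <- c("mitochondrion", "er_tube", "er_wrap", "actin", "other")

#' Construct a filament trace
#'
#' An ordered 3D polyline (in nm) representing one manually traced filament.
#'
#' @param points numeric matrix with >= 2 rows and 3 columns (x, y, z in nm).
#' @param region region label, one of [REGIONS].
#' @param id identifier (coerced to character).
#' @return An object of class `filament_trace`.
#' @export
filament_trace <- function(points, region = "mature_branch", id = "f1") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("a filament trace needs >= 2 points with 3 coordinates each")
  if (!all(is.finite(points)))
    stop("filament trace coordinates must be finite")
  steps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(steps == 0))
    stop("consecutive points of a filament trace must be distinct")
  region <- match.arg(region, REGIONS)
  structure(list(points = points, region = region, id = as.character(id)),
            class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("<filament_trace %s> %d vertices, region %s, arc length %.1f nm\n",
              x$id, nrow(x$points), x$region, polyline_length(x$points)))
  invisible(x)
}

#' Construct a particle set
#'
#' Picked particle coordinates in nm, with optional per-particle ZXZ Euler
#' orientations (degrees) and a region label.
#'
#' @param coords numeric matrix, n x 3, coordinates in nm.
#' @param orientations optional n x 3 matrix of ZXZ Euler angles (degrees).
#' @param region region label, one of [REGIONS].
#' @param tomogram_id identifier of the source tomogram.
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(coords, orientations = NULL,
                         region = "mature_branch", tomogram_id = "t1") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) < 1L)
    stop("coords must be an n x 3 matrix with n >= 1")
  if (!all(is.finite(coords))) stop("particle coordinates must be finite")
  if (!is.null(orientations)) {
    orientations <- as.matrix(orientations)
    if (!identical(dim(orientations), c(nrow(coords), 3L)))
      stop("orientations must be one ZXZ Euler triple per particle")
  }
  region <- match.arg(region, REGIONS)
  structure(list(coords = coords, orientations = orientations,
                 region = region, tomogram_id = as.character(tomogram_id)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, region %s, tomogram %s%s\n",
              nrow(x$coords), x$region, x$tomogram_id,
              if (is.null(x$orientations)) "" else ", oriented"))
  invisible(x)
}

#' Construct a density volume
#'
#' A 3D real-valued grid with its voxel size in Angstrom. Coordinates are
#' 0-based voxel-centre positions: physical position = index * voxel_size.
#'
#' @param data 3D numeric array, all dimensions >= 2.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical origin in Angstrom (3-vector).
#' @return An object of class `tomo_volume`.
#' @export
tomo_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("all three grid dimensions must be >= 2")
  if (!all(is.finite(data))) stop("volume data must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (Angstrom)")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "tomo_volume")
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels at %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' Construct a measurement table
#'
#' Per-structure scalar measurements (lengths or diameters, in nm) with
#' structure and region labels drawn from closed vocabularies.
#'
#' @param structure character vector of structure labels (see [STRUCTURES]).
#' @param region character vector of region labels (see [REGIONS]).
#' @param value positive measurements in nm.
#' @param source free-text provenance (e.g. "cryo_et", "light_microscopy").
#' @return A data.frame of class `measurement_table`.
#' @export
measurement_table <- function(structure = character(), region = character(),
                              value = numeric(), source = "") {
  df <- data.frame(structure = as.character(structure),
                   region = as.character(region),
                   value = as.numeric(value),
                   source = rep_len(as.character(source),
                                    length.out = length(structure)),
                   stringsAsFactors = FALSE)
  validate_measurement_table(df)
}

validate_measurement_table <- function(df) {
  required <- c("structure", "region", "value", "source")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "))
  bad_s <- setdiff(unique(df$structure), STRUCTURES)
  if (length(bad_s))
    stop("unknown structure label(s) ", paste(bad_s, collapse = ", "),
         "; allowed: ", paste(STRUCTURES, collapse = ", "))
  bad_r <- setdiff(unique(df$region), REGIONS)
  if (length(bad_r))
    stop("unknown region label(s) ", paste(bad_r, collapse = ", "),
         "; allowed: ", paste(REGIONS, collapse = ", "))
  if (nrow(df) && any(!is.finite(df$value) | df$value <= 0))
    stop("measurement values must be positive and finite (nm)")
  class(df) <- c("measurement_table", "data.frame")
  df
}

# arc length of a polyline given as an n x 3 matrix
polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums((points[-1L, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}
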