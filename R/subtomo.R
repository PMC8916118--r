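# Minimal subtomogram-averaging engine: exhaustive coarse-to-fine rigid
# alignment with FFT translation search under a missing-wedge mask, odd/even
# half-set averaging with Fourier-coverage normalization, FSC resolution
# estimation and adaptive bandpass filtering.

#' Rotate (and shift) a volume by a rigid transform
#'
#' Trilinear real-space resampling about the FFT-consistent centre
#' `floor(dim/2)`: the output equals the input rotated by `R` and then
#' translated by `shift` (voxels). Out-of-bounds samples are zero.
#'
#' @param data 3D array.
#' @param R 3 x 3 rotation matrix.
#' @param shift length-3 translation in voxels.
#' @return 3D array of the same dimensions.
#' @export
rotate_volume <- function(data, R, shift = c(0, 0, 0)) {
  d <- dim(data)
  out <- rotate_trilinear(as.numeric(data), as.integer(d), t(R),
                          as.numeric(shift))
  array(out, dim = d)
}

# fftshift / inverse for 3D arrays (even dimensions)
fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

# signed integer frequency index along one dimension of length n (even)
freq_index <- function(n) c(0:(n / 2 - 1), -(n / 2):-1)

# 3D arrays of kx, ky, kz in fft (unshifted) layout
freq_grids <- function(d) {
  kx <- array(freq_index(d[1]), dim = d)
  ky <- aperm(array(freq_index(d[2]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  kz <- aperm(array(freq_index(d[3]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  list(kx = kx, ky = ky, kz = kz)
}

#' Low-pass filter a volume at a target resolution
#'
#' Radial Fourier mask with a raised-cosine edge (2 Fourier voxels wide)
#' centred at the target frequency `1 / resolution`.
#'
#' @param data 3D array.
#' @param voxel_size voxel size in Angstrom.
#' @param resolution cutoff resolution in Angstrom.
#' @return filtered 3D array.
#' @export
lowpass_volume <- function(data, voxel_size, resolution) {
  d <- dim(data)
  k <- freq_grids(d)
  r <- sqrt(k$kx^2 + k$ky^2 + k$kz^2)
  r0 <- d[1] * voxel_size / resolution   # cutoff radius in Fourier voxels
  edge <- 2
  w <- ifelse(r <= r0, 1,
              ifelse(r >= r0 + edge, 0,
                     0.5 * (1 + cos(pi * (r - r0) / edge))))
  Re(fft(fft(data) * w, inverse = TRUE)) / length(data)
}

# quasi-uniform grid of ZXZ Euler triples at the given angular step:
# theta rows at `step`, phi sampling scaled by sin(theta), full psi rows
euler_grid <- function(step) {
  thetas <- seq(0, 180, by = step)
  psis <- seq(0, 360 - step, by = step)
  out <- list()
  for (th in thetas) {
    nphi <- max(1L, ceiling(360 * sin(th * pi / 180) / step))
    phis <- seq(0, 360, length.out = nphi + 1L)[seq_len(nphi)]
    for (ph in phis) out[[length(out) + 1L]] <- c(ph, th, psis)
  }
  # expand psi rows into triples
  do.call(rbind, lapply(out, function(row) {
    cbind(phi = row[1], theta = row[2], psi = row[-(1:2)])
  }))
}

# Build a closure that scores one rotation of the reference against a fixed
# particle: normalized cross-correlation under the wedge mask, translation
# as the FFT cross-correlation argmax constrained to shift_radius, with
# parabolic (subvoxel) refinement of the peak along each axis.
make_cc_scorer <- function(particle_data, reference_data, W, shift_radius) {
  d <- dim(particle_data)
  k <- freq_grids(d)
  shift_ok <- (k$kx^2 + k$ky^2 + k$kz^2) <= shift_radius^2 + 1e-9
  shift_idx <- which(shift_ok)
  Fp <- fft(particle_data); Fp[1] <- 0
  FpW <- Fp * W
  norm_p <- sqrt(sum(Mod(FpW)^2))
  function(R) {
    rot <- rotate_volume(reference_data, R)
    Fr <- fft(rot); Fr[1] <- 0
    FrW <- Fr * W
    norm_r <- sqrt(sum(Mod(FrW)^2))
    if (norm_r == 0 || norm_p == 0)
      return(list(score = -1, shift = c(0, 0, 0)))
    cc <- Re(fft(FpW * Conj(FrW), inverse = TRUE)) / (norm_p * norm_r)
    best <- shift_idx[which.max(cc[shift_idx])]
    ijk <- arrayInd(best, d)
    shift <- c(k$kx[best], k$ky[best], k$kz[best])
    # parabolic peak interpolation per axis (wrapped neighbours)
    for (ax in 1:3) {
      lo <- ijk; hi <- ijk
      lo[ax] <- (ijk[ax] - 2L) %% d[ax] + 1L
      hi[ax] <- ijk[ax] %% d[ax] + 1L
      cm <- cc[lo]; c0 <- cc[best]; cp <- cc[hi]
      denom <- cm - 2 * c0 + cp
      if (denom < 0) {
        off <- 0.5 * (cm - cp) / denom
        shift[ax] <- shift[ax] + max(-0.5, min(0.5, off))
      }
    }
    list(score = cc[best], shift = shift)
  }
}

# resolve a wedge argument (NULL / half-angle / mask array) to a mask array
resolve_wedge <- function(wedge, d) {
  if (is.null(wedge)) return(array(1, dim = d))
  if (is.numeric(wedge) && length(wedge) == 1L) return(wedge_mask(d[1], wedge))
  stopifnot(identical(dim(wedge), d))
  wedge
}

#' Align a particle volume to a reference
#'
#' Exhaustive search over a quasi-uniform ZXZ Euler grid at the first
#' angular step, followed by local 3^3 refinement at each subsequent step.
#' For every rotation the translation is the argmax of the FFT
#' cross-correlation constrained to `shift_radius` voxels; correlation is a
#' normalized cross-correlation computed under the missing-wedge mask (both
#' volumes are zero-meaned in Fourier space).
#'
#' @param particle,reference [tomo_volume] objects with equal box sizes.
#' @param angular_steps vector of angular steps in degrees; the first is the
#'   global grid step, later entries are local refinement steps.
#' @param shift_radius maximum shift in voxels (default box/8).
#' @param wedge missing-wedge specification: `NULL` (none), a half-angle in
#'   degrees, or a 0/1 Fourier mask array.
#' @param n_candidates number of top-scoring global-grid orientations kept
#'   and refined through the full schedule (guards against narrow
#'   correlation basins missed by the coarse grid).
#' @return An object of class `orientation`: list with `euler` (phi, theta,
#'   psi in degrees), `R`, `shift` (voxels) and `score` (normalized
#'   cross-correlation in \[-1, 1\]).
#' @export
align <- function(particle, reference, angular_steps = c(20, 10, 5, 2),
                  shift_radius = NULL, wedge = NULL, n_candidates = 6) {
  stopifnot(inherits(particle, "tomo_volume"),
            inherits(reference, "tomo_volume"))
  d <- dim(particle$data)
  if (!identical(d, dim(reference$data)))
    stop("particle and reference box sizes differ")
  stopifnot(all(angular_steps > 0))
  if (is.null(shift_radius)) shift_radius <- d[1] / 8
  W <- resolve_wedge(wedge, d)
  score_rot <- make_cc_scorer(particle$data, reference$data, W, shift_radius)

  grid <- euler_grid(angular_steps[1])
  scores <- numeric(nrow(grid))
  shifts <- matrix(0, nrow(grid), 3L)
  for (g in seq_len(nrow(grid))) {
    eul <- grid[g, ]
    res <- score_rot(euler_to_matrix(eul[1], eul[2], eul[3]))
    scores[g] <- res$score
    shifts[g, ] <- res$shift
  }
  top <- order(scores, decreasing = TRUE)[seq_len(min(n_candidates,
                                                      nrow(grid)))]
  best <- list(score = -Inf)
  for (cand in top) {
    cur <- list(score = scores[cand], euler = grid[cand, ],
                shift = shifts[cand, ])
    for (s in angular_steps[-1]) {
      offs <- expand.grid(dp = c(-s, 0, s), dt = c(-s, 0, s),
                          ds = c(-s, 0, s))
      for (o in seq_len(nrow(offs))) {
        if (all(offs[o, ] == 0)) next
        eul <- cur$euler + as.numeric(offs[o, ])
        res <- score_rot(euler_to_matrix(eul[1], eul[2], eul[3]))
        if (res$score > cur$score)
          cur <- list(score = res$score, euler = eul, shift = res$shift)
      }
    }
    if (cur$score > best$score) best <- cur
  }
  structure(list(euler = c(phi = unname(best$euler[1]),
                           theta = unname(best$euler[2]),
                           psi = unname(best$euler[3])),
                 R = euler_to_matrix(best$euler[1], best$euler[2],
                                     best$euler[3]),
                 shift = best$shift, score = best$score),
            class = "orientation")
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf(
    "<orientation> phi %.1f theta %.1f psi %.1f deg, shift (%g, %g, %g) vox, score %.3f\n",
    x$euler[1], x$euler[2], x$euler[3], x$shift[1], x$shift[2], x$shift[3],
    x$score))
  invisible(x)
}

# local refinement of an existing orientation (used by later iterations)
refine_orientation <- function(particle, reference, orientation, steps,
                               shift_radius, wedge) {
  d <- dim(particle$data)
  W <- resolve_wedge(wedge, d)
  score_rot <- make_cc_scorer(particle$data, reference$data, W, shift_radius)
  r0 <- score_rot(orientation$R)
  best <- list(score = r0$score, euler = orientation$euler, shift = r0$shift)
  for (s in steps) {
    offs <- expand.grid(dp = c(-s, 0, s), dt = c(-s, 0, s), ds = c(-s, 0, s))
    for (o in seq_len(nrow(offs))) {
      if (all(offs[o, ] == 0)) next
      eul <- best$euler + as.numeric(offs[o, ])
      res <- score_rot(euler_to_matrix(eul[1], eul[2], eul[3]))
      if (res$score > best$score)
        best <- list(score = res$score, euler = eul, shift = res$shift)
    }
  }
  structure(list(euler = c(phi = unname(best$euler[1]),
                           theta = unname(best$euler[2]),
                           psi = unname(best$euler[3])),
                 R = euler_to_matrix(best$euler[1], best$euler[2],
                                     best$euler[3]),
                 shift = best$shift, score = best$score),
            class = "orientation")
}

#' Fourier shell correlation between two volumes
#'
#' Per radial shell (1 Fourier voxel wide):
#' `Re(sum(Fa * conj(Fb))) / sqrt(sum |Fa|^2 * sum |Fb|^2)`.
#'
#' @param a,b [tomo_volume] objects with identical dimensions and voxel size.
#' @return An object of class `fsc_curve`: data.frame with `shell`, `freq`
#'   (1/Angstrom), `fsc` and `n_voxels`, shells 0..box/2.
#' @export
compute_fsc <- function(a, b) {
  stopifnot(inherits(a, "tomo_volume"), inherits(b, "tomo_volume"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("volume dimensions differ")
  if (abs(a$voxel_size - b$voxel_size) > 1e-9)
    stop("voxel sizes differ")
  d <- dim(a$data)
  k <- freq_grids(d)
  rad <- as.integer(round(sqrt(k$kx^2 + k$ky^2 + k$kz^2)))
  nshell <- d[1] %/% 2
  keep <- rad <= nshell
  Fa <- fft(a$data); Fb <- fft(b$data)
  shell_f <- factor(rad[keep], levels = 0:nshell)
  num <- tapply(Re(Fa[keep] * Conj(Fb[keep])), shell_f, sum)
  da <- tapply(Mod(Fa[keep])^2, shell_f, sum)
  db <- tapply(Mod(Fb[keep])^2, shell_f, sum)
  nvox <- as.integer(table(shell_f))
  denom <- sqrt(da * db)
  fsc <- ifelse(denom > 0, num / denom, 0)
  structure(data.frame(shell = 0:nshell,
                       freq = (0:nshell) / (d[1] * a$voxel_size),
                       fsc = as.numeric(fsc), n_voxels = nvox),
            class = c("fsc_curve", "data.frame"))
}

#' Resolution at an FSC threshold crossing
#'
#' Frequency of the first downward crossing of `threshold`, found by linear
#' interpolation between adjacent shells; resolution is its reciprocal in
#' Angstrom. The zero-frequency shell is excluded (its correlation is just
#' the sign of the product of the two means). If the curve already starts
#' below the threshold at the first non-zero shell the resolution is not
#' reached (`NA`). If the curve never drops below the threshold the estimate
#' is Nyquist-limited and `2 * voxel_size` is returned with attribute
#' `nyquist_limited = TRUE`.
#'
#' @param curve an `fsc_curve` from [compute_fsc()].
#' @param threshold FSC threshold in (0, 1) (commonly 0.143 or 0.5).
#' @param voxel_size voxel size in Angstrom (for the Nyquist sentinel).
#' @return resolution in Angstrom (possibly `NA`).
#' @export
resolution_at <- function(curve, threshold, voxel_size) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  keep <- curve$freq > 0
  f <- curve$fsc[keep]; fr <- curve$freq[keep]
  if (!length(f)) stop("empty FSC curve")
  if (f[1] < threshold) return(NA_real_)
  for (i in seq_len(length(f) - 1L)) {
    if (f[i] >= threshold && f[i + 1L] < threshold) {
      fx <- fr[i] + (f[i] - threshold) / (f[i] - f[i + 1L]) *
        (fr[i + 1L] - fr[i])
      return(1 / fx)
    }
  }
  out <- 2 * voxel_size
  attr(out, "nyquist_limited") <- TRUE
  out
}

#' Iterative subtomogram alignment and half-set averaging
#'
#' Per iteration: align all particles to the current reference (global grid
#' search in the first iteration, local refinement of the previous
#' orientations afterwards); split particles by index parity into odd and
#' even half-sets; average each half with per-voxel Fourier-coverage
#' normalization (sum of rotated binary wedge masks, floor-clamped at 1);
#' compute the FSC between the half-averages; low-pass both halves at the
#' current FSC-0.143 resolution before the next iteration (adaptive
#' bandpass). The final average is the sum of the two half-averages.
#'
#' @param particles list of >= 4 [tomo_volume] objects (equal boxes).
#' @param initial_reference a [tomo_volume]; low-pass filtered to
#'   `lowpass_start` before the first iteration.
#' @param n_iter number of iterations.
#' @param schedule list of angular-step vectors, one per iteration
#'   (default: `c(30, 15)` globally, then halving local refinements).
#' @param wedge missing-wedge specification (see [align()]).
#' @param shift_radius maximum shift in voxels (default box/8).
#' @param lowpass_start initial reference low-pass resolution in Angstrom.
#' @return list with `average` ([tomo_volume]), `half1`, `half2`,
#'   `orientations` (data.frame per particle), `fsc` (list of `fsc_curve`
#'   per iteration), `resolution_0143` and `resolution_05` (vectors per
#'   iteration, Angstrom).
#' @export
iterate_average <- function(particles, initial_reference, n_iter = 2,
                            schedule = NULL, wedge = 30,
                            shift_radius = NULL, lowpass_start = 100) {
  stopifnot(length(particles) >= 4L)
  d <- dim(particles[[1]]$data)
  vs <- particles[[1]]$voxel_size
  for (p in particles)
    if (!identical(dim(p$data), d)) stop("all particle boxes must match")
  if (!identical(dim(initial_reference$data), d))
    stop("reference box size differs from particles")
  if (is.null(shift_radius)) shift_radius <- d[1] / 8
  if (is.null(schedule)) {
    schedule <- vector("list", n_iter)
    schedule[[1]] <- c(30, 15)
    if (n_iter > 1)
      for (i in 2:n_iter) schedule[[i]] <- c(15, 7.5) / 2^(i - 2)
  }
  W <- resolve_wedge(wedge, d)
  Wshift <- fftshift3(W)  # centred layout for rotating the coverage mask
  np <- length(particles)
  ref <- tomo_volume(lowpass_volume(initial_reference$data, vs,
                                    lowpass_start), vs)
  orientations <- vector("list", np)
  fsc_list <- list(); res143 <- numeric(0); res05 <- numeric(0)
  half_avgs <- NULL
  for (it in seq_len(n_iter)) {
    for (i in seq_len(np)) {
      orientations[[i]] <- if (it == 1L)
        align(particles[[i]], ref, angular_steps = schedule[[1]],
              shift_radius = shift_radius, wedge = W)
      else
        refine_orientation(particles[[i]], ref, orientations[[i]],
                           steps = schedule[[it]],
                           shift_radius = shift_radius, wedge = W)
    }
    scores <- vapply(orientations, function(o) o$score, numeric(1))
    if (all(scores <= 0))
      stop("alignment failed: all cross-correlations <= 0 at iteration ", it,
           " (best score ", sprintf("%.3f", max(scores)), ")")
    halves <- list(seq(1, np, by = 2), seq(2, np, by = 2))
    half_data <- vector("list", 2L)
    for (h in 1:2) {
      Fsum <- array(0 + 0i, dim = d)
      Cov <- array(0, dim = d)
      for (i in halves[[h]]) {
        o <- orientations[[i]]
        back <- rotate_volume(particles[[i]]$data, t(o$R),
                              shift = as.numeric(-crossprod(o$R, o$shift)))
        Fsum <- Fsum + fft(back)
        wrot <- rotate_volume(Wshift, t(o$R))
        Cov <- Cov + (wrot >= 0.5)
      }
      Cov <- fftshift3(Cov)           # back to fft layout
      Favg <- Fsum / pmax(Cov, 1)
      half_data[[h]] <- Re(fft(Favg, inverse = TRUE)) / length(Favg)
    }
    h1 <- tomo_volume(half_data[[1]], vs)
    h2 <- tomo_volume(half_data[[2]], vs)
    curve <- compute_fsc(h1, h2)
    fsc_list[[it]] <- curve
    r143 <- resolution_at(curve, 0.143, vs)
    r05 <- resolution_at(curve, 0.5, vs)
    res143 <- c(res143, as.numeric(r143))
    res05 <- c(res05, as.numeric(r05))
    half_avgs <- list(h1, h2)
    # adaptive bandpass: carry only frequencies supported at this iteration
    if (!is.na(r143)) {
      h1f <- lowpass_volume(h1$data, vs, as.numeric(r143))
      h2f <- lowpass_volume(h2$data, vs, as.numeric(r143))
      ref <- tomo_volume(h1f + h2f, vs)
    } else {
      ref <- tomo_volume(h1$data + h2$data, vs)
    }
  }
  ori_df <- do.call(rbind, lapply(seq_len(np), function(i) {
    o <- orientations[[i]]
    data.frame(particle = i, phi = o$euler[1], theta = o$euler[2],
               psi = o$euler[3], sx = o$shift[1], sy = o$shift[2],
               sz = o$shift[3], score = o$score)
  }))
  rownames(ori_df) <- NULL
  list(average = tomo_volume(half_avgs[[1]]$data + half_avgs[[2]]$data, vs),
       half1 = half_avgs[[1]], half2 = half_avgs[[2]],
       orientations = ori_df, fsc = fsc_list,
       resolution_0143 = res143, resolution_05 = res05)
}
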