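# Independent oracles used across test files. These deliberately use naive
# loops rather than the package's vectorized code paths.

# O(n^2) nearest-neighbour scan
brute_nn <- function(coords) {
  n <- nrow(coords)
  nn_distance <- numeric(n); nn_index <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 +
              (coords[, 2] - coords[i, 2])^2 +
              (coords[, 3] - coords[i, 3])^2)
    d[i] <- Inf
    nn_index[i] <- which.min(d)
    nn_distance[i] <- d[nn_index[i]]
  }
  list(nn_distance = nn_distance, nn_index = nn_index)
}

# union-find connected components over the full distance matrix
brute_components <- function(coords, threshold) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# arc length of a polyline by explicit pairwise loop
loop_arc_length <- function(points) {
  total <- 0
  for (i in seq_len(nrow(points) - 1))
    total <- total + sqrt(sum((points[i + 1, ] - points[i, ])^2))
  total
}

# quarter-circle trace of radius r in the xy plane, ~1-nm vertex spacing
quarter_circle_trace <- function(r = 100, by_deg = 0.5) {
  th <- seq(0, pi / 2, by = by_deg * pi / 180)
  filament_trace(cbind(r * cos(th), r * sin(th), 0), id = "qc")
}

# random rigid transform applied to an n x 3 coordinate matrix
apply_rigid <- function(coords, R, t) {
  sweep(coords %*% t(R), 2, t, "+")
}
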