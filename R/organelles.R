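# Organelle measurement summaries, exact/approximate Mann-Whitney rank-sum
# testing, and per-region enrichment densities.

#' Summarize measurements per structure, region and source
#'
#' Median and quartiles (type-7 quantile rule: linear interpolation between
#' order statistics) per (structure, region, source) group.
#'
#' @param table a [measurement_table] with >= 1 row.
#' @return data.frame of class `group_summary` with columns `structure,
#'   region, source, n, median, q1, q3`.
#' @export
summarize_groups <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  if (!nrow(table)) stop("cannot summarize an empty measurement table")
  key <- interaction(table$structure, table$region, table$source,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- table[key == k, , drop = FALSE]
    q <- stats::quantile(sel$value, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(structure = sel$structure[1], region = sel$region[1],
               source = sel$source[1], n = nrow(sel),
               median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}

# cached exact null distributions of the rank-sum U statistic
.u_null_cache <- new.env(parent = emptyenv())

# exact null distribution of U for group sizes (n1, n2), by enumeration of
# all C(n1+n2, n1) rank assignments
u_null_distribution <- function(n1, n2) {
  key <- paste(n1, n2, sep = "_")
  if (!is.null(.u_null_cache[[key]])) return(.u_null_cache[[key]])
  n <- n1 + n2
  splits <- utils::combn(n, n1)
  u <- colSums(splits) - n1 * (n1 + 1) / 2
  tab <- tabulate(as.integer(u) + 1L, nbins = n1 * n2 + 1L)
  dist <- tab / sum(tab)          # P(U = 0..n1*n2)
  .u_null_cache[[key]] <- dist
  dist
}

#' Mann-Whitney rank-sum test
#'
#' `U = sum over pairs of [a_i > b_j] + 1/2 [a_i = b_j]`, reported as
#' `min(U, n1*n2 - U)`. The two-sided p-value is exact -- full enumeration
#' of rank assignments -- when `n1 + n2 <= 16` and there are no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. `stats::wilcox.test` computes the same
#' statistic and serves as an independent cross-check in the test suite.
#'
#' @param a,b numeric samples (each non-empty).
#' @param alternative only "two_sided" is implemented.
#' @return An object of class `rank_sum_result`: list with `U`, `method`
#'   ("exact" or "normal_approximation"), `p_two_sided`, `tie_corrected`,
#'   `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two_sided") {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  alternative <- match.arg(alternative, "two_sided")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_rep <- min(u1, n1 * n2 - u1)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (n <= 16L && !ties) {
    dist <- u_null_distribution(n1, n2)
    p <- min(1, 2 * sum(dist[seq_len(as.integer(u_rep) + 1L)]))
    method <- "exact"
  } else {
    tie_counts <- table(c(a, b))
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- max(0, abs(u1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approximation"
  }
  structure(list(U = u_rep, method = method, p_two_sided = p,
                 tie_corrected = ties, n1 = n1, n2 = n2),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> U = %g (n1 = %d, n2 = %d), p = %.4g [%s%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method,
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

#' Structure enrichment per surveyed region category
#'
#' Structures observed per surveyed tomogram: `density = count /
#' n_tomograms` per (structure, category). Categories without surveyed
#' tomograms are omitted with a message.
#'
#' @param counts data.frame with columns `structure, category, count`
#'   (non-negative integers).
#' @param areas_surveyed data.frame with columns `category, n_tomograms`.
#' @return data.frame with raw counts echoed and a `density` column.
#' @export
enrichment <- function(counts, areas_surveyed) {
  stopifnot(all(c("structure", "category", "count") %in% names(counts)),
            all(c("category", "n_tomograms") %in% names(areas_surveyed)),
            all(counts$count >= 0))
  m <- match(counts$category, areas_surveyed$category)
  n_tomo <- areas_surveyed$n_tomograms[m]
  drop <- is.na(n_tomo) | n_tomo == 0
  if (any(drop))
    message("omitting categories without surveyed tomograms: ",
            paste(unique(counts$category[drop]), collapse = ", "))
  out <- counts[!drop, , drop = FALSE]
  out$n_tomograms <- n_tomo[!drop]
  out$density <- out$count / out$n_tomograms
  rownames(out) <- NULL
  out
}
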