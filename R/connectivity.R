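#' Pearson correlation matrix of a multivariate time series
#'
#' @param ts T x N numeric matrix, one column per node; column names become
#'   node labels.
#' @return N x N product-moment correlation matrix, symmetric with unit
#'   diagonal.
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("zero-variance time series for ROI: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- stats::cor(ts)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}

#' Absolute-value connectivity matrix
#'
#' Functional anticorrelations are treated as connectivity regardless of
#' sign, so graph construction uses `|r|`. Idempotent.
#'
#' @param cm correlation matrix (as from [pearson_matrix()]).
#' @return matrix of absolute correlations in \[0, 1\].
#' @export
absolute_matrix <- function(cm) {
  abs(cm)
}

#' Edge-density grid anchored to integer mean degrees
#'
#' Densities are `k / (N - 1)` for integer target mean degrees `k` from
#' `k_min` to `k_max`. On a 112-node network with the default 4..44 range
#' this yields 41 levels spanning 3.6%-39.6%.
#'
#' @param n_nodes node count N.
#' @param k_min,k_max smallest and largest target mean degree (defaults 4
#'   and 44).
#' @return data.frame with columns `degree`, `density` and `percent`
#'   (density as a percentage rounded to one decimal).
#' @export
build_density_grid <- function(n_nodes, k_min = 4L, k_max = 44L) {
  n_nodes <- as.integer(n_nodes); k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (!(1L <= k_min && k_min <= k_max && k_max <= n_nodes - 1L)) {
    stop("need 1 <= k_min <= k_max <= n_nodes - 1", call. = FALSE)
  }
  k <- seq.int(k_min, k_max)
  d <- k / (n_nodes - 1)
  data.frame(degree = k, density = d, percent = round(100 * d, 1))
}

#' Threshold an absolute connectivity matrix to a binary network
#'
#' Keeps the `round(d * N * (N - 1) / 2)` largest off-diagonal values as
#' edges (halves round away from zero). Ties at the cutoff are broken by
#' ascending (row, column) index so the result is deterministic.
#'
#' @param am absolute connectivity matrix.
#' @param d target edge density in (0, 1].
#' @return object of class `binary_network`: list with `adjacency` (0/1
#'   matrix, zero diagonal), `density`, `n_edges`, `labels`.
#' @export
threshold_by_density <- function(am, d) {
  stop_if_not_scalar(d, "d")
  if (d <= 0 || d > 1) stop("density must lie in (0, 1]", call. = FALSE)
  am <- as.matrix(am)
  n <- nrow(am)
  stopifnot(n == ncol(am))
  labels <- rownames(am) %||% as.character(seq_len(n))
  n_pairs <- n * (n - 1) / 2
  n_edges <- as.integer(round_half_away(d * n_pairs))

  ut <- which(upper.tri(am), arr.ind = TRUE)
  w <- am[ut]
  # sort by weight descending, then row then column ascending (tie-break)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(n_edges, n_pairs))]
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  new_binary_network(adj, d)
}

new_binary_network <- function(adj, density) {
  n <- nrow(adj)
  labels <- rownames(adj) %||% as.character(seq_len(n))
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, density = density,
                 n_edges = sum(adj) / 2, labels = labels),
            class = "binary_network")
}

#' Build a binary network directly from an adjacency matrix
#'
#' Convenience constructor for toy graphs and tests.
#'
#' @param adj symmetric 0/1 matrix with zero diagonal.
#' @return a `binary_network`.
#' @export
binary_network <- function(adj) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "integer"
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adj) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  if (!all(adj %in% c(0L, 1L))) stop("adjacency must be 0/1", call. = FALSE)
  n <- nrow(adj)
  new_binary_network(adj, density = sum(adj) / (n * (n - 1)))
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.3f)\n",
              length(x$labels), x$n_edges, x$density))
  invisible(x)
}

#' Frame-to-frame head motion (or rotation) summary
#'
#' Mean over successive frame transitions of the Euclidean norm of the
#' 3-vector of parameter differences:
#' `(M-1)^-1 * sum_i sqrt(dx_i^2 + dy_i^2 + dz_i^2)`.
#'
#' @param trace a `motion_trace` (list with `translations` and `rotations`,
#'   each M x 3), or an M x 3 matrix.
#' @param kind which block to summarize when `trace` is a `motion_trace`.
#' @return non-negative scalar (mm or degrees per transition).
#' @export
head_motion_summary <- function(trace, kind = c("translations", "rotations")) {
  kind <- match.arg(kind)
  mat <- if (inherits(trace, "motion_trace")) trace[[kind]] else as.matrix(trace)
  if (ncol(mat) != 3L) stop("motion block must have 3 columns", call. = FALSE)
  m <- nrow(mat)
  if (m < 2L) stop("need at least 2 frames to summarize motion", call. = FALSE)
  steps <- diff(mat)
  mean(sqrt(rowSums(steps^2)))
}

#' Head-motion exclusion rule
#'
#' A subject is excluded when any translation parameter exceeds
#' `translation_mm` in absolute value or any rotation parameter exceeds
#' `rotation_deg` (strict inequalities: a subject sitting exactly on a limit
#' is retained).
#'
#' @param trace a `motion_trace`.
#' @param translation_mm translation limit in mm (default 2).
#' @param rotation_deg rotation limit in degrees (default 1).
#' @return list with `exclude` (logical) and `reason` (string naming the
#'   offending parameter, or `""` when retained).
#' @export
motion_exclude <- function(trace, translation_mm = 2, rotation_deg = 1) {
  stopifnot(inherits(trace, "motion_trace"))
  axes <- c("x", "y", "z")
  for (j in 1:3) {
    peak <- max(abs(trace$translations[, j]))
    if (peak > translation_mm) {
      return(list(exclude = TRUE,
                  reason = sprintf("translation_%s %.2f mm > %g mm",
                                   axes[j], peak, translation_mm)))
    }
  }
  for (j in 1:3) {
    peak <- max(abs(trace$rotations[, j]))
    if (peak > rotation_deg) {
      return(list(exclude = TRUE,
                  reason = sprintf("rotation_%s %.2f deg > %g deg",
                                   axes[j], peak, rotation_deg)))
    }
  }
  list(exclude = FALSE, reason = "")
}
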