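#' Equal-width distance-range boundaries
#'
#' Splits the observed inter-node distance range into `n_ranges` equal-width
#' classes (default 3: short, middle, long). Membership is half-open
#' `[lower, upper)` except the last range, which is closed at `d_max`.
#'
#' @param d_min,d_max smallest and largest pairwise distance (mm).
#' @param n_ranges number of classes (default 3).
#' @return object of class `distance_bins`: list with `d_min`, `d_max`,
#'   `breaks` (interior boundaries), `n_ranges`, `range_names`.
#' @export
range_boundaries <- function(d_min, d_max, n_ranges = 3L) {
  stop_if_not_scalar(d_min, "d_min"); stop_if_not_scalar(d_max, "d_max")
  n_ranges <- as.integer(n_ranges)
  if (!(d_max > d_min && d_min >= 0)) stop("need d_max > d_min >= 0", call. = FALSE)
  if (n_ranges < 1L) stop("n_ranges must be >= 1", call. = FALSE)
  breaks <- d_min + seq_len(n_ranges - 1L) * (d_max - d_min) / n_ranges
  nm <- if (n_ranges == 3L) c("short", "middle", "long")
        else sprintf("range_%d", seq_len(n_ranges))
  structure(list(d_min = d_min, d_max = d_max, breaks = breaks,
                 n_ranges = n_ranges, range_names = nm),
            class = "distance_bins")
}

#' Distance bins of an atlas
#'
#' Convenience wrapper: boundaries computed from the atlas's own minimum and
#' maximum pairwise distance, the same construction used by both the
#' generator and the analysis so that ground truth and analysis stratify
#' pairs identically.
#'
#' @param atlas an `roi_atlas`.
#' @param n_ranges number of classes (default 3).
#' @return a `distance_bins`.
#' @export
atlas_distance_bins <- function(atlas, n_ranges = 3L) {
  D <- pairwise_distances(atlas)
  offd <- D[upper.tri(D)]
  range_boundaries(min(offd), max(offd), n_ranges)
}

#' Classify distances into range indices
#'
#' @param d numeric vector or matrix of distances.
#' @param bins a `distance_bins`.
#' @return integer class indices (1 = shortest range), same shape as `d`.
#' @export
classify_distances <- function(d, bins) {
  stopifnot(inherits(bins, "distance_bins"))
  cls <- findInterval(d, c(-Inf, bins$breaks, Inf))
  cls <- pmin(pmax(cls, 1L), bins$n_ranges)
  if (is.matrix(d)) cls <- matrix(cls, nrow(d), ncol(d)) else cls
  cls
}

#' Mean connection strength per distance range
#'
#' By default the mean of `|r|` over all node pairs in each range,
#' independent of any threshold. Passing a `binary_network` restricts the
#' mean to pairs that survive thresholding at that network's density.
#'
#' @param am absolute connectivity matrix.
#' @param D pairwise distance matrix (mm), same node order as `am`.
#' @param bins a `distance_bins`.
#' @param net optional `binary_network`; when given, only surviving edges
#'   enter the means.
#' @return data.frame with columns `range` and `mean_strength`.
#' @export
range_strength_summary <- function(am, D, bins, net = NULL) {
  stopifnot(all(dim(am) == dim(D)))
  ut <- upper.tri(am)
  keep <- if (is.null(net)) ut else ut & net$adjacency == 1L
  cls <- classify_distances(D, bins)
  means <- vapply(seq_len(bins$n_ranges), function(k) {
    sel <- keep & cls == k
    if (!any(sel)) return(NA_real_)
    mean(am[sel])
  }, numeric(1))
  data.frame(range = factor(bins$range_names, levels = bins$range_names),
             mean_strength = means)
}

#' Count surviving edges per distance range
#'
#' @param net a `binary_network`.
#' @param D pairwise distance matrix (mm), same node order.
#' @param bins a `distance_bins`.
#' @return data.frame with columns `range` and `n_edges`; counts sum to the
#'   network's edge count.
#' @export
range_edge_counts <- function(net, D, bins) {
  stopifnot(inherits(net, "binary_network"), all(dim(net$adjacency) == dim(D)))
  cls <- classify_distances(D, bins)
  ut <- upper.tri(D)
  counts <- vapply(seq_len(bins$n_ranges), function(k) {
    sum(net$adjacency[ut & cls == k])
  }, numeric(1))
  data.frame(range = factor(bins$range_names, levels = bins$range_names),
             n_edges = as.integer(counts))
}

#' @export
print.distance_bins <- function(x, ...) {
  edges <- c(x$d_min, x$breaks, x$d_max)
  for (k in seq_len(x$n_ranges)) {
    cat(sprintf("%-8s %8.2f - %8.2f mm\n", x$range_names[k],
                edges[k], edges[k + 1]))
  }
  invisible(x)
}
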