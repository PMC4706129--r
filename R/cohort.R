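#' Group-specific target correlation matrix for a synthetic subject
#'
#' Builds the ground-truth cross-correlation matrix the time series of one
#' synthetic subject are drawn from: a distance-decaying kernel with a
#' within-module boost, then group-specific attenuation (middle/long-range
#' couplings for the DLB-like group, temporal-endpoint couplings for the
#' AD-like group; see [cohort_config()]), optional sign flips, and projection
#' to the nearest valid correlation matrix by eigenvalue clipping.
#'
#' @param atlas an `roi_atlas`.
#' @param group one of `"HC"`, `"DLB"`, `"AD"`.
#' @param config a `cohort_config`.
#' @param severity attenuation deviation in \[0, 1\]; larger means stronger
#'   attenuation for the patient groups. Ignored for `"HC"`.
#' @param ctx optional precomputed context from [sigma_context()]; passing it
#'   avoids recomputing distances and module assignments per subject.
#' @return N x N correlation matrix (unit diagonal, symmetric, positive
#'   semi-definite after projection).
#' @export
build_target_correlation <- function(atlas, group = c("HC", "DLB", "AD"),
                                     config = cohort_config(),
                                     severity = 0.5, ctx = NULL) {
  group <- match.arg(group)
  stop_if_not_scalar(severity, "severity")
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]", call. = FALSE)
  if (is.null(ctx)) ctx <- sigma_context(atlas, config)
  n <- length(atlas$labels)

  m <- matrix(1, n, n)
  same_mod <- outer(ctx$modules, ctx$modules, `==`)
  m[same_mod] <- 1 + config$mu_module
  S <- m * config$rho0 * exp(-ctx$D / config$lambda_mm)

  if (group != "HC") {
    jitter <- config$subject_jitter * (2 * severity - 1)
    if (group == "DLB") {
      factor <- config$gamma_dlb - jitter
      mask <- ctx$range_class >= 2L           # middle or long range
    } else {
      factor <- config$gamma_ad - jitter
      mask <- ctx$temporal_pair
    }
    if (factor <= 0 || factor >= 1) {
      stop("attenuation factor outside (0, 1); check gamma/subject_jitter",
           call. = FALSE)
    }
    S[mask] <- S[mask] * factor
  }

  if (config$flip_fraction > 0) {
    # deterministic hash-based pair selection: no RNG state touched
    idx <- outer(seq_len(n), seq_len(n),
                 function(i, j) ((pmin(i, j) * 2654435761 + pmax(i, j) * 40503) %% 104729) / 104729)
    flip <- idx < config$flip_fraction
    S[flip] <- -S[flip]
  }

  diag(S) <- 1
  S <- (S + t(S)) / 2
  off <- S[upper.tri(S)]
  if (any(abs(off) >= 1)) {
    stop("configuration implies |correlation| >= 1 before projection",
         call. = FALSE)
  }
  S <- nearest_correlation(S)
  dimnames(S) <- list(atlas$labels, atlas$labels)
  S
}

#' Precompute the per-atlas context of the generative covariance model
#'
#' @param atlas an `roi_atlas`.
#' @param config a `cohort_config`.
#' @return list with the distance matrix `D`, `modules`, the per-pair
#'   distance-range class matrix `range_class` (1 short, 2 middle, 3 long,
#'   same three equal-width ranges the analysis uses) and the logical matrix
#'   `temporal_pair` marking pairs with at least one temporal-tagged endpoint.
#' @export
sigma_context <- function(atlas, config = cohort_config()) {
  D <- pairwise_distances(atlas)
  offd <- D[upper.tri(D)]
  bins <- range_boundaries(min(offd), max(offd), n_ranges = 3L)
  range_class <- classify_distances(D, bins)
  diag(range_class) <- 0L
  tmp <- atlas$tags == "temporal"
  temporal_pair <- outer(tmp, tmp, `|`)
  list(D = D, modules = assign_modules(atlas, config$n_modules),
       bins = bins, range_class = range_class, temporal_pair = temporal_pair)
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to `floor`, the
#' matrix is reconstructed and rescaled to unit diagonal. Deterministic and
#' adequate at the dimensions used here (about 100 nodes).
#'
#' @param S symmetric matrix with unit diagonal.
#' @param floor smallest admissible eigenvalue (default 1e-6).
#' @return symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_correlation <- function(S, floor = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  A <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(A))
  A <- A / tcrossprod(d)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

#' Simulate one synthetic subject
#'
#' Draws `t_frames` samples from a zero-mean Gaussian with the subject's
#' target correlation, applies AR(1) temporal filtering per node (the same
#' filter for every node, so the cross-correlation target is preserved) and
#' re-standardizes each node's series. Clinical scores follow the declared
#' monotone links in the config; the motion trace is a reflected random walk
#' within the configured bounds.
#'
#' @param atlas an `roi_atlas`.
#' @param group `"HC"`, `"DLB"` or `"AD"`.
#' @param config a `cohort_config`.
#' @param seed integer seed for this subject's substream.
#' @param subject_id identifier string.
#' @param ctx optional [sigma_context()].
#' @return object of class `subject_record`: list with `id`, `group`,
#'   `severity`, `ts` (T x N matrix), `motion` (list of `translations`,
#'   `rotations`, each M x 3) and `clinical` (named numeric vector).
#' @export
simulate_subject <- function(atlas, group = c("HC", "DLB", "AD"),
                             config = cohort_config(), seed = 1L,
                             subject_id = "S01", ctx = NULL) {
  group <- match.arg(group)
  validate_cohort_config(config)
  if (is.null(ctx)) ctx <- sigma_context(atlas, config)
  set.seed(as.integer(seed))

  severity <- stats::runif(1)
  Sigma <- build_target_correlation(atlas, group, config, severity, ctx)
  n <- ncol(Sigma)
  tt <- config$t_frames

  eps <- MASS::mvrnorm(tt, mu = rep(0, n), Sigma = Sigma)
  phi <- config$ar1_phi
  if (phi != 0) {
    ts <- apply(eps, 2, function(col) {
      as.numeric(stats::filter(col, phi, method = "recursive"))
    })
  } else {
    ts <- eps
  }
  ts <- scale(ts)
  attr(ts, "scaled:center") <- NULL
  attr(ts, "scaled:scale") <- NULL
  colnames(ts) <- atlas$labels

  clinical <- simulate_clinical(group, severity, config$clinical_links)
  motion <- simulate_motion(tt, config)

  structure(list(id = subject_id, group = group, severity = severity,
                 ts = ts, motion = motion, clinical = clinical),
            class = "subject_record")
}

simulate_clinical <- function(group, severity, links) {
  rows <- links[links$group == group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no clinical links declared for group ", group,
                             call. = FALSE)
  vals <- rows$intercept + rows$slope * severity +
    stats::rnorm(nrow(rows), 0, rows$sd)
  vals <- pmin(pmax(vals, rows$lo), rows$hi)
  stats::setNames(vals, rows$score)
}

simulate_motion <- function(m, config) {
  walk <- function(steps_sd, bound) {
    x <- apply(matrix(stats::rnorm(m * 3, 0, steps_sd), m, 3), 2, cumsum)
    reflect_into(x, bound)
  }
  structure(list(translations = walk(config$motion_step_sd_mm,
                                     config$motion_bound_mm),
                 rotations = walk(config$motion_step_sd_deg,
                                  config$motion_bound_deg)),
            class = "motion_trace")
}

# triangle-wave fold of an unbounded walk into [-bound, bound]
reflect_into <- function(x, bound) {
  u <- (x + bound) %% (4 * bound)
  out <- ifelse(u <= 2 * bound, u - bound, 3 * bound - u)
  matrix(out, nrow = nrow(x), ncol = ncol(x))
}

#' Simulate a full three-group cohort
#'
#' Subjects are generated in the fixed order HC, DLB, AD, each from its own
#' seed substream derived from the master seed and the subject's global
#' index, so dropping any subject leaves all others bit-identical.
#'
#' @param config a `cohort_config`.
#' @param atlas an `roi_atlas` (default: packaged 112-node atlas).
#' @return object of class `synthetic_cohort`: list with `subjects` (list of
#'   `subject_record`), `atlas`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            atlas = load_default_atlas()) {
  validate_cohort_config(config)
  sizes <- c(HC = config$n_control, DLB = config$n_dlb, AD = config$n_ad)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 subjects (group statistics undefined); got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
         call. = FALSE)
  }
  ctx <- sigma_context(atlas, config)
  idx <- 0L
  subjects <- list()
  for (g in names(sizes)) {
    for (k in seq_len(sizes[[g]])) {
      idx <- idx + 1L
      id <- sprintf("%s%02d", g, k)
      subjects[[id]] <- simulate_subject(
        atlas, g, config, seed = derive_seed(config$seed, idx),
        subject_id = id, ctx = ctx)
    }
  }
  structure(list(subjects = subjects, atlas = atlas, config = config),
            class = "synthetic_cohort")
}

#' Write a cohort to disk as delimited text
#'
#' One time-series TSV per subject (T rows x N columns, header = node
#' labels), one motion TSV per subject (M x 6: tx, ty, tz, rx, ry, rz), one
#' cohort-level clinical table, plus the atlas.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas_df <- data.frame(label = cohort$atlas$labels,
                         x = cohort$atlas$coords[, 1],
                         y = cohort$atlas$coords[, 2],
                         z = cohort$atlas$coords[, 3],
                         tag = cohort$atlas$tags)
  write_tsv(atlas_df, file.path(dir, "atlas.tsv"))
  clin <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject = s$id, group = s$group, severity = s$severity,
               as.list(s$clinical), stringsAsFactors = FALSE)
  }))
  write_tsv(clin, file.path(dir, "clinical.tsv"))
  for (s in cohort$subjects) {
    write_tsv(as.data.frame(s$ts), file.path(dir, sprintf("ts_%s.tsv", s$id)))
    mo <- cbind(s$motion$translations, s$motion$rotations)
    colnames(mo) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    write_tsv(as.data.frame(mo), file.path(dir, sprintf("motion_%s.tsv", s$id)))
  }
  invisible(dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s), severity %.2f, %d frames x %d nodes\n",
              x$id, x$group, x$severity, nrow(x$ts), ncol(x$ts)))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  gr <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d nodes\n",
              length(x$subjects),
              paste(sprintf("%s: %d", names(gr), gr), collapse = ", "),
              length(x$atlas$labels)))
  invisible(x)
}
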