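#' Full run configuration
#'
#' Bundles the cohort generator settings, density grid, null-model and QC
#' parameters and statistics options into one serializable object. The
#' master `seed` drives every random stage through derived substreams.
#'
#' @param cohort a [cohort_config()].
#' @param k_min,k_max density grid endpoints as integer mean degrees.
#' @param null_R rewired null replicates per density (default 50).
#' @param swaps_per_edge attempted swaps per edge per replicate (default 10).
#' @param qc_translation_mm,qc_rotation_deg motion exclusion limits.
#' @param alpha significance level for the statistics stage.
#' @param gate gate post hoc flags on the omnibus ANOVA (default TRUE).
#' @param welch use Welch t tests (default FALSE).
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), k_min = 4L, k_max = 44L,
                       null_R = 50L, swaps_per_edge = 10,
                       qc_translation_mm = 2, qc_rotation_deg = 1,
                       alpha = 0.05, gate = TRUE, welch = FALSE, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), null_R = as.integer(null_R),
                 swaps_per_edge = swaps_per_edge,
                 qc_translation_mm = qc_translation_mm,
                 qc_rotation_deg = qc_rotation_deg,
                 alpha = alpha, gate = gate, welch = welch,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to JSON or YAML
#'
#' @param config a `run_config`.
#' @param path output path; `.yaml`/`.yml` selects YAML, anything else JSON.
#' @return invisibly, the path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' The configuration is rebuilt through the constructors, so a write/read
#' round trip reproduces an identical, revalidated config.
#'
#' @param path file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  co <- x$cohort
  links <- as.data.frame(co$clinical_links, stringsAsFactors = FALSE)
  cohort <- cohort_config(
    n_control = co$n_control, n_dlb = co$n_dlb, n_ad = co$n_ad,
    t_frames = co$t_frames, rho0 = co$rho0, lambda_mm = co$lambda_mm,
    mu_module = co$mu_module, n_modules = co$n_modules,
    gamma_dlb = co$gamma_dlb, gamma_ad = co$gamma_ad,
    subject_jitter = co$subject_jitter, ar1_phi = co$ar1_phi,
    flip_fraction = co$flip_fraction,
    motion_step_sd_mm = co$motion_step_sd_mm,
    motion_step_sd_deg = co$motion_step_sd_deg,
    motion_bound_mm = co$motion_bound_mm,
    motion_bound_deg = co$motion_bound_deg,
    clinical_links = links, seed = co$seed)
  run_config(cohort = cohort, k_min = x$k_min, k_max = x$k_max,
             null_R = x$null_R, swaps_per_edge = x$swaps_per_edge,
             qc_translation_mm = x$qc_translation_mm,
             qc_rotation_deg = x$qc_rotation_deg, alpha = x$alpha,
             gate = x$gate, welch = x$welch, seed = x$seed)
}

# ---- stages ----------------------------------------------------------------

#' Pipeline stage: simulate the cohort and write it to disk
#'
#' @param config a `run_config`.
#' @param out_dir run directory; outputs land in `<out_dir>/simulate/`.
#' @return invisibly, the simulated `synthetic_cohort`.
#' @export
stage_simulate <- function(config, out_dir) {
  cohort <- simulate_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "simulate"))
  invisible(cohort)
}

#' Pipeline stage: motion quality control
#'
#' Summarizes every subject's motion and rotation and applies the exclusion
#' rule; writes `qc/qc_summary.tsv`.
#'
#' @param config a `run_config`.
#' @param out_dir run directory containing `simulate/`.
#' @return invisibly, the QC table.
#' @export
stage_qc <- function(config, out_dir) {
  sim <- file.path(out_dir, "simulate")
  clin <- read_tsv(file.path(sim, "clinical.tsv"))
  rows <- lapply(clin$subject, function(id) {
    mo <- as.matrix(read_tsv(file.path(sim, sprintf("motion_%s.tsv", id))))
    trace <- structure(list(translations = mo[, 1:3], rotations = mo[, 4:6]),
                       class = "motion_trace")
    ex <- motion_exclude(trace, config$qc_translation_mm, config$qc_rotation_deg)
    data.frame(subject = id,
               group = clin$group[clin$subject == id],
               motion = head_motion_summary(trace, "translations"),
               rotation = head_motion_summary(trace, "rotations"),
               excluded = ex$exclude, reason = ex$reason,
               stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, rows)
  dir.create(file.path(out_dir, "qc"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(qc, file.path(out_dir, "qc", "qc_summary.tsv"))
  if (all(qc$excluded)) {
    stop("stage qc: every subject excluded by motion criteria (empty cohort)",
         call. = FALSE)
  }
  invisible(qc)
}

retained_subjects <- function(out_dir) {
  qc <- read_tsv(file.path(out_dir, "qc", "qc_summary.tsv"))
  qc[!qc$excluded, c("subject", "group")]
}

#' Pipeline stage: absolute correlation matrices
#'
#' Pearson correlation of every retained subject's time series, absolute
#' value taken; one dense TSV per subject under `connect/`.
#'
#' @param config a `run_config`.
#' @param out_dir run directory containing `simulate/` and `qc/`.
#' @return invisibly, the vector of retained subject ids.
#' @export
stage_connect <- function(config, out_dir) {
  keep <- retained_subjects(out_dir)
  dir.create(file.path(out_dir, "connect"), showWarnings = FALSE, recursive = TRUE)
  for (id in keep$subject) {
    ts <- tryCatch(
      as.matrix(read_tsv(file.path(out_dir, "simulate", sprintf("ts_%s.tsv", id)))),
      error = function(e) stop("stage connect, subject ", id, ": ",
                               conditionMessage(e), call. = FALSE))
    am <- absolute_matrix(pearson_matrix(ts))
    write_tsv(as.data.frame(am), file.path(out_dir, "connect",
                                           sprintf("abscorr_%s.tsv", id)))
  }
  invisible(keep$subject)
}

read_abscorr <- function(out_dir, id) {
  am <- as.matrix(read_tsv(file.path(out_dir, "connect",
                                     sprintf("abscorr_%s.tsv", id))))
  rownames(am) <- colnames(am)
  am
}

#' Pipeline stage: graph metrics along the density sweep
#'
#' For every retained subject and grid density: global measures (with
#' `null_R` rewired nulls for the normalized ones) and nodal degree,
#' clustering and betweenness. Writes tidy tables
#' `metrics/global_metrics.tsv` and `metrics/nodal_metrics.tsv`. Subjects
#' are independent work units with pre-derived seeds, so results do not
#' depend on `workers`.
#'
#' @param config a `run_config`.
#' @param out_dir run directory.
#' @param workers parallel workers over subjects (default 1).
#' @return invisibly, NULL.
#' @export
stage_metrics <- function(config, out_dir, workers = 1L) {
  keep <- retained_subjects(out_dir)
  atlas <- read_atlas(file.path(out_dir, "simulate", "atlas.tsv"))
  grid <- build_density_grid(length(atlas$labels), config$k_min, config$k_max)
  seeds <- vapply(seq_len(nrow(keep)),
                  function(i) derive_seed(config$seed, 1000L + i), integer(1))

  one_subject <- function(i) {
    id <- keep$subject[i]
    am <- read_abscorr(out_dir, id)
    glob <- density_sweep_metrics(am, grid, null_R = config$null_R,
                                  seed = seeds[i],
                                  swaps_per_edge = config$swaps_per_edge)
    cols <- c("C", "L", "E", "Q", "connected_fraction",
              "C_norm", "L_norm", "sigma")
    gl <- do.call(rbind, lapply(cols, function(mc) {
      data.frame(subject = id, group = keep$group[i],
                 degree = glob$degree, density = glob$density,
                 measure = mc, value = glob[[mc]])
    }))
    nod <- lapply(seq_len(nrow(grid)), function(k) {
      net <- threshold_by_density(am, grid$density[k])
      data.frame(subject = id, group = keep$group[i],
                 density = grid$density[k],
                 node = rep(net$labels, 3),
                 metric = rep(c("degree", "clustering", "betweenness"),
                              each = length(net$labels)),
                 value = c(node_degree(net), nodal_clustering(net),
                           betweenness_centrality(net)))
    })
    list(global = gl, nodal = do.call(rbind, nod))
  }
  res <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(keep)), one_subject, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(keep)), one_subject)
  }
  for (r in res) {
    if (inherits(r, "try-error")) stop("stage metrics failed: ", r, call. = FALSE)
  }
  dir.create(file.path(out_dir, "metrics"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(do.call(rbind, lapply(res, `[[`, "global")),
            file.path(out_dir, "metrics", "global_metrics.tsv"))
  write_tsv(do.call(rbind, lapply(res, `[[`, "nodal")),
            file.path(out_dir, "metrics", "nodal_metrics.tsv"))
  invisible(NULL)
}

#' Pipeline stage: edge-distance stratification
#'
#' Per-subject mean absolute correlation in the short/middle/long distance
#' ranges (all pairs) and per-density counts of surviving edges per range.
#'
#' @param config a `run_config`.
#' @param out_dir run directory.
#' @return invisibly, NULL.
#' @export
stage_distance <- function(config, out_dir) {
  keep <- retained_subjects(out_dir)
  atlas <- read_atlas(file.path(out_dir, "simulate", "atlas.tsv"))
  D <- pairwise_distances(atlas)
  bins <- atlas_distance_bins(atlas)
  grid <- build_density_grid(length(atlas$labels), config$k_min, config$k_max)
  strength <- list(); counts <- list()
  for (i in seq_len(nrow(keep))) {
    id <- keep$subject[i]
    am <- read_abscorr(out_dir, id)
    ss <- range_strength_summary(am, D, bins)
    strength[[i]] <- data.frame(subject = id, group = keep$group[i], ss)
    cc <- lapply(seq_len(nrow(grid)), function(k) {
      net <- threshold_by_density(am, grid$density[k])
      data.frame(subject = id, group = keep$group[i],
                 density = grid$density[k],
                 range_edge_counts(net, D, bins))
    })
    counts[[i]] <- do.call(rbind, cc)
  }
  dir.create(file.path(out_dir, "distance"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(do.call(rbind, strength),
            file.path(out_dir, "distance", "range_strength.tsv"))
  write_tsv(do.call(rbind, counts),
            file.path(out_dir, "distance", "range_counts.tsv"))
  invisible(NULL)
}

#' Pipeline stage: group statistics
#'
#' Per-density ANOVA with gated Bonferroni post hocs for every global
#' measure, density-integrated measures with pairwise t tests, nodal
#' consistency maps per contrast and metric, Spearman clinical correlations
#' within each patient group, and the two Kruskal-Wallis motion tests.
#'
#' @param config a `run_config`.
#' @param out_dir run directory with all upstream stages present.
#' @return invisibly, NULL.
#' @export
stage_stats <- function(config, out_dir) {
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE, recursive = TRUE)
  glob <- read_tsv(file.path(out_dir, "metrics", "global_metrics.tsv"))
  measures <- c("C", "L", "E", "Q", "C_norm", "L_norm", "sigma")
  measures <- measures[measures %in% unique(glob$measure)]

  # per-density omnibus + post hoc
  anova_rows <- list()
  for (ms in measures) {
    sub <- glob[glob$measure == ms & !is.na(glob$value), ]
    for (d in unique(sub$density)) {
      sl <- sub[sub$density == d, ]
      if (nlevels(factor(sl$group)) < 3L) next
      res <- anova_with_posthoc(sl$value, sl$group, alpha = config$alpha,
                                gate = config$gate, welch = config$welch)
      anova_rows[[length(anova_rows) + 1L]] <-
        data.frame(measure = ms, density = d, F = res$F, p_omnibus = res$p,
                   res$pairs)
    }
  }
  write_tsv(rbind_or_empty(anova_rows,
                           c("measure", "density", "F", "p_omnibus",
                             "group1", "group2", "t", "p", "significant")),
            file.path(out_dir, "stats", "global_anova.tsv"))

  # integrated measures + t tests
  integ <- stats::aggregate(value ~ subject + group + measure,
                            data = glob[glob$measure %in% measures, ],
                            FUN = integrate_measure)
  write_tsv(integ, file.path(out_dir, "stats", "integrated.tsv"))
  groups <- sort(unique(integ$group))
  it_rows <- list()
  for (ms in measures) {
    sl <- integ[integ$measure == ms & !is.na(integ$value), ]
    for (pr in utils::combn(groups, 2, simplify = FALSE)) {
      a <- sl$value[sl$group == pr[1]]; b <- sl$value[sl$group == pr[2]]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- ttest_integrated(a, b, welch = config$welch)
      it_rows[[length(it_rows) + 1L]] <-
        data.frame(measure = ms, group1 = pr[1], group2 = pr[2],
                   t = tt$t, p = tt$p)
    }
  }
  write_tsv(rbind_or_empty(it_rows, c("measure", "group1", "group2", "t", "p")),
            file.path(out_dir, "stats", "integrated_ttests.tsv"))

  # nodal consistency per contrast and metric
  nod <- read_tsv(file.path(out_dir, "metrics", "nodal_metrics.tsv"))
  cons_rows <- list()
  for (met in unique(nod$metric)) {
    slm <- nod[nod$metric == met, ]
    for (pr in utils::combn(groups, 2, simplify = FALSE)) {
      arr <- lapply(pr, function(g) nodal_array(slm[slm$group == g, ]))
      S <- nodal_consistency(arr[[1]], arr[[2]], alpha = config$alpha,
                             welch = config$welch)
      cons_rows[[length(cons_rows) + 1L]] <-
        data.frame(contrast = paste(pr, collapse = "_vs_"), metric = met,
                   node = names(S), S = as.integer(S))
    }
  }
  write_tsv(do.call(rbind, cons_rows),
            file.path(out_dir, "stats", "consistency.tsv"))

  # Spearman clinical correlations within each patient group
  clin <- read_tsv(file.path(out_dir, "simulate", "clinical.tsv"))
  sp_rows <- list()
  for (g in intersect(c("DLB", "AD"), groups)) {
    ids <- sort(unique(integ$subject[integ$group == g]))
    if (length(ids) < 4L) next
    gi <- integ[integ$group == g, ]
    wide <- data.frame(subject = ids)
    for (ms in unique(gi$measure)) {
      sel <- gi[gi$measure == ms, ]
      wide[[ms]] <- sel$value[match(ids, sel$subject)]
    }
    cl <- clin[match(wide$subject, clin$subject), ]
    sp <- spearman_clinical(cl, wide, alpha = config$alpha)
    sp_rows[[length(sp_rows) + 1L]] <- data.frame(group = g, sp)
  }
  write_tsv(rbind_or_empty(sp_rows,
                           c("group", "score", "measure", "rho", "p",
                             "significant", "bonferroni")),
            file.path(out_dir, "stats", "spearman.tsv"))

  # motion comparability
  qc <- read_tsv(file.path(out_dir, "qc", "qc_summary.tsv"))
  qc <- qc[!qc$excluded, ]
  kw <- rbind(
    data.frame(kind = "motion",
               as.data.frame(kruskal_wallis_motion(qc$motion, qc$group))),
    data.frame(kind = "rotation",
               as.data.frame(kruskal_wallis_motion(qc$rotation, qc$group))))
  write_tsv(kw, file.path(out_dir, "stats", "motion_kw.tsv"))
  invisible(NULL)
}

rbind_or_empty <- function(rows, col_names) {
  if (length(rows) > 0L) return(do.call(rbind, rows))
  df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(col_names)),
                                      col_names))
  df
}

# long nodal table (one metric, one group) -> subject x node x density array
nodal_array <- function(df) {
  subs <- sort(unique(df$subject))
  nodes <- sort(unique(df$node))
  dens <- sort(unique(df$density))
  arr <- array(NA_real_, dim = c(length(subs), length(nodes), length(dens)),
               dimnames = list(subs, nodes, format(dens, digits = 12)))
  arr[cbind(match(df$subject, subs), match(df$node, nodes),
            match(df$density, dens))] <- df$value
  arr
}

#' Run the whole pipeline
#'
#' simulate -> qc -> connect -> metrics -> distance -> stats, all under one
#' run directory, then write a JSON manifest with the config snapshot,
#' per-file checksums, the exclusion list, stage timings and the package
#' version. Identical config and seed reproduce identical checksums.
#'
#' @param config a `run_config`.
#' @param out_dir run directory (created if absent).
#' @param workers parallel workers for the metrics stage.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, workers = 1L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.json"))
  stages <- list(simulate = function() stage_simulate(config, out_dir),
                 qc = function() stage_qc(config, out_dir),
                 connect = function() stage_connect(config, out_dir),
                 metrics = function() stage_metrics(config, out_dir, workers),
                 distance = function() stage_distance(config, out_dir),
                 stats = function() stage_stats(config, out_dir))
  timing <- list()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch(stages[[nm]](),
             error = function(e) {
               stop(sprintf("pipeline aborted in stage '%s': %s", nm,
                            conditionMessage(e)), call. = FALSE)
             })
    timing[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  qc <- read_tsv(file.path(out_dir, "qc", "qc_summary.tsv"))
  manifest <- list(
    version = as.character(utils::packageVersion("lewynet")),
    seed = config$seed,
    config_file = "config.json",
    n_densities = config$k_max - config$k_min + 1L,
    excluded = qc[qc$excluded, c("subject", "reason")],
    timing_s = timing,
    checksums = as.list(stats::setNames(unname(sums),
                                        substring(files, nchar(out_dir) + 2L))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
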