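#' Three-level ANOVA with Bonferroni-corrected post hoc t tests
#'
#' One-way equal-variance ANOVA across the three groups, followed by all
#' three pairwise two-tailed unpaired t tests. A pair is flagged significant
#' when the omnibus p-value is below `alpha` (if `gate` is TRUE) and the
#' pairwise p-value is below `alpha / n_contrasts`.
#'
#' @param values numeric vector of subject-level values.
#' @param groups factor (or coercible) of group labels, one per value.
#' @param alpha omnibus level (default 0.05).
#' @param n_contrasts Bonferroni divisor for the pairwise tests (default:
#'   number of group pairs).
#' @param gate require omnibus significance before flagging pairs
#'   (default TRUE).
#' @param welch use Welch (unequal-variance) tests instead of Student
#'   (default FALSE).
#' @return list with `F`, `p` (omnibus) and `pairs`, a data.frame with
#'   columns `group1`, `group2`, `t`, `p`, `significant`.
#' @export
anova_with_posthoc <- function(values, groups, alpha = 0.05,
                               n_contrasts = NULL, gate = TRUE,
                               welch = FALSE) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 subjects", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  if (is.null(n_contrasts)) n_contrasts <- ncol(pairs)

  om <- tryCatch(stats::oneway.test(values ~ groups, var.equal = !welch),
                 error = function(e) NULL)
  Fstat <- if (is.null(om)) NA_real_ else unname(om$statistic)
  p_om <- if (is.null(om) || is.na(om$p.value)) NA_real_ else om$p.value

  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = NA_real_, p = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    tt <- tryCatch(stats::t.test(a, b, var.equal = !welch), error = function(e) NULL)
    if (!is.null(tt)) {
      res$t[i] <- unname(tt$statistic)
      res$p[i] <- tt$p.value
    }
  }
  gate_open <- if (gate) isTRUE(p_om < alpha) else TRUE
  res$significant <- gate_open & !is.na(res$p) & res$p < alpha / n_contrasts
  list(F = Fstat, p = p_om, pairs = res)
}

#' Density-integrated measure
#'
#' Arithmetic mean of a per-density measure across the whole grid, giving a
#' single value per subject and sidestepping the multiple comparisons
#' problem of testing every density.
#'
#' @param values numeric vector, one value per grid density; must be
#'   complete (no NA).
#' @return scalar mean.
#' @export
integrate_measure <- function(values) {
  if (length(values) == 0L || anyNA(values)) {
    stop("integration requires a value at every grid density", call. = FALSE)
  }
  mean(values)
}

#' Two-tailed unpaired t test on integrated measures
#'
#' @param a,b numeric vectors of subject-level integrated values for the two
#'   groups (each length >= 2).
#' @param welch use Welch instead of Student (default FALSE).
#' @return list with `t` and `p`.
#' @export
ttest_integrated <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 subjects",
                                             call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Nodal consistency map for one group contrast
#'
#' For every node, counts the grid densities at which the two-tailed
#' unpaired t test between the two groups has p < alpha (uncorrected across
#' nodes; exploratory by design). The maximum attainable count is the grid
#' length (41 on the default grid).
#'
#' @param a,b 3-d arrays of one nodal metric, dimensions
#'   subject x node x density, for the two groups (same node/density dims).
#' @param alpha per-test level (default 0.05).
#' @param welch use Welch instead of Student (default FALSE).
#' @return named integer vector S of per-node counts.
#' @export
nodal_consistency <- function(a, b, alpha = 0.05, welch = FALSE) {
  stopifnot(length(dim(a)) == 3L, length(dim(b)) == 3L,
            dim(a)[2] == dim(b)[2], dim(a)[3] == dim(b)[3])
  n_nodes <- dim(a)[2]; n_dens <- dim(a)[3]
  S <- integer(n_nodes)
  for (v in seq_len(n_nodes)) {
    for (d in seq_len(n_dens)) {
      p <- tryCatch(stats::t.test(a[, v, d], b[, v, d],
                                  var.equal = !welch)$p.value,
                    error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) S[v] <- S[v] + 1L
    }
  }
  names(S) <- dimnames(a)[[2]] %||% as.character(seq_len(n_nodes))
  S
}

#' Spearman correlations between clinical scores and integrated measures
#'
#' Rank correlations (average ranks for ties, two-tailed asymptotic p) for
#' every score x measure combination, with a Bonferroni family flag at
#' `alpha / m` where `m` is the number of combinations (35 for the default
#' 7 measures x 5 scores).
#'
#' @param clinical data.frame of clinical scores, one row per subject.
#' @param integrated data.frame of integrated measures, same row order.
#' @param scores character vector of clinical column names.
#' @param measures character vector of measure column names.
#' @param alpha base level (default 0.05).
#' @return data.frame with `score`, `measure`, `rho`, `p`, `significant`
#'   (uncorrected), `bonferroni` (survives alpha/m), plus attribute
#'   `family_size` = m.
#' @export
spearman_clinical <- function(clinical, integrated,
                              scores = intersect(
                                c("MMSE", "CAMCOG", "CAF", "NPI_hall", "UPDRS"),
                                names(clinical)),
                              measures = intersect(
                                c("C", "L", "E", "Q", "C_norm", "L_norm", "sigma"),
                                names(integrated)),
                              alpha = 0.05) {
  stopifnot(nrow(clinical) == nrow(integrated))
  if (nrow(clinical) < 4L) stop("need at least 4 subjects", call. = FALSE)
  m <- length(scores) * length(measures)
  out <- expand.grid(score = scores, measure = measures,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$rho <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    ct <- suppressWarnings(
      stats::cor.test(clinical[[out$score[i]]], integrated[[out$measure[i]]],
                      method = "spearman", exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  out$bonferroni <- !is.na(out$p) & out$p < alpha / m
  attr(out, "family_size") <- m
  out
}

#' Kruskal-Wallis test for motion comparability between groups
#'
#' Rank-based omnibus test (tie-corrected H, chi-square p) applied to the
#' per-subject motion or rotation summaries; used to check that groups do
#' not differ in residual head motion.
#'
#' @param values numeric vector of motion summaries.
#' @param groups group labels, one per value.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis_motion <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  }
  kw <- stats::kruskal.test(values, groups)
  list(H = unname(kw$statistic), p = kw$p.value)
}
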