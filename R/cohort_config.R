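#' Default clinical-score generative links
#'
#' Each clinical score is generated as `intercept + slope * severity + noise`,
#' truncated to the instrument's valid range, where `severity` is the
#' subject's realized attenuation deviation in \[0, 1\]. Slopes and intercepts
#' are chosen so that group means and spreads resemble a typical
#' three-group dementia cohort (controls cognitively intact; the two patient
#' groups matched on global cognition; cognitive fluctuations and parkinsonism
#' largely confined to the Lewy body group). Scores: MMSE (0-30, global
#' cognition, decreasing with severity), CAMCOG (0-107, cognition,
#' decreasing), CAF (0-12, cognitive fluctuations, increasing in the DLB-like
#' group only), NPI_hall (0-12, hallucinations, DLB-like only), UPDRS
#' (0-108, parkinsonian motor signs, DLB-like only).
#'
#' @return data.frame with columns `group`, `score`, `intercept`, `slope`,
#'   `sd`, `lo`, `hi`.
#' @export
default_clinical_links <- function() {
  link <- function(group, score, intercept, slope, sd, lo, hi) {
    data.frame(group = group, score = score, intercept = intercept,
               slope = slope, sd = sd, lo = lo, hi = hi,
               stringsAsFactors = FALSE)
  }
  rbind(
    link("HC",  "MMSE",     29.3,  -1.0, 0.5,  0, 30),
    link("HC",  "CAMCOG",   97.5,  -3.0, 1.5,  0, 107),
    link("HC",  "CAF",       0.1,   0.3, 0.4,  0, 12),
    link("HC",  "NPI_hall",  0.0,   0.0, 0.0,  0, 12),
    link("HC",  "UPDRS",     1.0,   1.0, 1.2,  0, 108),
    link("DLB", "MMSE",     27.0,  -7.0, 1.8,  0, 30),
    link("DLB", "CAMCOG",   85.0, -18.0, 5.0,  0, 107),
    link("DLB", "CAF",       0.3,   6.0, 1.2,  0, 12),
    link("DLB", "NPI_hall",  0.4,   2.5, 0.8,  0, 12),
    link("DLB", "UPDRS",    10.0,  15.0, 4.0,  0, 108),
    link("AD",  "MMSE",     26.2,  -7.0, 1.8,  0, 30),
    link("AD",  "CAMCOG",   81.0, -18.0, 5.0,  0, 107),
    link("AD",  "CAF",       0.3,   0.5, 0.8,  0, 12),
    link("AD",  "NPI_hall",  0.0,   0.0, 0.0,  0, 12),
    link("AD",  "UPDRS",     1.5,   0.5, 1.5,  0, 108)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the generative model. The covariance target for a
#' subject in group g is
#' `Sigma_ij = m_ij * rho0 * exp(-d_ij / lambda_mm)` with
#' `m_ij = 1 + mu_module` when nodes i and j share a spatial module, then
#' group-specific attenuation: the DLB-like group multiplies entries whose
#' inter-node distance falls in the middle or long third of the distance
#' range by `gamma_dlb - subject_jitter * (2*severity - 1)`; the AD-like
#' group multiplies entries with at least one temporal-tagged endpoint by
#' `gamma_ad - subject_jitter * (2*severity - 1)`. `severity` is drawn
#' uniformly on \[0, 1\] per subject, so larger severity means stronger
#' attenuation, and the clinical links (see [default_clinical_links()])
#' couple the scores monotonically to it.
#'
#' @param n_control,n_dlb,n_ad group sizes (defaults 17, 18, 19).
#' @param t_frames frames per subject (default 128).
#' @param rho0 baseline coupling at zero distance (default 0.5).
#' @param lambda_mm distance-decay length in mm (default 90).
#' @param mu_module within-module coupling boost (default 0.5).
#' @param n_modules number of spatial modules (default 4).
#' @param gamma_dlb middle/long-range attenuation factor for the DLB-like
#'   group (default 0.6).
#' @param gamma_ad temporal-node attenuation factor for the AD-like group
#'   (default 0.75).
#' @param subject_jitter half-width of the per-subject attenuation jitter
#'   (default 0.1).
#' @param ar1_phi AR(1) temporal autocorrelation of the node signals
#'   (default 0.3).
#' @param flip_fraction fraction of couplings whose sign is flipped before
#'   projection, exercising the absolute-value step downstream (default 0).
#' @param motion_step_sd_mm,motion_step_sd_deg random-walk step SD of the
#'   motion trace (mm and degrees).
#' @param motion_bound_mm,motion_bound_deg reflection bounds of the motion
#'   random walk; defaults keep simulated subjects inside the usual
#'   2 mm / 1 degree exclusion limits.
#' @param clinical_links data.frame of generative links, see
#'   [default_clinical_links()].
#' @param seed master seed for the cohort.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_control = 17L, n_dlb = 18L, n_ad = 19L,
                          t_frames = 128L,
                          rho0 = 0.5, lambda_mm = 90, mu_module = 0.5,
                          n_modules = 4L,
                          gamma_dlb = 0.6, gamma_ad = 0.75,
                          subject_jitter = 0.1, ar1_phi = 0.3,
                          flip_fraction = 0,
                          motion_step_sd_mm = 0.03,
                          motion_step_sd_deg = 0.015,
                          motion_bound_mm = 1.5,
                          motion_bound_deg = 0.8,
                          clinical_links = default_clinical_links(),
                          seed = 1L) {
  cfg <- list(n_control = as.integer(n_control), n_dlb = as.integer(n_dlb),
              n_ad = as.integer(n_ad), t_frames = as.integer(t_frames),
              rho0 = rho0, lambda_mm = lambda_mm, mu_module = mu_module,
              n_modules = as.integer(n_modules),
              gamma_dlb = gamma_dlb, gamma_ad = gamma_ad,
              subject_jitter = subject_jitter, ar1_phi = ar1_phi,
              flip_fraction = flip_fraction,
              motion_step_sd_mm = motion_step_sd_mm,
              motion_step_sd_deg = motion_step_sd_deg,
              motion_bound_mm = motion_bound_mm,
              motion_bound_deg = motion_bound_deg,
              clinical_links = clinical_links,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (g in c("gamma_dlb", "gamma_ad")) {
    if (!(cfg[[g]] > 0 && cfg[[g]] < 1)) {
      stop(sprintf("'%s' must lie strictly in (0, 1)", g), call. = FALSE)
    }
  }
  peak <- cfg$rho0 * (1 + cfg$mu_module)
  if (!(peak > 0 && peak < 1)) {
    stop("rho0 * (1 + mu_module) must lie strictly in (0, 1); got ",
         signif(peak, 4), call. = FALSE)
  }
  if (cfg$t_frames < 8L) stop("t_frames must be >= 8", call. = FALSE)
  if (cfg$subject_jitter < 0 || cfg$subject_jitter >= cfg$gamma_dlb ||
      cfg$subject_jitter >= cfg$gamma_ad) {
    stop("subject_jitter must be non-negative and smaller than both ",
         "attenuation factors", call. = FALSE)
  }
  if (abs(cfg$ar1_phi) >= 1) stop("ar1_phi must satisfy |phi| < 1", call. = FALSE)
  if (cfg$flip_fraction < 0 || cfg$flip_fraction > 1) {
    stop("flip_fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}
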