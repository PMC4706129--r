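toy_atlas <- function() {
  # two tight spatial clusters; hclust puts each cluster in its own module
  coords <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(100, 0, 0), c(100.5, 0, 0),
                  c(50, 80, 0), c(50, -80, 0))
  new_atlas <- lewynet:::new_roi_atlas(
    labels = paste0("n", 1:6), coords = coords,
    tags = c("frontal", "frontal", "occipital", "occipital",
             "temporal", "parietal"))
  new_atlas
}

test_that("target correlation follows the distance-decay kernel with module boost", {
  atlas <- toy_atlas()
  cfg <- cohort_config(n_modules = 2L)
  S <- build_target_correlation(atlas, "HC", cfg, severity = 0)
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, 6))
  expect_true(all(abs(S[upper.tri(S)]) < 1))
  # same-module pair at d = 0.5 mm: near the zero-distance limit rho0*(1+mu)
  expected <- 0.5 * 1.5 * exp(-0.5 / 90)
  expect_equal(S["n1", "n2"], expected, tolerance = 0.02)
  expect_gt(S["n1", "n2"], 0.7)
})

test_that("projection yields a positive semi-definite correlation matrix", {
  atlas <- load_default_atlas()
  cfg <- cohort_config()
  for (g in c("HC", "DLB", "AD")) {
    S <- build_target_correlation(atlas, g, cfg, severity = 0.5)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(unname(diag(S)), rep(1, 112))
  }
})

test_that("group attenuation lowers the targeted couplings relative to control", {
  atlas <- load_default_atlas()
  cfg <- cohort_config()
  ctx <- sigma_context(atlas, cfg)
  S_hc <- build_target_correlation(atlas, "HC", cfg, 0.5, ctx)
  S_dlb <- build_target_correlation(atlas, "DLB", cfg, 0.5, ctx)
  S_ad <- build_target_correlation(atlas, "AD", cfg, 0.5, ctx)
  ut <- upper.tri(S_hc)
  long <- ctx$range_class == 3L & ut
  expect_true(all(S_dlb[long] < S_hc[long]))
  # AD: mean coupling drops at temporal-endpoint pairs, not elsewhere
  tp <- ctx$temporal_pair & ut
  expect_lt(mean(S_ad[tp]), mean(S_hc[tp]))
  expect_equal(mean(S_ad[!ctx$temporal_pair & ut]),
               mean(S_hc[!ctx$temporal_pair & ut]), tolerance = 0.01)
})

test_that("higher severity means stronger attenuation in patient groups", {
  atlas <- load_default_atlas()
  cfg <- cohort_config()
  ctx <- sigma_context(atlas, cfg)
  lo <- build_target_correlation(atlas, "DLB", cfg, 0, ctx)
  hi <- build_target_correlation(atlas, "DLB", cfg, 1, ctx)
  long <- ctx$range_class == 3L & upper.tri(lo)
  expect_lt(mean(hi[long]), mean(lo[long]))
})

test_that("sign flips are exercised when flip_fraction > 0", {
  atlas <- load_default_atlas()
  cfg <- cohort_config(flip_fraction = 0.2)
  S <- build_target_correlation(atlas, "HC", cfg, 0.5)
  expect_gt(sum(S[upper.tri(S)] < 0), 0)
  expect_true(all(absolute_matrix(S) >= 0))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(gamma_dlb = 1), "gamma_dlb")
  expect_error(cohort_config(gamma_ad = 0), "gamma_ad")
  expect_error(cohort_config(rho0 = 0.8, mu_module = 0.5), "rho0")
  expect_error(cohort_config(t_frames = 4), "t_frames")
  expect_error(cohort_config(ar1_phi = 1), "ar1_phi")
  expect_error(build_target_correlation(load_default_atlas(), "DLB",
                                        cohort_config(), severity = 2),
               "severity")
})

test_that("subject simulation is seed-deterministic", {
  atlas <- load_default_atlas()
  cfg <- cohort_config()
  a <- simulate_subject(atlas, "DLB", cfg, seed = 7, subject_id = "X")
  b <- simulate_subject(atlas, "DLB", cfg, seed = 7, subject_id = "X")
  expect_identical(a$ts, b$ts)
  expect_identical(a$motion, b$motion)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$severity, b$severity)
  c2 <- simulate_subject(atlas, "DLB", cfg, seed = 8, subject_id = "X")
  expect_false(identical(a$ts, c2$ts))
})

test_that("empirical correlation converges to the target at long scan length", {
  atlas <- load_default_atlas()
  cfg <- cohort_config(t_frames = 10000L)
  s <- simulate_subject(atlas, "HC", cfg, seed = 1)
  Sigma <- build_target_correlation(atlas, "HC", cfg, s$severity)
  emp <- pearson_matrix(s$ts)
  expect_lt(max(abs(emp - Sigma)), 0.05)
})

test_that("clinical scores are monotone in severity and respect ranges", {
  links <- default_clinical_links()
  set.seed(42)
  mmse0 <- replicate(100, lewynet:::simulate_clinical("DLB", 0, links)[["MMSE"]])
  mmse1 <- replicate(100, lewynet:::simulate_clinical("DLB", 1, links)[["MMSE"]])
  expect_gt(mean(mmse0), mean(mmse1))
  caf0 <- replicate(100, lewynet:::simulate_clinical("DLB", 0, links)[["CAF"]])
  caf1 <- replicate(100, lewynet:::simulate_clinical("DLB", 1, links)[["CAF"]])
  expect_lt(mean(caf0), mean(caf1))
  for (g in c("HC", "DLB", "AD")) {
    v <- replicate(50, lewynet:::simulate_clinical(g, runif(1), links))
    expect_true(all(v["MMSE", ] >= 0 & v["MMSE", ] <= 30))
    expect_true(all(v["CAF", ] >= 0 & v["CAF", ] <= 12))
  }
})

test_that("cohort has the default three-group composition and substreams", {
  atlas <- load_default_atlas()
  cfg <- cohort_config(seed = 3)
  co <- simulate_cohort(cfg, atlas)
  groups <- vapply(co$subjects, `[[`, "", "group")
  expect_length(co$subjects, 54L)
  expect_equal(unname(table(groups)[c("HC", "DLB", "AD")]),
               c(17L, 18L, 19L), ignore_attr = TRUE)
  # substream independence: subject k reproducible in isolation
  k <- 20L
  solo <- simulate_subject(atlas, groups[k], cfg,
                           seed = derive_seed(cfg$seed, k),
                           subject_id = co$subjects[[k]]$id,
                           ctx = sigma_context(atlas, cfg))
  expect_identical(solo$ts, co$subjects[[k]]$ts)
  expect_error(simulate_cohort(cohort_config(n_dlb = 0)), "at least 2")
  co2 <- simulate_cohort(cohort_config(seed = 4, n_control = 2, n_dlb = 2,
                                       n_ad = 2, t_frames = 16), atlas)
  co3 <- simulate_cohort(cohort_config(seed = 5, n_control = 2, n_dlb = 2,
                                       n_ad = 2, t_frames = 16), atlas)
  expect_false(identical(co2$subjects[[1]]$ts, co3$subjects[[1]]$ts))
})

test_that("cohort round-trips through the TSV interface", {
  atlas <- load_default_atlas()
  co <- simulate_cohort(cohort_config(seed = 2, n_control = 2, n_dlb = 2,
                                      n_ad = 2, t_frames = 16), atlas)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
  expect_true(file.exists(file.path(dir, "clinical.tsv")))
  ts <- as.matrix(lewynet:::read_tsv(file.path(dir, "ts_HC01.tsv")))
  expect_equal(dim(ts), c(16L, 112L))
  expect_equal(unname(ts), unname(co$subjects$HC01$ts), tolerance = 1e-12)
  mo <- lewynet:::read_tsv(file.path(dir, "motion_HC01.tsv"))
  expect_equal(ncol(mo), 6L)
  expect_equal(nrow(mo), 16L)
  unlink(dir, recursive = TRUE)
})
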