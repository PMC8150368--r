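test_that("the shipped panel carries the published anchors", {
  panel <- default_panel()
  expect_equal(panel$mean_agi[panel$name == "Catechin"], 27)
  expect_equal(panel$mean_xin[panel$name == "Catechin"], 65)
  expect_equal(panel$marker_class[panel$name == "Indolelactic acid glycoside"],
               "Xinomavro")
  expect_equal(sum(panel$marker), 17)          # the published marker count
  expect_equal(sum(panel$role == "target"), 22)
  expect_equal(sum(panel$role == "internal_standard"), 1)
  expect_gte(sum(panel$role == "suspect"), 35)
  # malformed / empty sources are rejected, never silently defaulted
  empty <- tempfile(fileext = ".tsv")
  writeLines("name\tformula", empty)
  expect_error(build_compound_panel(empty))
})

test_that("the generator is seed-deterministic and seed-mandatory", {
  d <- study_design(n_class_a = 5, n_class_b = 4, n_qc = 1)
  nz <- noise_config(n_decoys = 5)
  g1 <- generate_study(d, noise = nz, seed = 7)
  g2 <- generate_study(d, noise = nz, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_study(d, noise = nz, seed = 8)
  expect_false(identical(g1$features, g3$features))
  expect_error(generate_study(d, noise = nz), "seed")
  expect_error(generate_calibration_series(noise = nz), "seed")
})

test_that("the default design reproduces the published study structure", {
  gen <- generate_study(seed = 2)
  meta <- gen$metadata
  expect_equal(sum(meta$type == "sample"), 46)
  expect_equal(sum(meta$class == "Agiorgitiko", na.rm = TRUE), 27)
  expect_equal(sum(meta$class == "Xinomavro", na.rm = TRUE), 19)
  expect_equal(sum(meta$type == "qc"), 5)
  expect_equal(sum(meta$type == "blank"), 5)   # one blank per 10 injections
  expect_setequal(unique(meta$vintage[meta$type == "sample"]), c(2017, 2018))
  # blanks contain no panel compounds at all
  blank_feats <- gen$features[gen$features$sample_id %in%
                                meta$sample_id[meta$type == "blank"], ]
  expect_true(all(is.na(blank_feats$compound_truth)))
  # truth record covers every sample x analyte pair
  expect_equal(nrow(gen$truth$concentrations),
               46 * sum(default_panel()$role != "internal_standard"))
  expect_equal(nrow(gen$truth$markers), 17)
})

test_that("in the noiseless limit screening recovers everything and quantification is exact", {
  panel <- default_panel()
  panel$frag_prob <- 1
  quiet <- noise_config(mz_sd = 0, rt_sd = 0, iso_sd = 0, injection_cv = 0,
                        qc_cv = 0, cal_cv = 0, frag_jitter_sd = 0,
                        n_decoys = 0)
  d <- study_design(n_class_a = 4, n_class_b = 3, n_qc = 0)
  gen <- generate_study(d, panel, quiet, seed = 5)
  db_cols <- c("name", "formula", "adduct", "role", "theoretical_mz", "rt",
               "descriptor", "fragments", "evidence")
  tdb <- panel[panel$role %in% c("target", "internal_standard"), db_cols]
  sdb <- panel[panel$role == "suspect", db_cols]
  th <- target_screen(gen$features, tdb)
  sh <- suspect_screen(gen$features, sdb, rt_model = fit_rt_model(tdb))
  # every panel compound detected in every injection
  expect_equal(nrow(th), nrow(tdb) * 7)
  expect_equal(nrow(sh), nrow(sdb) * 7)
  # quantification round-trips the generated concentrations exactly
  cal <- generate_calibration_series(panel, d, quiet, seed = 6)
  fm <- build_feature_matrix(rbind(th, sh), gen$metadata)
  for (a in c("Catechin", "Gallic acid", "Quercetin")) {
    cur <- fit_calibration(cal$solvent$concentration[cal$solvent$analyte == a],
                           cal$solvent$response[cal$solvent$analyte == a])
    est <- quantify(fm$values[, a], cur)$concentration
    truth <- gen$truth$concentrations
    tv <- truth$conc[truth$compound == a][match(rownames(fm$values),
                                                truth$sample_id[truth$compound == a])]
    expect_equal(unname(est), tv, tolerance = 1e-8)
  }
})

test_that("decoy features never pass suspect screening (false-positive control)", {
  gen <- generate_study(design = study_design(n_class_a = 8, n_class_b = 6),
                        seed = 13)
  decoys <- gen$features[is.na(gen$features$compound_truth), ]
  expect_gt(nrow(decoys), 500)
  panel <- default_panel()
  sdb <- panel[panel$role == "suspect",
               c("name", "formula", "adduct", "role", "theoretical_mz", "rt",
                 "descriptor", "fragments", "evidence")]
  hits <- suspect_screen(decoys, sdb, rt_model = fit_rt_model(
    panel[panel$role == "target", ]))
  expect_equal(nrow(hits), 0L)
})

test_that("a zero effect-size multiplier controls the type-I error", {
  gen <- generate_study(noise = noise_config(effect_size = 0, n_decoys = 0),
                        seed = 19)
  tf <- truth_feature_matrix(gen)
  samp <- tf$metadata$type == "sample"
  out <- univariate_screen(tf$values[samp, ], tf$metadata$class[samp])
  # Bonferroni-adjusted discoveries on a null study are (near) zero
  expect_lte(sum(out$significant), 1)
  # and the planted contrast at full scale is found
  gen1 <- generate_study(noise = noise_config(n_decoys = 0), seed = 19)
  tf1 <- truth_feature_matrix(gen1)
  out1 <- univariate_screen(tf1$values[samp, ], tf1$metadata$class[samp])
  expect_true(out1$significant[out1$variable == "Catechin"])
  expect_gt(sum(out1$significant), 10)
})

test_that("QC injections cluster tighter than the biological samples", {
  gen <- generate_study(seed = 23)
  fmeat <- gen$features[!is.na(gen$features$compound_truth), ]
  qc_ids <- gen$metadata$sample_id[gen$metadata$type == "qc"]
  samp_ids <- gen$metadata$sample_id[gen$metadata$type == "sample"]
  rsd <- function(ids) {
    sub <- fmeat[fmeat$sample_id %in% ids, ]
    tapply(sub$area, sub$compound_truth, function(a) sd(a) / mean(a))
  }
  expect_lt(median(rsd(qc_ids)), median(rsd(samp_ids)))
})

test_that("calibration series are deterministic with in-band matrix effects", {
  c1 <- generate_calibration_series(seed = 29)
  c2 <- generate_calibration_series(seed = 29)
  expect_identical(c1, c2)
  expect_true(all(c1$suppression >= 0.7 & c1$suppression <= 1.2))
  # suppression factor 1 means 0% matrix effect; 0.7 means -30%
  a <- names(c1$slopes)[1]
  expect_equal(matrix_effect(c1$slopes[[a]] * 0.7, c1$slopes[[a]]), -30)
  expect_equal(matrix_effect(c1$slopes[[a]], c1$slopes[[a]]), 0)
  expect_error(generate_calibration_series(
    design = study_design(calibration_levels = c(1, 2, 3, 4)), seed = 1),
    "strictly increasing|5")
})
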