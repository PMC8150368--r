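test_that("target screening confirms a catechin-like hit and stores criterion values", {
  hits <- target_screen(make_feature(), make_target_db())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$compound, "Catechin")
  expect_equal(hits$identification_level, "1")
  expect_lt(abs(hits$mass_error - (-0.6)), 0.05)
  expect_lt(abs(hits$rt_error - 0.05), 1e-9)
  expect_lte(hits$msigma, 50)
  expect_gte(hits$n_fragments, 1)
})

test_that("target criteria are conjunctive: each just-failing value removes the hit", {
  db <- make_target_db()
  cr <- target_criteria()
  failing <- list(
    mass      = make_feature(mz = adduct_mz("C15H14O6") + 0.0025),
    rt        = make_feature(rt = 2.6 + 0.35),
    area      = make_feature(area = 700),
    intensity = make_feature(intensity = 150),
    msigma    = make_feature(iso1 = catechin_iso[2] + 0.08),
    fragments = make_feature(fragments = "")
  )
  expect_equal(nrow(target_screen(make_feature(), db, cr)), 1L)
  for (nm in names(failing)) {
    expect_equal(nrow(target_screen(failing[[nm]], db, cr)), 0L,
                 label = paste("criterion", nm))
  }
})

test_that("best feature per (compound, sample) wins by |mass error| then |rt error|", {
  feats <- rbind(make_feature(mz = 289.0712),           # -0.6 mDa
                 make_feature(mz = 289.0716, rt = 2.55)) # -0.2 mDa, closer mass
  hits <- target_screen(feats, make_target_db())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$feature_row, 2L)
  # equal mass error: smaller |rt error| wins
  feats2 <- rbind(make_feature(rt = 2.75), make_feature(rt = 2.62))
  hits2 <- target_screen(feats2, make_target_db())
  expect_equal(hits2$feature_row, 2L)
})

test_that("relaxing target thresholds to suspect levels yields a superset", {
  set.seed(5)
  feats <- do.call(rbind, lapply(1:12, function(i) {
    make_feature(mz = 289.0718 + runif(1, -0.004, 0.004),
                 rt = 2.6 + runif(1, -0.4, 0.4),
                 area = runif(1, 500, 5e4),
                 intensity = runif(1, 100, 8e3),
                 sample_id = paste0("S", i))
  }))
  strict <- target_screen(feats, make_target_db(), target_criteria())
  relaxed <- target_screen(feats, make_target_db(),
                           target_criteria(max_mass_error = 5,
                                           max_rt_error = 1.8,
                                           max_msigma = 100,
                                           min_area = 400,
                                           min_intensity = 80))
  key <- function(h) paste(h$compound, h$sample_id)
  expect_true(all(key(strict) %in% key(relaxed)))
  expect_gt(nrow(relaxed), nrow(strict))
})

test_that("empty target database warns and returns no hits", {
  db <- make_target_db()[0, ]
  expect_warning(hits <- target_screen(make_feature(), db), "empty")
  expect_equal(nrow(hits), 0L)
})

test_that("suspect screening identifies the indolelactic-glucoside fixture", {
  hits <- suspect_screen(make_ila_feature(), make_suspect_db(),
                         rt_model = make_rt_model())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identification_level, "3")
  expect_lt(abs(hits$mass_error), 1)
  expect_gt(hits$peak_score, 4)
})

test_that("suspect criteria are conjunctive", {
  db <- make_suspect_db()
  rtm <- make_rt_model()
  failing <- list(
    mass       = make_ila_feature(mz = adduct_mz("C17H21NO8") + 0.006),
    area       = make_ila_feature(area = 1900, intensity = 380),
    intensity  = make_ila_feature(intensity = 700, area = 2.1e4),
    msigma     = make_ila_feature(iso1 = ila_iso[2] + 0.15),
    peak_score = make_ila_feature(area = 7800, intensity = 2000),  # score 3.9
    rt_window  = make_ila_feature(rt = 3.48 + 2.5),
    fragments  = make_ila_feature(fragments = "")
  )
  expect_equal(nrow(suspect_screen(make_ila_feature(), db, rt_model = rtm)), 1L)
  for (nm in names(failing)) {
    expect_equal(nrow(suspect_screen(failing[[nm]], db, rt_model = rtm)), 0L,
                 label = paste("criterion", nm))
  }
})

test_that("the predicted-RT window only gates entries inside the domain", {
  rtm <- make_rt_model()
  feat <- make_ila_feature(rt = 3.48 + 2.5)
  in_dom <- make_suspect_db()                    # descriptor inside [1, 10]
  out_dom <- make_suspect_db(descriptor = 30)    # far outside training range
  expect_equal(nrow(suspect_screen(feat, in_dom, rt_model = rtm)), 0L)
  hits <- suspect_screen(feat, out_dom, rt_model = rtm)
  expect_equal(nrow(hits), 1L)
  expect_false(is.na(hits$rt_error))  # recorded even when not gated
})

test_that("suspect screening without RT predictions or model is a configuration error", {
  expect_error(suspect_screen(make_ila_feature(), make_suspect_db()),
               "rt_model")
})

test_that("identification levels follow the evidence ladder, strongest first", {
  expect_equal(assign_identification_level(reference_standard = TRUE), "1")
  expect_equal(assign_identification_level(library_spectrum_match = TRUE), "2a")
  expect_equal(assign_identification_level(diagnostic_evidence = TRUE), "2b")
  expect_equal(assign_identification_level(), "3")
  # contradictory flags resolve to the strongest evidence
  expect_equal(assign_identification_level(TRUE, TRUE, TRUE), "1")
  expect_equal(assign_identification_level(FALSE, TRUE, TRUE), "2a")
  expect_equal(assign_identification_level(c(TRUE, FALSE), c(FALSE, TRUE)),
               c("1", "2a"))
})

test_that("the QSRR stand-in interpolates training points and flags the domain", {
  rtm <- make_rt_model()
  pred <- predict_retention_time(c(3, 30, NA), rtm)
  expect_lt(abs(pred$rt[1] - (1 + 0.6 * 3)), 0.05)
  expect_equal(pred$in_domain, c(TRUE, FALSE, FALSE))
  expect_true(is.na(pred$rt[3]))
  expect_error(fit_rt_model(data.frame(descriptor = 1:2, rt = 1:2)), "3")
})

test_that("in-domain suspect RT predictions land within 2 min of truth for >= 90%", {
  panel <- default_panel()
  rtm <- fit_rt_model(panel[panel$role == "target", ])
  susp <- panel[panel$role == "suspect", ]
  pred <- predict_retention_time(susp$descriptor, rtm)
  err <- abs(pred$rt - susp$rt)[pred$in_domain]
  expect_gte(mean(err <= 2), 0.9)
  expect_true(any(!pred$in_domain))  # the panel carries an out-of-domain entry
})

test_that("prevalence and blank filters apply the 80% / contamination rules", {
  meta <- data.frame(
    sample_id = c(sprintf("A%02d", 1:27), sprintf("B%02d", 1:19), "BL1"),
    class = c(rep("ClassA", 27), rep("ClassB", 19), NA),
    type = c(rep("sample", 46), "blank"), stringsAsFactors = FALSE)
  hit <- function(compound, ids, area = 1e4) {
    data.frame(compound = compound, sample_id = ids, area = area,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    hit("ok_81pct", sprintf("A%02d", 1:22)),          # 22/27 = 81% of class A
    hit("low_both", c(sprintf("A%02d", 1:21), sprintf("B%02d", 1:14))),
    hit("contam", c(sprintf("A%02d", 1:27), "BL1")))  # present in blank
  out <- prevalence_blank_filter(hits, meta)
  expect_true(out$retained[out$compound == "ok_81pct"])
  expect_false(out$retained[out$compound == "low_both"])  # 78% and 74%
  expect_false(out$retained[out$compound == "contam"])
  expect_true(out$in_blank[out$compound == "contam"])
  # a trace blank signal below 10% of the sample median is not contamination
  hits_tr <- rbind(hit("trace_blank", sprintf("A%02d", 1:27)),
                   hit("trace_blank", "BL1", area = 500))
  expect_true(prevalence_blank_filter(hits_tr, meta)$retained)
  expect_warning(prevalence_blank_filter(hits, meta[meta$type != "blank", ]),
                 "no blanks")
})

test_that("every returned hit satisfies its own stored criterion values", {
  gen <- generate_study(design = study_design(n_class_a = 6, n_class_b = 5,
                                              n_qc = 1),
                        noise = noise_config(n_decoys = 15), seed = 42)
  panel <- default_panel()
  db_cols <- c("name", "formula", "adduct", "role", "theoretical_mz", "rt",
               "descriptor", "fragments", "evidence")
  tdb <- panel[panel$role %in% c("target", "internal_standard"), db_cols]
  sdb <- panel[panel$role == "suspect", db_cols]
  rtm <- fit_rt_model(tdb)
  th <- target_screen(gen$features, tdb)
  cr <- target_criteria()
  expect_gt(nrow(th), 0)
  expect_true(all(abs(th$mass_error) < cr$max_mass_error))
  expect_true(all(abs(th$rt_error) < cr$max_rt_error))
  expect_true(all(th$msigma <= cr$max_msigma))
  expect_true(all(th$area > cr$min_area & th$intensity > cr$min_intensity))
  expect_true(all(th$n_fragments >= cr$min_fragments))
  sh <- suspect_screen(gen$features, sdb, rt_model = rtm)
  scr <- suspect_criteria()
  expect_gt(nrow(sh), 0)
  expect_true(all(abs(sh$mass_error) < scr$max_mass_error))
  expect_true(all(sh$msigma < scr$max_msigma))
  expect_true(all(sh$peak_score > scr$min_peak_score))
  expect_true(all(sh$area > scr$min_area & sh$intensity > scr$min_intensity))
})
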