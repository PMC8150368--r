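#!/usr/bin/env Rscript
# Step 3 — screening: match every injection's peak list against the target
# panel (mass < 2 mDa, RT < 0.2 min, mSigma <= 50, area > 800, intensity
# > 200, >= 1 fragment) and the suspect database (mass < 5 mDa, area
# > 2000, intensity > 800, mSigma < 100, peak score > 4, 1.8-min predicted
# RT window for in-domain entries), then apply the 80% per-class prevalence
# and blank-contamination filters.
library(oenoscreen)

seed <- 1
dir.create("results", showWarnings = FALSE)

gen <- generate_study(seed = seed)
panel <- default_panel()
db_cols <- c("name", "formula", "adduct", "role", "theoretical_mz", "rt",
             "descriptor", "fragments", "compound_class", "evidence")
tdb <- panel[panel$role %in% c("target", "internal_standard"), db_cols]
sdb <- panel[panel$role == "suspect", db_cols]
rtm <- fit_rt_model(tdb)

th <- target_screen(gen$features, tdb)
sh <- suspect_screen(gen$features, sdb, rt_model = rtm)
hits <- rbind(th, sh)
pf <- prevalence_blank_filter(hits, gen$metadata)

write_report(hits, "results/screening_hits.tsv", header = c(seed = seed))
write_report(pf, "results/prevalence_filter.tsv", header = c(seed = seed))

cat(sprintf("%d features screened: %d target hits, %d suspect hits\n",
            nrow(gen$features), nrow(th), nrow(sh)))
cat(sprintf("suspect compounds detected: %d (of %d in the database), retained after prevalence/blank filter: %d\n",
            length(unique(sh$compound)), nrow(sdb),
            sum(pf$retained & pf$compound %in% sdb$name)))
cat(sprintf("identification levels: %s\n",
            paste(names(table(hits$identification_level)),
                  table(hits$identification_level), sep = "=", collapse = ", ")))
pred <- predict_retention_time(sdb$descriptor, rtm)
cat(sprintf("QSRR: %d/%d suspects in the applicability domain\n",
            sum(pred$in_domain), nrow(sdb)))
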