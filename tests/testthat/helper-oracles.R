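# Independent oracles and fixture builders shared across test files.

# single-component PLS1 (NIPALS closed form), independent of the package's
# OPLS implementation path
pls1_oracle <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  w <- drop(crossprod(xc, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(xc %*% w)
  p1 <- drop(crossprod(xc, t1)) / sum(t1^2)
  list(w = w, t1 = t1, p1 = p1)
}

# isotope-cluster distribution by FFT-based open convolution (full length,
# truncated only at the end) -- a different numerical route than the
# package's direct truncated polynomial powers
conv_isotope_oracle <- function(formula, n_peaks = 3L) {
  counts <- oenoscreen::parse_formula(formula)
  iso <- oenoscreen::isotope_table()
  p <- 1
  for (el in names(counts)) {
    sub <- iso[iso$element == el, ]
    v <- numeric(max(sub$shift) + 1)
    v[sub$shift + 1] <- sub$abundance
    for (k in seq_len(counts[[el]])) {
      p <- stats::convolve(p, rev(v), type = "open")
    }
  }
  p <- p[seq_len(min(n_peaks, length(p)))]
  p / max(p)
}

# AUC by exhaustive pair counting (ties get half credit)
auc_pairs_oracle <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- screening fixtures -----------------------------------------------------

catechin_iso <- oenoscreen::theoretical_isotope_pattern("C15H14O6", 3)$intensity

make_target_db <- function() {
  data.frame(name = "Catechin", formula = "C15H14O6", adduct = "[M-H]-",
             role = "target", rt = 2.6, fragments = "245.0820;271.0612",
             evidence = "standard", stringsAsFactors = FALSE)
}

make_feature <- function(mz = 289.0712, rt = 2.65, area = 5e4,
                         intensity = 8e3, iso1 = catechin_iso[2],
                         iso2 = catechin_iso[3], fragments = "245.0820",
                         sample_id = "S1") {
  data.frame(sample_id = sample_id, mz = mz, rt = rt, area = area,
             intensity = intensity, iso1 = iso1, iso2 = iso2,
             fragments = fragments, stringsAsFactors = FALSE)
}

ila_iso <- oenoscreen::theoretical_isotope_pattern("C17H21NO8", 3)$intensity

make_suspect_db <- function(descriptor = 4.1333) {
  # descriptor maps to rt 3.48 under the linear rt model of make_rt_model()
  data.frame(name = "Indolelactic acid glycoside", formula = "C17H21NO8",
             adduct = "[M-H]-", role = "suspect", descriptor = descriptor,
             fragments = "204.0670;186.0560;142.0635", evidence = "none",
             stringsAsFactors = FALSE)
}

make_ila_feature <- function(mz = 366.1195, rt = 3.48, area = 2.5e4,
                             intensity = 2e3, fragments = "204.0670",
                             sample_id = "S1", iso1 = ila_iso[2],
                             iso2 = ila_iso[3]) {
  make_feature(mz = mz, rt = rt, area = area, intensity = intensity,
               iso1 = iso1, iso2 = iso2, fragments = fragments,
               sample_id = sample_id)
}

# exactly linear descriptor -> rt training set: rt = 1 + 0.6 d
make_rt_model <- function() {
  oenoscreen::fit_rt_model(
    data.frame(descriptor = 1:10, rt = 1 + 0.6 * (1:10)), lambda = 1e-9)
}

# samples x compounds matrix of noise-free IS-normalized abundances,
# reconstructed from the generator's truth record
truth_feature_matrix <- function(gen, panel = oenoscreen::default_panel()) {
  tc <- gen$truth$concentrations
  x <- t(with(tc, tapply(conc, list(compound, sample_id), identity)))
  rf <- panel$response_factor[match(colnames(x), panel$name)]
  is_area <- panel$response_factor[panel$role == "internal_standard"][1] * 2
  x <- sweep(x, 2, rf, `*`) / is_area
  meta <- gen$metadata[match(rownames(x), gen$metadata$sample_id), ]
  list(values = x, metadata = meta)
}
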