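test_that("OPLS-DA with zero orthogonal components equals the PLS1 oracle", {
  for (dims in list(c(10, 5), c(20, 8), c(30, 15))) {
    set.seed(sum(dims))
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    y <- rep_len(c(0, 1), dims[1])
    fit <- fit_oplsda(x, y, n_ortho = 0)
    oracle <- pls1_oracle(x, y)
    expect_lt(max(abs(fit$t1 - oracle$t1)), 1e-8)
    expect_lt(max(abs(unname(fit$p1) - oracle$p1)), 1e-8)
    expect_lt(max(abs(unname(fit$w) - oracle$w)), 1e-8)
  }
})

test_that("orthogonal scores carry no class information", {
  set.seed(21)
  x <- matrix(rnorm(240), 24, 10)
  y <- rep_len(c("A", "B"), 24)
  fit <- fit_oplsda(x, y, n_ortho = 2)
  yenc <- as.numeric(factor(y)) - 1
  for (i in seq_len(fit$n_ortho)) {
    expect_lt(abs(cor(fit$T_o[, i], yenc)), 1e-10)
  }
  # filtered predictive component explains the response at least as well
  fit0 <- fit_oplsda(x, y, n_ortho = 0)
  expect_gte(fit$r2y + 1e-12, fit0$r2y)
})

test_that("model guards: single class, rank limit, column mismatch", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_oplsda(x, rep("A", 10)), "two classes")
  expect_error(fit_oplsda(x, rep_len(c("A", "B"), 10), n_ortho = 3), "rank")
  fit <- fit_oplsda(x, rep_len(c("A", "B"), 10), n_ortho = 0)
  expect_error(predict(fit, x[, 1:3]), "columns")
})

test_that("VIP is normalized to unit mean square and proportional to |w|", {
  set.seed(31)
  for (k in 0:2) {
    x <- matrix(rnorm(26 * 9), 26, 9)
    y <- rep_len(c(0, 1), 26)
    fit <- fit_oplsda(x, y, n_ortho = k)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-12)
    # single predictive component: VIP / |w| is the same for every variable
    ratio <- fit$vip / abs(fit$w)
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  }
  # all-equal weights give VIP = 1 everywhere; strict > 1 selects nothing
  fake <- structure(list(
    w = stats::setNames(rep(0.2, 5), paste0("V", 1:5)),
    p1 = stats::setNames(rep(0.1, 5), paste0("V", 1:5)),
    pcorr1 = stats::setNames(rep(0.3, 5), paste0("V", 1:5)),
    classes = c("A", "B")), class = "oplsda")
  fake$vip <- compute_vip(fake)
  expect_equal(unname(fake$vip), rep(1, 5))
  expect_equal(nrow(select_markers(fake)), 0L)
})

test_that("p(corr) is the correlation of variables with the predictive score", {
  set.seed(41)
  x <- matrix(rnorm(200), 20, 10)
  y <- rep_len(c(0, 1), 20)
  fit <- fit_oplsda(x, y, n_ortho = 1)
  expect_equal(unname(fit$pcorr1), drop(cor(fit$t1, scale(x, scale = FALSE))),
               tolerance = 1e-12)
  expect_true(all(abs(fit$pcorr1) <= 1))
})

test_that("max-dist prediction thresholds at 0.5 with majority tie-break", {
  model <- structure(list(
    w = c(a = 1, b = 0), c_coef = 1, y_mean = 0.5, n_ortho = 0L,
    W_o = matrix(0, 2, 0), P_o = matrix(0, 2, 0),
    x_mean = c(a = 0, b = 0), classes = c("Agi", "Xin"),
    y = c(0, 0, 1, 1, 1)), class = "oplsda")
  nd <- matrix(c(0.4, -0.4, 0, 0, 0, 0), 3, 2,
               dimnames = list(NULL, c("a", "b")))
  pr <- predict_class_maxdist(model, nd)
  expect_equal(pr$y_hat, c(0.9, 0.1, 0.5))
  expect_equal(pr$labels, c("Xin", "Agi", "Xin"))  # tie -> majority class
})

test_that("cross-validated Q2Y is below R2Y and deterministic given the seed", {
  set.seed(51)
  x <- matrix(rnorm(280), 28, 10)
  y <- rep_len(c("A", "B"), 28)
  x[y == "B", 1:3] <- x[y == "B", 1:3] + 2.5
  fit <- fit_oplsda(x, y, n_ortho = 1)
  q2a <- cross_validate_q2(x, y, n_ortho = 1, seed = 99)
  q2b <- cross_validate_q2(x, y, n_ortho = 1, seed = 99)
  expect_identical(q2a, q2b)
  expect_gt(q2a, 0.5)          # separable data predicts well
  expect_gte(fit$r2y, q2a)     # fit never below cross-validated performance
  expect_error(cross_validate_q2(x[1:5, ], y[1:5], folds = 7), "folds")
})

test_that("the first-maximum Q2Y rule selects the orthogonal component count", {
  set.seed(61)
  n <- 40
  y <- rep_len(c("A", "B"), n)
  yenc <- as.numeric(factor(y)) - 1
  conf <- rnorm(n, sd = 4)  # strong structured variation orthogonal to class
  x <- cbind(outer(yenc, rep(1, 3)) + matrix(rnorm(n * 3, sd = 0.6), n),
             outer(conf, rep(1, 5)) + matrix(rnorm(n * 5, sd = 0.3), n),
             matrix(rnorm(n * 4), n))
  sel <- select_n_orthogonal(x, y, max_ortho = 3, seed = 5)
  expect_gte(sel$n_ortho, 1)  # the confounder warrants orthogonal filtering
  expect_equal(sel$q2y, max(sel$trace$q2y))
  # the trace stops one step after the first maximum
  expect_lte(nrow(sel$trace), sel$n_ortho + 2)
})

test_that("permutation testing separates real from chance class structure", {
  set.seed(71)
  n <- 30
  y <- rep_len(c("A", "B"), n)
  yenc <- as.numeric(factor(y)) - 1
  x <- cbind(outer(yenc, rep(1, 4)), matrix(0, n, 4)) +
    matrix(rnorm(n * 8, sd = 0.4), n, 8)
  pt <- permutation_test_oplsda(x, y, n_ortho = 0, n_perm = 20, seed = 8)
  expect_equal(nrow(pt$permuted), 20)
  expect_true(all(pt$permuted$q2y < pt$actual$q2y))
  # identical permutation set on rerun with the same seed
  pt2 <- permutation_test_oplsda(x, y, n_ortho = 0, n_perm = 20, seed = 8)
  expect_identical(pt$permuted, pt2$permuted)
  # pure noise: the actual Q2Y sits inside the permuted distribution
  xn <- matrix(rnorm(n * 8), n, 8)
  ptn <- permutation_test_oplsda(xn, y, n_ortho = 0, n_perm = 20, seed = 8)
  expect_gt(mean(ptn$permuted$q2y >= ptn$actual$q2y), 0)
  expect_error(permutation_test_oplsda(x, y, n_perm = 0), "n_perm")
})

test_that("ROC AUC equals the normalized Mann-Whitney pair count", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5), y), 1.0)
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), y), 0.0)
  set.seed(81)
  for (i in 1:10) {
    sc <- sample(1:6, 12, replace = TRUE)  # forces ties
    lab <- rep_len(c(0, 1), 12)
    expect_equal(roc_auc(sc, lab), auc_pairs_oracle(sc, lab))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "two classes")
})

test_that("marker selection is threshold-monotone and sign-maps classes", {
  set.seed(91)
  n <- 24
  y <- rep_len(c("Agi", "Xin"), n)
  yenc <- as.numeric(factor(y)) - 1
  x <- cbind(up = yenc * 2, down = -yenc * 2,
             matrix(rnorm(n * 6, sd = 0.5), n)) +
    matrix(rnorm(n * 8, sd = 0.3), n)
  colnames(x) <- c("up", "down", paste0("n", 1:6))
  fit <- fit_oplsda(x, y, n_ortho = 0)
  mk1 <- select_markers(fit, 1)
  mk2 <- select_markers(fit, 2)
  expect_true(all(mk2$variable %in% mk1$variable))  # monotone in threshold
  expect_true(all(diff(mk1$vip) <= 0))              # sorted descending
  expect_equal(mk1$class[mk1$variable == "up"], "Xin")
  expect_equal(mk1$class[mk1$variable == "down"], "Agi")
  vplot <- attr(mk1, "vplot")
  expect_equal(nrow(vplot), ncol(x))
})

test_that("scaling-method ranking returns bounded, reproducible scores", {
  gen <- generate_study(design = study_design(n_class_a = 12, n_class_b = 10,
                                              n_qc = 0),
                        noise = noise_config(n_decoys = 0), seed = 17)
  # raw concentrations: organic acids dominate the scale by orders of
  # magnitude, the regime scaling is meant to fix
  tc <- gen$truth$concentrations
  x <- t(with(tc, tapply(conc, list(compound, sample_id), identity)))
  meta <- gen$metadata[match(rownames(x), gen$metadata$sample_id), ]
  y <- meta$class
  rk <- rank_scaling_methods(x, y, seed = 2)
  expect_true(all(rk$score >= 0 & rk$score <= 1))
  expect_true(all(diff(rk$score) <= 0))
  rk2 <- rank_scaling_methods(x, y, seed = 2)
  expect_identical(rk, rk2)
  # concentration-scale heteroscedasticity: pareto or auto outranks "none"
  s <- function(m) rk$score[rk$method == m]
  expect_gt(max(s("pareto"), s("auto")), s("none"))
})
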