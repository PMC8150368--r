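# OPLS-DA for two-class discrimination: orthogonal-signal-correction NIPALS
# with one predictive component, VIP and p(corr), cross-validated Q2Y,
# permutation testing, ROC and max-dist class prediction.

.encode_classes <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) stop("exactly two classes required")
  list(enc = as.numeric(f) - 1, classes = levels(f))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures, Trygg-Wold style: the class
#' response (0/1 encoding) defines one predictive component; variation in X
#' orthogonal to the response is peeled off into `n_ortho`
#' orthogonal-signal-correction components before the predictive component
#' is extracted.  With `n_ortho = 0` the predictive component coincides
#' with single-component PLS1.
#'
#' @param x Numeric matrix (samples x variables), already column-scaled
#'   (e.g. Pareto); the fit centers columns internally.
#' @param y Two-level class vector (factor, character or 0/1 numeric).
#' @param n_ortho Number of orthogonal components (>= 0).
#' @return An `oplsda` object: predictive weights/loadings/scores (`w`,
#'   `p1`, `t1`), orthogonal `W_o`/`P_o`/`T_o`, per-variable `vip` and
#'   `pcorr1`, `r2x`, `r2y`, `rmsee`, fitted values and the class encoding.
#' @export
fit_oplsda <- function(x, y, n_ortho = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  cls <- .encode_classes(y)
  yenc <- cls$enc
  stopifnot(nrow(x) == length(yenc), n_ortho >= 0)
  x_mean <- colMeans(x)
  xc0 <- sweep(x, 2, x_mean)
  r <- qr(xc0)$rank
  if (n_ortho >= r - 1) {
    stop("n_ortho (", n_ortho, ") must be smaller than rank(X) - 1 = ", r - 1)
  }
  y_mean <- mean(yenc)
  yc <- yenc - y_mean
  m <- ncol(x)

  xc <- xc0
  W_o <- P_o <- matrix(0, m, 0)
  T_o <- matrix(0, nrow(x), 0)
  for (i in seq_len(n_ortho)) {
    w <- drop(crossprod(xc, yc))
    w <- w / sqrt(sum(w^2))
    t_p <- drop(xc %*% w)
    p <- drop(crossprod(xc, t_p)) / sum(t_p^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) {
      warning("no orthogonal variation left after ", i - 1,
              " component(s); stopping early")
      break
    }
    w_o <- w_o / nw
    t_o <- drop(xc %*% w_o)
    p_o <- drop(crossprod(xc, t_o)) / sum(t_o^2)
    xc <- xc - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  w <- drop(crossprod(xc, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(xc %*% w)
  p1 <- drop(crossprod(xc, t1)) / sum(t1^2)
  c_coef <- sum(yc * t1) / sum(t1^2)

  fitted <- t1 * c_coef + y_mean
  res <- yenc - fitted
  ssx <- sum(xc0^2)
  expl <- sum(t1^2) * sum(p1^2)
  if (ncol(T_o)) {
    expl <- expl + sum(vapply(seq_len(ncol(T_o)), function(i) {
      sum(T_o[, i]^2) * sum(P_o[, i]^2)
    }, numeric(1)))
  }
  sds <- apply(xc0, 2, stats::sd)
  pcorr1 <- rep(NA_real_, m)
  ok <- sds > 0
  pcorr1[ok] <- drop(stats::cor(t1, xc0[, ok, drop = FALSE]))

  model <- structure(list(
    w = stats::setNames(w, colnames(x)),
    p1 = stats::setNames(p1, colnames(x)),
    t1 = t1, c_coef = c_coef,
    W_o = W_o, P_o = P_o, T_o = T_o, n_ortho = ncol(W_o),
    x_mean = x_mean, y_mean = y_mean,
    classes = cls$classes, y = yenc, fitted = fitted,
    pcorr1 = stats::setNames(pcorr1, colnames(x)),
    r2x = expl / ssx,
    r2y = 1 - sum(res^2) / sum(yc^2),
    rmsee = sqrt(mean(res^2))
  ), class = "oplsda")
  model$vip <- compute_vip(model)
  model
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive +", x$n_ortho, "orthogonal component(s)\n")
  cat(sprintf("  classes: %s (0) vs %s (1)\n", x$classes[1], x$classes[2]))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  RMSEE = %.4f\n",
              x$r2x, x$r2y, x$rmsee))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP from the predictive-component weights, normalized so that the mean
#' squared VIP over variables is exactly 1; with a single predictive
#' component VIP is proportional to |w|, so VIP > 1 flags variables whose
#' weight exceeds the root-mean-square weight.
#'
#' @param model An [fit_oplsda()] model.
#' @return Named numeric vector of VIP scores.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  w <- model$w
  sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
}

#' Predict continuous response for new samples
#'
#' Applies the training centering, removes the stored orthogonal
#' components, and projects on the predictive weights.
#'
#' @param object An `oplsda` model.
#' @param newdata Matrix with the training variables (scaled like the
#'   training data).
#' @param ... Unused.
#' @return List with `y_hat` (continuous response on the 0/1 encoding) and
#'   `t1` (predictive scores).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean) ||
      (!is.null(colnames(newdata)) &&
       !identical(colnames(newdata), names(object$w)))) {
    stop("newdata columns do not match the training variables")
  }
  xn <- sweep(newdata, 2, object$x_mean)
  for (i in seq_len(object$n_ortho)) {
    t_o <- drop(xn %*% object$W_o[, i])
    xn <- xn - tcrossprod(t_o, object$P_o[, i])
  }
  t1 <- drop(xn %*% object$w)
  list(y_hat = t1 * object$c_coef + object$y_mean, t1 = t1)
}

#' Max-dist class prediction
#'
#' Assigns each sample to the class whose encoded value (0 or 1) is nearest
#' to the predicted continuous response; a response of exactly 0.5 goes to
#' the majority training class.
#'
#' @param model An `oplsda` model.
#' @param newdata Matrix of (scaled) new samples.
#' @param y_true Optional true classes for accuracy / RMSEP.
#' @return List with `labels`, `y_hat`, and — when `y_true` is given —
#'   `accuracy` (fraction correct) and `rmsep` (on the encoded response).
#' @export
predict_class_maxdist <- function(model, newdata, y_true = NULL) {
  pr <- predict.oplsda(model, newdata)
  majority <- model$classes[1 + (mean(model$y) > 0.5)]
  lab <- ifelse(pr$y_hat > 0.5, model$classes[2],
                ifelse(pr$y_hat < 0.5, model$classes[1], majority))
  out <- list(labels = lab, y_hat = pr$y_hat)
  if (!is.null(y_true)) {
    yt <- factor(y_true, levels = model$classes)
    if (anyNA(yt)) stop("y_true contains classes unseen in training")
    out$accuracy <- mean(lab == as.character(yt))
    out$rmsep <- sqrt(mean(((as.numeric(yt) - 1) - pr$y_hat)^2))
  }
  out
}

# stratified fold assignment: class-wise shuffle then round-robin
.stratified_folds <- function(yenc, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(yenc))
  for (cl in unique(yenc)) {
    idx <- sample(which(yenc == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated predictive performance Q2Y
#'
#' Leave-one-seventh-out (by default) cross validation with class-stratified
#' folds: Q2Y = 1 - PRESS / TSS on the encoded response.
#'
#' @param x Scaled matrix; @param y two-level classes.
#' @param n_ortho Orthogonal components per refit.
#' @param folds Number of CV folds (default 7).
#' @param seed Seed for the fold shuffle (deterministic folds given seed).
#' @return Q2Y (scalar).
#' @export
cross_validate_q2 <- function(x, y, n_ortho = 1L, folds = 7L, seed = NULL) {
  x <- as.matrix(x)
  cls <- .encode_classes(y)
  yenc <- cls$enc
  if (nrow(x) < folds) stop("need at least as many samples as folds")
  if (any(table(yenc) < 2)) stop("each class needs at least 2 samples")
  fold <- .stratified_folds(yenc, folds, seed)
  press <- 0
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(yenc[tr])) < 2) {
      stop("cross-validation fold left a single-class training set")
    }
    fit <- fit_oplsda(x[tr, , drop = FALSE], yenc[tr], n_ortho = n_ortho)
    pr <- predict.oplsda(fit, x[!tr, , drop = FALSE])
    press <- press + sum((yenc[!tr] - pr$y_hat)^2)
  }
  1 - press / sum((yenc - mean(yenc))^2)
}

#' Choose the number of orthogonal components by the Q2Y rule
#'
#' Adds orthogonal components while the cross-validated Q2Y improves and
#' stops at the first maximum, favouring model simplicity.
#'
#' @inheritParams cross_validate_q2
#' @param max_ortho Largest number of orthogonal components considered.
#' @return List with `n_ortho`, the selected `q2y`, and the full `trace`.
#' @export
select_n_orthogonal <- function(x, y, max_ortho = 3L, folds = 7L, seed = NULL) {
  q2 <- cross_validate_q2(x, y, n_ortho = 0L, folds = folds, seed = seed)
  trace <- data.frame(n_ortho = 0L, q2y = q2)
  best <- 0L
  for (k in seq_len(max_ortho)) {
    qk <- tryCatch(
      cross_validate_q2(x, y, n_ortho = k, folds = folds, seed = seed),
      error = function(e) -Inf)
    trace <- rbind(trace, data.frame(n_ortho = k, q2y = qk))
    if (qk > trace$q2y[trace$n_ortho == best]) best <- k else break
  }
  list(n_ortho = best, q2y = trace$q2y[trace$n_ortho == best], trace = trace)
}

#' Permutation test of R2Y / Q2Y
#'
#' Refits the model on `n_perm` random permutations of the class labels; a
#' reliable model's actual Q2Y exceeds all permuted values.
#'
#' @inheritParams cross_validate_q2
#' @param n_perm Number of permutations (default 20).
#' @return List with `actual` (one-row data frame of R2Y/Q2Y) and
#'   `permuted` (`n_perm` rows).
#' @export
permutation_test_oplsda <- function(x, y, n_ortho = 1L, n_perm = 20L,
                                    folds = 7L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  x <- as.matrix(x)
  cls <- .encode_classes(y)
  actual_fit <- fit_oplsda(x, y, n_ortho = n_ortho)
  actual <- data.frame(
    r2y = actual_fit$r2y,
    q2y = cross_validate_q2(x, y, n_ortho = n_ortho, folds = folds, seed = seed)
  )
  set.seed(seed)
  perms <- replicate(n_perm, sample(cls$enc), simplify = FALSE)
  permuted <- do.call(rbind, lapply(seq_along(perms), function(i) {
    yp <- perms[[i]]
    fit <- fit_oplsda(x, yp, n_ortho = n_ortho)
    data.frame(
      perm = i, r2y = fit$r2y,
      q2y = cross_validate_q2(x, yp, n_ortho = n_ortho, folds = folds,
                              seed = seed + i)
    )
  }))
  list(actual = actual, permuted = permuted)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over all thresholds, computed through its equivalence
#' with the normalized Mann-Whitney U statistic (ties get half credit).
#'
#' @param scores Continuous classifier scores (higher = more like the
#'   positive class).
#' @param labels Two-level class vector; the second factor level is the
#'   positive class.
#' @return AUC between 0 and 1.
#' @export
roc_auc <- function(scores, labels) {
  cls <- .encode_classes(labels)
  n1 <- sum(cls$enc == 1)
  n0 <- sum(cls$enc == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[cls$enc == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select VIP markers and V-plot coordinates
#'
#' Variables with VIP above the threshold (strictly), carrying the
#' predictive loading p1 and p(corr); the sign of p1 maps each marker to a
#' class (positive = second class of the encoding).  Sorted by VIP
#' descending.  The full V-plot coordinate table (p1, p(corr), VIP for all
#' variables) is attached as attribute `"vplot"`.
#'
#' @param model An `oplsda` model.
#' @param vip_threshold Strict VIP cutoff (default 1).
#' @return Data frame `variable`, `class`, `p1`, `pcorr1`, `vip`.
#' @export
select_markers <- function(model, vip_threshold = 1) {
  stopifnot(inherits(model, "oplsda"))
  vplot <- data.frame(variable = names(model$w), p1 = unname(model$p1),
                      pcorr1 = unname(model$pcorr1),
                      vip = unname(model$vip), stringsAsFactors = FALSE)
  keep <- vplot[vplot$vip > vip_threshold, , drop = FALSE]
  keep$class <- ifelse(keep$p1 > 0, model$classes[2], model$classes[1])
  keep <- keep[order(-keep$vip), c("variable", "class", "p1", "pcorr1", "vip")]
  rownames(keep) <- NULL
  structure(keep, vplot = vplot)
}

#' Rank column-scaling methods by model performance
#'
#' Fits the whole classification pipeline (scale, Kennard-Stone split,
#' OPLS-DA) once per candidate scaling method and scores each method by the
#' mean of min-max-normalized {Q2Y, external accuracy, 1 - RMSEP} — a
#' composite between 0 and 1 standing in for the published ranking score whose
#' formula is not public.
#'
#' @param x Unscaled feature matrix (samples x variables).
#' @param y Two-level classes.
#' @param methods Candidate methods for [scale_matrix()].
#' @param train_fraction Kennard-Stone training fraction.
#' @param n_ortho Orthogonal components.
#' @param folds,seed Cross-validation controls.
#' @return Data frame of methods with their metrics and composite `score`,
#'   sorted descending.
#' @export
rank_scaling_methods <- function(x, y,
                                 methods = c("none", "center", "auto",
                                             "pareto", "range"),
                                 train_fraction = 0.8, n_ortho = 1L,
                                 folds = 7L, seed = 1L) {
  if (length(methods) < 2) stop("need at least 2 candidate methods")
  y <- factor(y)
  metrics <- lapply(methods, function(mth) {
    res <- tryCatch({
      xs <- scale_matrix(x, mth)
      sp <- kennard_stone_split(xs, train_fraction)
      q2 <- cross_validate_q2(xs[sp$train, , drop = FALSE], y[sp$train],
                              n_ortho = n_ortho, folds = folds, seed = seed)
      fit <- fit_oplsda(xs[sp$train, , drop = FALSE], y[sp$train],
                        n_ortho = n_ortho)
      ext <- predict_class_maxdist(fit, xs[sp$test, , drop = FALSE],
                                   y_true = y[sp$test])
      data.frame(method = mth, q2y = q2, accuracy = ext$accuracy,
                 rmsep = ext$rmsep, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("scaling method '", mth, "' failed: ", conditionMessage(e))
      data.frame(method = mth, q2y = NA, accuracy = NA, rmsep = NA,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, metrics)
  minmax <- function(v) {
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[2] == rng[1]) return(rep(0.5, length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  }
  parts <- cbind(minmax(out$q2y), minmax(out$accuracy), minmax(-out$rmsep))
  out$score <- rowMeans(parts)
  out$score[!stats::complete.cases(out[c("q2y", "accuracy", "rmsep")])] <- 0
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}
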