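#' Stratified k-fold assignment
#'
#' Shuffles each class's trials (seeded) and deals them round-robin into
#' `k` folds, so per-class counts differ by at most one across folds and
#' the folds partition all trials disjointly.
#'
#' @param labels per-trial class labels.
#' @param k number of folds (>= 2; every class must have >= k trials).
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per trial.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  y <- factor(labels)
  .assert(k >= 2, "k must be >= 2")
  .assert(all(table(y) >= k),
          "every class needs >= k trials (smallest class has %d)",
          min(table(y)))
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the marginal products. Degenerate marginals
#' (`p_e = 1`) return 0 with a warning.
#'
#' @param confusion square contingency matrix of counts (rows = predicted
#'   or true, columns the other; kappa is symmetric in that choice).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  .assert(nrow(confusion) == ncol(confusion), "confusion matrix not square")
  n <- sum(confusion)
  .assert(n > 0, "empty confusion matrix")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) {
    warning("degenerate marginals (p_e = 1); kappa defined as 0",
            call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC of the ROC curve over all score thresholds, for a
#' binary problem with larger scores indicating the positive class.
#'
#' @param scores numeric decision scores.
#' @param labels binary labels.
#' @param positive label treated as positive; default the second level.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- droplevels(factor(labels))
  .assert(nlevels(y) == 2, "need both classes present")
  positive <- positive %||% levels(y)[2]
  .assert(positive %in% levels(y), "positive class '%s' not in labels",
          positive)
  negative <- setdiff(levels(y), positive)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Macro-averaged one-vs-rest ROC AUC
#'
#' Unweighted mean of the per-class one-vs-rest AUCs, each computed from
#' that class's score column against the binary membership indicator.
#'
#' @param scores numeric `n x C` matrix, columns named by class.
#' @param labels per-trial labels covering every score column.
#' @return macro-average AUC.
#' @export
macro_roc_auc <- function(scores, labels) {
  y <- factor(labels)
  cls <- colnames(scores)
  .assert(!is.null(cls) && all(cls %in% levels(y)),
          "score columns must be named by class labels")
  aucs <- vapply(cls, function(cl) {
    member <- factor(ifelse(y == cl, cl, ".rest"), levels = c(".rest", cl))
    .assert(length(unique(member)) == 2,
            "class '%s' absent from labels", cl)
    roc_auc(scores[, cl], member, positive = cl)
  }, numeric(1))
  mean(aucs)
}

#' Student-t confidence interval for a mean
#'
#' `mean(x) +/- t(alpha/2, n-1) * s / sqrt(n)` with the sample (n-1)
#' standard deviation.
#'
#' @param values numeric vector, length >= 2.
#' @param alpha two-sided significance level (default 0.05 for 95% CI).
#' @return named numeric `c(lower, upper)` with attributes `mean`, `sd`,
#'   `n`, `t`.
#' @export
confidence_interval <- function(values, alpha = 0.05) {
  n <- length(values)
  .assert(n >= 2, "need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  tq <- stats::qt(1 - alpha / 2, n - 1)
  half <- tq * s / sqrt(n)
  structure(c(lower = m - half, upper = m + half),
            mean = m, sd = s, n = n, t = tq)
}

#' One-way repeated-measures ANOVA across methods
#'
#' Decomposes a complete subjects x methods accuracy matrix into subject,
#' method, and residual sums of squares;
#' `F = MS_method / MS_error` with `(m - 1)` and `(m - 1)(n - 1)` degrees
#' of freedom.
#'
#' @param mat complete numeric matrix, rows = subjects, columns = methods.
#' @return list with `F`, `p`, `df`, and the SS decomposition.
#' @export
repeated_measures_anova <- function(mat) {
  mat <- as.matrix(mat)
  .assert(!anyNA(mat), "matrix has missing cells")
  n <- nrow(mat); m <- ncol(mat)
  .assert(n >= 2 && m >= 2, "need >= 2 subjects and >= 2 methods")
  grand <- mean(mat)
  ss_subj <- m * sum((rowMeans(mat) - grand)^2)
  ss_meth <- n * sum((colMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- max(0, ss_tot - ss_subj - ss_meth)
  df1 <- m - 1
  df2 <- (m - 1) * (n - 1)
  f <- if (ss_meth == 0) 0
       else if (ss_err == 0) Inf
       else (ss_meth / df1) / (ss_err / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2),
       ss = c(subject = ss_subj, method = ss_meth, error = ss_err))
}

#' Bonferroni-corrected paired t tests between all method pairs
#'
#' Paired t test (df = n - 1) for every column pair; p-values are
#' multiplied by the number of comparisons and capped at 1.
#'
#' @param mat complete numeric matrix, rows = subjects, columns = methods.
#' @return data frame with one row per pair: `method1`, `method2`, `t`,
#'   `df`, `p_raw`, `p_bonferroni`.
#' @export
bonferroni_paired_t <- function(mat) {
  mat <- as.matrix(mat)
  .assert(!anyNA(mat), "matrix has missing cells")
  m <- ncol(mat)
  .assert(m >= 2, "need >= 2 methods")
  nms <- colnames(mat) %||% paste0("method", seq_len(m))
  pairs <- utils::combn(m, 2)
  ncomp <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(ncomp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    dif <- mat[, i1] - mat[, i2]
    if (stats::sd(dif) == 0) {       # identical columns: no effect
      tval <- 0; pval <- 1
    } else {
      tt <- stats::t.test(mat[, i1], mat[, i2], paired = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(method1 = nms[i1], method2 = nms[i2],
               t = tval, df = length(dif) - 1L,
               p_raw = pval,
               p_bonferroni = min(1, pval * ncomp),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Per-method column summaries
#'
#' Mean, sample SD, population SD, count, and the t confidence interval
#' for each column of a per-subject results table. `digits` applies
#' half-away-from-zero rounding for comparison against published tables;
#' `NULL` leaves values unrounded.
#'
#' @param mat numeric matrix or data frame, rows = subjects, columns =
#'   methods.
#' @param alpha CI significance level.
#' @param digits optional rounding digits for the reported mean/SDs.
#' @return data frame with one row per method.
#' @export
column_summary <- function(mat, alpha = 0.05, digits = NULL) {
  mat <- as.matrix(mat)
  nms <- colnames(mat) %||% paste0("method", seq_len(ncol(mat)))
  out <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    ci <- confidence_interval(x, alpha)
    data.frame(method = nms[j], n = length(x), mean = mean(x),
               sd_sample = stats::sd(x),
               sd_population = sqrt(mean((x - mean(x))^2)),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(digits)) {
    num <- c("mean", "sd_sample", "sd_population", "ci_lower", "ci_upper")
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}

#' ERD/ERS band-power time course
#'
#' Band-pass filters every trial, squares, averages over trials, smooths
#' with a centred moving average, and expresses each channel's power as
#' percent change relative to its mean power in the baseline window.
#' Negative deflections are event-related desynchronization (ERD),
#' positive ones synchronization (ERS). The curve is invariant to
#' rescaling all amplitudes.
#'
#' Band-pass edge transients make the first and last fraction of a second
#' unreliable, so `trim_s` seconds are dropped from each end of the
#' returned curve.
#'
#' @param epochs an `epoch_set` (typically full 0--8 s trials).
#' @param band_hz two-element band in Hz (default mu, 8--12).
#' @param baseline_window_s two-element window in seconds, in epoch time,
#'   whose mean power is the 0% reference.
#' @param smooth_s moving-average width in seconds.
#' @param trim_s seconds discarded at each epoch edge (at least half the
#'   smoothing window is always trimmed).
#' @return list with `times` (seconds, epoch time), `percent`
#'   (channels x samples matrix of percent power change), and
#'   `channel_names`.
#' @export
erd_ers_timecourse <- function(epochs, band_hz = c(8, 12),
                               baseline_window_s = c(0, 1),
                               smooth_s = 0.25, trim_s = 0.25) {
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  fs <- epochs$sampling_rate
  t0 <- epochs$window[1]
  nsamp <- dim(epochs$data)[3]
  times <- t0 + (seq_len(nsamp) - 1L) / fs
  .assert(baseline_window_s[1] >= times[1] &&
            baseline_window_s[2] <= times[nsamp] + 1 / fs,
          "baseline window outside the epoch")
  filtered <- bandpass_zero_phase(epochs, band_hz[1], band_hz[2], order = 4)
  power <- apply(filtered$data^2, c(2, 3), mean)    # channels x samples
  wlen <- max(1L, round(smooth_s * fs))
  kern <- rep(1 / wlen, wlen)
  smooth <- t(apply(power, 1, function(p) {
    as.numeric(stats::filter(p, kern, sides = 2, circular = FALSE))
  }))
  # moving average is NA at the edges; fall back to raw power there
  smooth[is.na(smooth)] <- power[is.na(smooth)]
  # edge region must cover both filter transients and the half-window in
  # which the moving average is undefined
  trim <- round(max(trim_s, smooth_s / 2) * fs)
  keep <- if (trim > 0) (trim + 1):(nsamp - trim) else seq_len(nsamp)
  times <- times[keep]
  smooth <- smooth[, keep, drop = FALSE]
  base_idx <- which(times >= baseline_window_s[1] &
                      times < baseline_window_s[2])
  .assert(length(base_idx) > 0, "baseline window outside the epoch")
  pct <- smooth
  for (ch in seq_len(nrow(power))) {
    b <- mean(smooth[ch, base_idx])
    .assert(b > 0, "zero baseline power on channel %s",
            epochs$channel_names[ch])
    pct[ch, ] <- 100 * (smooth[ch, ] - b) / b
  }
  list(times = times, percent = pct, channel_names = epochs$channel_names)
}
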