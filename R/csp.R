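#' Trace-normalized spatial covariance of one trial
#'
#' `X X' / trace(X X')` for a channels x samples trial matrix `X`, the
#' unit-trace covariance on which CSP operates. Requires more samples
#' than channels.
#'
#' @param trial numeric channels x samples matrix.
#' @return symmetric channels x channels matrix with trace 1.
#' @export
normalized_covariance <- function(trial) {
  .assert(is.matrix(trial) && all(is.finite(trial)),
          "trial must be a finite numeric matrix")
  .assert(ncol(trial) > nrow(trial),
          "need more samples (%d) than channels (%d)",
          ncol(trial), nrow(trial))
  cc <- tcrossprod(trial)
  tr <- sum(diag(cc))
  .assert(tr > 0, "zero-energy trial: trace of X X' is 0")
  cc / tr
}

#' Fit a two-class common spatial pattern model
#'
#' Averages trace-normalized covariances per class, eigendecomposes the
#' composite covariance `R = R1 + R2`, whitens with
#' `P = diag(eigenvalues)^(-1/2) U'`, diagonalizes the whitened class-1
#' covariance `S1 = P R1 P'` to obtain the rotation `B` (eigenvalues
#' sorted descending), and returns the projection `W = B' P`. By
#' construction the whitened class eigenvalue spectra are complementary:
#' `lambda1 + lambda2 = 1` componentwise, so the first/last rows of `W`
#' maximize the class-1/class-2 variance ratio.
#'
#' @param trials_class1,trials_class2 lists of channels x samples trial
#'   matrices (>= 2 per class, common channel count).
#' @param reg ridge fraction mixed into each mean covariance
#'   (`(1-reg) Rc + reg (trace/N) I`) to guard rank deficiency.
#' @return an object of class `csp_model` with elements `mean_cov_class1`,
#'   `mean_cov_class2`, `whitening` (P), `rotation` (B), `filters` (W),
#'   `eigenvalues_class1` and `eigenvalues_class2`.
#' @export
fit_csp <- function(trials_class1, trials_class2, reg = 1e-9) {
  .assert(length(trials_class1) >= 2 && length(trials_class2) >= 2,
          "need at least 2 trials per class")
  nch <- nrow(trials_class1[[1]])
  all_tr <- c(trials_class1, trials_class2)
  .assert(all(vapply(all_tr, nrow, 0L) == nch),
          "trials have mismatched channel counts")

  avg_cov <- function(trials) {
    s <- Reduce(`+`, lapply(trials, normalized_covariance)) / length(trials)
    s <- (s + t(s)) / 2
    (1 - reg) * s + reg * (sum(diag(s)) / nch) * diag(nch)
  }
  r1 <- avg_cov(trials_class1)
  r2 <- avg_cov(trials_class2)

  comp <- eigen(r1 + r2, symmetric = TRUE)      # descending eigenvalues
  .assert(min(comp$values) > 1e-12 * max(comp$values),
          "composite covariance is rank-deficient")
  u <- .fix_signs(comp$vectors)
  p <- diag(1 / sqrt(comp$values)) %*% t(u)

  s1 <- p %*% r1 %*% t(p)
  s1 <- (s1 + t(s1)) / 2
  dec <- eigen(s1, symmetric = TRUE)
  b <- .fix_signs(dec$vectors)

  structure(list(mean_cov_class1 = r1,
                 mean_cov_class2 = r2,
                 whitening = p,
                 rotation = b,
                 filters = t(b) %*% p,
                 eigenvalues_class1 = dec$values,
                 eigenvalues_class2 = 1 - dec$values,
                 n_channels = nch),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("csp_model:", x$n_channels, "channels; class-1 eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues_class1), collapse = " "), "\n")
  invisible(x)
}

#' Normalized-variance CSP features of one trial
#'
#' Projects the trial through the spatial filters, `Z = W x`, and returns
#' the per-component variance share `f_j = Var(Z_j) / sum(Var(Z))`.
#' Features are nonnegative, sum to one, and are invariant to positive
#' rescaling of the trial. With `log = TRUE` the log of the variance share
#' is returned instead.
#'
#' @param model a `csp_model`.
#' @param trial channels x samples matrix.
#' @param n_filters optionally keep only the `n_filters` most extreme
#'   components (split between the top and bottom of the eigenvalue
#'   ordering); default all.
#' @param log return log variance shares.
#' @return numeric feature vector.
#' @export
csp_features <- function(model, trial, n_filters = NULL, log = FALSE) {
  .assert(inherits(model, "csp_model"), "not a csp_model")
  .assert(nrow(trial) == model$n_channels,
          "trial has %d channels, model expects %d",
          nrow(trial), model$n_channels)
  w <- model$filters
  if (!is.null(n_filters) && n_filters < nrow(w)) {
    half <- ceiling(n_filters / 2)
    idx <- unique(c(seq_len(half),
                    seq(nrow(w) - (n_filters - half) + 1L, nrow(w))))
    w <- w[idx, , drop = FALSE]
  }
  z <- w %*% trial
  v <- .row_vars(z)
  s <- sum(v)
  .assert(s > 0, "all projected components have zero variance")
  f <- v / s
  if (log) base::log(f) else f
}

# feature matrix (trials x components) for every trial of an epoch_set
.csp_feature_matrix <- function(model, es, n_filters = NULL, log = FALSE) {
  t(vapply(seq_len(n_trials(es)),
           function(i) csp_features(model, .trial(es, i), n_filters, log),
           numeric(if (is.null(n_filters)) model$n_channels
                   else min(n_filters, model$n_channels))))
}
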