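#' Sub-band filter bank
#'
#' The default bank splits 4--40 Hz into nine contiguous 4-Hz-wide bands
#' (4--8, 8--12, ..., 36--40 Hz), the decomposition feeding per-band CSP.
#' Sub-band filters are zero-phase Butterworth band-passes of 4th-order
#' prototype (8 poles): with 4-Hz-wide passbands a shallower design
#' leaks neighbouring rhythms at only ~-10 dB, which blurs the band
#' ranking; the 8-pole skirts keep adjacent-band leakage below -18 dB.
#'
#' @param bands numeric matrix with two columns (low, high) in Hz, one row
#'   per band.
#' @param order overall band-pass order per sub-band (even; poles per
#'   filter).
#' @return an object of class `filter_bank`.
#' @export
filter_bank <- function(bands = cbind(seq(4, 36, by = 4),
                                      seq(8, 40, by = 4)),
                        order = 8) {
  bands <- as.matrix(bands)
  .assert(ncol(bands) == 2 && nrow(bands) >= 1,
          "'bands' must be a two-column matrix")
  .assert(all(bands[, 1] < bands[, 2]), "degenerate band: low >= high")
  structure(list(bands = unname(bands), order = order,
                 n_bands = nrow(bands)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("filter_bank:", x$n_bands, "bands:",
      paste(sprintf("%g-%g", x$bands[, 1], x$bands[, 2]), collapse = ", "),
      "Hz\n")
  invisible(x)
}

#' Decompose epochs into sub-band copies
#'
#' Applies each band of the filter bank (zero-phase) to every trial and
#' channel, returning one filtered `epoch_set` per band, all with the
#' input's shape.
#'
#' @param epochs an `epoch_set`.
#' @param bank a [filter_bank()].
#' @return list of `epoch_set`s, one per band.
#' @export
apply_filter_bank <- function(epochs, bank = filter_bank()) {
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  .assert(inherits(bank, "filter_bank"), "not a filter_bank")
  nyq <- epochs$sampling_rate / 2
  .assert(all(bank$bands[, 2] < nyq),
          "band above Nyquist frequency (%g Hz)", nyq)
  lapply(seq_len(bank$n_bands), function(k) {
    bandpass_zero_phase(epochs, bank$bands[k, 1], bank$bands[k, 2],
                        order = bank$order)
  })
}

#' Histogram mutual information between features and class labels
#'
#' Discretizes each scalar feature dimension into `n_bins` equal-width
#' intervals over its observed range and computes
#' `MI = sum p(f, y) log2( p(f, y) / (p(f) p(y)) )` from the empirical
#' joint histogram, in bits. For vector-valued features the per-dimension
#' MIs are averaged. Bin edges may be supplied (e.g. frozen from training
#' data); out-of-range values fall into the end bins.
#'
#' @param features numeric vector or trials x dimensions matrix.
#' @param labels factor/character class labels (>= 2 classes present).
#' @param n_bins number of equal-width bins (>= 2).
#' @param edges optional list of per-dimension numeric edge vectors.
#' @return mean MI in bits, with attributes `per_dimension` and `edges`.
#' @export
band_mutual_information <- function(features, labels, n_bins = 10,
                                    edges = NULL) {
  if (!is.matrix(features)) features <- matrix(features, ncol = 1)
  .assert(nrow(features) > 0, "empty feature matrix")
  y <- factor(labels)
  y <- droplevels(y)
  .assert(nlevels(y) >= 2, "labels are constant: need >= 2 classes")
  .assert(length(y) == nrow(features),
          "labels length != number of feature rows")
  .assert(n_bins >= 2, "'n_bins' must be >= 2")

  d <- ncol(features)
  per_dim <- numeric(d)
  used_edges <- vector("list", d)
  yi <- as.integer(y)
  ny <- nlevels(y)
  n <- length(yi)
  for (j in seq_len(d)) {
    x <- features[, j]
    e <- if (!is.null(edges)) edges[[j]] else {
      rng <- range(x)
      if (rng[1] == rng[2]) NULL else seq(rng[1], rng[2],
                                          length.out = n_bins + 1)
    }
    used_edges[[j]] <- e
    if (is.null(e)) { per_dim[j] <- 0; next }   # constant feature
    b <- findInterval(x, e, rightmost.closed = TRUE, all.inside = TRUE)
    joint <- matrix(0, n_bins, ny)
    for (i in seq_len(n)) joint[b[i], yi[i]] <- joint[b[i], yi[i]] + 1
    p <- joint / n
    pf <- rowSums(p)
    py <- colSums(p)
    nz <- which(p > 0, arr.ind = TRUE)
    per_dim[j] <- sum(p[nz] * log2(p[nz] / (pf[nz[, 1]] * py[nz[, 2]])))
  }
  structure(mean(per_dim), per_dimension = per_dim, edges = used_edges)
}

#' Fit a discriminative filter-bank CSP model (two classes)
#'
#' Filters the training epochs into the bank's sub-bands, fits one CSP
#' model per band, extracts normalized-variance features for every
#' training trial, scores each band by the mutual information (in bits)
#' between its discretized features and the class labels, and selects the
#' top `m` bands by descending MI. Bin edges are computed on the training
#' data only and frozen into the model. A band whose covariance is too
#' degenerate for CSP receives MI 0 with a warning.
#'
#' @param epochs training `epoch_set` (typically broadband-filtered and
#'   artifact-cleaned).
#' @param labels per-trial labels with exactly two classes; defaults to
#'   `epochs$labels`.
#' @param bank a [filter_bank()].
#' @param n_bins histogram bins for the MI score.
#' @param m number of sub-bands kept (`<=` number of bands).
#' @param n_filters optional CSP components kept per band (default all).
#' @param banded optional precomputed [apply_filter_bank()] output for
#'   `epochs` (an optimization for cross-validation loops; must match
#'   `bank`).
#' @return an object of class `dfbcsp_model`: per-band `csp_model`s,
#'   `mi_scores`, `selected_bands` (indices, descending MI), frozen MI bin
#'   edges, and the training feature matrix of the selected bands.
#' @export
fit_dfbcsp <- function(epochs, labels = epochs$labels,
                       bank = filter_bank(), n_bins = 10, m = 4,
                       n_filters = NULL, banded = NULL) {
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  y <- droplevels(factor(labels))
  .assert(nlevels(y) == 2,
          "fit_dfbcsp needs exactly 2 classes (got %d); use fit_dfbcsp_multiclass",
          nlevels(y))
  .assert(all(table(y) >= 2), "need >= 2 trials per class")
  .assert(m >= 1 && m <= bank$n_bands,
          "m = %s out of range 1..%d", m, bank$n_bands)

  if (is.null(banded)) banded <- apply_filter_bank(epochs, bank)
  k_bands <- bank$n_bands
  band_csp <- vector("list", k_bands)
  band_feats <- vector("list", k_bands)
  mi <- numeric(k_bands)
  mi_edges <- vector("list", k_bands)
  idx1 <- which(y == levels(y)[1])
  idx2 <- which(y == levels(y)[2])
  for (k in seq_len(k_bands)) {
    fit <- tryCatch(fit_csp(.trial_list(banded[[k]], idx1),
                            .trial_list(banded[[k]], idx2)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("band %d (%g-%g Hz): %s; MI set to 0", k,
                      bank$bands[k, 1], bank$bands[k, 2],
                      conditionMessage(fit)), call. = FALSE)
      mi[k] <- 0
      next
    }
    band_csp[[k]] <- fit
    band_feats[[k]] <- .csp_feature_matrix(fit, banded[[k]], n_filters)
    score <- band_mutual_information(band_feats[[k]], y, n_bins)
    mi[k] <- as.numeric(score)
    mi_edges[[k]] <- attr(score, "edges")
  }
  selected <- order(-mi, seq_len(k_bands))[seq_len(m)]
  structure(list(filter_bank = bank,
                 band_csp = band_csp,
                 mi_scores = mi,
                 mi_edges = mi_edges,
                 selected_bands = selected,
                 m = m, n_bins = n_bins,
                 n_filters = n_filters,
                 classes = levels(y),
                 channel_names = epochs$channel_names,
                 training_features = do.call(cbind, band_feats[selected])),
            class = "dfbcsp_model")
}

#' @export
print.dfbcsp_model <- function(x, ...) {
  cat("dfbcsp_model (", paste(x$classes, collapse = " vs "), ")\n", sep = "")
  cat("  MI (bits):", paste(sprintf("%.3f", x$mi_scores), collapse = " "), "\n")
  cat("  selected bands:",
      paste(sprintf("%g-%g Hz", x$filter_bank$bands[x$selected_bands, 1],
                    x$filter_bank$bands[x$selected_bands, 2]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Concatenated sub-band CSP features
#'
#' Filters the epochs into the model's selected sub-bands and concatenates
#' each band's normalized-variance CSP feature vectors in descending-MI
#' order; with `m` bands and `N` retained components per band the feature
#' width is `m * N`.
#'
#' @param model a fitted `dfbcsp_model`.
#' @param epochs an `epoch_set` with the model's channel count.
#' @param banded optional precomputed [apply_filter_bank()] output for
#'   `epochs`.
#' @return numeric trials x (m * N) feature matrix.
#' @export
dfbcsp_features <- function(model, epochs, banded = NULL) {
  do.call(cbind, dfbcsp_band_features(model, epochs, banded))
}

#' Per-band CSP features for the selected sub-bands
#'
#' Like [dfbcsp_features()] but returns one feature matrix per selected
#' band (descending-MI order) instead of their concatenation; used by the
#' score-fusion pipeline mode.
#'
#' @inheritParams dfbcsp_features
#' @param banded optional precomputed [apply_filter_bank()] output for
#'   `epochs`.
#' @return list of trials x N feature matrices.
#' @export
dfbcsp_band_features <- function(model, epochs, banded = NULL) {
  .assert(inherits(model, "dfbcsp_model"), "not a dfbcsp_model")
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  .assert(dim(epochs$data)[2] == length(model$channel_names),
          "channel count mismatch")
  bank <- model$filter_bank
  lapply(model$selected_bands, function(k) {
    .assert(!is.null(model$band_csp[[k]]),
            "model has no CSP fit for band %d", k)
    bnd <- if (!is.null(banded)) banded[[k]]
           else bandpass_zero_phase(epochs, bank$bands[k, 1],
                                    bank$bands[k, 2], order = bank$order)
    .csp_feature_matrix(model$band_csp[[k]], bnd, model$n_filters)
  })
}

#' Fit one-vs-rest DFBCSP models for three or more classes
#'
#' The two-class machinery is applied once per class, contrasting that
#' class against all others pooled; each one-vs-rest model carries its own
#' band ranking. Predictions are resolved by training one binary
#' classifier per model and taking the per-trial argmax of the per-class
#' scores (see [fuse_scores()]).
#'
#' @inheritParams fit_dfbcsp
#' @return an object of class `dfbcsp_ovr`: list of `dfbcsp_model`s named
#'   by class.
#' @export
fit_dfbcsp_multiclass <- function(epochs, labels = epochs$labels,
                                  bank = filter_bank(), n_bins = 10,
                                  m = 4, n_filters = NULL, banded = NULL) {
  y <- droplevels(factor(labels))
  .assert(nlevels(y) >= 3, "need >= 3 classes (got %d)", nlevels(y))
  .assert(all(table(y) >= 2), "every class needs >= 2 trials")
  if (is.null(banded)) banded <- apply_filter_bank(epochs, bank)
  models <- lapply(levels(y), function(cl) {
    ybin <- factor(ifelse(y == cl, cl, ".rest"), levels = c(cl, ".rest"))
    fit_dfbcsp(epochs, ybin, bank, n_bins, m, n_filters, banded = banded)
  })
  names(models) <- levels(y)
  structure(list(models = models, classes = levels(y)),
            class = "dfbcsp_ovr")
}

#' @export
print.dfbcsp_ovr <- function(x, ...) {
  cat("dfbcsp_ovr:", length(x$models), "one-vs-rest models (",
      paste(x$classes, collapse = ", "), ")\n")
  invisible(x)
}
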