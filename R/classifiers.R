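#' Train a soft-margin linear support vector machine
#'
#' C-classification with a linear kernel at the stated penalty (default
#' `C = 1`), on unscaled features. Binary only; multiclass problems are
#' handled one-vs-rest upstream. The stored sign alignment makes positive
#' decision scores vote for the first class level.
#'
#' @param features numeric trials x dimensions matrix.
#' @param labels two-class factor/character labels.
#' @param C soft-margin penalty.
#' @return an object of class `svm_model` with elements `weights`, `bias`
#'   (of the aligned decision function `w'x + b`), `classes`, and the
#'   underlying fit.
#' @export
train_linear_svm <- function(features, labels, C = 1) {
  features <- as.matrix(features)
  y <- droplevels(factor(labels))
  .assert(nlevels(y) == 2, "need exactly 2 classes (got %d)", nlevels(y))
  fit <- e1071::svm(features, y, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
  d <- attr(stats::predict(fit, features, decision.values = TRUE),
            "decision.values")[, 1]
  align <- if (mean(d[y == levels(y)[1]]) >= mean(d[y == levels(y)[2]]))
    1 else -1
  w <- align * drop(t(fit$coefs) %*% fit$SV)
  b <- align * (-fit$rho)
  structure(list(fit = fit, align = align, weights = w, bias = b,
                 classes = levels(y), n_features = ncol(features)),
            class = "svm_model")
}

# ---------------------------------------------------------------------------
# multilayer perceptron: one ReLU hidden layer, logistic (2-class) or
# softmax (multiclass) output, cross-entropy loss, Adam updates
# ---------------------------------------------------------------------------

# forward pass + loss + analytic gradients for one batch.
# par: list(w1 d x h, b1 h, w2 h x c_out, b2 c_out); yk: n x c_out one-hot
# (c_out = 1 for binary with 0/1 column). Returns list(loss, grads).
.mlp_loss_grad <- function(par, x, yk) {
  n <- nrow(x)
  a1 <- sweep(x %*% par$w1, 2, par$b1, `+`)
  h <- pmax(a1, 0)
  a2 <- sweep(h %*% par$w2, 2, par$b2, `+`)
  if (ncol(yk) == 1L) {
    p <- 1 / (1 + exp(-a2))
    eps <- 1e-12
    loss <- -mean(yk * log(p + eps) + (1 - yk) * log(1 - p + eps))
    delta2 <- (p - yk) / n
  } else {
    z <- a2 - apply(a2, 1, max)
    ez <- exp(z)
    p <- ez / rowSums(ez)
    eps <- 1e-12
    loss <- -mean(log(p[cbind(seq_len(n), max.col(yk))] + eps))
    delta2 <- (p - yk) / n
  }
  gw2 <- t(h) %*% delta2
  gb2 <- colSums(delta2)
  delta1 <- (delta2 %*% t(par$w2)) * (a1 > 0)
  gw1 <- t(x) %*% delta1
  gb1 <- colSums(delta1)
  list(loss = loss,
       grads = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}

.mlp_forward_prob <- function(par, x, classes) {
  a1 <- sweep(x %*% par$w1, 2, par$b1, `+`)
  h <- pmax(a1, 0)
  a2 <- sweep(h %*% par$w2, 2, par$b2, `+`)
  if (length(classes) == 2L) {
    p <- 1 / (1 + exp(-a2[, 1]))
    cbind(1 - p, p, deparse.level = 0)
  } else {
    z <- a2 - apply(a2, 1, max)
    ez <- exp(z)
    ez / rowSums(ez)
  }
}

#' Train a one-hidden-layer perceptron classifier
#'
#' Feedforward network with a 64-unit rectified-linear hidden layer, a
#' logistic output for two classes (softmax for three or more), and
#' cross-entropy loss, trained by backpropagation with adaptive-moment
#' (Adam) mini-batch updates. All stochastic steps (weight init, batch
#' shuffling) derive from `seed`, so training is reproducible.
#'
#' @param features numeric trials x dimensions matrix.
#' @param labels factor/character labels (>= 2 classes).
#' @param hidden hidden-layer width.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param seed RNG seed.
#' @return an object of class `mlp_model` with the weight matrices,
#'   `classes`, and the per-epoch mean training `loss_history`.
#' @export
train_mlp <- function(features, labels, hidden = 64, epochs = 200,
                      lr = 1e-3, batch = 16, seed = 1) {
  x <- as.matrix(features)
  .assert(all(is.finite(x)), "non-finite feature values")
  y <- droplevels(factor(labels))
  .assert(nlevels(y) >= 2, "need >= 2 classes")
  n <- nrow(x); d <- ncol(x)
  ncls <- nlevels(y)
  c_out <- if (ncls == 2L) 1L else ncls
  yk <- if (c_out == 1L) matrix(as.numeric(y == levels(y)[2]), ncol = 1)
        else diag(ncls)[as.integer(y), , drop = FALSE]

  with_seed(seed, {
    par <- list(w1 = matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)),
                            d, hidden),
                b1 = rep(0, hidden),
                w2 = matrix(stats::rnorm(hidden * c_out, 0,
                                         sqrt(2 / hidden)), hidden, c_out),
                b2 = rep(0, c_out))
    mom <- lapply(par, function(p) p * 0)
    vel <- lapply(par, function(p) p * 0)
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    t_step <- 0
    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      idx <- sample(n)
      starts <- seq(1, n, by = batch)
      ep_loss <- 0
      for (s in starts) {
        bi <- idx[s:min(s + batch - 1, n)]
        lg <- .mlp_loss_grad(par, x[bi, , drop = FALSE],
                             yk[bi, , drop = FALSE])
        .assert(is.finite(lg$loss),
                "non-finite training loss at epoch %d", ep)
        ep_loss <- ep_loss + lg$loss * length(bi)
        t_step <- t_step + 1
        for (nm in names(par)) {
          g <- lg$grads[[nm]]
          mom[[nm]] <- b1m * mom[[nm]] + (1 - b1m) * g
          vel[[nm]] <- b2m * vel[[nm]] + (1 - b2m) * g^2
          mhat <- mom[[nm]] / (1 - b1m^t_step)
          vhat <- vel[[nm]] / (1 - b2m^t_step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_hist[ep] <- ep_loss / n
    }
    structure(list(w1 = par$w1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
                   classes = levels(y), hidden = hidden,
                   loss_history = loss_hist, n_features = d,
                   seed = seed),
              class = "mlp_model")
  })
}

# Ledoit-Wolf shrinkage intensity for rows-as-observations centred data
.lw_shrinkage <- function(xc) {
  n <- nrow(xc); d <- ncol(xc)
  s <- crossprod(xc) / n
  nu <- sum(diag(s)) / d
  target <- diag(nu, d)
  num <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    num <- num + sum((tcrossprod(xi) - s)^2)
  }
  num <- num / n^2
  den <- sum((s - target)^2)
  if (den <= 0) return(0)
  max(0, min(1, num / den))
}

#' Train a (shrinkage-regularized) linear discriminant classifier
#'
#' Two-class Fisher discriminant: projection
#' `w = Sw_shrunk^{-1} (mu1 - mu2)` with the pooled within-class
#' covariance shrunk toward a scaled identity,
#' `(1 - gamma) Sw + gamma (trace(Sw)/d) I`. With `shrinkage = "auto"`
#' the intensity `gamma` is the analytic Ledoit--Wolf estimate; `gamma = 1`
#' reduces `w` to the mean-difference direction, `gamma = 0` to classical
#' LDA. The decision boundary passes through the projected class-mean
#' midpoint.
#'
#' @param features numeric trials x dimensions matrix.
#' @param labels two-class labels (>= 2 trials per class).
#' @param shrinkage `"auto"`, or a numeric intensity in `[0, 1]` (0
#'   disables shrinkage and errors on singular scatter).
#' @return an object of class `lda_model` with `w`, `threshold`,
#'   class means, the shrunk covariance, and `classes`.
#' @export
train_lda <- function(features, labels, shrinkage = "auto") {
  x <- as.matrix(features)
  y <- droplevels(factor(labels))
  .assert(nlevels(y) == 2, "need exactly 2 classes (got %d)", nlevels(y))
  .assert(all(table(y) >= 2), "need >= 2 trials per class")
  d <- ncol(x)
  mu1 <- colMeans(x[y == levels(y)[1], , drop = FALSE])
  mu2 <- colMeans(x[y == levels(y)[2], , drop = FALSE])
  xc <- rbind(sweep(x[y == levels(y)[1], , drop = FALSE], 2, mu1),
              sweep(x[y == levels(y)[2], , drop = FALSE], 2, mu2))
  sw <- crossprod(xc) / nrow(xc)
  gamma <- if (identical(shrinkage, "auto")) .lw_shrinkage(xc)
           else { .assert(is.numeric(shrinkage) && shrinkage >= 0 &&
                            shrinkage <= 1,
                          "'shrinkage' must be \"auto\" or in [0, 1]")
                  shrinkage }
  nu <- sum(diag(sw)) / d
  sw_sh <- (1 - gamma) * sw + gamma * diag(nu, d)
  w <- tryCatch(solve(sw_sh, mu1 - mu2), error = function(e)
    .stop("within-class scatter is singular; enable shrinkage"))
  structure(list(w = w, threshold = sum(w * (mu1 + mu2)) / 2,
                 mu1 = mu1, mu2 = mu2, gamma = gamma, sw = sw_sh,
                 classes = levels(y), n_features = d),
            class = "lda_model")
}

#' Continuous per-class decision scores
#'
#' Returns an `n x n_classes` matrix of scores before any argmax/sign,
#' monotone in each model's decision function, with columns named by the
#' class labels. For the binary margin classifiers (SVM, LDA) the two
#' columns are `(+s, -s)` with `s` the signed decision value for the first
#' class; for the perceptron the rows are class probabilities (summing
#' to one).
#'
#' @param model an `svm_model`, `mlp_model`, or `lda_model`.
#' @param features numeric trials x dimensions matrix matching the
#'   training width.
#' @return numeric score matrix with one column per class.
#' @export
predict_scores <- function(model, features) UseMethod("predict_scores")

.check_width <- function(model, features) {
  .assert(ncol(features) == model$n_features,
          "feature width %d does not match model width %d",
          ncol(features), model$n_features)
}

#' @export
predict_scores.svm_model <- function(model, features) {
  features <- as.matrix(features)
  .check_width(model, features)
  s <- drop(features %*% model$weights) + model$bias
  matrix(c(s, -s), ncol = 2, dimnames = list(NULL, model$classes))
}

#' @export
predict_scores.lda_model <- function(model, features) {
  features <- as.matrix(features)
  .check_width(model, features)
  s <- drop(features %*% model$w) - model$threshold
  matrix(c(s, -s), ncol = 2, dimnames = list(NULL, model$classes))
}

#' @export
predict_scores.mlp_model <- function(model, features) {
  features <- as.matrix(features)
  .check_width(model, features)
  p <- .mlp_forward_prob(model, features, model$classes)
  colnames(p) <- model$classes
  p
}

#' Fuse score matrices into final class labels
#'
#' Arithmetic-mean fusion of a list of per-class score matrices followed
#' by a per-trial argmax; ties break deterministically toward the lowest
#' class index. The same operation resolves one-vs-rest multiclass
#' decisions when each entry carries one class's score column.
#'
#' @param score_list non-empty list of `n x C` score matrices with
#'   identical dimensions and column names.
#' @return factor of predicted labels (levels = score columns).
#' @export
fuse_scores <- function(score_list) {
  .assert(is.list(score_list) && length(score_list) > 0,
          "empty score list")
  dims <- vapply(score_list, function(s) paste(dim(s), collapse = "x"), "")
  .assert(length(unique(dims)) == 1, "score matrices differ in shape")
  avg <- Reduce(`+`, score_list) / length(score_list)
  cls <- colnames(avg)
  .assert(!is.null(cls), "score matrices must have class column names")
  factor(cls[max.col(avg, ties.method = "first")], levels = cls)
}

#' Fit a feature standardizer on training data
#'
#' @param features training feature matrix.
#' @return a `feature_scaler` (per-column center and scale; zero-variance
#'   columns get scale 1).
#' @export
feature_scaler <- function(features) {
  features <- as.matrix(features)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  structure(list(center = ctr, scale = scl), class = "feature_scaler")
}

#' Apply a fitted standardizer
#' @param scaler a [feature_scaler()].
#' @param features feature matrix to transform.
#' @return standardized matrix.
#' @export
apply_scaler <- function(scaler, features) {
  sweep(sweep(as.matrix(features), 2, scaler$center), 2, scaler$scale, `/`)
}
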