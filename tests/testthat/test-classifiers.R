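test_that("a symmetric separable pair puts the SVM boundary at zero", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- factor(c("neg", "pos"))
  mod <- train_linear_svm(x, y, C = 1)
  boundary <- -mod$bias / mod$weights
  expect_equal(as.numeric(boundary), 0, tolerance = 1e-6)
  margins <- abs(c(-1, 1) * mod$weights + mod$bias)
  expect_true(all(margins >= 1 - 1e-6))
  expect_error(train_linear_svm(x, factor(c("a", "a"))), "2 classes")
})

test_that("the SVM hyperplane matches a brute-force primal minimizer", {
  d <- separable_2d(20, gap = 6, sd = 0.5, seed = 42)
  mod <- train_linear_svm(d$x, d$y, C = 1)
  ysign <- ifelse(d$y == levels(d$y)[1], 1, -1)   # positive scores = level 1
  # oracle: over a fine angle grid, the smallest-norm w satisfying the
  # margin constraints; objective 0.5 ||w||^2 (slacks vanish at optimum
  # for this well-separated fixture)
  thetas <- seq(0, pi, by = 2e-4)
  best <- list(obj = Inf, theta = NA)
  for (th in thetas) {
    u <- c(cos(th), sin(th))
    proj <- drop(d$x %*% u)
    lo <- max(proj[ysign == -1]); hi <- min(proj[ysign == 1])
    width <- hi - lo
    if (width <= 0) next
    s <- 2 / width
    if (0.5 * s^2 < best$obj) best <- list(obj = 0.5 * s^2, theta = th)
  }
  ang <- function(v) atan2(v[2], v[1]) %% pi
  diff_ang <- abs(ang(mod$weights) - best$theta)
  diff_ang <- min(diff_ang, pi - diff_ang)
  expect_lt(diff_ang, 1e-3)
  # duplicating every training point leaves the decision function unchanged
  mod2 <- train_linear_svm(rbind(d$x, d$x), factor(c(d$y, d$y),
                                                   labels = levels(d$y)))
  expect_equal(mod2$weights, mod$weights, tolerance = 1e-6)
  expect_equal(mod2$bias, mod$bias, tolerance = 1e-6)
})

test_that("analytic MLP gradients match central finite differences", {
  set.seed(20)
  grad_check <- function(x, yk) {
    d <- ncol(x); h <- 5
    c_out <- ncol(yk)
    par <- list(w1 = matrix(rnorm(d * h), d, h), b1 = rnorm(h),
                w2 = matrix(rnorm(h * c_out), h, c_out), b2 = rnorm(c_out))
    got <- dfbcsp:::.mlp_loss_grad(par, x, yk)
    eps <- 1e-6
    worst <- 0
    for (nm in names(par)) {
      for (i in seq_along(par[[nm]])) {
        pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (dfbcsp:::.mlp_loss_grad(pp, x, yk)$loss -
                 dfbcsp:::.mlp_loss_grad(pm, x, yk)$loss) / (2 * eps)
        an <- got$grads[[nm]][i]
        worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd), abs(an)))
      }
    }
    worst
  }
  x <- matrix(rnorm(9), 3, 3)
  expect_lt(grad_check(x, matrix(c(1, 0, 1), ncol = 1)), 1e-5)   # logistic
  expect_lt(grad_check(x, diag(3)), 1e-5)                        # softmax
})

test_that("the MLP solves XOR for almost every seed", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- factor(c("a", "b", "b", "a"))
  wins <- 0
  for (s in 1:20) {
    mod <- train_mlp(x, y, hidden = 64, epochs = 500, batch = 4, seed = s)
    pred <- fuse_scores(list(predict_scores(mod, x)))
    if (all(pred == y)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("MLP training is seed-reproducible with softening loss", {
  d <- separable_2d(15, seed = 30)
  a <- train_mlp(d$x, d$y, epochs = 50, seed = 9)
  b <- train_mlp(d$x, d$y, epochs = 50, seed = 9)
  expect_identical(a$w1, b$w1)
  expect_identical(a$loss_history, b$loss_history)
  # averaged training loss decreases from start to finish
  expect_lt(tail(a$loss_history, 1), a$loss_history[1])
})

test_that("an uninformative problem yields near-half probabilities", {
  x <- matrix(1, 40, 3)
  y <- factor(rep(c("a", "b"), 20))
  mod <- train_mlp(x, y, epochs = 100, seed = 2)
  p <- predict_scores(mod, x)
  expect_true(all(abs(p[, 2] - 0.5) < 0.05))
})

test_that("LDA recovers the Fisher direction on spherical clouds", {
  set.seed(31)
  x <- rbind(matrix(rnorm(400), 200, 2),
             sweep(matrix(rnorm(400), 200, 2), 2, c(2, 0), `+`))
  y <- factor(rep(c("a", "b"), each = 200))
  mod <- train_lda(x, y)
  ang <- acos(abs(sum(mod$w * c(1, 0))) / sqrt(sum(mod$w^2))) * 180 / pi
  expect_lt(ang, 5)
  # label swap negates scores exactly
  mod2 <- train_lda(x, factor(y, levels = c("b", "a")))
  expect_equal(predict_scores(mod2, x)[, "a"],
               predict_scores(mod, x)[, "a"], tolerance = 1e-9)
  expect_equal(predict_scores(mod2, x)[, "b"],
               -predict_scores(mod2, x)[, "a"], tolerance = 1e-12)
})

test_that("full shrinkage collapses the projection onto the mean difference", {
  set.seed(32)
  x <- rbind(matrix(rnorm(60, sd = c(4, 0.2)), 30, 2, byrow = FALSE),
             sweep(matrix(rnorm(60, sd = c(4, 0.2)), 30, 2), 2,
                   c(1, 3), `+`))
  y <- factor(rep(c("a", "b"), each = 30))
  mod <- train_lda(x, y, shrinkage = 1)
  mu_diff <- colMeans(x[y == "a", ]) - colMeans(x[y == "b", ])
  cosine <- sum(mod$w * mu_diff) /
    sqrt(sum(mod$w^2) * sum(mu_diff^2))
  expect_equal(cosine, 1, tolerance = 1e-6)
  expect_error(train_lda(x, y, shrinkage = 2), "shrinkage")
})

test_that("LDA scores equal the explicit projection formula", {
  d <- separable_2d(25, seed = 33)
  mod <- train_lda(d$x, d$y)
  expected <- drop(d$x %*% mod$w) -
    sum(mod$w * (mod$mu1 + mod$mu2)) / 2
  expect_equal(predict_scores(mod, d$x)[, 1], expected, tolerance = 1e-12)
})

test_that("score matrices respect shape, normalization, and sign contracts", {
  d <- separable_2d(20, seed = 34)
  svm <- train_linear_svm(d$x, d$y)
  s <- predict_scores(svm, d$x)
  expect_identical(colnames(s), levels(d$y))
  # training points on their own side of the margin score with their label
  expect_true(all(s[d$y == "a", "a"] > 0))
  expect_true(all(s[d$y == "b", "a"] < 0))

  y3 <- factor(rep(c("a", "b", "c"), length.out = 40))
  set.seed(35)
  x3 <- matrix(rnorm(120), 40, 3) + 3 * diag(3)[as.integer(y3), ]
  mlp <- train_mlp(x3, y3, epochs = 100, seed = 3)
  p <- predict_scores(mlp, x3)
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-9)
  expect_error(predict_scores(mlp, x3[, 1:2]), "width")
})

test_that("all three classifiers master a separable fixture", {
  d <- separable_2d(30, gap = 6, seed = 36)
  for (fit in list(train_linear_svm(d$x, d$y),
                   train_mlp(d$x, d$y, epochs = 150, seed = 4),
                   train_lda(d$x, d$y))) {
    pred <- fuse_scores(list(predict_scores(fit, d$x)))
    expect_gte(mean(pred == d$y), 0.99)
  }
})

test_that("standardization leaves margin-classifier predictions unchanged", {
  d <- separable_2d(25, seed = 37)
  sc <- feature_scaler(d$x)
  xs <- apply_scaler(sc, d$x)
  for (trainer in list(train_linear_svm, train_lda)) {
    raw <- fuse_scores(list(predict_scores(trainer(d$x, d$y), d$x)))
    std <- fuse_scores(list(predict_scores(trainer(xs, d$y), xs)))
    expect_identical(raw, std)
  }
})

test_that("score fusion averages and breaks ties deterministically", {
  s1 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  expect_identical(as.character(fuse_scores(list(s1))), c("a", "b"))
  s2 <- matrix(c(0.4, 0.6, 0.4, 0.6), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  # 0.9-magnitude preference dominates a 0.6 counter-preference
  expect_identical(as.character(fuse_scores(list(s1, s2))[1]), "a")
  tie <- matrix(0.5, 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(as.character(fuse_scores(list(tie))), "a")
  expect_error(fuse_scores(list()), "empty")
  expect_error(fuse_scores(list(s1, tie)), "shape")
})

test_that("one-vs-rest fusion equals the brute-force per-trial maximum", {
  set.seed(38)
  y3 <- factor(rep(c("a", "b", "c"), each = 15))
  x3 <- matrix(rnorm(135), 45, 3) + 2.5 * diag(3)[as.integer(y3), ]
  score_cols <- sapply(levels(y3), function(cl) {
    ybin <- factor(ifelse(y3 == cl, cl, ".rest"), levels = c(cl, ".rest"))
    predict_scores(train_linear_svm(x3, ybin), x3)[, cl]
  })
  fused <- fuse_scores(list(score_cols))
  brute <- levels(y3)[apply(score_cols, 1, which.max)]
  expect_identical(as.character(fused), brute)
})
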