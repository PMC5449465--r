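# PCA + multiclass LDA decoder: fitting, posteriors against an independent
# Bayes-rule oracle, winner-take-all thresholding, force readout, and
# leave-one-out decoding (including equivalence of the two PCA routes).

test_that("full-rank PCA reconstruction has negligible residual", {
  toy <- toy_clusters(n_per_class = 8, dim = 5, sep = 3)
  dec <- sd_decoder(toy$x, toy$labels, k = 5, p_thr = 1)
  xc <- sweep(toy$x, 2, dec$center)
  recon <- (xc %*% dec$loadings) %*% t(dec$loadings)
  expect_lt(max(abs(recon - xc)) / max(abs(xc)), 1e-8)
  # loadings columns orthonormal
  expect_equal(crossprod(dec$loadings), diag(5), tolerance = 1e-10)
})

test_that("fitting validates k, labels and class counts", {
  toy <- toy_clusters(n_per_class = 5, dim = 4)
  expect_error(sd_decoder(toy$x, toy$labels, k = 0), "'k'")
  expect_error(sd_decoder(toy$x, toy$labels, k = 10), "'k'")
  expect_error(sd_decoder(toy$x, toy$labels[-1], k = 2), "align")
  bad <- toy$labels; bad[bad == 4] <- 3; bad[1] <- 4  # one trial in class 4
  expect_error(sd_decoder(toy$x, bad, k = 2), "2 training trials")
})

test_that("posteriors on separated Gaussians match the Bayes-rule oracle", {
  set.seed(3)
  # two classes in 2-D, separation 10 sigma -> near-certain posteriors
  x <- rbind(matrix(rnorm(60), 30, 2),
             sweep(matrix(rnorm(60), 30, 2), 2, c(10, 0), `+`))
  labels <- rep(1:2, each = 30)
  dec <- sd_decoder(x, labels, k = 2, p_thr = 1)
  p_train <- predict(dec, x)
  expect_true(all(p_train[cbind(1:60, labels)] > 0.99))

  # random 4-class model: posteriors equal a hand-rolled Gaussian
  # discriminant with the same means, pooled covariance and priors
  toy <- toy_clusters(n_per_class = 15, dim = 4, sep = 1.5)
  dec4 <- sd_decoder(toy$x, toy$labels, k = 4, p_thr = 1)
  pt <- matrix(rnorm(20), 5, 4)
  p_pkg <- predict(dec4, pt)
  h <- sweep(pt, 2, dec4$center) %*% dec4$loadings
  sigma <- t(dec4$lda$chol) %*% dec4$lda$chol
  loglik <- sapply(1:4, function(j) {
    d <- sweep(h, 2, dec4$lda$means[j, ])
    log(dec4$lda$priors[j]) - 0.5 * rowSums((d %*% solve(sigma)) * d)
  })
  p_hand <- exp(loglik - apply(loglik, 1, max))
  p_hand <- p_hand / rowSums(p_hand)
  expect_equal(unname(p_pkg), unname(p_hand), tolerance = 1e-10)
  expect_true(all(abs(rowSums(p_pkg) - 1) < 1e-12))
})

test_that("duplicating every training trial leaves decision surfaces fixed", {
  toy <- toy_clusters(n_per_class = 10, dim = 4, sep = 2)
  d1 <- sd_decoder(toy$x, toy$labels, k = 3, p_thr = 1)
  d2 <- sd_decoder(rbind(toy$x, toy$x), c(toy$labels, toy$labels),
                   k = 3, p_thr = 1)
  pt <- matrix(rnorm(40), 10, 4)
  expect_equal(predict(d1, pt), predict(d2, pt), tolerance = 1e-8)
})

test_that("degenerate geometries give the textbook posteriors", {
  set.seed(8)
  x <- matrix(rnorm(160), 80, 2)
  labels <- rep(1:4, each = 20)
  # all class means essentially identical -> posteriors ~ priors
  dec <- sd_decoder(x, labels, k = 2, p_thr = 1)
  p <- predict(dec, c(0, 0))
  expect_equal(as.numeric(p), dec$lda$priors, tolerance = 0.12)

  # a test point at a well-separated class mean -> that class wins
  toy <- toy_clusters(n_per_class = 10, dim = 3, sep = 8)
  dec4 <- sd_decoder(toy$x, toy$labels, k = 3, p_thr = 1)
  expect_equal(unname(predict(dec4, toy$mu[2, ], type = "class")), 2L)
})

test_that("winner-take-all follows both branches of the threshold rule", {
  expect_equal(apply_wta(c(0.9, 0.05, 0.03, 0.02), 0.8), c(1, 0, 0, 0))
  expect_equal(apply_wta(c(0.4, 0.3, 0.2, 0.1), 0.8), c(0.4, 0.3, 0.2, 0.1))
  # threshold 1 never triggers
  set.seed(2)
  p <- t(replicate(50, { v <- runif(4); v / sum(v) }))
  expect_equal(apply_wta(p, 1), p)
  # never decreases the maximum entry; ties go to the lowest index
  p8 <- apply_wta(p, 0.2)
  expect_true(all(apply(p8, 1, max) >= apply(p, 1, max)))
  expect_equal(apply_wta(c(0.4, 0.4, 0.1, 0.1), 0.3), c(1, 0, 0, 0))
  expect_error(apply_wta(c(1, 0, 0, 0), 1.2), "p_thr")
})

test_that("decoded force is the posterior-weighted sum of region forces", {
  forces <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(decode_force(c(0, 0, 1, 0), forces), c(-1, 0))
  expect_equal(decode_force(rep(0.25, 4), forces), c(0, 0))
  expect_equal(decode_force(c(0.5, 0.5, 0, 0), forces), c(0.5, 0.5))
  # convex combination never exceeds the largest force magnitude
  set.seed(5)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    f <- decode_force(p, forces)
    expect_lte(sqrt(sum(f^2)), 1 + 1e-12)
  }
})

test_that("leave-one-out decoding separates tight clusters perfectly", {
  toy <- toy_clusters(n_per_class = 20, dim = 6, sep = 10)
  res <- loo_decode(toy$x, k = 6, p_thr = 1, labels = toy$labels)
  expect_equal(res$predicted, toy$labels)
  expect_true(all(abs(rowSums(res$p_tilde) - 1) < 1e-9))
  # determinism
  res2 <- loo_decode(toy$x, k = 6, p_thr = 1, labels = toy$labels)
  expect_identical(res$p_tilde, res2$p_tilde)
})

test_that("shuffled labels decode at chance", {
  set.seed(11)
  toy <- toy_clusters(n_per_class = 50, dim = 6, sep = 8)
  shuffled <- sample(toy$labels)
  res <- loo_decode(toy$x, k = 6, p_thr = 1, labels = shuffled)
  acc <- mean(res$predicted == shuffled)
  # binomial 99% band around 0.25 with n = 200
  expect_lt(abs(acc - 0.25), 2.58 * sqrt(0.25 * 0.75 / 200))
})

test_that("both leave-one-out PCA routes give identical posteriors", {
  set.seed(9)
  labels <- rep(1:4, each = 10)
  x_wide <- matrix(rpois(40 * 60, 2), 40, 60)   # F > M - 1: Gram route
  x_wide[, 1] <- x_wide[, 1] + 4 * (labels == 2)
  res_gram <- loo_decode(x_wide, k = 5, p_thr = 1, labels = labels)
  # naive reference: explicit SVD refit per fold
  p_naive <- t(vapply(seq_len(40), function(i) {
    tr <- x_wide[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sv <- svd(sweep(tr, 2, mu))
    v <- sv$v[, 1:5]
    h <- sweep(tr, 2, mu) %*% v
    lda <- sdbmi:::lda_fit(h, labels[-i], 1:4)
    as.numeric(sdbmi:::lda_posterior(lda, (x_wide[i, ] - mu) %*% v))
  }, numeric(4)))
  expect_equal(unname(res_gram$p_raw), p_naive, tolerance = 1e-8)

  # and the feature-space route agrees with the same reference
  x_tall <- x_wide[, 1:20]
  res_feat <- loo_decode(x_tall, k = 5, p_thr = 1, labels = labels)
  p_naive2 <- t(vapply(seq_len(40), function(i) {
    tr <- x_tall[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sv <- svd(sweep(tr, 2, mu))
    v <- sv$v[, 1:5]
    lda <- sdbmi:::lda_fit(sweep(tr, 2, mu) %*% v, labels[-i], 1:4)
    as.numeric(sdbmi:::lda_posterior(lda, (x_tall[i, ] - mu) %*% v))
  }, numeric(4)))
  expect_equal(unname(res_feat$p_raw), p_naive2, tolerance = 1e-8)
})

test_that("predictions agree with MASS::lda on well-conditioned toy data", {
  skip_if_not_installed("MASS")
  toy <- toy_clusters(n_per_class = 25, dim = 5, sep = 2.5)
  dec <- sd_decoder(toy$x, toy$labels, k = 5, p_thr = 1)
  set.seed(14)
  pt <- toy$mu[rep(1:4, each = 5), ] + matrix(rnorm(100), 20, 5)
  ref <- MASS::lda(toy$x, grouping = toy$labels)
  expect_equal(unname(predict(dec, pt, type = "class")),
               as.integer(as.character(predict(ref, pt)$class)))
})

test_that("dimension mismatches are rejected at prediction time", {
  toy <- toy_clusters(n_per_class = 6, dim = 4)
  dec <- sd_decoder(toy$x, toy$labels, k = 2)
  expect_error(predict(dec, rnorm(3)), "feature length")
})
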