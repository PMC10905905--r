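std_tibble <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(colMeans(X^2)), `/`)
  colnames(X) <- paste0("d", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::tibble(molecule = paste0("m", seq_len(nrow(X)))),
                   tibble::as_tibble(X))
}

test_that("a rank-one matrix yields q = 1 with all variance on the first component", {
  set.seed(4)
  x <- rnorm(40)
  dat <- std_tibble(cbind(x, x))
  lab <- fit_pseudo_labeler(dat, explained_variance_target = 0.99)
  expect_equal(lab$q, 1L)
  expect_equal(lab$explained_variance, 1, tolerance = 1e-12)
})

test_that("eigenpairs match a dense covariance eigendecomposition oracle", {
  for (case in list(c(n = 50, p = 6), c(n = 200, p = 20))) {
    set.seed(case[["n"]])
    X <- matrix(rnorm(case[["n"]] * case[["p"]]), case[["n"]])
    X[, 1] <- X[, 1] * 3            # give the spectrum some structure
    X[, 2] <- X[, 2] + 0.5 * X[, 1]
    dat <- std_tibble(X)
    lab <- fit_pseudo_labeler(dat, q_override = case[["p"]] - 1)

    # independent oracle: eigendecomposition of the sample covariance
    Xs <- as.matrix(dat[, -1])
    eo <- eigen(stats::cov(Xs), symmetric = TRUE)
    expect_equal(lab$eigenvalues_all, eo$values, tolerance = 1e-8)
    expect_equal(sum(lab$eigenvalues_all), sum(diag(stats::cov(Xs))),
                 tolerance = 1e-8)
    # components agree up to sign
    for (j in seq_len(lab$q)) {
      u <- lab$components[, j]; v <- eo$vectors[, j]
      expect_equal(abs(sum(u * v)), 1, tolerance = 1e-8)
    }
    # orthonormality
    G <- t(lab$components) %*% lab$components
    expect_equal(G, diag(lab$q), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("fitting-set scores have covariance diag(eigenvalues)", {
  set.seed(9)
  dat <- std_tibble(matrix(rnorm(120 * 8), 120))
  lab <- fit_pseudo_labeler(dat, q_override = 4)
  X <- as.matrix(dat[, -1])
  scores <- sweep(X, 2, lab$center) %*% lab$components
  expect_equal(stats::cov(scores), diag(lab$eigenvalues),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reconstruction error with q components equals the trailing eigenvalue sum", {
  set.seed(12)
  dat <- std_tibble(matrix(rnorm(80 * 10), 80) %*% diag(seq(0.3, 3,
                                                            length.out = 10)))
  lab <- fit_pseudo_labeler(dat, q_override = 4)
  X <- as.matrix(dat[, -1])
  Xc <- sweep(X, 2, lab$center)
  recon <- Xc %*% lab$components %*% t(lab$components)
  sse_per_df <- sum((Xc - recon)^2) / (nrow(X) - 1)
  expect_equal(sse_per_df, sum(lab$eigenvalues_all[-seq_len(lab$q)]),
               tolerance = 1e-8)
})

test_that("q is the smallest k reaching the target and cumulative variance is monotone", {
  set.seed(21)
  dat <- std_tibble(matrix(rnorm(60 * 9), 60) %*% diag(c(4, 3, 2, rep(0.5, 6))))
  for (target in c(0.3, 0.5, 0.7, 0.9)) {
    lab <- fit_pseudo_labeler(dat, explained_variance_target = target)
    cv <- cumsum(lab$eigenvalues_all) / lab$total_variance
    expect_true(all(diff(cv) >= -1e-12))
    expect_gte(cv[lab$q], target)
    if (lab$q > 1) expect_lt(cv[lab$q - 1], target)
  }
  expect_error(fit_pseudo_labeler(dat, explained_variance_target = 0),
               class = "ginyield_parameter_error")
  expect_error(fit_pseudo_labeler(dat, explained_variance_target = 1.2),
               class = "ginyield_parameter_error")
})

test_that("typical scores pass through clipping unchanged; outliers hit the boundary", {
  set.seed(30)
  dat <- std_tibble(matrix(rnorm(100 * 5), 100))
  lab <- fit_pseudo_labeler(dat, q_override = 3)
  labels <- make_pseudo_labels(lab, dat)
  expect_false(anyNA(labels))
  # fitting-set labels have mean 0, population SD 1 per dimension
  Z <- as.matrix(labels[, -1])
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2))),
               rep(1, 3), tolerance = 1e-10)

  # an artificial far outlier is clipped to the boundary before re-scaling
  extreme <- dat
  extreme[2, -1] <- as.list(as.numeric(dat[2, -1]) * 500)
  z_out <- make_pseudo_labels(lab, extreme)
  raw_scores <- sweep(as.matrix(extreme[, -1]), 2, lab$center) %*%
    lab$components
  lim <- lab$clip_multiplier * lab$score_sd
  hit <- which(abs(raw_scores[2, ]) > lim)
  expect_gt(length(hit), 0)
  expected <- (sign(raw_scores[2, hit]) * lim[hit] -
                 lab$post_clip_means[hit]) / lab$post_clip_sds[hit]
  expect_equal(as.numeric(z_out[2, 1 + hit]), unname(expected),
               tolerance = 1e-12)
})

test_that("pseudo-labelling replays bit-identically, including through JSON persistence", {
  set.seed(44)
  dat <- std_tibble(matrix(rnorm(50 * 6), 50))
  lab <- fit_pseudo_labeler(dat, q_override = 3)
  l1 <- make_pseudo_labels(lab, dat)
  l2 <- make_pseudo_labels(lab, dat)
  expect_identical(l1, l2)

  path <- withr::local_tempfile(fileext = ".json")
  write_pseudo_labeler(lab, path)
  lab2 <- read_pseudo_labeler(path)
  l3 <- make_pseudo_labels(lab2, dat)
  expect_equal(as.matrix(l3[, -1]), as.matrix(l1[, -1]), tolerance = 1e-12)
})
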