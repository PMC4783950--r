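# Common Spatial Patterns: normalized covariance, whitening contract,
# eigenvalue complementarity and log-variance features.

test_that("normalized_covariance has unit trace and matches direct algebra", {
  R <- normalized_covariance(diag(20))
  expect_equal(R, diag(20) / 20)

  set.seed(71)
  for (rep_i in 1:10) {
    E <- rand_evo()
    R <- normalized_covariance(E)
    expect_equal(sum(diag(R)), 1, tolerance = 1e-12)
    direct <- E %*% t(E) / sum(diag(E %*% t(E)))
    expect_equal(R, (direct + t(direct)) / 2)
    expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values >
                      -1e-12))
  }
  expect_error(normalized_covariance(matrix(0, 20, 20)), "degenerate")
})

test_that("identical classes give all class-1 eigenvalues equal to 1/2", {
  set.seed(72)
  ms <- replicate(8, rand_evo(), simplify = FALSE)
  mod <- fit_csp(ms, ms)
  expect_equal(mod$eigvals_class1, rep(0.5, 20), tolerance = 1e-10)
})

test_that("disjoint dominant subspaces drive eigenvalues to 1 and 0", {
  set.seed(73)
  top <- replicate(6, rbind(matrix(rnorm(200), 10, 20), matrix(0, 10, 20)),
                   simplify = FALSE)
  bottom <- replicate(6, rbind(matrix(0, 10, 20), matrix(rnorm(200), 10, 20)),
                      simplify = FALSE)
  mod <- fit_csp(top, bottom)
  expect_gt(max(mod$eigvals_class1), 1 - 1e-8)
  expect_lt(min(mod$eigvals_class1), 1e-8)
})

test_that("whitening and eigenvalue complementarity contracts hold", {
  set.seed(74)
  for (rep_i in 1:5) {
    c1 <- replicate(sample(3:8, 1), rand_evo(), simplify = FALSE)
    c2 <- replicate(sample(3:8, 1), rand_evo(), simplify = FALSE)
    mod <- fit_csp(c1, c2)
    R1 <- Reduce(`+`, lapply(c1, normalized_covariance)) / length(c1)
    R2 <- Reduce(`+`, lapply(c2, normalized_covariance)) / length(c2)
    # all eigenvalues of P Rc P' equal one
    PRcP <- mod$P %*% (R1 + R2) %*% t(mod$P)
    expect_lt(max(abs(PRcP - diag(20))), 1e-8)
    # lambda1 + lambda2 = I in the common eigenbasis
    l1 <- diag(t(mod$B) %*% (mod$P %*% R1 %*% t(mod$P)) %*% mod$B)
    l2 <- diag(t(mod$B) %*% (mod$P %*% R2 %*% t(mod$P)) %*% mod$B)
    expect_lt(max(abs(l1 + l2 - 1)), 1e-8)
    # sorting lambda1 descending sorts lambda2 ascending, pairwise sum 1
    expect_equal(mod$eigvals_class1, sort(mod$eigvals_class1,
                                          decreasing = TRUE))
    expect_equal(mod$eigvals_class1 + sort(l2), rep(1, 20),
                 tolerance = 1e-8)
    expect_true(all(mod$eigvals_class1 > -1e-10 &
                      mod$eigvals_class1 < 1 + 1e-10))
  }
})

test_that("csp_features normalizes variances and matches the oracle", {
  set.seed(75)
  c1 <- replicate(6, rand_evo(), simplify = FALSE)
  c2 <- replicate(6, rand_evo(), simplify = FALSE)
  mod <- fit_csp(c1, c2)
  for (rep_i in 1:10) {
    E <- rand_evo()
    f <- csp_features(mod, E)
    expect_length(f, 20)
    expect_equal(sum(exp(f)), 1, tolerance = 1e-10)
    expect_equal(unname(f), oracle_csp_features(mod, E))
  }
})

test_that("features are invariant to positive rescaling of the input", {
  set.seed(76)
  mod <- fit_csp(replicate(5, rand_evo(), simplify = FALSE),
                 replicate(5, rand_evo(), simplify = FALSE))
  E <- rand_evo()
  expect_equal(csp_features(mod, E), csp_features(mod, 10 * E),
               tolerance = 1e-9)
})

test_that("kind bookkeeping and degenerate inputs error out", {
  set.seed(77)
  mk <- function(kind) {
    p <- rand_pssm(L = 6)
    switch(kind, "ED" = ed_pssm(p), "BIGRAM" = bigram_pssm(p))
  }
  c1 <- replicate(4, mk("ED"), simplify = FALSE)
  c2 <- replicate(4, mk("ED"), simplify = FALSE)
  mod <- fit_csp(c1, c2)
  expect_identical(mod$kind, "ED")
  expect_error(csp_features(mod, mk("BIGRAM")), "kind")
  expect_error(fit_csp(c1, replicate(3, mk("BIGRAM"), simplify = FALSE)),
               "kind")
  expect_error(csp_features(mod, matrix(0, 20, 20)), "degenerate")
  expect_error(fit_csp(list(), c1), "non-empty")
})

test_that("the standard orientation projects with B'P and row variances", {
  set.seed(78)
  c1 <- replicate(5, rand_evo(), simplify = FALSE)
  c2 <- replicate(5, rand_evo(), simplify = FALSE)
  mod_std <- fit_csp(c1, c2, orientation = "standard")
  E <- rand_evo()
  Z <- t(mod_std$B) %*% mod_std$P %*% E
  v <- apply(Z, 1, function(x) mean((x - mean(x))^2))
  expect_equal(unname(csp_features(mod_std, E)), log(v / sum(v)))
  expect_equal(sum(exp(csp_features(mod_std, E))), 1, tolerance = 1e-10)
})

test_that("CSP model JSON serialization round-trips feature extraction", {
  set.seed(79)
  c1 <- replicate(5, rand_evo(), simplify = FALSE)
  c2 <- replicate(5, rand_evo(), simplify = FALSE)
  mod <- fit_csp(c1, c2)
  f <- withr::local_tempfile(fileext = ".json")
  write_csp_model(mod, f)
  mod2 <- read_csp_model(f)
  expect_equal(mod2$W, mod$W, tolerance = 1e-12)
  expect_equal(mod2$eigvals_class1, mod$eigvals_class1, tolerance = 1e-12)
  E <- rand_evo()
  expect_equal(csp_features(mod2, E), csp_features(mod, E),
               tolerance = 1e-12)
})

test_that("a linear threshold on the leading component separates structured
          classes and is at chance for identical ones", {
  # classes with different dominant row subspaces are separable on f1 of
  # the classical (row-variance) orientation
  set.seed(80)
  gen <- function(top) replicate(30, {
    E <- matrix(rnorm(400, sd = 0.1), 20, 20)
    rows <- if (top) 1:6 else 15:20
    E[rows, ] <- E[rows, ] + matrix(rnorm(6 * 20, sd = 2), 6, 20)
    E
  }, simplify = FALSE)
  threshold_acc <- function(c1, c2) {
    mod <- fit_csp(c1, c2, orientation = "standard")
    f1_pos <- vapply(c1, function(E) csp_features(mod, E)[1], numeric(1))
    f1_neg <- vapply(c2, function(E) csp_features(mod, E)[1], numeric(1))
    thr <- stats::median(c(f1_pos, f1_neg))
    acc <- (sum(f1_pos > thr) + sum(f1_neg <= thr)) /
      (length(c1) + length(c2))
    max(acc, 1 - acc)
  }
  c1 <- gen(TRUE); c2 <- gen(FALSE)
  expect_gte(threshold_acc(c1, c2), 0.9)
  # structurally identical classes: no better than weak chance fluctuation
  c3 <- gen(TRUE); c4 <- gen(TRUE)
  expect_lte(threshold_acc(c3, c4), 0.75)
})
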