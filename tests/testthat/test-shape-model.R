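# Statistical shape model: PCA identities, mode recovery, synthesis,
# mirror symmetry of the mean.

test_that("identical members give a zero-variance model with their shape as mean", {
  tpl <- small_template()
  co <- generate_corpus(tpl, no_variation(), 3)
  m <- nasal_ssm(co)
  expect_length(m$variances, 0)
  expect_equal(m$mean_vertices, co$members[[1]]$vertices, tolerance = 1e-12)
  expect_error(modes_for_variance(m, 0.95), "zero")
})

test_that("a two-member corpus has one mode and the midpoint as mean", {
  tpl <- small_template()
  spec <- shape_variation(n_modes = 2, mode_sd = c(5, 3), noise_sd = 0.02,
                          seed = 9)
  co <- generate_corpus(tpl, spec, 2)
  m <- nasal_ssm(co)
  expect_length(m$variances, 1)
  mid <- (co$members[[1]]$vertices + co$members[[2]]$vertices) / 2
  expect_equal(m$mean_vertices, mid, tolerance = 1e-12)
})

test_that("noise-free k-mode corpora are recovered: counts, subspace, realized variances", {
  tpl <- small_template()
  for (k in c(1, 2)) {
    spec <- shape_variation(n_modes = k, noise_sd = 0, seed = 20 + k)
    co <- generate_corpus(tpl, spec, 12)
    m <- nasal_ssm(co)
    expect_length(m$variances, k)
    expect_identical(modes_for_variance(m, 0.999), as.integer(k))
    # subspace identity: projectors agree
    truth <- noseflow:::mode_field_matrix(tpl, k)
    P_fit <- tcrossprod(m$modes)
    P_true <- tcrossprod(truth)
    expect_lt(max(abs(P_fit - P_true)), 1e-8)
    # variances equal the eigenvalues of the realized weight covariance
    W <- do.call(rbind, lapply(co$members,
                               function(g) g$provenance$weights))
    Wc <- sweep(W, 2, colMeans(W))
    emp <- sort(eigen(crossprod(Wc) / (nrow(W) - 1),
                      symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(m$variances, emp, tolerance = 1e-10)
  }
})

test_that("modes_for_variance matches the cumulative-sum oracle", {
  v <- c(4, 3, 2, 1)   # cumulative fractions 0.4, 0.7, 0.9, 1.0
  expect_identical(modes_for_variance(v, 0.90), 3L)
  expect_identical(modes_for_variance(v, 0.95), 4L)
  expect_identical(modes_for_variance(v, 1.0), 4L)
  expect_identical(modes_for_variance(v, 0.05), 1L)
  expect_error(modes_for_variance(v, 0), "fraction")
})

test_that("PCA reconstruction and variance conservation hold", {
  tpl <- small_template()
  spec <- shape_variation(n_modes = 3, noise_sd = 0.05, seed = 4)
  co <- generate_corpus(tpl, spec, 7)
  m <- nasal_ssm(co)
  # orthonormal modes
  gram <- crossprod(m$modes)
  expect_lt(max(abs(gram - diag(ncol(m$modes)))), 1e-10)
  # non-increasing variances, sign convention
  expect_true(all(diff(m$variances) <= 1e-15))
  for (k in seq_len(ncol(m$modes)))
    expect_gt(m$modes[which.max(abs(m$modes[, k])), k], 0)
  # exact reconstruction with all modes
  sc <- coef(m)
  for (j in c(1, 4, 7)) {
    rec <- predict(m, sc[j, ])
    expect_equal(rec$vertices, co$members[[j]]$vertices, tolerance = 1e-8)
  }
  # conservation: sum of variances = total centered variance
  X <- t(vapply(co$members, function(g) as.vector(g$vertices),
                numeric(3 * nrow(co$members[[1]]$vertices))))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(m$variances), sum(Xc^2) / (nrow(X) - 1),
               tolerance = 1e-8)
  # zero weights reproduce the mean
  expect_identical(predict(m)$vertices, mean_shape(m)$vertices)
  expect_error(predict(m, rep(0, ncol(m$modes) + 1)), "longer")
})

test_that("mean shape of a mirror-augmented corpus is mirror-symmetric", {
  tpl <- small_template()
  spec <- shape_variation(n_modes = 3, noise_sd = 0.05, seed = 6)
  aug <- mirror_augment(generate_corpus(tpl, spec, 5))
  m <- nasal_ssm(aug)
  mg <- mean_shape(m)
  expect_equal(mirror_subject(mg)$vertices, mg$vertices, tolerance = 1e-9)
  # vertex-wise mean of members equals the mean shape exactly
  mean_v <- Reduce(`+`, lapply(aug$members, `[[`, "vertices")) /
    length(aug$members)
  expect_equal(mg$vertices, mean_v, tolerance = 1e-12)
})

test_that("mirrored members are reproduced by flipping antisymmetric mode weights", {
  tpl <- small_template()
  # 2-member augmented corpus: single antisymmetric mode, so negating all
  # weights reproduces the mirrored member exactly.
  spec <- shape_variation(n_modes = 3, noise_sd = 0.05, seed = 13)
  aug2 <- mirror_augment(generate_corpus(tpl, spec, 2))
  co1 <- structure(list(members = aug2$members[1:2],
                        mirrored = c(FALSE, TRUE),
                        provenance = aug2$provenance),
                   class = "duct_corpus")
  m1 <- nasal_ssm(co1)
  expect_length(m1$variances, 1)
  rec <- predict(m1, -coef(m1)[1, ])
  expect_equal(rec$vertices, co1$members[[2]]$vertices, tolerance = 1e-8)

  # general case: classify each mode as symmetric/antisymmetric under the
  # mirror operator and flip only the antisymmetric weights.
  aug <- mirror_augment(generate_corpus(tpl, spec, 4))
  m <- nasal_ssm(aug)
  sm <- aug$members[[1]]$symmetry_map
  mirror_vec <- function(x) {
    v <- matrix(x, ncol = 3)[sm, , drop = FALSE]
    v[, 1] <- -v[, 1]
    as.vector(v)
  }
  signs <- vapply(seq_along(m$variances), function(k) {
    mk <- m$modes[, k]
    tk <- mirror_vec(mk)
    if (sum(tk * mk) > 0) 1 else -1
  }, numeric(1))
  j <- 3   # an unmirrored member
  w <- coef(m)[j, ]
  rec <- predict(m, w * signs)
  expect_equal(rec$vertices, mirror_subject(aug$members[[j]])$vertices,
               tolerance = 1e-7)
})

test_that("rigid alignment removes pose-only variation", {
  tpl <- small_template()
  g <- template_geometry(tpl)
  rot <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
  posed <- lapply(c(0, 0.1, -0.15), function(th)
    noseflow:::new_duct_geometry(g$vertices %*% t(rot(th)) +
                                   matrix(th * 5, nrow(g$vertices), 3),
                                 g$topology, g$ring_dirs))
  co <- structure(list(members = posed, mirrored = rep(FALSE, 3),
                       provenance = list()), class = "duct_corpus")
  m_raw <- nasal_ssm(co)
  m_aln <- nasal_ssm(co, align = TRUE)
  expect_gt(sum(m_raw$variances), 1)
  expect_lt(sum(m_aln$variances), 1e-8)
})

test_that("model methods run: summary, simulate, residuals", {
  tpl <- small_template()
  spec <- shape_variation(n_modes = 2, mode_sd = c(5, 3), noise_sd = 0.02,
                          seed = 8)
  m <- nasal_ssm(generate_corpus(tpl, spec, 6))
  s <- summary(m)
  expect_s3_class(s, "summary.nasal_ssm")
  expect_identical(nrow(s$table), length(m$variances))
  draws <- simulate(m, nsim = 2, seed = 1)
  expect_length(draws, 2)
  expect_identical(simulate(m, 1, seed = 3)[[1]]$vertices,
                   simulate(m, 1, seed = 3)[[1]]$vertices)
  r_all <- residuals(m)
  expect_lt(max(r_all), 1e-8)
  r_one <- residuals(m, k = 1)
  expect_true(all(r_one >= 0))
})
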