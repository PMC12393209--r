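# Phantom-truth eigenvalues used in several examples: the axially symmetric
# tensor with MD = 1.66e-3 mm^2/s and FA = 0.31 (closed-form inversion,
# verified against the forward FA formula in test-phantom.R).
lam_par <- 2.274e-3
lam_perp <- 1.353e-3
d_axial <- c(lam_par, lam_perp, lam_perp, 0, 0, 0)

test_that("dapp returns the quadratic form and respects axial symmetry", {
  expect_equal(dapp(diag(3) * 1.7e-3, c(1, 0, 0) / 1), 1.7e-3)
  expect_equal(dapp(d_axial, c(1, 0, 0)), 2.274e-3)
  for (phi in c(0, 0.3, 1.1, 2.5)) {
    expect_equal(dapp(d_axial, c(0, cos(phi), sin(phi))), 1.353e-3)
  }
  expect_error(dapp(d_axial, c(1, 1, 0)), "unit")
})

test_that("kapp has the isotropic identity, Gaussian limit and axial value", {
  d_iso <- diag(3) * 1.66e-3
  w <- iso_w(0.4)
  dirs <- fibonacci_sphere(50)
  expect_equal(kapp(d_iso, w, dirs), rep(0.4, 50), tolerance = 1e-12)
  expect_equal(kapp(d_iso, rep(0, 15), dirs), rep(0, 50))
  # axially symmetric truth: W1111 = AK * lambda_par^2 / MD^2 gives Kapp = AK
  w_ax <- setNames(numeric(15), cardiodki:::.w_names)
  w_ax["w1111"] <- 0.5067
  expect_equal(kapp(d_axial, w_ax, c(1, 0, 0)), 0.27, tolerance = 1e-3)
})

test_that("kapp is undefined (NA), not an error, where Dapp <= 0", {
  d_bad <- c(-1e-3, 1e-3, 1e-3, 0, 0, 0)
  expect_true(is.na(kapp(d_bad, iso_w(0.3), c(1, 0, 0))))
  expect_false(is.na(kapp(d_bad, iso_w(0.3), c(0, 1, 0))))
})

test_that("multiplicity bookkeeping matches the brute-force 81-term sum", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      w <- rnorm(15)
      n <- .normalize_rows2(matrix(rnorm(3), 1, 3))
      fast <- as.vector(cardiodki:::.quartic_design(n) %*% w)
      expect_equal(fast, contract_w_brute(w, as.vector(n)), tolerance = 1e-12)
    }
  })
})

test_that("predict_signal matches the hand-evaluated cumulant expansion", {
  m <- voxel_model(1, diag(3) * 1.66e-3, iso_w(0.32))
  sch <- acquisition_scheme(c(0, 1350), rbind(c(0, 0, 0), c(1, 0, 0)))
  s <- predict_signal(m, sch)
  expect_equal(s[1], 1)                      # b = 0 returns S0 exactly
  # exp(-1350 * 1.66e-3 + (1/6) * 1350^2 * (1.66e-3)^2 * 0.32)
  expect_equal(s[2], 0.13903, tolerance = 1e-4)
  expect_equal(s[2], exp(-2.241 + 0.26785), tolerance = 1e-4)
})

test_that("the MD^2- and Dapp^2-scaled kurtosis forms are identical", {
  withr::with_seed(11, {
    for (rep in 1:4) {
      R <- random_rotation()
      d <- cardiodki:::.rotate_d6(R, c(2.3e-3, 1.4e-3, 1.1e-3, 0, 0, 0))
      w <- cardiodki:::.rotate_w15(R, iso_w(0.3) + rnorm(15, 0, 0.05))
      m <- voxel_model(2.5, d, w)
      sch <- quick_scheme()
      s1 <- predict_signal(m, sch, method = "tensor")
      s2 <- predict_signal(m, sch, method = "apparent")
      expect_equal(s1, s2, tolerance = 1e-12)
    }
  })
})

test_that("W = 0 gives log-signals linear in b (zero second differences)", {
  m <- voxel_model(1, d_axial)
  n <- c(0.6, 0.64, sqrt(1 - 0.6^2 - 0.64^2))
  bs <- seq(0, 1500, by = 300)
  sch <- acquisition_scheme(bs, matrix(n, length(bs), 3, byrow = TRUE))
  lns <- log(predict_signal(m, sch))
  expect_lt(max(abs(diff(diff(lns)))), 1e-12)
})

test_that("rotating tensors and directions together leaves dapp/kapp/signals fixed", {
  withr::with_seed(3, {
    d <- c(2.3e-3, 1.5e-3, 1.0e-3, 1e-4, -2e-4, 5e-5)
    w <- iso_w(0.35) + rnorm(15, 0, 0.04)
    n0 <- .normalize_rows2(matrix(rnorm(30), 10, 3))
    for (rep in 1:3) {
      R <- random_rotation()
      dr <- cardiodki:::.rotate_d6(R, d)
      wr <- cardiodki:::.rotate_w15(R, w)
      nr <- t(R %*% t(n0))
      expect_equal(dapp(dr, nr), dapp(d, n0), tolerance = 1e-12)
      expect_equal(kapp(dr, wr, nr), kapp(d, w, n0), tolerance = 1e-10)
    }
  })
})

test_that("expansion to 81 entries and reduction back is the identity", {
  withr::with_seed(5, {
    w <- rnorm(15)
    full <- cardiodki:::.w15_to_full(w)
    expect_equal(unname(cardiodki:::.full_to_w15(full)), w)
    # full symmetry of the expanded array under index permutation
    expect_equal(full[1, 2, 1, 3], full[3, 1, 2, 1])
    expect_equal(full[2, 2, 3, 1], full[1, 2, 2, 3])
  })
})

test_that("the DKI design matrix has 22 full-rank columns on the protocol", {
  sch <- cardiac_dki_protocol(30, 6, seed = 1)
  X <- dki_design_matrix(sch)
  expect_equal(dim(X), c(756, 22))
  expect_equal(qr(X)$rank, 22)
  expect_error(
    dki_design_matrix(acquisition_scheme(rep(900, 30),
                                         generate_directions(30))),
    "2 distinct non-zero")
})

test_that("a single direction reduces the model to the 1-D Vandermonde", {
  n <- c(1, 0, 0)
  bs <- c(100, 900, 1350)
  sch <- acquisition_scheme(bs, matrix(n, 3, 3, byrow = TRUE))
  X <- dki_design_matrix(sch, check_shells = FALSE)
  # for n = e1 only the intercept, d11 and w1111 columns are non-zero:
  # (1, -b, b^2/6), the quadratic polynomial design of the 1-D expansion
  nz <- which(colSums(abs(X)) > 0)
  expect_equal(colnames(X)[nz], c("ln_s0", "d11", "w1111"))
  expect_equal(unname(X[, nz]), cbind(1, -bs, bs^2 / 6))
})
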