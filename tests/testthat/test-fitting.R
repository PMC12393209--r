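test_that("noiseless Gaussian signals give exact DTI recovery", {
  sch <- quick_scheme()
  withr::with_seed(2, {
    R <- random_rotation()
    d <- cardiodki:::.rotate_d6(R, c(2.2e-3, 1.5e-3, 1.1e-3, 0, 0, 0))
  })
  s <- predict_signal(voxel_model(1.3, d), sch)
  fit <- fit_dti_wls(s, sch)
  expect_true(fit$ok)
  expect_equal(as.numeric(fit[1, cardiodki:::.d_names]), d,
               tolerance = 1e-10)
  expect_equal(fit$s0, 1.3, tolerance = 1e-10)
})

test_that("two-point ADC fits match the closed-form kurtosis-biased slope", {
  # isotropic truth MD = 1.66e-3, K = 0.32: the fitted two-point ADC is
  # D - ((b1 + b2)/6) D^2 K
  m <- voxel_model(1, diag(3) * 1.66e-3, iso_w(0.32))
  n <- c(1, 0, 0)
  for (cases in list(c(100, 450, 1.5792e-3), c(100, 1350, 1.4469e-3))) {
    sch <- acquisition_scheme(cases[1:2], rbind(n, n))
    s <- predict_signal(m, sch)
    fit <- fit_adc_1d(s, cases[1:2])
    expect_equal(fit$dapp, cases[3], tolerance = 1e-4)
    closed <- 1.66e-3 - (sum(cases[1:2]) / 6) * (1.66e-3)^2 * 0.32
    expect_equal(fit$dapp, closed, tolerance = 1e-12)
  }
})

test_that("noiseless phantom voxels give exact 22-parameter DKI recovery", {
  truth <- build_ground_truth(small_spec())
  sch <- quick_scheme()
  S <- cardiodki:::.truth_signals(truth, sch)
  pick <- c(1, nrow(S) %/% 2, nrow(S))
  fit <- fit_dki_wls(S[pick, ], sch)
  expect_true(all(fit$ok))
  for (k in seq_along(pick)) {
    v <- truth$voxels[pick[k], ]
    expect_equal(as.numeric(fit[k, cardiodki:::.d_names]),
                 as.numeric(v[, cardiodki:::.d_names]), tolerance = 1e-8)
    expect_equal(as.numeric(fit[k, cardiodki:::.w_names]),
                 as.numeric(v[, cardiodki:::.w_names]), tolerance = 1e-6)
    expect_equal(fit$s0[k], v$s0, tolerance = 1e-9)
  }
})

test_that("tensor-fit Dapp/Kapp along a direction equals the 1-D 3-point fit", {
  truth <- build_ground_truth(small_spec())
  v <- truth$voxels[5, ]
  d <- as.numeric(v[, cardiodki:::.d_names])
  w <- as.numeric(v[, cardiodki:::.w_names])
  n <- .normalize_rows2(matrix(c(0.2, -0.5, 0.9), 1, 3))
  bs <- c(100, 450, 900)
  sch1 <- acquisition_scheme(bs, matrix(n, 3, 3, byrow = TRUE))
  s <- predict_signal(voxel_model(v$s0, d, w), sch1)
  f1 <- fit_adc_1d(s, bs, kurtosis = TRUE)
  expect_equal(f1$dapp, dapp(d, n), tolerance = 1e-9)
  expect_equal(f1$kapp, kapp(d, w, n), tolerance = 1e-6)
})

test_that("WLS estimates are invariant to global signal scaling", {
  truth <- build_ground_truth(small_spec())
  sch <- quick_scheme()
  S <- cardiodki:::.truth_signals(truth, sch)[1:3, ]
  f1 <- fit_dki_wls(S, sch)
  f2 <- fit_dki_wls(100 * S, sch)
  expect_equal(f2$s0, 100 * f1$s0, tolerance = 1e-9)
  expect_equal(as.matrix(f2[, cardiodki:::.d_names]),
               as.matrix(f1[, cardiodki:::.d_names]), tolerance = 1e-9)
  expect_equal(as.matrix(f2[, cardiodki:::.w_names]),
               as.matrix(f1[, cardiodki:::.w_names]), tolerance = 1e-7)
})

test_that("DKI fit of mono-exponential data returns W ~ 0", {
  sch <- quick_scheme()
  d <- c(2.0e-3, 1.4e-3, 1.2e-3, 1e-4, 0, -5e-5)
  s <- predict_signal(voxel_model(1, d), sch)
  fit <- fit_dki_wls(s, sch)
  expect_lt(max(abs(as.numeric(fit[1, cardiodki:::.w_names]))), 1e-8)
})

test_that("DTI on kurtosis signals underestimates MD, increasingly with bmax", {
  truth <- build_ground_truth(small_spec())
  sch <- quick_scheme()
  S <- cardiodki:::.truth_signals(truth, sch)
  mds <- sapply(c(450, 900, 1200, 1350), function(bh) {
    fit <- dti_scalars(fit_dti_wls(S, sch, subset_bvals = c(100, bh)))
    mean(fit$md[fit$ok])
  })
  expect_true(all(mds < truth$spec$target_md))
  expect_true(all(diff(mds) < 0))
})

test_that("rank-deficient or invalid subsets are reported, not crashed", {
  sch <- quick_scheme()
  s <- predict_signal(voxel_model(1, diag(3) * 1.6e-3), sch)
  expect_error(fit_dti_wls(s, sch, subset_bvals = 450), "2 distinct")
  expect_error(fit_dti_wls(s, sch, subset_bvals = c(100, 475)), "no shell")
  low <- sch$bval <= 450
  expect_error(fit_dki_wls(s[low], sch[low, , drop = FALSE]),
               "quartic|rank-deficient")
  # non-positive signals are excluded per measurement, and counted
  s2 <- s
  s2[c(3, 10)] <- -1
  fit <- fit_dti_wls(s2, sch)
  expect_true(fit$ok)
  expect_equal(fit$n_included, nrow(sch) - 2)
})

test_that("median fitted MK under the study noise ladder is close to truth", {
  # Monte-Carlo at the in-vivo SNR: 150 voxels of the default truth,
  # Gaussian noise scaled to SNR 40 at b = 100
  truth <- build_ground_truth(small_spec(seed = 9))
  sch <- quick_scheme(repeats = 2)
  S <- cardiodki:::.truth_signals(truth, sch)
  pick <- seq_len(min(150, nrow(S)))
  S <- S[pick, ]
  sigma <- mean(S[, sch$bval == 100]) / 40
  withr::with_seed(31, {
    Sn <- S + matrix(rnorm(length(S), 0, sigma), nrow(S))
  })
  maps <- dki_scalar_maps(fit_dki_wls(Sn, sch), n_dirs = 500)
  mks <- maps$mk[maps$ok]
  expect_lt(abs(median(mks, na.rm = TRUE) - truth$spec$target_mk), 0.03)
})
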