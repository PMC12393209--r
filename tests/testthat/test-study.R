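test_that("bmax-subset DTI fits reproduce the closed-form MD decline", {
  truth <- build_ground_truth(small_spec())
  sch <- quick_scheme()
  S <- cardiodki:::.truth_signals(truth, sch)
  tab <- run_bmax_subset_analysis(S, sch)
  expect_equal(tab$bmax, c(450, 900, 1200, 1350))
  # analytic oracle: two-point slope D - ((b1+b2)/6) D^2 K at the printed
  # global values (1.66e-3, 0.32); anisotropy shifts stay within 0.02
  oracle <- (1.66e-3 - ((100 + tab$bmax) / 6) * (1.66e-3)^2 * 0.32) * 1e3
  expect_equal(tab$md_mean, oracle, tolerance = 0.02)
  expect_true(all(diff(tab$md_mean) < 0))
})

test_that("Gaussian-phantom MD is bmax-independent (W = 0 control)", {
  sch <- quick_scheme()
  lam <- cardiodki:::.solve_eigenvalues(1.66e-3, 0.31, 0)
  d <- c(lam, 0, 0, 0)
  S <- rbind(predict_signal(voxel_model(1, d), sch))
  tab <- run_bmax_subset_analysis(S, sch)
  expect_lt(max(tab$md_mean) - min(tab$md_mean), 1e-8)
})

test_that("DKI-MD is subset invariant while DTI-MD declines (noiseless)", {
  truth <- build_ground_truth(small_spec())
  sch <- quick_scheme()
  S <- cardiodki:::.truth_signals(truth, sch)[seq(1, 120, by = 2), ]
  tab <- run_dti_dki_subset_comparison(S, sch, n_dirs = 500)
  dki_md <- tab$md_mean[tab$model == "dki"]
  dti_md <- tab$md_mean[tab$model == "dti"][match(c("subset1", "subset2", "fullset"),
                                                  tab$subset[tab$model == "dti"])]
  expect_lt(max(dki_md) - min(dki_md), 1e-6)
  expect_true(all(diff(dti_md) < 0))
  # DKI kurtosis metrics are also subset invariant without noise
  for (met in c("mk_mean", "ak_mean", "rk_mean")) {
    v <- tab[[met]][tab$model == "dki"]
    expect_lt(max(v) - min(v), 1e-5)
  }
})

test_that("1-D curves: mono-exponential fit underpredicts the kurtosis decay", {
  bs <- c(100, 450, 900, 1200, 1350)
  dtrue <- 1.66e-3; k <- 0.32
  s <- exp(-bs * dtrue + (1 / 6) * bs^2 * dtrue^2 * k)
  res <- one_dim_fit_curves(s, bs)
  # closed form: the two-point mono fit passes through b = 100 and 450
  # exactly, so the log deficit at b is (1/6) D^2 K times the quadratic
  # remainder b^2 - b1^2 - (b - b1)(b1 + b2)
  pred_mono <- res$mono$s0 * exp(-1350 * res$mono$dapp)
  deficit <- log(s[5]) - log(pred_mono)
  remainder <- 1350^2 - 100^2 - (1350 - 100) * (100 + 450)
  expect_equal(deficit, (1 / 6) * dtrue^2 * k * remainder, tolerance = 1e-10)
  expect_gt(deficit, 0)
  # the measured-minus-mono residual grows with b beyond the mono range
  resid <- log(s) - log(res$mono$s0 * exp(-bs * res$mono$dapp))
  expect_true(all(diff(resid[bs >= 450]) > 0))
  # 1-D DKI fit on 3 exact points is an exact interpolation
  res3 <- fit_adc_1d(s[c(1, 3, 5)], bs[c(1, 3, 5)], kurtosis = TRUE)
  expect_equal(res3$dapp, dtrue, tolerance = 1e-10)
  expect_equal(res3$kapp, k, tolerance = 1e-8)
  # K = 0: both curves coincide
  s0k <- exp(-bs * dtrue)
  res0 <- one_dim_fit_curves(s0k, bs)
  expect_equal(res0$curves$s_mono, res0$curves$s_dki, tolerance = 1e-10)
  expect_error(one_dim_fit_curves(s[3:5], bs[3:5]), ">= 2 distinct")
})

test_that("bland_altman matches hand arithmetic", {
  expect_error(bland_altman(1:3, 1:4), "differ in length")
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  const <- bland_altman(c(1.1, 2.1, 3.1), c(1, 2, 3))
  expect_equal(const$mean_diff, 0.1)
  expect_equal(const$loa_upper - const$loa_lower, 0, tolerance = 1e-12)
  ba <- bland_altman(c(0.1, 0.2, 0.3), c(0, 0, 0))
  expect_equal(ba$mean_diff, 0.2)
  expect_equal(ba$sd_diff, 0.1)
  expect_equal(ba$loa_lower, 0.2 - 1.96 * 0.1)
  expect_equal(ba$loa_upper, 0.2 + 1.96 * 0.1)
})

test_that("wilcoxon signed-rank: exact p-values match brute-force enumeration", {
  # n = 10 all-positive differences: the most extreme two-sided outcome
  p10 <- wilcoxon_signed_rank(seq_len(10))
  expect_equal(p10$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_equal(p10$method, "exact")
  # symmetric pairs: no evidence
  expect_equal(wilcoxon_signed_rank(c(-2, 2, -1, 1, -3, 3, -4, 4, -5, 5))$p_value,
               1, tolerance = 1e-12)
  expect_warning(out <- wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(out$p_value, 1)

  # brute-force oracle at n = 8: enumerate all 2^8 sign patterns of the
  # rank statistic to build the exact null, for several observed patterns
  d8 <- c(0.3, -0.1, 0.25, 0.7, -0.45, 0.55, 0.2, 0.65)
  r <- rank(abs(d8))
  v_obs <- sum(r[d8 > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  v_null <- as.matrix(signs) %*% r
  p_brute <- 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs))
  expect_equal(wilcoxon_signed_rank(d8)$p_value, p_brute, tolerance = 1e-12)
  # and against the base-R implementation
  expect_equal(wilcoxon_signed_rank(d8)$p_value,
               stats::wilcox.test(d8, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("wilcoxon handles ties/zeros by the documented convention", {
  d <- c(1, 1, -1, 2, 2, -2, 3, 0, 0, 4)
  out <- wilcoxon_signed_rank(d)
  expect_equal(out$n_nonzero, 8L)       # zeros dropped
  expect_equal(out$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE))
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("snr_gain evaluates the T2-decay echo-time trade-off", {
  expect_equal(round(snr_gain(61, 90, 46), 2), 1.88)
  expect_equal(snr_gain(70, 70, 46), 1)
  expect_equal(snr_gain(61, 118, 46), exp(57 / 46), tolerance = 1e-12)
  expect_error(snr_gain(-1, 90, 46), "positive")
})

test_that("a reduced noiseless study recovers targets and is deterministic", {
  cfg <- study_config(
    n_subjects = 2, base_spec = small_spec(), jitter = 0, noisy = FALSE,
    analyses = c("bmax", "kurtosis"), n_dirs = 500, seed = 7)
  rep1 <- run_full_study(cfg)
  expect_equal(rep1$table_dki$mk_mean_grp, 0.32, tolerance = 5e-3)
  expect_equal(rep1$table_dki$ak_mean_grp, 0.27, tolerance = 5e-3)
  expect_equal(rep1$table_dki$rk_mean_grp, 0.35, tolerance = 5e-3)
  expect_equal(rep1$table_dki$md_mean_grp * 1, 1.66e-3, tolerance = 2e-5)
  expect_equal(rep1$rk_minus_ak$mean, 0.08, tolerance = 5e-3)
  expect_true(all(diff(rep1$table_bmax$md) < 0))
  # determinism: identical config, identical report tables
  rep2 <- run_full_study(cfg)
  expect_identical(rep1$table_dki, rep2$table_dki)
  expect_identical(rep1$table_bmax, rep2$table_bmax)
  expect_identical(rep1$ha_histogram, rep2$ha_histogram)
  # tidiers return per-subject rows / a one-row summary
  expect_equal(nrow(tidy(rep1)), 2)
  expect_equal(glance(rep1)$rk_minus_ak, rep1$rk_minus_ak$mean)
})

test_that("fit tidiers return long parameter tables and one-row summaries", {
  truth <- build_ground_truth(small_spec())
  sch <- quick_scheme()
  S <- cardiodki:::.truth_signals(truth, sch)[1:4, ]
  fit <- fit_dki_wls(S, sch)
  td <- tidy(fit)
  expect_equal(nrow(td), 4 * 22)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$model, "dki")
  expect_equal(gl$frac_ok, 1)
  expect_equal(gl$md_mean, 1.66e-3, tolerance = 1e-6)
})

test_that("plot builders return ggplot objects", {
  bs <- c(100, 450, 900, 1350)
  s <- exp(-bs * 1.6e-3 + bs^2 * (1.6e-3)^2 * 0.3 / 6)
  cv <- one_dim_fit_curves(s, bs)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(plot_bland_altman(c(1, 2, 3), c(1.1, 2.2, 2.9)), "ggplot")
  expect_s3_class(plot_ha_histogram(runif(50, -90, 90)), "ggplot")
  tab <- tibble::tibble(bmax = c(450, 900), md_mean = c(1.58, 1.51))
  expect_s3_class(plot_bmax_trend(tab), "ggplot")
})

test_that("NIfTI and sidecar round-trips preserve series and maps", {
  spec <- small_spec(seed = 30, n_noise_frames = 4)
  truth <- build_ground_truth(spec)
  sch <- quick_scheme()
  sch <- sch[sch$bval %in% c(100, 450, 900), ]
  ser <- synthesize_series(truth, sch)
  dir <- withr::local_tempdir()
  write_dwi_series(ser, dir)
  re <- RNifti::readNifti(file.path(dir, "dwi_real.nii"))
  im <- RNifti::readNifti(file.path(dir, "dwi_imag.nii"))
  expect_equal(dim(re), dim(ser$data))
  expect_equal(max(abs(re - Re(ser$data))), 0, tolerance = 1e-6)
  expect_equal(max(abs(im - Im(ser$data))), 0, tolerance = 1e-6)
  back <- read_gradient_table(file.path(dir, "dwi"))
  expect_equal(back$bval, sch$bval)

  maps <- fit_dki_wls(phase_correct_real(ser), sch) |> dti_scalars()
  write_scalar_maps(maps, truth$mask, dir, metrics = c("md", "fa"),
                    voxel_mm = spec$voxel_mm)
  md_vol <- RNifti::readNifti(file.path(dir, "md.nii"))
  expect_equal(sum(!is.nan(md_vol)), nrow(maps))
  expect_equal(md_vol[cbind(maps$row, maps$col, maps$slice)], maps$md,
               tolerance = 1e-6)
})
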