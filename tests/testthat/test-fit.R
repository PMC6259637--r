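tab1 <- amino_acid_stability()
chi <- chi_table()

test_that("feature construction normalises on the nickel complex", {
  f <- stability_features(tab1, chi, "K1")
  expect_equal(nrow(f), 12L)
  expect_false(any(f$metal == "Cu"))
  ni_gly <- f[f$metal == "Ni" & f$ligand == "glycine", ]
  expect_equal(ni_gly$x, 0)
  expect_equal(ni_gly$yref, 1.90, tolerance = 0.003)
  mn_gly <- f[f$metal == "Mn" & f$ligand == "glycine", ]
  expect_equal(mn_gly$x, 0.34, tolerance = 0.01)
  # yref depends on the ligand only
  expect_equal(length(unique(round(f$yref[f$ligand == "leucine"], 10))), 1L)
  # Ni/valine chi is available as reference although it has no constants
  fb <- stability_features(tab1, chi, "B2")
  expect_equal(nrow(fb), 14L)
  expect_equal(unique(fb$yref[fb$ligand == "valine"]), 6.89,
               tolerance = 0.005)
})

fitK <- fit_stability("K1", data = tab1, chi = chi)
fitB <- fit_stability("B2", data = tab1, chi = chi)

test_that("log K1 model reproduces the published regression summary", {
  cf <- coef(fitK)
  expect_equal(unname(cf["a1"]), 12.2, tolerance = 1.4 / 12.2)
  expect_equal(unname(cf["a2"]), -12.10, tolerance = 0.55 / 12.10)
  expect_equal(unname(cf["a3"]), -0.676, tolerance = 0.046 / 0.676)
  expect_equal(unname(cf["intercept"]), 7.49, tolerance = 0.12 / 7.49)
  expect_equal(fitK$r, 0.999, tolerance = 0.001)
  expect_equal(fitK$se_fit, 0.05, tolerance = 0.01 / 0.05)
  expect_equal(fitK$n, 12L)
})

test_that("log beta2 model reproduces the published regression summary", {
  cf <- coef(fitB)
  expect_equal(unname(cf["a1"]), 3.10, tolerance = 0.33 / 3.10)
  expect_equal(unname(cf["a2"]), -7.66, tolerance = 0.36 / 7.66)
  expect_equal(unname(cf["a3"]), -0.646, tolerance = 0.052 / 0.646)
  expect_equal(unname(cf["intercept"]), 14.58, tolerance = 0.33 / 14.58)
  expect_equal(fitB$r, 0.998, tolerance = 0.001)
  expect_equal(fitB$se_fit, 0.11, tolerance = 0.01 / 0.11)
  expect_equal(fitB$n, 14L)
})

test_that("cross-validation errors match the published ones", {
  expect_equal(fitK$se_cv, 0.08, tolerance = 0.02 / 0.08)
  expect_equal(fitB$se_cv, 0.15, tolerance = 0.02 / 0.15)
  expect_equal(fitK$max_cv_error, 0.13, tolerance = 0.05 / 0.13)
  expect_equal(fitB$max_cv_error, 0.29, tolerance = 0.05 / 0.29)
  expect_gte(fitK$se_cv, fitK$se_fit)
  expect_gte(fitB$se_cv, fitB$se_fit)
})

test_that("predictions follow the normalised model algebra", {
  cf <- coef(fitK)
  # at Ni the quadratic terms vanish: prediction = a3 * chi(NiB) + b
  for (l in supported_ligands()) {
    yref <- chi[chi$metal == "Ni" & chi$ligand == l, "chi_mono"]
    expect_equal(predict(fitK, "Ni", l),
                 unname(cf["a3"] * yref + cf["intercept"]))
  }
  expect_equal(predict(fitK, "Mn", "glycine"), 3.51, tolerance = 0.05 / 3.51)
  expect_equal(predict(fitB, "Fe", "alanine"), 7.13, tolerance = 0.05 / 7.13)
  expect_error(predict(fitK, "Cu", "glycine"), "excluded")
  expect_error(predict(fitK, "Cr", "glycine"), "unsupported metal")
})

test_that("refitting on its own fitted values returns the same model", {
  noiseless <- tab1
  idx <- match(paste(fitK$features$metal, fitK$features$ligand),
               paste(noiseless$metal, noiseless$ligand))
  noiseless$logK1[idx] <- fitK$fitted
  # lm warns about the essentially perfect fit; that is the point here
  refit <- suppressWarnings(fit_stability("K1", data = noiseless, chi = chi))
  expect_equal(coef(refit), coef(fitK), tolerance = 1e-8)
  expect_equal(refit$se_fit, 0, tolerance = 1e-8)
})

test_that("known coefficients are recovered from noisy synthetic data", {
  set.seed(2718)
  truth <- c(a1 = 10, a2 = -11, a3 = -0.7, intercept = 7.2)
  feats <- stability_features(tab1, chi, "K1")
  synth <- tab1
  idx <- match(paste(feats$metal, feats$ligand),
               paste(synth$metal, synth$ligand))
  for (rep in 1:5) {
    y <- truth["a1"] * feats$x2 + truth["a2"] * feats$x +
      truth["a3"] * feats$yref + truth["intercept"] +
      rnorm(nrow(feats), sd = 0.05)
    synth$logK1[idx] <- y
    f <- fit_stability("K1", data = synth, chi = chi)
    expect_true(all(abs(coef(f) - truth) <= 3 * f$se_coef))
    expect_gte(f$se_cv, f$se_fit)
  }
})

test_that("the fit refuses degenerate inputs", {
  expect_error(fit_stability("K1", data = tab1[1:6, ], chi = chi),
               "at least 5")
  # single-ligand data makes yref constant and collinear with intercept
  one_lig <- tab1[tab1$ligand == "glycine", ]
  one_lig <- rbind(one_lig, one_lig)   # enough rows, still rank deficient
  expect_error(fit_stability("K1", data = one_lig, chi = chi), "singular")
})

test_that("stability falls linearly with chi within every metal", {
  ycols <- c(K1 = "logK1", B2 = "logB2")
  for (resp in c("K1", "B2")) {
    for (m in supported_metals()) {   # Cu included in the per-metal trend
      # Fe has a single log K1 record: no line to fit there
      if (sum(!is.na(tab1[tab1$metal == m, ycols[resp]])) < 2L) next
      lf <- fit_linear_per_metal(m, resp, data = tab1, chi = chi)
      expect_lt(lf$slope, 0)
      expect_lt(lf$r, -0.9)           # tight linear decrease
    }
  }
  two <- tab1[tab1$metal == "Ni" & tab1$ligand %in% c("glycine", "alanine"), ]
  lf2 <- fit_linear_per_metal("Ni", "K1", data = two, chi = chi)
  expect_equal(abs(lf2$r), 1)
  expect_error(fit_linear_per_metal("Ni", "K1", data = two[1L, ], chi = chi),
               "at least 2")
})

test_that("metals follow a quadratic within a ligand and Cu sits above it", {
  qf <- fit_quadratic_per_ligand("glycine", "K1", data = tab1, chi = chi)
  expect_equal(qf$n, 4L)
  expect_true(all(abs(qf$residuals) < 0.1))
  expect_gt(qf$cu_deviation, 0)
  for (l in supported_ligands()) {
    qb <- fit_quadratic_per_ligand(l, "B2", data = tab1, chi = chi)
    expect_gt(qb$cu_deviation, 0)
  }
  # three points and three parameters interpolate exactly
  three <- tab1[tab1$ligand == "glycine" & tab1$metal %in%
                  c("Ni", "Co", "Mn"), ]
  q3 <- fit_quadratic_per_ligand("glycine", "K1", data = three, chi = chi)
  expect_equal(q3$residuals, rep(0, 3), tolerance = 1e-10)
})
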