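test_that("noise estimation finds the elbow between populations", {
  # two-population spectrum: 10 strong ions (~1000), 500 weak ions (~10)
  set.seed(11)
  strong <- stats::rnorm(10, 1000, 30)
  weak <- stats::rnorm(500, 10, 1)
  sp <- new_spectrum(seq_len(510) + 100, c(strong, weak), rt = 1)
  thr <- estimate_noise(sp)
  expect_gt(thr, max(weak))
  expect_lt(thr, min(strong))
  # degenerate inputs
  expect_equal(estimate_noise(new_spectrum(1:5 + 100, rep(7, 5), rt = 1)), 0)
  expect_equal(estimate_noise(new_spectrum(numeric(0), numeric(0), rt = 1)), 0)
  expect_equal(estimate_noise(new_spectrum(c(100, 200), c(5, 9), rt = 1)), 0)
})

.gauss_run <- function(mzs, amps, rt0 = 1, sigma = 0.05, rts = seq(0.02, 2, by = 0.02)) {
  spectra <- lapply(rts, function(rt) {
    y <- amps * exp(-(rt - rt0)^2 / (2 * sigma^2))
    keep <- y > 1e-3
    new_spectrum(mzs[keep], y[keep], rt = rt)
  })
  new_run(spectra, role = "incubation", time = 1)
}

test_that("EIC extraction respects the ppm window", {
  run <- .gauss_run(c(500, 500.015), c(1000, 800))  # 30 ppm apart
  eic <- build_eic(run, 500, tol_ppm = 10)
  expect_equal(which.max(eic$intensity), which.min(abs(eic$rt - 1)))
  expect_equal(max(eic$intensity), 1000, tolerance = 1e-3)
  # absent mass: all-zero EIC
  eic0 <- build_eic(run, 900, tol_ppm = 10)
  expect_true(all(eic0$intensity == 0))
  expect_error(build_eic(new_run(list(new_spectrum(1, 1, rt = 1, level = 2L)),
                                 "incubation"), 500), "MS1")
})

test_that("peak detection recovers Gaussian area and resolves doublets", {
  rts <- seq(0.005, 2, by = 0.005)
  A <- 1000; sigma <- 0.05
  run <- .gauss_run(500, A, rt0 = 1, sigma = sigma, rts = rts)
  eic <- build_eic(run, 500)
  pks <- detect_peaks(eic, noise = 1, k = 3)
  expect_equal(nrow(pks), 1)
  expect_equal(pks$rt_apex, 1, tolerance = 0.01)
  expect_lt(abs(pks$area - A * sigma * sqrt(2 * pi)) / (A * sigma * sqrt(2 * pi)),
            0.02)
  expect_true(pks$rt_start < pks$rt_apex && pks$rt_apex < pks$rt_end)
  # flat zero EIC
  expect_equal(nrow(detect_peaks(build_eic(run, 900), noise = 1)), 0)
  # two resolved Gaussians
  spectra <- lapply(rts, function(rt) {
    y <- 800 * exp(-(rt - 0.6)^2 / (2 * 0.04^2)) +
      600 * exp(-(rt - 1.4)^2 / (2 * 0.04^2))
    new_spectrum(500, y, rt = rt)
  })
  eic2 <- build_eic(new_run(spectra, "incubation"), 500)
  pks2 <- detect_peaks(eic2, noise = 1, k = 3)
  expect_equal(nrow(pks2), 2)
  expect_equal(pks2$rt_apex, c(0.6, 1.4), tolerance = 0.01)
})

test_that("hodgkin index properties", {
  x <- c(0, 1, 5, 9, 5, 1, 0)
  expect_equal(hodgkin_index(x, x), 1)
  expect_equal(hodgkin_index(x, 2 * x), 0.8)
  y <- rev(c(9, 5, 1, 0, 0, 0, 0))
  expect_equal(hodgkin_index(c(1, 2, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 2, 1)), 0)
  expect_error(hodgkin_index(rep(0, 3), rep(0, 3)), "all-zero")
  # symmetric, bounded, equals 1 iff identical (property over random draws)
  set.seed(3)
  for (i in 1:50) {
    a <- stats::runif(10); b <- stats::runif(10)
    h <- hodgkin_index(a, b)
    expect_equal(h, hodgkin_index(b, a))
    expect_lte(h, 1)
    expect_gte(h, 0)
    if (h == 1) expect_equal(a, b)
  }
})

test_that("blank exclusion drops only blank-like peaks", {
  rts <- seq(0.02, 2, by = 0.02)
  mkrun <- function(amp, role = "incubation")
    new_run(lapply(rts, function(rt)
      new_spectrum(500, amp * exp(-(rt - 1)^2 / (2 * 0.05^2)) + 1e-9, rt = rt)),
      role = role)
  sample_run <- mkrun(1000)
  eic <- build_eic(sample_run, 500)
  pk <- detect_peaks(eic, noise = 1)[1, ]
  # identical blank: drop with NCAR ~ 1
  bx <- blank_exclusion(pk, eic, mkrun(1000, "blank"))
  expect_false(bx$keep)
  expect_equal(bx$ncar, 1, tolerance = 0.01)
  # blank at half intensity: same shape but keep, NCAR ~ 2
  bx2 <- blank_exclusion(pk, eic, mkrun(500, "blank"))
  expect_true(bx2$keep)
  expect_equal(bx2$ncar, 2, tolerance = 0.01)
  expect_gt(bx2$hodgkin, 0.7)
  # absent in blank: keep with capped NCAR
  empty_blank <- new_run(lapply(rts, function(rt)
    new_spectrum(900, 5, rt = rt)), role = "blank")
  bx3 <- blank_exclusion(pk, eic, empty_blank)
  expect_true(bx3$keep)
  expect_equal(bx3$ncar, 1e6)
})

test_that("filtered spectrum keeps co-eluting ions and rejects background", {
  rts <- seq(0.02, 2, by = 0.02)
  env_mz <- c(500, 500.5, 501)
  env_ab <- c(1, 0.6, 0.25)
  spectra <- lapply(rts, function(rt) {
    g <- 1000 * exp(-(rt - 1)^2 / (2 * 0.05^2))
    new_spectrum(c(env_mz, 777), c(env_ab * g + 1e-9, 50), rt = rt)
  })
  run <- new_run(spectra, "incubation")
  eic <- build_eic(run, 500)
  pk <- detect_peaks(eic, noise = 1)[1, ]
  fs <- filtered_spectrum(run, pk, eic)
  expect_true(attr(fs, "filtered"))
  for (m in env_mz) expect_true(any(abs(fs$mz - m) < 0.01))
  expect_false(any(abs(fs$mz - 777) < 0.01))  # flat background removed
  # single-scan peak: merged but flagged unfiltered
  pk1 <- pk; pk1$rt_start <- pk1$rt_apex - 0.001; pk1$rt_end <- pk1$rt_apex + 0.001
  fs1 <- filtered_spectrum(run, pk1, eic)
  expect_false(attr(fs1, "filtered"))
})

test_that("isotope similarity discriminates charge and pattern", {
  cmp <- parse_formula("C76H104N18O19S2")
  pat <- isotope_pattern(cmp)
  z <- 2
  mzs <- mz_for_charge(pat$mass, z)
  perfect <- new_spectrum(mzs, pat$abundance, rt = 1)
  expect_equal(isotope_similarity(perfect, pat, z), 1, tolerance = 1e-9)
  # only M0 present
  m0 <- new_spectrum(mzs[1], 1, rt = 1)
  want <- 1 - 0.5 * (abs(1 - pat$abundance[1] / sum(pat$abundance)) +
                       sum(pat$abundance[-1]) / sum(pat$abundance))
  expect_equal(isotope_similarity(m0, pat, z), want, tolerance = 1e-9)
  # wrong charge (spacing mismatch) scores strictly lower
  expect_lt(isotope_similarity(perfect, pat, z = 1),
            isotope_similarity(perfect, pat, z = 2))
  # no predicted position observed
  far <- new_spectrum(mzs + 5.13, pat$abundance, rt = 1)
  expect_equal(isotope_similarity(far, pat, z), 0)
})

test_that("candidate assignment picks the highest matching m/z and flags reds", {
  reg <- default_registry()
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  cand <- list(list(composition = polymer_formula(som), generation = 1L))
  pat <- isotope_pattern(cand[[1]]$composition)
  z <- 2
  fs <- new_spectrum(mz_for_charge(pat$mass, z), pat$abundance * 1000, rt = 1)
  for (mode in c("MiM", "MaM")) {
    asg <- assign_candidates(fs, cand, mode = mode, charges = 1:3)
    expect_equal(nrow(asg), 1)
    expect_equal(asg$z, 2)
    expect_lt(abs(asg$ppm), 1)
    expect_gt(asg$isotope_sim, 0.95)
  }
  # MiM and MaM coincide here because M0 is the most abundant peak
  expect_equal(most_abundant_mass(cand[[1]]$composition),
               monoisotopic_mass(cand[[1]]$composition))
  # empty candidate list: nothing assigned -> red classification
  asg0 <- assign_candidates(fs, list(), charges = 1:3)
  expect_equal(nrow(asg0), 0)
  expect_identical(classify_assignment(asg0, list()), "red")
})

test_that("assignment classification maps generations and adducts", {
  fs <- new_spectrum(1001.007276 + 21.981944, 100, rt = 1)
  asg <- assign_candidates(fs, list(), charges = 1)
  attr(asg, "representative_mz") <- fs$mz
  expect_identical(classify_assignment(asg, list(), parent_mass = 1000),
                   "adduct-or-insource")
  gen2 <- list(list(composition = parse_formula("C6H12O6"), generation = 2L))
  pat <- isotope_pattern(gen2[[1]]$composition)
  fs2 <- new_spectrum(mz_for_charge(pat$mass, 1), pat$abundance, rt = 1)
  asg2 <- assign_candidates(fs2, gen2, charges = 1)
  expect_identical(classify_assignment(asg2, gen2), "higher-gen")
})
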