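test_that("paired score test matches the closed form and t.test", {
  # textbook 3-pair hand computation: d = (2, 4, 6), mean 4, sd 2
  a <- c(12, 14, 16); b <- c(10, 10, 10)
  res <- paired_score_test(a, b)
  expect_equal(res$t, 4 / (2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), 2), tolerance = 1e-12)
  # d = (1, -1): t = 0, p = 1
  res0 <- paired_score_test(c(1, 0), c(0, 1))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # reference implementation agreement on random inputs
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- stats::rnorm(n, 5, 2); y <- stats::rnorm(n, 4, 2)
    want <- stats::t.test(x, y, paired = TRUE)
    got <- paired_score_test(x, y)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }
  expect_error(paired_score_test(1, 2), "at least 2")
  expect_error(paired_score_test(c(1, 2), c(1, 2)), "zero")
})

test_that("reference score tables reproduce the reported mode difference", {
  tab <- reference_score_table("printed")
  both <- !is.na(tab$mam_score) & !is.na(tab$mim_score)
  expect_equal(sum(both), 20)
  res <- paired_score_test(tab$mam_score[both], tab$mim_score[both])
  expect_equal(res$p, 0.0002904, tolerance = 1e-3)
  expect_gt(res$mean_diff, 0)  # MaM scores higher on average
  # the realigned reading remains significant at the same order
  tab2 <- reference_score_table("realigned")
  both2 <- !is.na(tab2$mam_score) & !is.na(tab2$mim_score)
  expect_equal(sum(both2), 20)
  res2 <- paired_score_test(tab2$mam_score[both2], tab2$mim_score[both2])
  expect_lt(res2$p, 0.001)
})

test_that("consolidation clusters by rt and m/z across samples", {
  row <- function(rt, mz, time, cand = 1L, area = 100) data.frame(
    rt_start = rt - 0.05, rt_apex = rt, rt_end = rt + 0.05, area = area,
    apex_intensity = 10, mz = mz, z = 2L, candidate = cand,
    nominal_delta = -71L, generation = 1L, score = 10, n_match = 1L,
    n_mismatch = 0L, n_metmatch = 0L, ppm = 1, isotope_sim = 0.9,
    ncar = 100, classification = "first-gen", time = time)
  # same species at three time points -> one entity with three areas
  ent <- consolidate(list(row(1.0, 500.25, 0), row(1.05, 500.251, 30),
                          row(0.98, 500.2495, 60)))
  expect_equal(nrow(ent), 1)
  expect_equal(ent$total_area, 300)
  expect_identical(sort(grep("^area_t", names(ent), value = TRUE)),
                   c("area_t0", "area_t30", "area_t60"))
  # close rt but 500 ppm apart: two entities
  ent2 <- consolidate(list(rbind(row(1.0, 500.0, 30), row(1.05, 500.25, 30))))
  expect_equal(nrow(ent2), 2)
  # empty input
  expect_equal(nrow(consolidate(list())), 0)
  # relative areas sum to 100
  expect_equal(sum(ent2$relative_area_pct), 100, tolerance = 1e-6)
})

test_that("filters drop entities conjunctively with an audit trail", {
  ent <- consolidate(list(data.frame(
    rt_start = c(0.9, 1.9, 2.9), rt_apex = c(1, 2, 3), rt_end = c(1.1, 2.1, 3.1),
    area = c(1000, 3, 996), apex_intensity = 10, mz = c(400, 500, 600), z = 2L,
    candidate = c(0L, 1L, 2L), nominal_delta = c(0L, -71L, 18L),
    generation = c(0L, 1L, 1L), score = 10, n_match = 1L, n_mismatch = 0L,
    n_metmatch = 0L, ppm = c(1, 2, 12), isotope_sim = 0.9, ncar = 100,
    classification = c("parent", "first-gen", "first-gen"), time = 30)))
  fl <- apply_filters(ent, min_relative_area = 0.5, max_ppm = 10)
  expect_equal(nrow(fl$entities), 1 + 0 + 0)  # parent survives always
  expect_setequal(fl$audit$criterion, c("relative_area", "ppm"))
  # all-pass case
  ent$relative_area_pct <- c(50, 25, 25)
  ent$ppm <- c(1, 1, 1)
  fl2 <- apply_filters(ent)
  expect_equal(nrow(fl2$entities), 3)
  expect_equal(nrow(fl2$audit), 0)
})

test_that("kinetic profiles extract per-time relative areas", {
  rows <- list(
    data.frame(rt_start = .95, rt_apex = 1, rt_end = 1.05, area = 900,
               apex_intensity = 10, mz = 400, z = 2L, candidate = 0L,
               nominal_delta = 0L, generation = 0L, score = 0, n_match = 0L,
               n_mismatch = 0L, n_metmatch = 0L, ppm = 0, isotope_sim = 1,
               ncar = 1e6, classification = "parent", time = 0),
    data.frame(rt_start = c(.95, 1.95), rt_apex = c(1, 2), rt_end = c(1.05, 2.05),
               area = c(700, 300), apex_intensity = 10, mz = c(400, 500), z = 2L,
               candidate = c(0L, 1L), nominal_delta = c(0L, -71L),
               generation = c(0L, 1L), score = 0, n_match = 0L, n_mismatch = 0L,
               n_metmatch = 0L, ppm = 0, isotope_sim = 1, ncar = 1e6,
               classification = c("parent", "first-gen"), time = 30))
  ent <- consolidate(rows)
  met_id <- ent$entity[ent$classification == "first-gen"]
  prof <- kinetics_profile(ent, met_id)
  expect_equal(prof$time, c(0, 30))
  expect_equal(prof$relative_area[1], 0)  # nothing but parent at t = 0
  expect_equal(prof$relative_area[2], 0.3)
  par_id <- ent$entity[ent$classification == "parent"]
  pprof <- kinetics_profile(ent, par_id)
  expect_true(all(diff(pprof$relative_area) <= 0))  # parent decays
})

test_that("report writing emits systematic names and deterministic order", {
  reg <- default_registry()
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  cands <- enumerate_metabolites(som, rule_catalog()["amide_hydrolysis"], 1)
  ring <- which(vapply(cands, function(c)
    nrow(c$site_mods) == 1 && c$site_mods$type[1] == "bond_open" &&
      c$site_mods$i[1] == 8, logical(1)))[1]
  minus_ala <- which(vapply(cands, function(c)
    identical(unname(c$monomer_map), 2:14), logical(1)))[1]
  ent <- consolidate(list(data.frame(
    rt_start = c(.85, 1.4, 2), rt_apex = c(.9, 1.45, 2.1),
    rt_end = c(.95, 1.5, 2.2), area = c(300, 200, 500), apex_intensity = 10,
    mz = c(828, 784, 819), z = 2L,
    candidate = c(ring, minus_ala, 0L),
    nominal_delta = c(18L, -71L, 0L), generation = c(1L, 1L, 0L),
    score = c(90, 50, 0), n_match = 1L, n_mismatch = 0L, n_metmatch = 2L,
    ppm = 1, isotope_sim = .95, ncar = 1e6,
    classification = c("first-gen", "first-gen", "parent"), time = 30)))
  path <- tempfile(fileext = ".tsv")
  rep <- write_report(ent, cands, path)
  expect_true(file.exists(path))
  back <- utils::read.delim(path)
  expect_identical(back$name, c("M1+18", "M2-71", "parent"))
  expect_true(all(diff(back$rt_min) > 0))
  expect_match(rep$rules[1], "amide_hydrolysis@8-9")
  expect_true("ccs" %in% names(back))
})
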