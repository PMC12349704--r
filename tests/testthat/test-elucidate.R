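test_that("spectrum pairing finds non-shifted and shifted pairs", {
  par <- new_spectrum(c(100, 200, 300, 400), c(10, 20, 30, 40), rt = 1, level = 2L)
  # identical spectra, no deltas: all non-shifted
  p1 <- pair_spectra(par, par)
  expect_equal(nrow(p1), 4)
  expect_true(all(p1$status == "non-shifted"))
  # half the peaks shifted by +18.0106 at z = 1
  met <- new_spectrum(c(100, 200, 318.0106, 418.0106), c(10, 20, 30, 40),
                      rt = 1, level = 2L)
  p2 <- pair_spectra(par, met, deltas = 18.0106, charges = 1)
  expect_equal(sum(p2$status == "non-shifted"), 2)
  expect_equal(sum(p2$status == "shifted"), 2)
  expect_true(all(abs(p2$met_mz[p2$status == "shifted"] -
                        (p2$par_mz[p2$status == "shifted"] + 18.0106)) < 0.01))
  # disjoint spectra: no pairs
  far <- new_spectrum(c(555, 666), c(1, 1), rt = 1, level = 2L)
  expect_equal(nrow(pair_spectra(par, far)), 0)
  # each metabolite centroid used once per status
  dup_par <- new_spectrum(c(100, 100.0001), c(5, 5), rt = 1, level = 2L)
  one_met <- new_spectrum(100, 9, rt = 1, level = 2L)
  expect_equal(nrow(pair_spectra(dup_par, one_met)), 1)
})

# small worked example: tripeptide parent, loss of the N-terminal residue
.evidence_fixture <- function() {
  reg <- default_registry()
  p <- parse_sequence("H-Ala-Gly-Phe-OH", reg)
  cands <- enumerate_metabolites(p, rule_catalog()["amide_hydrolysis"], 1)
  keep <- which(vapply(cands, function(c)
    identical(unname(c$monomer_map), 2:3), logical(1)))[1]
  frag <- backbone_fragments(p, c("b", "y"), max_charge = 1, h_shifts = 0)
  list(parent = p, cand = cands[[keep]], frag = frag)
}

test_that("evidence classification follows the covered-site logic", {
  fx <- .evidence_fixture()
  # parent MS2 = its own fragments; metabolite spectrum drops b ions and
  # keeps y ions (unchanged: they exclude the lost monomer)
  par_ms2 <- new_spectrum(fx$frag$mz, rep(100, nrow(fx$frag)), rt = 1, level = 2L)
  ysel <- fx$frag$series == "y"
  met_ms2 <- new_spectrum(fx$frag$mz[ysel], rep(100, sum(ysel)), rt = 1,
                          level = 2L)
  pairs <- pair_spectra(par_ms2, met_ms2,
                        deltas = unique(fx$cand$site_mods$dmass))
  fa <- assign_fragments(par_ms2, fx$frag)
  rec <- classify_evidence(pairs, fa, fx$frag, fx$cand)
  # y1/y2 exclude the modification -> matches; b ions give no pair
  expect_true(all(rec$class == "match"))
  expect_equal(nrow(rec), 2)
})

test_that("a non-shifted pair on a fragment covering the site is a mismatch", {
  fx <- .evidence_fixture()
  # b2 covers the lost N-terminal monomer: a metabolite peak at the same
  # m/z contradicts the candidate
  b2 <- fx$frag[fx$frag$series == "b" & fx$frag$cleavage == 2, ]
  par_ms2 <- new_spectrum(b2$mz, 100, rt = 1, level = 2L)
  met_ms2 <- new_spectrum(b2$mz, 100, rt = 1, level = 2L)
  pairs <- pair_spectra(par_ms2, met_ms2)
  fa <- assign_fragments(par_ms2, fx$frag)
  rec <- classify_evidence(pairs, fa, fx$frag, fx$cand)
  expect_equal(nrow(rec), 0)  # absent prediction: no record either way
  # a candidate where b2 is expected shifted: in-place modification at 1
  reg <- default_registry()
  p2 <- parse_sequence("H-Tyr(Me)-Ala-Gly-OH", reg)
  cand2 <- enumerate_metabolites(p2, rule_catalog()["o_dealkylation"], 1)[[1]]
  frag2 <- backbone_fragments(p2, c("b", "y"), max_charge = 1, h_shifts = 0)
  b2b <- frag2[frag2$series == "b" & frag2$cleavage == 2, ]
  par2 <- new_spectrum(b2b$mz, 100, rt = 1, level = 2L)
  met_same <- new_spectrum(b2b$mz, 100, rt = 1, level = 2L)
  rec2 <- classify_evidence(pair_spectra(par2, met_same,
                                         deltas = cand2$site_mods$dmass),
                            assign_fragments(par2, frag2), frag2, cand2)
  expect_equal(rec2$class, "mismatch")
  # and the correctly shifted peak is a match
  met_shift <- new_spectrum(b2b$mz + cand2$site_mods$dmass[1], 100,
                            rt = 1, level = 2L)
  rec3 <- classify_evidence(pair_spectra(par2, met_shift,
                                         deltas = cand2$site_mods$dmass),
                            assign_fragments(par2, frag2), frag2, cand2)
  expect_equal(rec3$class, "match")
})

test_that("metmatches explain metabolite-only fragments once", {
  reg <- default_registry()
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  cands <- enumerate_metabolites(som, rule_catalog()["amide_hydrolysis"], 1)
  ro <- Filter(function(c)
    nrow(c$site_mods) == 1 && c$site_mods$type[1] == "bond_open" &&
      c$site_mods$i[1] == 8, cands)[[1]]
  met_frag <- backbone_fragments(ro$structure, c("b", "y"), max_charge = 1,
                                 h_shifts = 0)
  par_frag <- backbone_fragments(som, c("b", "y"), max_charge = 1,
                                 h_shifts = 0)
  # fragments unique to the ring-opened structure
  uniq <- met_frag[!vapply(met_frag$mz, function(m)
    any(abs(par_frag$mz - m) < 0.01), logical(1)), ]
  expect_gt(nrow(uniq), 5)
  met_ms2 <- new_spectrum(uniq$mz, rep(50, nrow(uniq)), rt = 1, level = 2L)
  mm <- metmatch_evidence(met_frag, met_ms2)
  expect_equal(nrow(mm), nrow(uniq))
  expect_true(all(mm$class == "metmatch"))
  # already-paired centroids are not reused
  mm2 <- metmatch_evidence(met_frag, met_ms2, used_met_mz = met_ms2$mz)
  expect_equal(nrow(mm2), 0)
  # no metabolite fragments: empty
  empty <- met_frag[0, ]
  expect_equal(nrow(metmatch_evidence(empty, met_ms2)), 0)
})

test_that("the score is the signed intensity sum", {
  rec <- data.frame(class = c("match", "match", "metmatch", "mismatch"),
                    intensity = c(100, 50, 30, 20),
                    par_mz = NA, met_mz = NA, label = "")
  sr <- score_evidence(rec)
  expect_equal(sr$score, 160)
  expect_equal(c(sr$n_match, sr$n_metmatch, sr$n_mismatch), c(2, 1, 1))
  expect_identical(sr$records$annotation,
                   c("red", "red", "coral", "cyan"))
  expect_equal(score_evidence(NULL)$score, 0)
  only_mm <- data.frame(class = c("mismatch", "mismatch"),
                        intensity = c(10, 10), par_mz = NA, met_mz = NA,
                        label = "")
  expect_equal(score_evidence(only_mm)$score, -20)
})

test_that("score is monotone under record addition", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(0:6, 1)
    rec <- if (n == 0) NULL else
      data.frame(class = sample(c("match", "mismatch", "metmatch"), n, TRUE),
                 intensity = stats::runif(n, 0, 100),
                 par_mz = NA, met_mz = NA, label = "")
    s0 <- score_evidence(rec)$score
    add <- data.frame(class = sample(c("match", "metmatch"), 1),
                      intensity = stats::runif(1, 0, 100),
                      par_mz = NA, met_mz = NA, label = "")
    expect_gte(score_evidence(rbind(rec, add))$score, s0)
    bad <- add; bad$class <- "mismatch"
    expect_lte(score_evidence(rbind(rec, bad))$score, s0)
    # removing a record and re-scoring equals scoring the reduced set
    if (!is.null(rec) && nrow(rec) > 0)
      expect_equal(score_evidence(rec[-1, , drop = FALSE])$score,
                   score_evidence(rec)$score -
                     ifelse(rec$class[1] == "mismatch", -1, 1) * rec$intensity[1])
  }
})

test_that("candidate ranking and auto-selection", {
  rk <- rank_candidates(c(40, 160))
  expect_equal(rk$candidate, c(2, 1))
  expect_identical(rk$auto_selected, c(TRUE, FALSE))
  # tie broken by generation, then ppm
  rk2 <- rank_candidates(c(100, 100), generations = c(2L, 1L))
  expect_equal(rk2$candidate, c(2, 1))
  rk3 <- rank_candidates(c(100, 100), generations = c(1L, 1L),
                         ppm = c(5, -1))
  expect_equal(rk3$candidate, c(2, 1))
  rk4 <- rank_candidates(50)
  expect_true(rk4$auto_selected)
})
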