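reg <- default_registry()

test_that("series fragments match hand-computed values", {
  ags <- parse_sequence("H-Ala-Gly-Ser-OH", reg)
  fr <- backbone_fragments(ags, series = "b", max_charge = 1, h_shifts = 0)
  b2 <- fr$mz[fr$cleavage == 2]
  expect_equal(b2, 71.03711 + 57.02146 + 1.00728, tolerance = 1e-5)
  # six series on a linear 9-mer give 6 * (n-1) = 48 neutral species
  lin <- parse_sequence("H-Ala-Gly-Ser-Pro-Val-Thr-Leu-Phe-Lys-OH", reg)
  f6 <- backbone_fragments(lin, series = c("a", "b", "c", "x", "y", "z"),
                           max_charge = 1, h_shifts = 0)
  expect_equal(nrow(f6), 48)
  expect_error(backbone_fragments(lin, series = character(0)), "series")
})

test_that("b/y complementarity holds at every cleavage of random peptides", {
  set.seed(7)
  for (rep in 1:50) {
    p <- random_peptide(sample(4:10, 1), reg)
    M <- monoisotopic_mass(polymer_formula(p))
    fr <- backbone_fragments(p, series = c("b", "y"), max_charge = 1,
                             h_shifts = 0)
    n <- length(p$codes)
    for (i in seq_len(n - 1)) {
      b <- fr$mz[fr$series == "b" & fr$cleavage == i]
      y <- fr$mz[fr$series == "y" & fr$cleavage == i]
      expect_lt(abs((b - PROTON_MASS) + (y - PROTON_MASS) - M), 1e-6)
    }
  }
})

test_that("fragment m/z is reproduced by mz_for_charge from the neutral mass", {
  p <- parse_sequence("H-Ala-Gly-Ser-Pro-Val-OH", reg)
  fr <- backbone_fragments(p, series = c("b", "y"), max_charge = 3,
                           h_shifts = -1:1)
  want <- mz_for_charge(fr$neutral_mass + fr$h * 1.0078250319, fr$z)
  expect_equal(fr$mz, want, tolerance = 1e-10)
})

test_that("hydrogen-rearrangement variants span the configured set", {
  p <- parse_sequence("H-Ala-Gly-OH", reg)
  fr <- backbone_fragments(p, series = "b", max_charge = 1, h_shifts = -1:1)
  expect_setequal(fr$h, -1:1)
  d <- diff(sort(fr$mz))
  expect_equal(d, rep(1.0078250319, 2), tolerance = 1e-6)
})

test_that("cyclic structures suppress dangling-arc fragments", {
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  fr <- backbone_fragments(som, series = c("b", "y"), max_charge = 1,
                           h_shifts = 0)
  # only tail fragments (b1, b2) and ring-containing suffixes (y13, y12)
  expect_setequal(fr$label, c("b1", "b2", "y13", "y12"))
  y13 <- fr[fr$label == "y13", ]
  # y13 spans both Cys: mass includes the -H2 of the intact disulfide
  M <- monoisotopic_mass(polymer_formula(som))
  expect_equal(y13$neutral_mass, M - 71.03711, tolerance = 1e-4)
})

test_that("two-chain fragments pull in the disulfide-linked partner chain", {
  rules <- rule_catalog()
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  cands <- enumerate_metabolites(som, rules["amide_hydrolysis"], 1)
  ro <- Filter(function(c)
    nrow(c$site_mods) == 1 && c$site_mods$type[1] == "bond_open" &&
      c$site_mods$i[1] == 8, cands)[[1]]
  fm <- backbone_fragments(ro$structure, series = c("b", "y"), max_charge = 1,
                           h_shifts = 0)
  # the y fragment crossing the former ring bond covers both chains
  y7 <- fm[fm$label == "y7(ch1)", ]
  expect_identical(sort(y7$covered[[1]]), c(2:8, 9:14))
  M <- monoisotopic_mass(polymer_formula(som))
  expect_equal(y7$neutral_mass, M + 18.0105646 - 71.03711, tolerance = 1e-4)
})

test_that("expanded fragmentation matches brute-force bond deletion", {
  gg <- expand(parse_sequence("H-Gly-Gly-OH", reg), 1:2)
  ef1 <- expanded_fragments(gg$graph, 1)
  # oracle: every single-bond deletion of a connected graph (acyclic here)
  # yields exactly two components; count unique atom sets
  nb <- nrow(gg$graph$bonds)
  seen <- character(0)
  for (b in seq_len(nb)) {
    keep <- setdiff(seq_len(nb), b)
    adj <- lapply(seq_len(nrow(gg$graph$atoms)), function(i) integer(0))
    for (r in keep) {
      adj[[gg$graph$bonds$a[r]]] <- c(adj[[gg$graph$bonds$a[r]]], gg$graph$bonds$b[r])
      adj[[gg$graph$bonds$b[r]]] <- c(adj[[gg$graph$bonds$b[r]]], gg$graph$bonds$a[r])
    }
    comp_id <- rep(NA_integer_, nrow(gg$graph$atoms))
    cur <- 0
    for (s in seq_along(comp_id)) {
      if (!is.na(comp_id[s])) next
      cur <- cur + 1
      q <- s; comp_id[s] <- cur
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in adj[[v]]) if (is.na(comp_id[w])) { comp_id[w] <- cur; q <- c(q, w) }
      }
    }
    for (cc in seq_len(max(comp_id)))
      seen <- union(seen, paste(which(comp_id == cc), collapse = ","))
  }
  expect_equal(nrow(ef1), length(seen))
  # monotonicity in allowed breaks
  ef2 <- expanded_fragments(gg$graph, 2)
  expect_gte(nrow(ef2), nrow(ef1))
  # two-atom demo graph: one break, two single-atom fragments
  demo <- list(atoms = data.frame(element = c("C", "C"), monomer = c(1L, 1L)),
               bonds = data.frame(a = 1L, b = 2L))
  expect_equal(nrow(expanded_fragments(demo, 1)), 2)
  # disconnected input errors
  disc <- list(atoms = data.frame(element = c("C", "C"), monomer = c(1L, 1L)),
               bonds = data.frame(a = integer(0), b = integer(0)))
  expect_error(expanded_fragments(disc, 1), "not connected")
})

test_that("all-bond fragments contain the series compositions up to H shifts", {
  gg <- parse_sequence("H-Gly-Gly-OH", reg)
  full <- expand(gg, 1:2)
  ef <- expanded_fragments(full$graph, 1)
  fr <- backbone_fragments(gg, series = c("b", "y"), max_charge = 1,
                           h_shifts = 0)
  for (r in seq_len(nrow(fr))) {
    diffs <- abs(outer(ef$neutral_mass, fr$neutral_mass[r] +
                         (-2:2) * 1.0078250319, "-"))
    expect_lt(min(diffs), 1e-6)
  }
})

test_that("fragment-to-metabolite mapping distinguishes the three statuses", {
  rules <- rule_catalog()
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  cands <- enumerate_metabolites(som, rules["amide_hydrolysis"], 1)
  ro <- Filter(function(c)
    nrow(c$site_mods) == 1 && c$site_mods$type[1] == "bond_open" &&
      c$site_mods$i[1] == 8, cands)[[1]]
  expect_identical(map_fragment_to_metabolite(1:2, ro)$status, "non-shifted")
  sh <- map_fragment_to_metabolite(3:14, ro)
  expect_identical(sh$status, "shifted")
  expect_equal(sh$dmz, 18.0105646, tolerance = 1e-6)
  expect_equal(map_fragment_to_metabolite(3:14, ro, z = 2)$dmz,
               18.0105646 / 2, tolerance = 1e-6)
  minus_ala <- Filter(function(c) c$nominal_delta == -71L, cands)[[1]]
  expect_identical(map_fragment_to_metabolite(1:2, minus_ala)$status, "absent")
  expect_identical(map_fragment_to_metabolite(3:5, minus_ala)$status,
                   "non-shifted")
})
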