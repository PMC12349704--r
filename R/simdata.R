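#' Build a simulation plan
#'
#' Describes a synthetic LC-MS/MS experiment: the parent compound elutes as
#' a Gaussian chromatographic peak carrying its multi-charge isotope
#' envelope; planted metabolites (given as `metab_candidate` objects) elute
#' at their own retention times with per-time-point abundances relative to
#' the parent amplitude; a shared background ion population emulates the
#' incubation matrix and is reproduced in the blank run; intensities carry
#' log-normal jitter and centroid m/z carries Gaussian ppm jitter. All
#' randomness is fixed by the seed.
#'
#' @param parent A `polymer`.
#' @param metabolites List of planted species; each element is a list with
#'   `candidate` (a `metab_candidate`), `rt` (minutes), `sigma` (minutes),
#'   `abundance` (named numeric: per-time-point amplitude relative to
#'   `parent_amplitude`).
#' @param charges Named numeric vector: envelope weight per charge state
#'   (names are the charges), shared by parent and metabolites.
#' @param times Incubation time points (one run each).
#' @param parent_rt,parent_sigma Parent elution position and width (min).
#' @param parent_amplitude Apex intensity scale of the parent envelope.
#' @param parent_decay Fraction of parent remaining per time point (named
#'   by time; default 1 for all).
#' @param background_n Number of matrix background ions.
#' @param background_shared Fraction of background ions present in the
#'   blank run as well.
#' @param background_mean Median background ion intensity.
#' @param noise_sdlog Log-normal intensity jitter (sdlog).
#' @param mz_jitter_ppm Gaussian centroid m/z jitter (1 sd, ppm).
#' @param gradient Gradient length in minutes.
#' @param scan_dt MS1 scan interval in minutes.
#' @param ms2 `"dda"` plants one MS2 scan per species near its apex;
#'   `"none"` disables MS2.
#' @param series Ion series used to build MS2 content.
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_plan` list.
#' @export
sim_plan <- function(parent, metabolites = list(),
                     charges = c("2" = 1), times = c(30, 60),
                     parent_rt = 1.0, parent_sigma = 0.05,
                     parent_amplitude = 5000, parent_decay = NULL,
                     background_n = 120, background_shared = 0.9,
                     background_mean = 20, noise_sdlog = 0.15,
                     mz_jitter_ppm = 2, gradient = 3, scan_dt = 2 / 60,
                     ms2 = c("dda", "none"), series = c("b", "y"),
                     seed = 1) {
  ms2 <- match.arg(ms2)
  for (m in metabolites) {
    stopifnot(inherits(m$candidate, "metab_candidate"),
              m$rt > 0, m$rt < gradient, all(m$abundance >= 0))
  }
  if (is.null(parent_decay))
    parent_decay <- stats::setNames(rep(1, length(times)), times)
  structure(list(parent = parent, metabolites = metabolites,
                 charges = charges, times = times, parent_rt = parent_rt,
                 parent_sigma = parent_sigma,
                 parent_amplitude = parent_amplitude,
                 parent_decay = parent_decay,
                 background_n = background_n,
                 background_shared = background_shared,
                 background_mean = background_mean,
                 noise_sdlog = noise_sdlog, mz_jitter_ppm = mz_jitter_ppm,
                 gradient = gradient, scan_dt = scan_dt, ms2 = ms2,
                 series = series, seed = seed),
            class = "sim_plan")
}

# Envelope of (mz, abundance) rows for a composition at one charge.
.species_envelope <- function(cmp, z, min_rel = 2e-3) {
  pat <- isotope_pattern(cmp)
  keep <- pat$abundance >= min_rel * max(pat$abundance)
  data.frame(mz = mz_for_charge(pat$mass[keep], z),
             ab = pat$abundance[keep])
}

#' Simulate a synthetic LC-MS/MS experiment
#'
#' Generates blank, substrate and per-time-point incubation runs according
#' to the plan: MS1 scans on a fixed retention grid containing the shared
#' background population plus Gaussian chromatographic profiles carrying
#' the isotope envelopes of the parent and planted metabolites at the
#' configured charges, and (in DDA mode) one MS2 scan per species near its
#' apex built from the backbone fragments of the species' structure.
#' Everything is reproducible from the seed.
#'
#' @param plan A `sim_plan`.
#' @return An `experiment` list: `blank`, `substrate`, `incubations`
#'   (one `msrun` per time point), `parent`, `plan`.
#' @export
simulate_experiment <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(plan$seed)

  rts <- seq(plan$scan_dt, plan$gradient, by = plan$scan_dt)
  nbg <- plan$background_n
  bg_mz <- sort(stats::runif(nbg, 200, 1400))
  bg_base <- stats::rlnorm(nbg, log(plan$background_mean), 0.4)
  bg_shared <- seq_len(nbg) <= round(plan$background_shared * nbg)

  jitter_mz <- function(mz) mz * (1 + stats::rnorm(length(mz), 0,
                                                   plan$mz_jitter_ppm * 1e-6))
  jitter_int <- function(x) x * stats::rlnorm(length(x), 0, plan$noise_sdlog)

  # per-species static description: envelopes per charge + structure
  species <- list()
  add_species <- function(id, structure, cmp, rt, sigma, amp_by_time, substrate_amp) {
    envs <- lapply(names(plan$charges), function(zs)
      .species_envelope(cmp, as.integer(zs)))
    names(envs) <- names(plan$charges)
    species[[id]] <<- list(id = id, structure = structure, cmp = cmp,
                           rt = rt, sigma = sigma,
                           amp_by_time = amp_by_time,
                           substrate_amp = substrate_amp, envs = envs)
  }
  pc <- polymer_formula(plan$parent)
  add_species("parent", plan$parent, pc, plan$parent_rt, plan$parent_sigma,
              stats::setNames(plan$parent_amplitude *
                                plan$parent_decay[as.character(plan$times)],
                              plan$times),
              plan$parent_amplitude)
  for (k in seq_along(plan$metabolites)) {
    m <- plan$metabolites[[k]]
    add_species(paste0("met", k), m$candidate$structure,
                m$candidate$composition, m$rt,
                if (is.null(m$sigma)) 0.05 else m$sigma,
                stats::setNames(plan$parent_amplitude *
                                  m$abundance[as.character(plan$times)],
                                plan$times),
                0)
  }

  build_ms1 <- function(rt, amps) {
    mzs <- ints <- numeric(0)
    sel <- stats::runif(nbg) < 0.95  # background ions flicker slightly
    mzs <- c(mzs, jitter_mz(bg_mz[sel]))
    ints <- c(ints, jitter_int(bg_base[sel]))
    for (sp in species) {
      amp <- amps[[sp$id]]
      if (is.null(amp) || amp <= 0) next
      g <- amp * exp(-(rt - sp$rt)^2 / (2 * sp$sigma^2))
      if (g < 1) next
      for (zs in names(sp$envs)) {
        env <- sp$envs[[zs]]
        w <- plan$charges[[zs]]
        y <- jitter_int(g * w * env$ab)
        keep <- y > 0.5
        mzs <- c(mzs, jitter_mz(env$mz[keep]))
        ints <- c(ints, y[keep])
      }
    }
    new_spectrum(mzs, ints, rt = rt, level = 1L)
  }

  species_ms2 <- function(sp, rt) {
    fr <- backbone_fragments(sp$structure, plan$series, max_charge = 1,
                             h_shifts = 0)
    if (nrow(fr) == 0) return(NULL)
    main_z <- as.integer(names(which.max(plan$charges)))
    env <- sp$envs[[as.character(main_z)]]
    prec <- env$mz[which.max(env$ab)]
    ints <- jitter_int(rep(200, nrow(fr)))
    new_spectrum(jitter_mz(fr$mz), ints, rt = rt, level = 2L,
                 precursor = prec)
  }

  make_run <- function(role, amps, time = NA_real_, with_ms2 = TRUE) {
    scans <- list()
    for (rt in rts) {
      scans[[length(scans) + 1]] <- build_ms1(rt, amps)
      if (plan$ms2 == "dda" && with_ms2) {
        for (sp in species) {
          amp <- amps[[sp$id]]
          if (is.null(amp) || amp <= 0) next
          # plant the MS2 scan right after the apex scan
          if (abs(rt - sp$rt) < plan$scan_dt / 2) {
            s2 <- species_ms2(sp, rt + plan$scan_dt / 4)
            if (!is.null(s2)) scans[[length(scans) + 1]] <- s2
          }
        }
      }
    }
    new_run(scans, role = role, time = time)
  }

  blank_amps <- list()
  # blank: shared background only (species absent)
  blank_bg_mz <- bg_mz[bg_shared]; blank_bg_base <- bg_base[bg_shared]
  blank_scans <- lapply(rts, function(rt) {
    sel <- stats::runif(sum(bg_shared)) < 0.95
    new_spectrum(jitter_mz(blank_bg_mz[sel]),
                 jitter_int(blank_bg_base[sel]), rt = rt, level = 1L)
  })
  blank <- new_run(blank_scans, role = "blank")

  sub_amps <- list(parent = plan$parent_amplitude)
  substrate <- make_run("substrate", sub_amps)

  incubations <- lapply(plan$times, function(t) {
    amps <- lapply(species, function(sp) unname(sp$amp_by_time[as.character(t)]))
    names(amps) <- names(species)
    make_run("incubation", amps, time = t)
  })

  structure(list(blank = blank, substrate = substrate,
                 incubations = incubations, parent = plan$parent,
                 plan = plan),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat("<experiment> blank + substrate + ", length(x$incubations),
      " incubation run(s)\n", sep = "")
  invisible(x)
}

#' Deterministic fixture suite
#'
#' Builds the small set of synthetic experiments used for end-to-end
#' validation: a tiny tripeptide, the cyclic nonapeptide oxytocin, the
#' disulfide-cyclic somatostatin (with a planted ring-opening product and a
#' planted terminal-alanine loss), a hexanucleotide with a planted
#' phosphoester cleavage product, and a two-chain insulin-scale dummy whose
#' planted large cleavage product has its monoisotopic isotopologue below
#' the detection threshold (exercising the MaM vs MiM difference). The same
#' seed always produces identical experiments.
#'
#' @param seed Integer seed.
#' @return A named list of lists, each with `experiment`, `candidates`
#'   (enumerated for the parent), `planted` (indices into `candidates`),
#'   `charges` (sensible charge range for processing).
#' @export
make_fixture_suite <- function(seed = 1) {
  reg <- default_registry()
  rules <- rule_catalog()
  out <- list()

  # 1. tiny tripeptide, one truncation product, z = 1
  tri <- parse_sequence("H-Ala-Gly-Phe-OH", reg)
  tri_c <- enumerate_metabolites(tri, rules["amide_hydrolysis"], 1)
  tri_pick <- which(vapply(tri_c, function(c)
    identical(unname(c$monomer_map), 2:3), logical(1)))[1]
  out$tripeptide <- list(
    candidates = tri_c, planted = tri_pick, charges = 1:2,
    experiment = simulate_experiment(sim_plan(
      tri, list(list(candidate = tri_c[[tri_pick]], rt = 0.7, sigma = 0.05,
                     abundance = c("30" = 0.3, "60" = 0.5))),
      charges = c("1" = 1), parent_rt = 1.6, parent_amplitude = 4000,
      parent_decay = c("30" = 0.8, "60" = 0.6), seed = seed)))

  # 2. oxytocin: tail truncation (-Gly-NH2 unit) at z = 1..2
  oxy <- parse_sequence("H-Cys (1)-Tyr-Ile-Gln-Asn-Cys (1)-Pro-Leu-Gly-NH_2_", reg)
  oxy_c <- enumerate_metabolites(oxy, rules["amide_hydrolysis"], 1)
  oxy_pick <- which(vapply(oxy_c, function(c)
    identical(unname(c$monomer_map), 1:8), logical(1)))[1]
  out$oxytocin <- list(
    candidates = oxy_c, planted = oxy_pick, charges = 1:2,
    experiment = simulate_experiment(sim_plan(
      oxy, list(list(candidate = oxy_c[[oxy_pick]], rt = 1.1, sigma = 0.05,
                     abundance = c("30" = 0.25, "60" = 0.4))),
      charges = c("2" = 1), parent_rt = 1.9, parent_amplitude = 5000,
      parent_decay = c("30" = 0.8, "60" = 0.55), seed = seed + 1)))

  # 3. somatostatin: ring opening between monomers 8 and 9 (+18) and
  #    N-terminal alanine loss (-71)
  som <- parse_sequence(
    "H-Ala-Gly-Cys (1)-Lys-Asn-Phe-Phe-Trp-Lys-Thr-Phe-Thr-Ser-Cys (1)-OH", reg)
  som_c <- enumerate_metabolites(som, rules["amide_hydrolysis"], 1)
  ring <- which(vapply(som_c, function(c)
    c$nominal_delta == 18L && nrow(c$site_mods) == 1 &&
      c$site_mods$i[1] == 8, logical(1)))[1]
  minus_ala <- which(vapply(som_c, function(c)
    identical(unname(c$monomer_map), 2:14), logical(1)))[1]
  out$somatostatin <- list(
    candidates = som_c, planted = c(ring, minus_ala), charges = 2:3,
    experiment = simulate_experiment(sim_plan(
      som,
      list(list(candidate = som_c[[ring]], rt = 0.9, sigma = 0.05,
                abundance = c("30" = 0.3, "60" = 0.45)),
           list(candidate = som_c[[minus_ala]], rt = 1.45, sigma = 0.05,
                abundance = c("30" = 0.2, "60" = 0.35))),
      charges = c("2" = 1), parent_rt = 2.1, parent_amplitude = 6000,
      parent_decay = c("30" = 0.7, "60" = 0.45), seed = seed + 2)))

  # 4. hexanucleotide with a planted 3' phosphoester cleavage product
  oligo <- parse_sequence("H-dA-dC-dG-dT-dC-dA-OH", reg)
  oli_c <- enumerate_metabolites(oligo, rules["phosphoester_hydrolysis"], 1)
  oli_pick <- which(vapply(oli_c, function(c)
    identical(unname(c$monomer_map), 1:4), logical(1)))[1]
  out$oligo <- list(
    candidates = oli_c, planted = oli_pick, charges = 1:2,
    experiment = simulate_experiment(sim_plan(
      oligo, list(list(candidate = oli_c[[oli_pick]], rt = 0.8, sigma = 0.05,
                       abundance = c("30" = 0.3, "60" = 0.5))),
      charges = c("2" = 1), parent_rt = 1.7, parent_amplitude = 4500,
      parent_decay = c("30" = 0.75, "60" = 0.5), seed = seed + 3)))

  # 5. insulin-scale two-chain dummy; the planted cleavage product keeps
  #    both chains (held by the inter-chain disulfides). Its monoisotopic
  #    peak carries only a small fraction of the envelope.
  chainA <- parse_sequence(paste0(
    "H-Gly-Ile-Val-Glu-Gln-Cys-Cys-Thr-Ser-Ile-Cys-Ser-Leu-Tyr-Gln-Leu-",
    "Glu-Asn-Tyr-Cys-Asn-OH"), reg)
  chainB <- parse_sequence(paste0(
    "H-Phe-Val-Asn-Gln-His-Leu-Cys-Gly-Ser-His-Leu-Val-Glu-Ala-Leu-Tyr-",
    "Leu-Val-Cys-Gly-Glu-Arg-Gly-Phe-Phe-Tyr-Thr-Pro-Lys-Thr-OH"), reg)
  insulin <- combine_chains(chainA, chainB, rbind(c(7, 7), c(20, 19)))
  insulin$disulfides <- rbind(insulin$disulfides, data.frame(i = 6, j = 11))
  ins_c <- enumerate_metabolites(insulin, rules["amide_hydrolysis"], 1)
  # B-chain cleavage losing the B-chain C-terminal tail (positions 41-51)
  ins_pick <- which(vapply(ins_c, function(c)
    identical(unname(c$monomer_map), 1:40), logical(1)))[1]
  out$insulin_scale <- list(
    candidates = ins_c, planted = ins_pick, charges = 3:4,
    experiment = simulate_experiment(sim_plan(
      insulin, list(list(candidate = ins_c[[ins_pick]], rt = 1.0,
                         sigma = 0.05,
                         abundance = c("30" = 0.1, "60" = 0.16))),
      charges = c("4" = 1), parent_rt = 2.2, parent_amplitude = 12000,
      parent_decay = c("30" = 0.75, "60" = 0.55), seed = seed + 4)))

  out
}
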