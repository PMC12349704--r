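# --- rule objects -----------------------------------------------------------

#' Create a biotransformation rule
#'
#' Two kinds of rules exist. `"cleave"` rules hydrolyze a backbone bond:
#' when the bond is part of a macrocycle (its removal leaves the molecule
#' connected through a disulfide or head-to-tail closure) the product is a
#' single ring-opened species gaining one water; otherwise the molecule
#' splits into two products whose compositions sum to parent + H2O, and both
#' halves are retained as candidates. `"modify"` rules apply an in-place
#' composition delta at matching monomers (O-dealkylation, deamination,
#' nucleobase loss, user-defined deltas).
#'
#' @param name Rule name (used in site labels and reports).
#' @param kind `"cleave"` or `"modify"`.
#' @param classes For cleave rules: monomer classes both bond flanks must
#'   belong to (e.g. `"amino-acid"` for amide hydrolysis).
#' @param codes For modify rules: monomer codes the rule applies to.
#' @param gain,loss `elemcomp` deltas for modify rules (added/removed).
#' @param loss_by_code Optional named list of per-code `loss` compositions
#'   (overrides `loss`), e.g. one nucleobase composition per nucleotide.
#' @return A `biotrans_rule` object.
#' @export
make_rule <- function(name, kind = c("cleave", "modify"),
                      classes = "amino-acid", codes = NULL,
                      gain = comp(), loss = comp(), loss_by_code = NULL) {
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind, classes = classes, codes = codes,
                 gain = gain, loss = loss, loss_by_code = loss_by_code),
            class = "biotrans_rule")
}

#' Default biotransformation rule catalog
#'
#' Ships the reactions relevant to proteolytic and hepatic degradation of
#' peptides and oligonucleotides: amide hydrolysis (which also produces
#' ring-opened species on cyclic peptides), phosphoester hydrolysis,
#' O-dealkylation of ether-bearing side chains, aromatic deamination of
#' nucleobases (net -NH2 +OH, +0.98402 Da), and nucleobase loss to an
#' abasic site. Additional user-defined composition-delta rules (e.g.
#' beta-oxidation steps on fatty-acid side monomers) can be appended with
#' [make_rule()].
#'
#' @return A named list of `biotrans_rule` objects.
#' @export
rule_catalog <- function() {
  list(
    amide_hydrolysis = make_rule("amide_hydrolysis", "cleave",
                                 classes = "amino-acid"),
    phosphoester_hydrolysis = make_rule("phosphoester_hydrolysis", "cleave",
                                        classes = "nucleotide"),
    o_dealkylation = make_rule("o_dealkylation", "modify",
                               codes = c("Tyr(Me)", "Ser-tBu", "Tyr(Et)"),
                               loss = comp(C = 1, H = 2)),
    aromatic_deamination = make_rule("aromatic_deamination", "modify",
                                     codes = c("dA", "dC", "dG"),
                                     gain = comp(O = 1, H = 1),
                                     loss = comp(N = 1, H = 2)),
    nucleobase_loss = make_rule("nucleobase_loss", "modify",
                                codes = c("dA", "dC", "dG", "dT"),
                                gain = comp(H = 2, O = 1),
                                loss_by_code = list(
                                  dA = comp(C = 5, H = 5, N = 5),
                                  dC = comp(C = 4, H = 5, N = 3, O = 1),
                                  dG = comp(C = 5, H = 5, N = 5, O = 1),
                                  dT = comp(C = 5, H = 6, N = 2, O = 2)
                                ))
  )
}

# --- structure surgery ------------------------------------------------------

# Split the chain containing backbone bond (from, to); new termini H / OH.
.split_bond <- function(structure, from, to) {
  ch <- structure$chains
  ci <- which(ch$start <= from & ch$end >= from)[1]
  row <- ch[ci, ]
  if (row$head_tail && from == row$end && to == row$start) {
    row$head_tail <- FALSE
    row$n_cap <- "H"
    row$c_cap <- "OH"
    ch[ci, ] <- row
  } else {
    left <- row; right <- row
    left$end <- from; left$c_cap <- "OH"; left$head_tail <- FALSE
    right$start <- to; right$n_cap <- "H"; right$head_tail <- FALSE
    ch <- rbind(ch[-ci, , drop = FALSE], left, right)
    ch <- ch[order(ch$start), , drop = FALSE]
    rownames(ch) <- NULL
  }
  structure$chains <- ch
  structure
}

# Connected components over monomers (backbone bonds + disulfides).
.components <- function(structure) {
  n <- length(structure$codes)
  adj <- vector("list", n)
  addedge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  bb <- .backbone_bonds(structure)
  for (r in seq_len(nrow(bb))) addedge(bb$from[r], bb$to[r])
  for (r in seq_len(nrow(structure$disulfides)))
    addedge(structure$disulfides$i[r], structure$disulfides$j[r])
  compid <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(compid[s])) next
    cur <- cur + 1L
    queue <- s
    compid[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(compid[w])) {
        compid[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  compid
}

# Restrict a polymer to a monomer index subset; returns list(structure, map)
# where map[new_position] = old_position.
.subset_polymer <- function(structure, keep) {
  keep <- sort(keep)
  newidx <- match(seq_along(structure$codes), keep)  # old -> new (NA if dropped)
  chains <- structure$chains[0, ]
  for (ci in seq_len(nrow(structure$chains))) {
    ch <- structure$chains[ci, ]
    span <- ch$start:ch$end
    inkeep <- span %in% keep
    if (!any(inkeep)) next
    if (!all(inkeep))
      stop("internal error: chain partially outside component")
    ch$start <- newidx[span[1]]
    ch$end <- newidx[span[length(span)]]
    chains <- rbind(chains, ch)
  }
  rownames(chains) <- NULL
  ds <- structure$disulfides
  ds <- ds[ds$i %in% keep & ds$j %in% keep, , drop = FALSE]
  if (nrow(ds)) { ds$i <- newidx[ds$i]; ds$j <- newidx[ds$j] }
  mods <- Filter(function(m) m$site %in% keep, structure$mods)
  mods <- lapply(mods, function(m) { m$site <- newidx[m$site]; m })
  out <- structure
  out$codes <- structure$codes[keep]
  out$labels <- structure$labels[keep]
  out$chains <- chains
  out$disulfides <- ds
  out$mods <- mods
  out$expanded <- structure$expanded[keep]
  out$graph <- NULL
  list(structure = out, map = keep)
}

# --- candidate objects ------------------------------------------------------

.new_candidate <- function(parent, structure, map, steps, generation, site_mods) {
  cmp <- polymer_formula(structure)
  pmass <- monoisotopic_mass(polymer_formula(parent))
  mono_delta <- monoisotopic_mass(cmp) - pmass
  structure(
    list(parent = parent, structure = structure, monomer_map = map,
         steps = steps, generation = generation, site_mods = site_mods,
         composition = cmp, mono_delta = mono_delta,
         nominal_delta = as.integer(round(mono_delta))),
    class = "metab_candidate"
  )
}

#' @export
print.metab_candidate <- function(x, ...) {
  cat("<metabolite candidate> generation ", x$generation,
      ", nominal delta ", sprintf("%+d", x$nominal_delta),
      " (", sprintf("%+.4f", x$mono_delta), " Da)\n", sep = "")
  cat("  steps: ", paste(vapply(x$steps, function(s)
    paste0(s$rule, "@", s$site), ""), collapse = " ; "), "\n", sep = "")
  cat("  ", format_sequence(x$structure), "\n", sep = "")
  invisible(x)
}

# All applicable sites of a rule on a structure.
.rule_sites <- function(structure, rule) {
  reg <- structure$registry
  if (rule$kind == "cleave") {
    bb <- .backbone_bonds(structure)
    if (nrow(bb) == 0) return(bb)
    ok <- vapply(seq_len(nrow(bb)), function(r) {
      cls <- c(reg[[structure$codes[bb$from[r]]]]$klass,
               reg[[structure$codes[bb$to[r]]]]$klass)
      all(cls %in% rule$classes)
    }, logical(1))
    bb[ok, , drop = FALSE]
  } else {
    idx <- which(structure$codes %in% rule$codes)
    data.frame(site = idx)
  }
}

# Apply a rule at one site of a candidate; returns a list of new candidates.
.apply_rule <- function(cand, rule, site_row) {
  parent <- cand$parent
  structure <- cand$structure
  gen <- cand$generation + 1L
  if (rule$kind == "cleave") {
    from <- site_row$from; to <- site_row$to
    pfrom <- cand$monomer_map[from]; pto <- cand$monomer_map[to]
    step <- list(rule = rule$name, site = paste0(pfrom, "-", pto))
    split <- .split_bond(structure, from, to)
    compid <- .components(split)
    if (max(compid) == 1L) {
      sm <- rbind(cand$site_mods,
                  data.frame(type = "bond_open", i = pfrom, j = pto,
                             dmass = 18.0105646))
      return(list(.new_candidate(parent, split, cand$monomer_map,
                                 c(cand$steps, list(step)), gen, sm)))
    }
    out <- list()
    for (cc in sort(unique(compid))) {
      sub <- .subset_polymer(split, which(compid == cc))
      map <- cand$monomer_map[sub$map]
      sm <- cand$site_mods
      keepmod <- sm$i %in% map & (is.na(sm$j) | sm$j %in% map)
      sm <- sm[keepmod, , drop = FALSE]
      out[[length(out) + 1]] <-
        .new_candidate(parent, sub$structure, map,
                       c(cand$steps, list(step)), gen, sm)
    }
    return(out)
  }
  # modify
  i <- site_row$site
  pi <- cand$monomer_map[i]
  code <- structure$codes[i]
  loss <- if (!is.null(rule$loss_by_code)) rule$loss_by_code[[code]] else rule$loss
  dmass <- monoisotopic_mass(rule$gain) - monoisotopic_mass(loss)
  new_struct <- structure
  new_struct$mods <- c(new_struct$mods,
                       list(list(site = i, name = rule$name,
                                 gain = rule$gain, loss = loss)))
  sm <- rbind(cand$site_mods,
              data.frame(type = "modify", i = pi, j = NA_integer_,
                         dmass = dmass))
  step <- list(rule = rule$name, site = as.character(pi))
  list(.new_candidate(parent, new_struct, cand$monomer_map,
                      c(cand$steps, list(step)), gen, sm))
}

#' Mass delta of a rule applied at a site
#'
#' @param rule A `biotrans_rule`.
#' @param site For cleave rules, a list/row with `from` and `to` monomer
#'   indices; for modify rules a list/row with `site`.
#' @param parent The parent `polymer`.
#' @return A data.frame with one row per product: monoisotopic delta (Da)
#'   and nominal (rounded integer) delta versus the parent.
#' @export
rule_delta <- function(rule, site, parent) {
  cand0 <- .new_candidate(parent, parent, seq_along(parent$codes), list(), 0L,
                          data.frame(type = character(0), i = integer(0),
                                     j = integer(0), dmass = numeric(0)))
  prods <- .apply_rule(cand0, rule, as.data.frame(site))
  data.frame(
    mono_delta = vapply(prods, function(p) p$mono_delta, 0),
    nominal_delta = vapply(prods, function(p) p$nominal_delta, 0L)
  )
}

.candidate_key <- function(cand) {
  paste(format_formula(cand$composition),
        paste(cand$monomer_map, collapse = ","),
        paste(cand$site_mods$type, cand$site_mods$i, cand$site_mods$j,
              collapse = ";"),
        sep = "|")
}

#' Enumerate metabolite candidates
#'
#' Breadth-first application of the rule set to the parent, then to each
#' first-generation product, and so on up to `max_generation`. Candidates
#' are de-duplicated on (composition, surviving-monomer map, modification
#' site set), keeping the lowest generation; both halves of a linear
#' cleavage are retained. Each candidate carries a map from its monomers to
#' the parent monomers (used to shift fragments) and a site-modification
#' table recording opened bonds and in-place deltas in parent coordinates.
#'
#' @param parent A `polymer`.
#' @param rules List of `biotrans_rule` objects, e.g. [rule_catalog()].
#' @param max_generation Maximum number of stacked rule applications.
#' @param max_products Hard cap on the number of candidates enumerated.
#' @return A list of `metab_candidate` objects in deterministic
#'   (generation, rule, site) order.
#' @export
enumerate_metabolites <- function(parent, rules, max_generation = 2,
                                  max_products = 10000) {
  stopifnot(max_generation >= 1, length(rules) >= 1)
  seed <- .new_candidate(parent, parent, seq_along(parent$codes), list(), 0L,
                         data.frame(type = character(0), i = integer(0),
                                    j = integer(0), dmass = numeric(0)))
  seen <- character(0)
  out <- list()
  frontier <- list(seed)
  for (gen in seq_len(max_generation)) {
    nxt <- list()
    for (cand in frontier) {
      for (rule in rules) {
        sites <- .rule_sites(cand$structure, rule)
        for (r in seq_len(nrow(sites))) {
          prods <- .apply_rule(cand, rule, sites[r, , drop = FALSE])
          for (p in prods) {
            if (length(p$structure$codes) == 0) next
            key <- .candidate_key(p)
            if (key %in% seen) next
            seen <- c(seen, key)
            out[[length(out) + 1]] <- p
            nxt[[length(nxt) + 1]] <- p
            if (length(out) >= max_products) return(out)
          }
        }
      }
    }
    frontier <- nxt
  }
  out
}

#' Classify a candidate's metabolic generation
#'
#' First-generation products (one applied reaction) are distinguished from
#' second-or-higher generation products, matching the usual green/brown
#' color coding of metabolite chromatogram reports.
#'
#' @param candidate A `metab_candidate`.
#' @return `"first"` or `"higher"`.
#' @export
classify_generation <- function(candidate) {
  if (candidate$generation <= 1L) "first" else "higher"
}
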