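.H_MASS  <- 1.0078250319
.CO_MASS <- 12 + 15.9949146221
.NH3_MASS <- 14.0030740052 + 3 * 1.0078250319
.H2O_MASS <- 18.0105646
.H2_MASS <- 2 * 1.0078250319

# Neutral-mass offsets of the six backbone ion series relative to the summed
# residue compositions plus the relevant terminal group. b is the acylium-
# derived neutral (sum(res) + n_cap - H); y is the intact C-terminal peptide
# (sum(res) + c_cap + H); the others follow the usual even-electron
# relations a = b - CO, c = b + NH3, x = y + CO - H2, z = y - NH3.
.series_offsets <- function() {
  c(a = -.H_MASS - .CO_MASS,
    b = -.H_MASS,
    c = -.H_MASS + .NH3_MASS,
    x = .H_MASS + .CO_MASS - .H2_MASS,
    y = .H_MASS,
    z = .H_MASS - .NH3_MASS)
}

.residue_mass <- function(structure, idx) {
  sum(vapply(structure$codes[idx], function(code)
    monoisotopic_mass(structure$registry[[code]]$composition), 0))
}

# Resolve disulfide connectivity for a candidate covered set on one chain:
# returns list(covered, extra_mass, keep). Fragments dangling on an intact
# same-chain disulfide (cyclic arc) are dropped; a disulfide to another
# chain pulls in that whole chain (minus H2), iterated to closure.
.resolve_disulfides <- function(structure, covered, chain_of) {
  extra <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(structure$disulfides))) {
      p <- structure$disulfides$i[r]; q <- structure$disulfides$j[r]
      inside <- c(p %in% covered, q %in% covered)
      if (sum(inside) == 2 || sum(inside) == 0) next
      dangling <- if (inside[1]) q else p
      if (chain_of[dangling] %in% chain_of[covered])
        return(list(keep = FALSE))
      ch <- structure$chains[chain_of[dangling], ]
      span <- ch$start:ch$end
      caps <- .cap_comps()
      extra <- extra + .residue_mass(structure, span) +
        monoisotopic_mass(caps[[ch$n_cap]]) +
        monoisotopic_mass(caps[[ch$c_cap]])
      covered <- sort(c(covered, span))
      changed <- TRUE
    }
    if (!changed) break
  }
  # subtract H2 per disulfide fully inside the covered set
  nd <- 0
  for (r in seq_len(nrow(structure$disulfides))) {
    if (structure$disulfides$i[r] %in% covered &&
        structure$disulfides$j[r] %in% covered) nd <- nd + 1
  }
  list(keep = TRUE, covered = covered, extra_mass = extra - nd * .H2_MASS)
}

#' Backbone ion series fragments
#'
#' Generates the classic a/b/c (N-terminal) and x/y/z (C-terminal) ion
#' series at every backbone cleavage of every chain, for charges 1 to
#' `max_charge` and each hydrogen-rearrangement variant. Fragments carrying
#' only one endpoint of an intact same-chain disulfide (a cyclic arc that
#' cannot detach) are suppressed; a fragment whose disulfide partner sits on
#' another chain pulls in that whole chain minus H2, yielding two-chain
#' fragments. In-place modification deltas of the structure's `mods`
#' records are applied when the modified monomer is covered.
#'
#' @param structure A `polymer`.
#' @param series Character subset of `c("a","b","c","x","y","z")`.
#' @param max_charge Maximum charge state (protonation assumed).
#' @param h_shifts Integer hydrogen-rearrangement variants, default -1:1.
#' @param polarity `"+"` or `"-"` for m/z computation.
#' @return A data.frame with one row per (fragment, z, h): columns `series`,
#'   `cleavage` (global bond position), `chain`, `covered` (list-column of
#'   parent monomer indices), `neutral_mass` (h = 0 variant), `z`, `h`,
#'   `mz`, `label`.
#' @export
backbone_fragments <- function(structure, series = c("b", "y"), max_charge = 1,
                               h_shifts = -1:1, polarity = "+") {
  if (length(series) == 0) stop("empty series set")
  series <- match.arg(series, c("a", "b", "c", "x", "y", "z"),
                      several.ok = TRUE)
  offsets <- .series_offsets()
  caps <- .cap_comps()
  n <- length(structure$codes)
  chain_of <- integer(n)
  for (ci in seq_len(nrow(structure$chains)))
    chain_of[structure$chains$start[ci]:structure$chains$end[ci]] <- ci
  mod_sites <- vapply(structure$mods, function(m) m$site, 0L)
  mod_dmass <- vapply(structure$mods, function(m)
    monoisotopic_mass(m$gain) - monoisotopic_mass(m$loss), 0)

  rows <- list()
  for (ci in seq_len(nrow(structure$chains))) {
    ch <- structure$chains[ci, ]
    if (ch$end == ch$start) next
    for (i in ch$start:(ch$end - 1L)) {
      for (ss in series) {
        nterm <- ss %in% c("a", "b", "c")
        covered <- if (nterm) ch$start:i else (i + 1L):ch$end
        cap <- if (nterm) ch$n_cap else ch$c_cap
        base <- .residue_mass(structure, covered) +
          monoisotopic_mass(caps[[cap]]) + offsets[[ss]]
        res <- .resolve_disulfides(structure, covered, chain_of)
        if (!res$keep) next
        base <- base + res$extra_mass
        covered <- res$covered
        if (length(mod_sites))
          base <- base + sum(mod_dmass[mod_sites %in% covered])
        idx <- if (nterm) i - ch$start + 1L else ch$end - i
        rows[[length(rows) + 1]] <- list(
          series = ss, cleavage = i, chain = ci, covered = covered,
          neutral_mass = base, label = paste0(ss, idx,
                                              if (nrow(structure$chains) > 1)
                                                paste0("(ch", ci, ")") else "")
        )
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(series = character(0), cleavage = integer(0),
                      chain = integer(0), neutral_mass = numeric(0),
                      z = integer(0), h = integer(0), mz = numeric(0),
                      label = character(0)))
  out <- do.call(rbind, lapply(rows, function(fr) {
    grid <- expand.grid(z = seq_len(max_charge), h = h_shifts)
    data.frame(series = fr$series, cleavage = fr$cleavage, chain = fr$chain,
               neutral_mass = fr$neutral_mass, z = grid$z, h = grid$h,
               mz = mz_for_charge(fr$neutral_mass + grid$h * .H_MASS,
                                  grid$z, polarity),
               label = fr$label, stringsAsFactors = FALSE)
  }))
  out$covered <- rep(lapply(rows, function(fr) fr$covered),
                     each = max_charge * length(h_shifts))
  out
}

#' All-bond fragments of an atom graph
#'
#' Enumerates every connected component obtainable by deleting up to
#' `max_bond_breaks` bonds of the expanded structure's atom graph,
#' de-duplicated by atom set. This is the atom-level counterpart of the
#' backbone ion series and produces a much larger fragment space.
#'
#' @param graph The `graph` element of an expanded `polymer` (must be
#'   connected).
#' @param max_bond_breaks Maximum number of simultaneously broken bonds.
#' @return A data.frame with columns `atoms` (list-column of atom indices),
#'   `formula`, `neutral_mass` (no H rearrangement), `n_breaks`.
#' @export
expanded_fragments <- function(graph, max_bond_breaks = 1) {
  stopifnot(max_bond_breaks >= 1)
  nb <- nrow(graph$bonds)
  na <- nrow(graph$atoms)
  adj_of <- function(drop) {
    adj <- vector("list", na)
    for (r in setdiff(seq_len(nb), drop)) {
      a <- graph$bonds$a[r]; b <- graph$bonds$b[r]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj
  }
  components <- function(adj) {
    compid <- rep(NA_integer_, na)
    cur <- 0L
    for (s in seq_len(na)) {
      if (!is.na(compid[s])) next
      cur <- cur + 1L
      queue <- s; compid[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (is.na(compid[w])) {
          compid[w] <- cur; queue <- c(queue, w)
        }
      }
    }
    compid
  }
  if (max(components(adj_of(integer(0)))) != 1L)
    stop("atom graph is not connected")
  seen <- new.env(parent = emptyenv())
  out <- list()
  add_components <- function(drop) {
    compid <- components(adj_of(drop))
    if (max(compid) == 1L) return()
    for (cc in seq_len(max(compid))) {
      atoms <- which(compid == cc)
      key <- paste(atoms, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cmp <- do.call(comp, as.list(table(graph$atoms$element[atoms])))
      out[[length(out) + 1]] <<- list(atoms = atoms,
                                      formula = format_formula(cmp),
                                      neutral_mass = monoisotopic_mass(cmp),
                                      n_breaks = length(drop))
    }
  }
  for (b1 in seq_len(nb)) add_components(b1)
  if (max_bond_breaks >= 2 && nb >= 2) {
    pairs <- utils::combn(nb, 2)
    for (cidx in seq_len(ncol(pairs))) add_components(pairs[, cidx])
  }
  if (max_bond_breaks >= 3)
    warning("only up to 2 simultaneous bond breaks are enumerated")
  if (length(out) == 0)
    return(data.frame(formula = character(0), neutral_mass = numeric(0),
                      n_breaks = integer(0)))
  res <- data.frame(
    formula = vapply(out, `[[`, "", "formula"),
    neutral_mass = vapply(out, `[[`, 0, "neutral_mass"),
    n_breaks = vapply(out, `[[`, 0L, "n_breaks")
  )
  res$atoms <- lapply(out, `[[`, "atoms")
  res
}

#' Expected m/z status of a parent fragment in a metabolite spectrum
#'
#' Given a parent fragment's covered monomer set and a metabolite candidate,
#' predicts whether the corresponding metabolite fragment appears at the
#' same m/z (`"non-shifted"`), at a shifted m/z (`"shifted"`, with the site
#' delta divided by the charge), or not at all (`"absent"`, when the covered
#' set includes monomers lost by cleavage, or dangles across an opened bond).
#'
#' @param covered Integer vector of parent monomer indices the fragment spans.
#' @param candidate A `metab_candidate`.
#' @param z Charge used for the delta-m/z conversion.
#' @return A list with `status` and `dmz` (0 for non-shifted, NA for absent).
#' @export
map_fragment_to_metabolite <- function(covered, candidate, z = 1) {
  lost <- setdiff(seq_along(candidate$parent$codes), candidate$monomer_map)
  if (any(covered %in% lost))
    return(list(status = "absent", dmz = NA_real_))
  shift <- 0
  sm <- candidate$site_mods
  for (r in seq_len(nrow(sm))) {
    if (sm$type[r] == "modify") {
      if (sm$i[r] %in% covered) shift <- shift + sm$dmass[r]
    } else {  # bond_open
      inside <- sum(c(sm$i[r], sm$j[r]) %in% covered)
      if (inside == 1) return(list(status = "absent", dmz = NA_real_))
      if (inside == 2) shift <- shift + sm$dmass[r]
    }
  }
  if (abs(shift) < 1e-9) list(status = "non-shifted", dmz = 0)
  else list(status = "shifted", dmz = shift / z)
}
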