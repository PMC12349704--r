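# Terminal-group composition deltas, applied per chain on top of the summed
# residue compositions. A linear free peptide is sum(residues) + H ("H") +
# OH ("OH"), i.e. + H2O. "ol" is a reduced C-terminus (carbonyl -> CH2OH,
# net +H3 vs the bare acyl chain); "none" is used for acyl N-termini
# (e.g. deamino-Cys) and for head-to-tail cyclic chains.
.cap_comps <- function() {
  list(
    H         = comp(H = 1),
    OH        = comp(H = 1, O = 1),
    NH2       = comp(N = 1, H = 2),
    NHEt      = comp(C = 2, H = 6, N = 1),
    NHNHCONH2 = comp(C = 1, H = 4, N = 3, O = 1),
    ol        = comp(H = 3),
    Ac        = comp(C = 2, H = 3, O = 1),
    none      = comp()
  )
}

.cap_mass <- function(cap) monoisotopic_mass(.cap_comps()[[cap]])

# Atom-level residue templates for expanded-mode demos. Atoms are element
# symbols; bonds are index pairs; n_attach/c_attach mark the backbone
# nitrogen and carbonyl carbon used to join consecutive expanded monomers.
.builtin_templates <- function() {
  gly <- list(
    atoms = c("N", "H", "C", "H", "H", "C", "O"),
    bonds = rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(3, 6), c(6, 7)),
    n_attach = 1L, c_attach = 6L
  )
  ala <- list(
    atoms = c("N", "H", "C", "H", "C", "H", "H", "H", "C", "O"),
    bonds = rbind(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(5, 6), c(5, 7),
                  c(5, 8), c(3, 9), c(9, 10)),
    n_attach = 1L, c_attach = 9L
  )
  list(Gly = gly, Ala = ala)
}

#' Default monomer registry
#'
#' Loads the registry shipped with the package: the 20 proteinogenic amino
#' acid residues (compositions as incorporated in the chain, i.e. amino acid
#' minus water), the unnatural residues appearing in published therapeutic
#' peptides (pyroglutamate/Glp, Aib, ornithine, sarcosine, Msa,
#' 2-naphthylalanine, tert-butyl serine, benzyl histidine, O-methyl/O-ethyl
#' tyrosine, methionine sulfone, deamino-cysteine), and DNA nucleotide
#' residues. D-isomers share the composition of their L counterparts and are
#' resolved by stripping the `D-` prefix during parsing. Atom-level
#' templates are attached for the small built-in demo set (Gly, Ala).
#'
#' @return A named list of class `"monomer_registry"`; each entry has
#'   `code`, `composition`, `klass`, `thiol` and optional `template`.
#' @export
default_registry <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "monomers.tsv", package = "macromet"),
    stringsAsFactors = FALSE
  )
  tpl <- .builtin_templates()
  reg <- lapply(seq_len(nrow(tab)), function(i) {
    list(
      code = tab$code[i],
      composition = parse_formula(tab$formula[i]),
      klass = tab$class[i],
      thiol = isTRUE(tab$thiol[i]),
      template = tpl[[tab$code[i]]]
    )
  })
  names(reg) <- tab$code
  class(reg) <- "monomer_registry"
  reg
}

#' Register a custom monomer
#'
#' Side-chain conjugates (e.g. fatty-acid modified lysines) are treated as
#' single custom monomers in non-expanded mode.
#'
#' @param registry A `monomer_registry`.
#' @param code Unique short symbol.
#' @param formula Residue composition (formula string or `elemcomp`),
#'   as incorporated in the chain.
#' @param klass One of `"amino-acid"`, `"nucleotide"`, `"cap"`, `"other"`.
#' @param thiol Whether the residue carries a free thiol (disulfide-capable).
#' @param template Optional atom-level template (see [default_registry()]).
#' @return The updated registry.
#' @export
register_monomer <- function(registry, code, formula,
                             klass = "other", thiol = FALSE, template = NULL) {
  if (code %in% names(registry))
    stop("monomer code already registered: ", code)
  cmp <- if (inherits(formula, "elemcomp")) formula else parse_formula(formula)
  if (length(cmp) == 0) stop("residue composition must be non-empty")
  registry[[code]] <- list(code = code, composition = cmp, klass = klass,
                           thiol = thiol, template = template)
  registry
}

# Split a sequence string on "-" at parenthesis depth 0, trimming whitespace.
.split_tokens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0
  cur <- character(0)
  toks <- character(0)
  for (ch in chars) {
    if (ch %in% c("(", "[")) depth <- depth + 1
    if (ch %in% c(")", "]")) depth <- depth - 1
    if (ch == "-" && depth == 0) {
      toks <- c(toks, paste(cur, collapse = ""))
      cur <- character(0)
    } else cur <- c(cur, ch)
  }
  toks <- c(toks, paste(cur, collapse = ""))
  toks <- trimws(toks)
  toks[nzchar(toks)]
}

.resolvable <- function(tk, registry) {
  tk2 <- sub("^[DL]-", "", tk)
  tk %in% names(registry) || tk2 %in% names(registry) ||
    gsub("\\s", "", tk) %in% c("OH", "NH2", "NHEt", "NHNHCONH2", "ol", "H", "Ac")
}

.resolve_code <- function(tk, registry) {
  if (tk %in% names(registry)) return(tk)
  tk2 <- sub("^[DL]-", "", tk)
  if (tk2 %in% names(registry)) return(tk2)
  NULL
}

#' Parse a polymer sequence in dash notation
#'
#' Parses sequences such as
#' `"H-Cys (1)-Tyr-Ile-Gln-Asn-Cys (1)-Pro-Leu-Gly-NH_2_"`:
#' tokens are split on dashes outside parentheses; a leading `H`/`Ac` and a
#' trailing `OH`/`NH2`/`NHEt`/`NHNHCONH2`/`ol` map to terminal groups;
#' numeric `(n)` labels pair up into disulfide bridges; a `D-` prefix selects
#' the D-isomer (same composition); compound tokens such as `Ser-tBu` or
#' `deamino-Cys` are re-joined when the fragment alone is not resolvable.
#' Underscore subscripts (`NH_2_`) are normalized away. When no explicit
#' N-terminal token is given, a nitrogen-bearing first residue receives the
#' implicit N-terminal hydrogen (so `Glp-` sequences carry the pyroglutamate
#' ring N-H), while acyl starters such as deamino-Cys do not.
#'
#' @param text Sequence string.
#' @param registry A `monomer_registry`, by default [default_registry()].
#' @param head_tail Set `TRUE` for head-to-tail (backbone) cyclization; the
#'   chain then has no terminal groups and loses one water relative to the
#'   free linear peptide.
#' @return A `polymer` object: ordered monomers grouped into chains (one
#'   chain after parsing; hydrolytic ring opening splits chains), terminal
#'   groups per chain, disulfide linkages, in-place modification records and
#'   per-monomer representation flags.
#' @examples
#' parse_sequence("H-Ala-Gly-OH")
#' @export
parse_sequence <- function(text, registry = default_registry(), head_tail = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("_", "", trimws(text))
  if (!nzchar(s)) stop("empty sequence")
  toks <- .split_tokens(s)

  # merge unresolvable fragments with their neighbours (D-, deamino-, Ser-tBu)
  merged <- character(0)
  i <- 1
  while (i <= length(toks)) {
    tk <- toks[i]
    if (tk %in% c("D", "deamino", "L") && i < length(toks)) {
      merged <- c(merged, paste0(tk, "-", toks[i + 1]))
      i <- i + 2
    } else if (length(merged) > 0 &&
               !.resolvable(tk, registry) &&
               .resolvable(paste0(merged[length(merged)], "-", tk), registry)) {
      merged[length(merged)] <- paste0(merged[length(merged)], "-", tk)
      i <- i + 1
    } else {
      merged <- c(merged, tk)
      i <- i + 1
    }
  }
  toks <- merged

  n_cap <- NULL
  if (toks[1] == "H") { n_cap <- "H"; toks <- toks[-1] }
  else if (toks[1] == "Ac") { n_cap <- "Ac"; toks <- toks[-1] }
  c_cap <- NULL
  last <- gsub("\\s", "", toks[length(toks)])
  if (length(toks) > 1 && last %in% c("OH", "NH2", "NHEt", "NHNHCONH2", "ol")) {
    c_cap <- last
    toks <- toks[-length(toks)]
  }
  if (length(toks) == 0) stop("sequence contains no monomers")

  labels <- character(0)
  codes <- character(0)
  ring <- list()
  for (idx in seq_along(toks)) {
    tk <- toks[idx]
    m <- regmatches(tk, regexec("^(.*?)\\s*\\((\\d+)\\)$", tk))[[1]]
    if (length(m) == 3) {
      ring[[m[3]]] <- c(ring[[m[3]]], idx)
      tk <- m[2]
    }
    code <- .resolve_code(tk, registry)
    if (is.null(code)) stop("unknown monomer token: '", tk, "'")
    labels <- c(labels, tk)
    codes <- c(codes, code)
  }

  if (isTRUE(head_tail)) {
    n_cap <- "none"; c_cap <- "none"
  } else {
    if (is.null(n_cap)) {
      first <- registry[[codes[1]]]$composition
      n_cap <- if ("N" %in% names(first)) "H" else "none"
    }
    if (is.null(c_cap)) c_cap <- "OH"
  }

  disulfides <- data.frame(i = integer(0), j = integer(0))
  for (lab in names(ring)) {
    idxs <- ring[[lab]]
    if (length(idxs) != 2)
      stop("ring label (", lab, ") appears ", length(idxs), " time(s); must pair")
    for (ii in idxs) {
      if (!isTRUE(registry[[codes[ii]]]$thiol))
        stop("disulfide endpoint ", labels[ii], " is not a thiol-bearing monomer")
    }
    disulfides <- rbind(disulfides, data.frame(i = idxs[1], j = idxs[2]))
  }

  structure(
    list(
      registry = registry,
      codes = codes,
      labels = labels,
      chains = data.frame(start = 1L, end = length(codes),
                          n_cap = n_cap, c_cap = c_cap,
                          head_tail = isTRUE(head_tail),
                          stringsAsFactors = FALSE),
      disulfides = disulfides,
      mods = list(),
      expanded = rep(FALSE, length(codes)),
      graph = NULL
    ),
    class = "polymer"
  )
}

#' Assemble a multi-chain polymer
#'
#' Joins two parsed chains into a single molecule connected by disulfide
#' bridges, as in two-chain peptide hormones.
#'
#' @param a,b `polymer` objects sharing a registry (single chain each).
#' @param bridges A two-column matrix/data.frame of (position in `a`,
#'   position in `b`) disulfide pairs; positions are 1-based monomer indices
#'   within each chain.
#' @return A `polymer` with two chains and the combined linkages.
#' @export
combine_chains <- function(a, b, bridges) {
  stopifnot(nrow(a$chains) == 1, nrow(b$chains) == 1)
  bridges <- as.matrix(bridges)
  off <- length(a$codes)
  chains <- rbind(a$chains,
                  transform(b$chains, start = start + off, end = end + off))
  ds <- rbind(a$disulfides,
              transform(b$disulfides, i = i + off, j = j + off),
              data.frame(i = as.integer(bridges[, 1]),
                         j = as.integer(bridges[, 2]) + off))
  for (r in seq_len(nrow(ds))) {
    for (p in c(ds$i[r], ds$j[r])) {
      code <- c(a$codes, b$codes)[p]
      if (!isTRUE(a$registry[[code]]$thiol))
        stop("disulfide endpoint at position ", p, " is not thiol-bearing")
    }
  }
  structure(
    list(registry = a$registry,
         codes = c(a$codes, b$codes),
         labels = c(a$labels, b$labels),
         chains = chains,
         disulfides = ds,
         mods = c(a$mods, b$mods),
         expanded = c(a$expanded, b$expanded),
         graph = NULL),
    class = "polymer"
  )
}

#' @export
print.polymer <- function(x, ...) {
  cat("<polymer> ", length(x$codes), " monomers in ", nrow(x$chains),
      " chain(s), ", if (is_cyclic(x)) "cyclic" else "linear",
      "; formula ", format_formula(polymer_formula(x)), "\n", sep = "")
  cat("  ", format_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Is a polymer structure cyclic?
#'
#' A structure is cyclic iff it carries any non-backbone linkage (disulfide)
#' or a head-to-tail closure.
#' @param structure A `polymer`.
#' @export
is_cyclic <- function(structure) {
  nrow(structure$disulfides) > 0 || any(structure$chains$head_tail)
}

#' Format a polymer back into dash notation
#' @param structure A `polymer`.
#' @return The sequence string; multiple chains are joined with `" | "`.
#' @export
format_sequence <- function(structure) {
  labs <- structure$labels
  if (nrow(structure$disulfides) > 0) {
    for (r in seq_len(nrow(structure$disulfides))) {
      for (ii in c(structure$disulfides$i[r], structure$disulfides$j[r]))
        labs[ii] <- paste0(labs[ii], " (", r, ")")
    }
  }
  parts <- character(0)
  for (ci in seq_len(nrow(structure$chains))) {
    ch <- structure$chains[ci, ]
    left <- if (ch$n_cap %in% c("H", "Ac")) paste0(ch$n_cap, "-") else ""
    right <- if (!ch$c_cap %in% c("none")) paste0("-", ch$c_cap) else ""
    body <- paste(labs[ch$start:ch$end], collapse = "-")
    parts <- c(parts, paste0(left, body, right,
                             if (ch$head_tail) " (head-to-tail cyclic)" else ""))
  }
  paste(parts, collapse = " | ")
}

#' Elemental composition of a polymer structure
#'
#' Sum of residue compositions plus both terminal-group deltas of every
#' chain, minus H2 per disulfide, plus the net delta of any in-place
#' modification records. For a linear peptide with free termini this is the
#' classic sum(residues) + H2O; a head-to-tail cyclic chain contributes no
#' terminal groups (one water less); a hydrolytic ring opening splits a
#' chain and therefore gains exactly one water through the two new termini.
#'
#' @param structure A `polymer`.
#' @return An `elemcomp`.
#' @export
polymer_formula <- function(structure) {
  caps <- .cap_comps()
  total <- comp()
  for (code in structure$codes) {
    m <- structure$registry[[code]]
    if (is.null(m)) stop("monomer missing from registry: ", code)
    total <- total + m$composition
  }
  for (ci in seq_len(nrow(structure$chains))) {
    total <- total + caps[[structure$chains$n_cap[ci]]] +
      caps[[structure$chains$c_cap[ci]]]
  }
  nd <- nrow(structure$disulfides)
  if (nd > 0) total <- total - comp_times(comp(H = 2), nd)
  for (mod in structure$mods) {
    if (length(mod$gain)) total <- total + mod$gain
    if (length(mod$loss)) total <- total - mod$loss
  }
  total
}

# Backbone bonds of a structure: data.frame(from, to, chain); head-to-tail
# closures contribute the end->start bond.
.backbone_bonds <- function(structure) {
  out <- data.frame(from = integer(0), to = integer(0), chain = integer(0))
  for (ci in seq_len(nrow(structure$chains))) {
    ch <- structure$chains[ci, ]
    if (ch$end > ch$start) {
      out <- rbind(out, data.frame(from = ch$start:(ch$end - 1L),
                                   to = (ch$start + 1L):ch$end, chain = ci))
    }
    if (ch$head_tail)
      out <- rbind(out, data.frame(from = ch$end, to = ch$start, chain = ci))
  }
  out
}

#' Expand monomers to atom level
#'
#' Builds the atom graph for the selected monomers from their registry
#' templates, producing a hybrid structure: expanded monomers carry atoms
#' and bonds, the rest stay at monomer level. Consecutive expanded monomers
#' are joined by a backbone bond between the carbonyl carbon and the next
#' backbone nitrogen; terminal hydrogens/hydroxyls are materialized when the
#' expansion includes the corresponding end of a chain.
#'
#' @param structure A `polymer`.
#' @param indices Integer monomer indices to expand (1-based). Empty vector
#'   returns the structure unchanged.
#' @return The structure with `expanded` flags set and a `graph` element
#'   (list with `atoms` and `bonds` data.frames).
#' @export
expand <- function(structure, indices = integer(0)) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0) return(structure)
  if (any(indices < 1 | indices > length(structure$codes)))
    stop("expansion index out of range")
  atoms <- data.frame(element = character(0), monomer = integer(0))
  bonds <- data.frame(a = integer(0), b = integer(0))
  attach_n <- attach_c <- rep(NA_integer_, length(structure$codes))
  for (ii in indices) {
    tpl <- structure$registry[[structure$codes[ii]]]$template
    if (is.null(tpl))
      stop("no atom template for monomer ", structure$labels[ii])
    off <- nrow(atoms)
    atoms <- rbind(atoms, data.frame(element = tpl$atoms, monomer = ii))
    bonds <- rbind(bonds, data.frame(a = tpl$bonds[, 1] + off,
                                     b = tpl$bonds[, 2] + off))
    attach_n[ii] <- tpl$n_attach + off
    attach_c[ii] <- tpl$c_attach + off
  }
  bb <- .backbone_bonds(structure)
  for (r in seq_len(nrow(bb))) {
    if (bb$from[r] %in% indices && bb$to[r] %in% indices)
      bonds <- rbind(bonds, data.frame(a = attach_c[bb$from[r]],
                                       b = attach_n[bb$to[r]]))
  }
  caps <- .cap_comps()
  add_cap <- function(cmp, at) {
    for (el in names(cmp)) for (k in seq_len(unclass(cmp)[[el]])) {
      atoms <<- rbind(atoms, data.frame(element = el, monomer = NA_integer_))
      bonds <<- rbind(bonds, data.frame(a = at, b = nrow(atoms)))
    }
  }
  for (ci in seq_len(nrow(structure$chains))) {
    ch <- structure$chains[ci, ]
    if (ch$start %in% indices && ch$n_cap != "none" && !ch$head_tail)
      add_cap(caps[[ch$n_cap]], attach_n[ch$start])
    if (ch$end %in% indices && ch$c_cap != "none" && !ch$head_tail)
      add_cap(caps[[ch$c_cap]], attach_c[ch$end])
  }
  structure$expanded[indices] <- TRUE
  structure$graph <- list(atoms = atoms, bonds = bonds,
                          attach_n = attach_n, attach_c = attach_c)
  structure
}

#' Composition of an atom graph
#' @param graph The `graph` element of an expanded `polymer`.
#' @return An `elemcomp` counting the atoms in the graph.
#' @export
graph_composition <- function(graph) {
  tab <- table(graph$atoms$element)
  do.call(comp, as.list(tab))
}
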