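#' Assign theoretical fragments to a spectrum
#'
#' Greedy nearest-m/z assignment of fragment ions to centroids within a ppm
#' tolerance; each centroid receives at most one fragment (the closest).
#'
#' @param spectrum A `spectrum`.
#' @param fragments Output of [backbone_fragments()].
#' @param tol_ppm Tolerance in ppm.
#' @return A data.frame with one row per assigned centroid: `mz`,
#'   `intensity`, `frag_row` (row index into `fragments`), `label`, `z`,
#'   `h`, `ppm`.
#' @export
assign_fragments <- function(spectrum, fragments, tol_ppm = 10) {
  out <- data.frame(mz = numeric(0), intensity = numeric(0),
                    frag_row = integer(0), label = character(0),
                    z = integer(0), h = integer(0), ppm = numeric(0))
  if (length(spectrum$mz) == 0 || nrow(fragments) == 0) return(out)
  for (i in seq_along(spectrum$mz)) {
    m <- spectrum$mz[i]
    d <- abs(fragments$mz - m)
    j <- which.min(d)
    if (d[j] <= m * tol_ppm * 1e-6) {
      out <- rbind(out, data.frame(
        mz = m, intensity = spectrum$intensity[i], frag_row = j,
        label = fragments$label[j], z = fragments$z[j], h = fragments$h[j],
        ppm = d[j] / m * 1e6))
    }
  }
  out
}

#' Pair parent and metabolite MS2 spectra
#'
#' Finds substrate-metabolite peak pairs: non-shifted pairs at equal m/z
#' within tolerance, and shifted pairs at the parent m/z plus each candidate
#' site delta divided by each charge. Matching is greedy in descending
#' parent intensity; each metabolite centroid is used at most once per
#' status.
#'
#' @param parent_ms2,met_ms2 `spectrum` objects (non-empty).
#' @param deltas Numeric vector of candidate site mass deltas (Da); may be
#'   empty for non-shifted-only pairing.
#' @param charges Charges considered for the delta conversion.
#' @param tol_ppm Tolerance in ppm.
#' @return A data.frame of pairs: `par_mz`, `par_int`, `met_mz`, `met_int`,
#'   `status` (`"non-shifted"`/`"shifted"`), `delta`, `z`.
#' @export
pair_spectra <- function(parent_ms2, met_ms2, deltas = numeric(0),
                         charges = 1, tol_ppm = 10) {
  stopifnot(length(parent_ms2$mz) > 0, length(met_ms2$mz) > 0)
  out <- data.frame(par_mz = numeric(0), par_int = numeric(0),
                    met_mz = numeric(0), met_int = numeric(0),
                    status = character(0), delta = numeric(0), z = integer(0))
  ord <- order(parent_ms2$intensity, decreasing = TRUE)
  used_ns <- logical(length(met_ms2$mz))
  used_sh <- logical(length(met_ms2$mz))
  for (i in ord) {
    pm <- parent_ms2$mz[i]
    tol <- pm * tol_ppm * 1e-6
    # non-shifted
    cand <- which(!used_ns & abs(met_ms2$mz - pm) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(met_ms2$mz[cand] - pm))]
      used_ns[j] <- TRUE
      out <- rbind(out, data.frame(par_mz = pm, par_int = parent_ms2$intensity[i],
                                   met_mz = met_ms2$mz[j],
                                   met_int = met_ms2$intensity[j],
                                   status = "non-shifted", delta = 0, z = NA_integer_))
    }
    # shifted
    for (d in deltas) for (z in charges) {
      if (abs(d) < 1e-9) next
      target <- pm + d / z
      cand <- which(!used_sh & abs(met_ms2$mz - target) <= tol)
      if (length(cand)) {
        j <- cand[which.min(abs(met_ms2$mz[cand] - target))]
        used_sh[j] <- TRUE
        out <- rbind(out, data.frame(par_mz = pm, par_int = parent_ms2$intensity[i],
                                     met_mz = met_ms2$mz[j],
                                     met_int = met_ms2$intensity[j],
                                     status = "shifted", delta = d, z = z))
      }
    }
  }
  out
}

#' Classify substrate-metabolite pairs into matches and mismatches
#'
#' For every parent centroid with an assigned fragment and at least one
#' pair, the expected metabolite-side behaviour is predicted from the
#' fragment's covered monomer set ([map_fragment_to_metabolite()]): a
#' fragment away from all modification sites should pair non-shifted; a
#' fragment covering modified sites should pair shifted by the site delta.
#' Agreement yields a match, contradiction a mismatch; when both a shifted
#' and a non-shifted pair exist for one centroid the interpretation
#' consistent with the prediction wins. Parent centroids without fragment
#' assignment contribute nothing (black peaks).
#'
#' @param pairs Output of [pair_spectra()].
#' @param frag_assign Output of [assign_fragments()] on the parent
#'   spectrum.
#' @param fragments The fragment table `frag_assign` refers to (for the
#'   covered sets).
#' @param candidate The `metab_candidate` under evaluation.
#' @param tol Absolute m/z agreement tolerance for the shift delta.
#' @return A data.frame of records: `class` (`"match"`/`"mismatch"`),
#'   `intensity` (metabolite-side), `par_mz`, `met_mz`, `label`.
#' @export
classify_evidence <- function(pairs, frag_assign, fragments, candidate,
                              tol = 0.02) {
  out <- data.frame(class = character(0), intensity = numeric(0),
                    par_mz = numeric(0), met_mz = numeric(0),
                    label = character(0))
  if (nrow(pairs) == 0 || nrow(frag_assign) == 0) return(out)
  for (r in seq_len(nrow(frag_assign))) {
    pm <- frag_assign$mz[r]
    covered <- fragments$covered[[frag_assign$frag_row[r]]]
    z <- frag_assign$z[r]
    expect <- map_fragment_to_metabolite(covered, candidate, z)
    prs <- pairs[abs(pairs$par_mz - pm) < 1e-9, , drop = FALSE]
    if (nrow(prs) == 0 || expect$status == "absent") next
    ns <- prs[prs$status == "non-shifted", , drop = FALSE]
    sh <- prs[prs$status == "shifted", , drop = FALSE]
    if (expect$status == "non-shifted") {
      if (nrow(ns)) {
        rec <- c("match", ns$met_int[1], pm, ns$met_mz[1])
      } else {
        rec <- c("mismatch", sh$met_int[1], pm, sh$met_mz[1])
      }
    } else {  # expected shifted by expect$dmz
      good <- sh[abs(sh$delta / ifelse(is.na(sh$z), 1, sh$z) - expect$dmz) <= tol, ,
                 drop = FALSE]
      if (nrow(good)) {
        rec <- c("match", good$met_int[1], pm, good$met_mz[1])
      } else if (nrow(ns)) {
        rec <- c("mismatch", ns$met_int[1], pm, ns$met_mz[1])
      } else if (nrow(sh)) {
        rec <- c("mismatch", sh$met_int[1], pm, sh$met_mz[1])
      } else next
    }
    out <- rbind(out, data.frame(class = rec[1],
                                 intensity = as.numeric(rec[2]),
                                 par_mz = as.numeric(rec[3]),
                                 met_mz = as.numeric(rec[4]),
                                 label = frag_assign$label[r]))
  }
  out
}

#' Metabolite-side fragment evidence (metmatches)
#'
#' Metabolite spectrum centroids not already consumed by substrate pairing
#' that are explained by direct fragmentation of the metabolite structure
#' become metmatches. This is the decisive evidence channel for ring-opened
#' cyclic peptides, whose linearized backbone produces fragments with no
#' parent counterpart.
#'
#' @param met_fragments [backbone_fragments()] of the candidate structure
#'   (may have zero rows).
#' @param met_ms2 The metabolite `spectrum`.
#' @param used_met_mz m/z values already used in substrate-metabolite pairs.
#' @param tol_ppm Tolerance in ppm.
#' @return A data.frame of records with `class = "metmatch"`.
#' @export
metmatch_evidence <- function(met_fragments, met_ms2, used_met_mz = numeric(0),
                              tol_ppm = 10) {
  out <- data.frame(class = character(0), intensity = numeric(0),
                    par_mz = numeric(0), met_mz = numeric(0),
                    label = character(0))
  if (nrow(met_fragments) == 0 || length(met_ms2$mz) == 0) return(out)
  for (i in seq_along(met_ms2$mz)) {
    m <- met_ms2$mz[i]
    if (length(used_met_mz) && any(abs(used_met_mz - m) <= m * 1e-6 * tol_ppm))
      next
    d <- abs(met_fragments$mz - m)
    j <- which.min(d)
    if (d[j] <= m * tol_ppm * 1e-6) {
      out <- rbind(out, data.frame(class = "metmatch",
                                   intensity = met_ms2$intensity[i],
                                   par_mz = NA_real_, met_mz = m,
                                   label = met_fragments$label[j]))
    }
  }
  out
}

#' Score classified evidence
#'
#' The score is the summed metabolite-side intensity of the matching peaks,
#' plus the summed intensity of the metmatching peaks, minus the summed
#' intensity of the mismatching peaks. Centroid annotations follow the
#' conventional colors: match = red, mismatch = cyan, metmatch = coral;
#' unassigned peaks are black and contribute nothing.
#'
#' @param records A data.frame of match records (rbind of
#'   [classify_evidence()] and [metmatch_evidence()] output; zero rows
#'   allowed).
#' @return A list of class `"score_result"`: `score`, `n_match`,
#'   `n_mismatch`, `n_metmatch`, and the annotated `records` (with an
#'   `annotation` column).
#' @export
score_evidence <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(structure(list(score = 0, n_match = 0L, n_mismatch = 0L,
                          n_metmatch = 0L,
                          records = data.frame(class = character(0),
                                               intensity = numeric(0),
                                               annotation = character(0))),
                     class = "score_result"))
  }
  stopifnot(all(records$class %in% c("match", "mismatch", "metmatch")))
  sgn <- ifelse(records$class == "mismatch", -1, 1)
  records$annotation <- c(match = "red", mismatch = "cyan",
                          metmatch = "coral")[records$class]
  structure(list(
    score = sum(sgn * records$intensity),
    n_match = sum(records$class == "match"),
    n_mismatch = sum(records$class == "mismatch"),
    n_metmatch = sum(records$class == "metmatch"),
    records = records
  ), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("<score> ", round(x$score, 1), " (", x$n_match, " match / ",
      x$n_mismatch, " mismatch / ", x$n_metmatch, " metmatch)\n", sep = "")
  invisible(x)
}

#' Rank scored candidates
#'
#' Orders candidates by descending score; ties break toward fewer applied
#' rules (lower generation), then lower absolute ppm error. The top
#' candidate is flagged auto-selected.
#'
#' @param scores Numeric vector of scores, one per candidate.
#' @param generations Generations (applied-rule counts) per candidate.
#' @param ppm Observed ppm errors per candidate (NA allowed).
#' @return A data.frame ordered by rank with columns `candidate` (original
#'   index), `score`, `generation`, `ppm`, `auto_selected`.
#' @export
rank_candidates <- function(scores, generations = rep(1L, length(scores)),
                            ppm = rep(NA_real_, length(scores))) {
  stopifnot(length(scores) >= 1)
  ppm_abs <- ifelse(is.na(ppm), Inf, abs(ppm))
  ord <- order(-scores, generations, ppm_abs)
  out <- data.frame(candidate = ord, score = scores[ord],
                    generation = generations[ord], ppm = ppm[ord],
                    auto_selected = FALSE)
  out$auto_selected[1] <- TRUE
  out
}
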