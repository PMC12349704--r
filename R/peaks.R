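#' Construct a centroided mass spectrum
#'
#' @param mz,intensity Equal-length numeric vectors; centroids are stored
#'   sorted by m/z and must have non-negative intensities.
#' @param rt Retention time in minutes.
#' @param level MS level (1 or 2).
#' @param precursor Precursor m/z for MS2 spectra.
#' @return A `spectrum` object.
#' @export
new_spectrum <- function(mz, intensity, rt = NA_real_, level = 1L,
                         precursor = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative intensities")
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o], rt = rt,
                 level = as.integer(level), precursor = precursor),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> MS", x$level, ", rt ", round(x$rt, 3), " min, ",
      length(x$mz), " centroids\n", sep = "")
  invisible(x)
}

#' Construct an LC-MS run
#'
#' @param spectra List of `spectrum` objects, in retention-time order.
#' @param role `"blank"`, `"substrate"` or `"incubation"`.
#' @param time Incubation time point (same units across the experiment).
#' @param matrix Optional matrix annotation.
#' @return An `msrun` object.
#' @export
new_run <- function(spectra, role = c("incubation", "blank", "substrate"),
                    time = NA_real_, matrix = NA_character_) {
  role <- match.arg(role)
  rts <- vapply(spectra, function(s) s$rt, 0)
  if (is.unsorted(rts, na.rm = TRUE)) stop("spectra must be in rt order")
  structure(list(spectra = spectra, role = role, time = time, matrix = matrix),
            class = "msrun")
}

#' @export
print.msrun <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$level, 0L)
  cat("<msrun> role ", x$role, ", ", sum(lv == 1), " MS1 + ", sum(lv == 2),
      " MS2 scans", if (!is.na(x$time)) paste0(", t = ", x$time), "\n", sep = "")
  invisible(x)
}

#' Spectral noise level by slope change
#'
#' Sorts the centroid intensities in descending order and locates the elbow
#' of the intensity-rank curve as the rank with the largest change in slope
#' (discrete second difference). The noise threshold is the midpoint between
#' that rank's intensity and the previous one, which for a two-population
#' spectrum falls between the signal and noise intensity regimes. Spectra
#' with fewer than three centroids, or with no elbow (all intensities
#' equal), get a threshold of 0.
#'
#' @param spectrum A `spectrum`.
#' @return Intensity threshold (scalar).
#' @export
estimate_noise <- function(spectrum) {
  y <- sort(spectrum$intensity, decreasing = TRUE)
  n <- length(y)
  if (n < 3) return(0)
  d2 <- y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]  # second difference at rank i+1
  if (max(d2) <= 1e-12 * max(y)) return(0)
  r <- which.max(d2) + 1L
  (y[r - 1] + y[r]) / 2
}

#' Extracted ion chromatogram
#'
#' Sums, per MS1 scan, the intensities of centroids within `tol_ppm` of the
#' target m/z; scans without matching centroids contribute zero.
#'
#' @param run An `msrun`.
#' @param mz Target m/z.
#' @param tol_ppm Mass tolerance in ppm.
#' @return A data.frame of class `"eic"` with columns `rt` and `intensity`;
#'   the target and tolerance are kept as attributes.
#' @export
build_eic <- function(run, mz, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  ms1 <- Filter(function(s) s$level == 1L, run$spectra)
  if (length(ms1) == 0) stop("run contains no MS1 scans")
  tol <- mz * tol_ppm * 1e-6
  rt <- vapply(ms1, function(s) s$rt, 0)
  intensity <- vapply(ms1, function(s) {
    sel <- abs(s$mz - mz) <= tol
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, 0)
  out <- data.frame(rt = rt, intensity = intensity)
  attr(out, "mz") <- mz
  attr(out, "tol_ppm") <- tol_ppm
  class(out) <- c("eic", "data.frame")
  out
}

.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Detect chromatographic peaks in an EIC
#'
#' Local maxima with apex intensity at least `k` times the noise level are
#' reported as peaks; peak boundaries extend to the surrounding local
#' minima or to the baseline crossing, and overlapping peaks are split at
#' the valley between their apexes. Areas are computed by trapezoidal
#' integration (intensity x minutes).
#'
#' @param eic An `eic`.
#' @param noise Noise level (intensity units).
#' @param k Apex-to-noise multiplier (default 3).
#' @param min_points Minimum number of scans a peak must span.
#' @return A data.frame with one row per peak: `rt_start`, `rt_apex`,
#'   `rt_end`, `apex_intensity`, `area`, plus the scan index range
#'   (`i_start`, `i_apex`, `i_end`).
#' @export
detect_peaks <- function(eic, noise = 0, k = 3, min_points = 3) {
  y <- eic$intensity
  rt <- eic$rt
  n <- length(y)
  empty <- data.frame(rt_start = numeric(0), rt_apex = numeric(0),
                      rt_end = numeric(0), apex_intensity = numeric(0),
                      area = numeric(0), i_start = integer(0),
                      i_apex = integer(0), i_end = integer(0))
  if (n == 0 || all(y <= 0)) return(empty)
  thr <- k * noise
  base <- max(noise, 0)
  above <- y > base
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- empty
  for (ri in which(runs$values)) {
    i0 <- starts[ri]; i1 <- ends[ri]
    if (i1 - i0 + 1 < min_points) next
    seg <- y[i0:i1]
    # local maxima inside the segment that clear the detection threshold
    locmax <- which(diff(sign(diff(c(-Inf, seg, -Inf)))) == -2)
    locmax <- locmax[seg[locmax] >= thr & seg[locmax] > 0]
    if (length(locmax) == 0) next
    # split at the deepest valley between consecutive apexes when the
    # valley drops below half of the smaller apex
    bounds <- i0 - 1L
    keep_apex <- locmax[1]
    apexes <- c()
    for (j in seq_along(locmax)[-1]) {
      lo <- locmax[j - 1]; hi <- locmax[j]
      valley <- which.min(seg[lo:hi]) + lo - 1L
      if (seg[valley] < 0.5 * min(seg[lo], seg[hi])) {
        apexes <- c(apexes, keep_apex)
        bounds <- c(bounds, valley + i0 - 1L)
        keep_apex <- hi
      } else if (seg[hi] > seg[keep_apex]) keep_apex <- hi
    }
    apexes <- c(apexes, keep_apex)
    bounds <- c(bounds, i1)
    for (j in seq_along(apexes)) {
      a <- bounds[j] + ifelse(j == 1, 1L, 0L)
      b <- bounds[j + 1]
      ia <- apexes[j] + i0 - 1L
      if (b - a + 1 < min_points) next
      out <- rbind(out, data.frame(
        rt_start = rt[a], rt_apex = rt[ia], rt_end = rt[b],
        apex_intensity = y[ia], area = .trapz(rt[a:b], y[a:b]),
        i_start = a, i_apex = ia, i_end = b))
    }
  }
  out[order(out$rt_apex), , drop = FALSE]
}

#' Hodgkin similarity index
#'
#' `2 * sum(x*y) / (sum(x^2) + sum(y^2))`, a shape-and-magnitude similarity
#' in `[0, 1]` for non-negative profiles that equals 1 only for identical
#' vectors.
#'
#' @param x,y Equal-length intensity profiles, not both all-zero.
#' @return Similarity in `[0, 1]` (can be negative for signed inputs).
#' @export
hodgkin_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  den <- sum(x^2) + sum(y^2)
  if (den == 0) stop("both profiles are all-zero")
  2 * sum(x * y) / den
}

#' Check a sample peak against the blank run
#'
#' Builds the blank EIC at the peak's m/z, aligns it over the peak's
#' retention window by the shift maximizing the Hodgkin index, and calls
#' the shapes similar when both the Hodgkin and Pearson indexes clear their
#' thresholds. The peak is excluded when it is similar to the blank and the
#' blank area matches or exceeds the sample area; the Negative Control Area
#' Ratio (NCAR, sample/blank) is reported either way, capped when the blank
#' shows no signal.
#'
#' @param peak One row of [detect_peaks()] output.
#' @param eic The sample `eic` the peak was found in.
#' @param blank_run The blank `msrun`.
#' @param h_min,r_min Hodgkin and Pearson similarity thresholds.
#' @param max_shift Maximum alignment shift, in scans.
#' @param ncar_cap NCAR value reported when the blank area is zero.
#' @return A list: `keep`, `ncar`, `hodgkin`, `pearson`, `blank_area`.
#' @export
blank_exclusion <- function(peak, eic, blank_run, h_min = 0.9, r_min = 0.8,
                            max_shift = 5, ncar_cap = 1e6) {
  mz <- attr(eic, "mz")
  blank_eic <- build_eic(blank_run, mz, attr(eic, "tol_ppm"))
  idx <- peak$i_start:peak$i_end
  seg <- eic$intensity[idx]
  seg_rt <- eic$rt[idx]
  dt <- if (length(eic$rt) > 1) stats::median(diff(eic$rt)) else 0.01
  best <- list(h = -Inf, p = -Inf, blank = rep(0, length(seg)))
  for (sh in -max_shift:max_shift) {
    bl <- stats::approx(blank_eic$rt, blank_eic$intensity,
                        xout = seg_rt + sh * dt, rule = 2)$y
    if (all(bl == 0) && all(seg == 0)) next
    h <- if (all(bl == 0)) 0 else hodgkin_index(seg, bl)
    if (h > best$h) {
      p <- if (stats::sd(bl) == 0 || stats::sd(seg) == 0) 0
           else stats::cor(seg, bl)
      best <- list(h = h, p = p, blank = bl)
    }
  }
  blank_area <- .trapz(seg_rt, best$blank)
  ncar <- if (blank_area <= 0) ncar_cap else peak$area / blank_area
  similar <- best$h >= h_min && best$p >= r_min
  drop <- similar && blank_area >= peak$area
  list(keep = !drop, ncar = min(ncar, ncar_cap),
       hodgkin = max(best$h, 0), pearson = max(best$p, 0),
       blank_area = blank_area)
}

#' Filtered spectrum over a chromatographic peak
#'
#' Merges the centroids of all MS1 scans inside the peak's retention
#' window, clustering m/z values within the ppm tolerance
#' (intensity-weighted mean m/z, summed intensity), and keeps only clusters
#' whose per-scan intensity profile correlates with the peak's EIC shape
#' (Pearson at least `c_min`). With fewer than two in-peak scans no
#' correlation filter can be applied; the merged spectrum is returned
#' flagged as unfiltered.
#'
#' @param run The sample `msrun`.
#' @param peak One row of [detect_peaks()] output.
#' @param eic The `eic` the peak was detected in (provides the shape).
#' @param tol_ppm Clustering tolerance in ppm.
#' @param c_min Minimum shape correlation for a cluster to be kept.
#' @return A `spectrum` (rt = apex rt) with attribute `"filtered"`.
#' @export
filtered_spectrum <- function(run, peak, eic, tol_ppm = 10, c_min = 0.7) {
  ms1 <- Filter(function(s) s$level == 1L, run$spectra)
  rts <- vapply(ms1, function(s) s$rt, 0)
  inpeak <- which(rts >= peak$rt_start & rts <= peak$rt_end)
  if (length(inpeak) == 0)
    return(structure(new_spectrum(numeric(0), numeric(0), rt = peak$rt_apex),
                     filtered = FALSE))
  allmz <- unlist(lapply(inpeak, function(i) ms1[[i]]$mz))
  allint <- unlist(lapply(inpeak, function(i) ms1[[i]]$intensity))
  allscan <- rep(seq_along(inpeak),
                 vapply(inpeak, function(i) length(ms1[[i]]$mz), 0L))
  if (length(allmz) == 0)
    return(structure(new_spectrum(numeric(0), numeric(0), rt = peak$rt_apex),
                     filtered = FALSE))
  o <- order(allmz)
  allmz <- allmz[o]; allint <- allint[o]; allscan <- allscan[o]
  gap <- c(FALSE, diff(allmz) > allmz[-length(allmz)] * tol_ppm * 1e-6)
  cluster <- cumsum(gap) + 1L
  shape <- eic$intensity[peak$i_start:peak$i_end]
  shape <- shape[seq_along(inpeak)]  # guard length mismatch
  mzs <- ints <- numeric(0)
  kept <- logical(0)
  for (cl in unique(cluster)) {
    sel <- cluster == cl
    wmz <- sum(allmz[sel] * allint[sel]) / sum(allint[sel])
    tot <- sum(allint[sel])
    if (length(inpeak) < 2) {
      ok <- TRUE
    } else {
      prof <- vapply(seq_along(inpeak), function(sc)
        sum(allint[sel][allscan[sel] == sc]), 0)
      ok <- if (stats::sd(prof) == 0 || stats::sd(shape) == 0) FALSE
            else stats::cor(prof, shape) >= c_min
    }
    mzs <- c(mzs, wmz); ints <- c(ints, tot); kept <- c(kept, ok)
  }
  filtered <- length(inpeak) >= 2
  if (filtered) { mzs <- mzs[kept]; ints <- ints[kept] }
  structure(new_spectrum(mzs, ints, rt = peak$rt_apex), filtered = filtered)
}

#' Isotope-pattern similarity
#'
#' Extracts the observed abundances at the predicted isotopologue m/z
#' positions (pattern spacing divided by the charge), normalizes observed
#' and predicted vectors to unit sum, and returns
#' `1 - 0.5 * sum(|obs - pred|)`, which lies in `[0, 1]` and equals 1 for a
#' perfect pattern match. If none of the predicted positions shows signal
#' the similarity is 0.
#'
#' @param spectrum A `spectrum` (e.g. a filtered spectrum).
#' @param pattern An `isopattern` from [isotope_pattern()].
#' @param z Charge state assumed for the envelope spacing.
#' @param tol_ppm Matching tolerance in ppm.
#' @param polarity `"+"` or `"-"`.
#' @return Similarity in `[0, 1]`.
#' @export
isotope_similarity <- function(spectrum, pattern, z, tol_ppm = 10,
                               polarity = "+") {
  stopifnot(nrow(pattern) > 0)
  pred_mz <- mz_for_charge(pattern$mass, z, polarity)
  obs <- vapply(pred_mz, function(m) {
    sel <- abs(spectrum$mz - m) <= m * tol_ppm * 1e-6
    if (any(sel)) sum(spectrum$intensity[sel]) else 0
  }, 0)
  if (sum(obs) == 0) return(0)
  obs <- obs / sum(obs)
  pred <- pattern$abundance / sum(pattern$abundance)
  1 - 0.5 * sum(abs(obs - pred))
}

#' Assign metabolite candidates to a filtered spectrum
#'
#' For every candidate and charge state, the theoretical target m/z is
#' computed from the monoisotopic (MiM) or most abundant (MaM) mass of the
#' candidate composition. A candidate matches when the target m/z is found
#' in the spectrum within tolerance and the isotope-pattern similarity at
#' that charge clears `s_min`. Each match is scored by the equal-weighted
#' composite of isotope similarity and ppm closeness; among the matches the
#' representative m/z is the highest matching m/z.
#'
#' @param fs A filtered `spectrum`.
#' @param candidates List of `metab_candidate` objects (may include the
#'   parent as a pseudo-candidate).
#' @param mode `"MiM"` or `"MaM"`.
#' @param charges Integer vector of charge states to try.
#' @param tol_ppm Mass tolerance in ppm.
#' @param s_min Minimum isotope similarity.
#' @param polarity `"+"` or `"-"`.
#' @return A data.frame with one row per matching (candidate, charge):
#'   `candidate` (index), `z`, `target_mz`, `observed_mz`, `ppm`,
#'   `isotope_sim`, `composite`; the representative m/z is attached as
#'   attribute `"representative_mz"`. Zero rows mean a red/unknown peak.
#' @export
assign_candidates <- function(fs, candidates, mode = c("MaM", "MiM"),
                              charges = 1:3, tol_ppm = 10, s_min = 0.6,
                              polarity = "+") {
  mode <- match.arg(mode)
  out <- data.frame(candidate = integer(0), z = integer(0),
                    target_mz = numeric(0), observed_mz = numeric(0),
                    ppm = numeric(0), isotope_sim = numeric(0),
                    composite = numeric(0))
  if (length(fs$mz) == 0) return(out)
  for (ci in seq_along(candidates)) {
    cmp <- candidates[[ci]]$composition
    m <- if (mode == "MiM") monoisotopic_mass(cmp) else most_abundant_mass(cmp)
    pat <- isotope_pattern(cmp)
    for (z in charges) {
      target <- mz_for_charge(m, z, polarity)
      tol <- target * tol_ppm * 1e-6
      sel <- abs(fs$mz - target) <= tol
      if (!any(sel)) next
      obs_mz <- sum(fs$mz[sel] * fs$intensity[sel]) / sum(fs$intensity[sel])
      sim <- isotope_similarity(fs, pat, z, tol_ppm, polarity)
      if (sim < s_min) next
      ppm <- (obs_mz - target) / target * 1e6
      composite <- mean(c(sim, 1 - abs(ppm) / tol_ppm))
      out <- rbind(out, data.frame(candidate = ci, z = z, target_mz = target,
                                   observed_mz = obs_mz, ppm = ppm,
                                   isotope_sim = sim, composite = composite))
    }
  }
  attr(out, "representative_mz") <-
    if (nrow(out)) max(out$observed_mz) else NA_real_
  out
}

#' Classify a peak assignment
#'
#' Maps a matched candidate to `"first-gen"`/`"higher-gen"`; otherwise
#' checks whether the representative m/z is explained by the parent mass
#' plus a configured adduct or in-source loss delta; otherwise the peak is
#' an unknown (`"red"`).
#'
#' @param assignments Output of [assign_candidates()].
#' @param candidates The candidate list the assignment indexes into.
#' @param parent_mass Neutral parent mass (for adduct explanation).
#' @param adduct_deltas Named numeric vector of neutral-mass deltas (e.g.
#'   `c("Na-H" = 21.9819)`).
#' @param charges Charges to try for the adduct explanation.
#' @param tol_ppm Tolerance in ppm.
#' @return A character classification: `"first-gen"`, `"higher-gen"`,
#'   `"adduct-or-insource"` or `"red"`.
#' @export
classify_assignment <- function(assignments, candidates, parent_mass = NA,
                                adduct_deltas = c("Na-H" = 21.981944,
                                                  "K-H" = 37.955882,
                                                  "-H2O" = -18.010565,
                                                  "-NH3" = -17.026549),
                                charges = 1:3, tol_ppm = 10) {
  if (nrow(assignments) > 0) {
    best <- assignments[which.max(assignments$composite), ]
    gen <- candidates[[best$candidate]]$generation
    return(if (gen <= 1L) "first-gen" else "higher-gen")
  }
  rep_mz <- attr(assignments, "representative_mz")
  if (!is.na(parent_mass) && !is.na(rep_mz)) {
    for (d in adduct_deltas) for (z in charges) {
      target <- mz_for_charge(parent_mass + d, z)
      if (abs(rep_mz - target) <= target * tol_ppm * 1e-6)
        return("adduct-or-insource")
    }
  }
  "red"
}
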