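#' Write a run to mzML
#'
#' Serializes an `msrun` as a centroided mzML file through the mzR/proteowizard
#' writer.
#'
#' @param run An `msrun`.
#' @param path Output path (".mzML").
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML I/O requires the mzR package")
  n <- length(run$spectra)
  pk <- vector("list", n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(run$spectra, function(s) s$level, 0L),
    polarity = rep(1L, n),
    peaksCount = vapply(run$spectra, function(s) length(s$mz), 0L),
    totIonCurrent = vapply(run$spectra, function(s) sum(s$intensity), 0),
    retentionTime = vapply(run$spectra, function(s) s$rt * 60, 0),
    basePeakMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0),
    basePeakIntensity = vapply(run$spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, 0),
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = rep(0L, n),
    precursorMZ = vapply(run$spectra, function(s)
      if (is.na(s$precursor)) 0 else s$precursor, 0),
    precursorCharge = rep(0L, n),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n))
    pk[[i]] <- cbind(mz = run$spectra[[i]]$mz,
                     intensity = run$spectra[[i]]$intensity)
  mzR::writeMSData(pk, path, header = hdr)
  invisible(path)
}

#' Read a centroided mzML run
#'
#' @param path mzML file path.
#' @param role Run role annotation (`"blank"`, `"substrate"`,
#'   `"incubation"`).
#' @param time Incubation time point.
#' @return An `msrun`.
#' @export
read_mzml <- function(path, role = "incubation", time = NA_real_) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML I/O requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- mzR::peaks(h, i)
    prec <- hdr$precursorMZ[i]
    new_spectrum(p[, 1], p[, 2], rt = hdr$retentionTime[i] / 60,
                 level = hdr$msLevel[i],
                 precursor = if (!is.na(prec) && prec > 0) prec else NA_real_)
  })
  new_run(spectra, role = role, time = time)
}
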