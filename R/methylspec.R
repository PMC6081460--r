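# Expected mass ladders for K36 methylation states and MALDI spectrum
# readout of methylation-state composition.

# monoisotopic mass of one CH2 (methyl increment), Da
METHYL_DELTA_DA <- 14.015650

#' Expected mass ladder of a methylated peptide
#'
#' The me0..me(n-1) series of expected singly-charged m/z values: each methyl
#' group adds one CH2, 14.015650 Da monoisotopic. The peptide's me0 mass is a
#' required input (peptide sequences vary; no base mass is hard-coded).
#'
#' @param base_mz Monoisotopic m/z of the unmethylated (me0) species, Da.
#' @param n_states Number of states, me0 upwards (default 4: me0..me3).
#' @param delta_methyl Mass increment per methyl group (default monoisotopic
#'   CH2).
#' @return A `MethylSeries`: list with `base_mz`, `delta_methyl`, `states`
#'   (numeric, strictly increasing), `labels`.
#' @export
methyl_mass_series <- function(base_mz, n_states = 4L,
                               delta_methyl = METHYL_DELTA_DA) {
  if (!is.numeric(base_mz) || length(base_mz) != 1L || base_mz <= 0)
    stop("base_mz must be a single positive mass", call. = FALSE)
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  k <- seq_len(n_states) - 1L
  structure(list(base_mz = base_mz, delta_methyl = delta_methyl,
                 states = base_mz + k * delta_methyl,
                 labels = paste0("me", k)),
            class = "MethylSeries")
}

#' Construct a spectrum
#'
#' @param mz Strictly increasing m/z values (Da).
#' @param intensity Non-negative intensities, same length.
#' @return A `Spectrum` list.
#' @export
spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ", call. = FALSE)
  if (length(mz) < 3L) stop("spectrum too short", call. = FALSE)
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative",
                               call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "Spectrum")
}

#' Read a two-column (m/z, intensity) CSV spectrum
#'
#' @param path CSV path; a header line is tolerated.
#' @return A `Spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9.+-]", first)
  df <- utils::read.csv(path, header = has_header)
  spectrum(df[[1]], df[[2]])
}

#' Quantify methylation-state composition from a spectrum
#'
#' Peak picking: local maxima above a noise floor of
#' `median(intensity) + 3 * mad(intensity)`. For each expected state mass the
#' nearest peak within `tolerance_ppm` is matched; its apex intensity becomes
#' the state's signal, and signals are normalized to relative abundances
#' summing to 1. Unmatched states get 0; if no state matches, an all-zero
#' profile is returned with `no_peaks = TRUE`.
#'
#' @param spec A `Spectrum`.
#' @param series A [methyl_mass_series()].
#' @param tolerance_ppm Mass tolerance in ppm (default 200, externally
#'   calibrated reflector MALDI).
#' @return A `MethylProfile`: list with `abundance` (named, sums to 1 when
#'   any state matched), `matched_mz`, `mass_error_ppm`, `intensity`,
#'   `no_peaks`.
#' @export
assign_methyl_states <- function(spec, series, tolerance_ppm = 200) {
  stopifnot(inherits(spec, "Spectrum"), inherits(series, "MethylSeries"))
  int <- spec$intensity
  n <- length(int)
  floor_ <- median(int) + 3 * mad(int)
  is_peak <- c(FALSE, int[2:(n - 1)] > int[1:(n - 2)] &
                 int[2:(n - 1)] >= int[3:n], FALSE) & int > floor_
  pk_mz <- spec$mz[is_peak]
  pk_int <- int[is_peak]
  k <- length(series$states)
  matched_mz <- rep(NA_real_, k)
  err_ppm <- rep(NA_real_, k)
  sig <- numeric(k)
  for (i in seq_len(k)) {
    target <- series$states[i]
    if (length(pk_mz) == 0L) next
    d <- abs(pk_mz - target)
    j <- which.min(d)
    if (d[j] / target * 1e6 <= tolerance_ppm) {
      matched_mz[i] <- pk_mz[j]
      err_ppm[i] <- (pk_mz[j] - target) / target * 1e6
      sig[i] <- pk_int[j]
    }
  }
  no_peaks <- sum(sig) == 0
  abundance <- if (no_peaks) sig else sig / sum(sig)
  structure(list(abundance = setNames(abundance, series$labels),
                 matched_mz = setNames(matched_mz, series$labels),
                 mass_error_ppm = setNames(err_ppm, series$labels),
                 intensity = setNames(sig, series$labels),
                 no_peaks = no_peaks),
            class = "MethylProfile")
}

#' @export
print.MethylProfile <- function(x, ...) {
  cat("MethylProfile\n")
  for (nm in names(x$abundance))
    cat(sprintf("  %-4s abundance %.3f  (peak %s)\n", nm, x$abundance[[nm]],
                ifelse(is.na(x$matched_mz[[nm]]), "unmatched",
                       sprintf("%.4f Da, %+.1f ppm", x$matched_mz[[nm]],
                               x$mass_error_ppm[[nm]]))))
  if (x$no_peaks) cat("  [no peaks matched]\n")
  invisible(x)
}
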