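#' Segmented multichannel recordings
#'
#' A recording split into `L` equal-length segments per channel, e.g. the
#' 1-second epochs time-locked to each of `L` repeated stimuli in an
#' event-related design. Coherence is estimated by averaging cross- and
#' auto-spectra over the segments, and the significance threshold
#' [significance_threshold()] is calibrated to that same `L`.
#'
#' @param data numeric array `channels x segments x samples`, or a matrix
#'   `channels x (L * T)` together with `L`.
#' @param labels channel labels (matching an electrode layout).
#' @param fs sampling rate in Hz.
#' @param L segment count (required when `data` is a matrix).
#' @return An object of class `segmented_recording`: list with `labels`,
#'   `fs`, `L`, `T` (samples per segment) and `data` (3D array).
#' @export
segmented_recording <- function(data, labels, fs, L = NULL) {
  labels <- as.character(labels)
  if (is.matrix(data)) {
    if (is.null(L)) stop("L is required when data is a channels x samples matrix")
    if (ncol(data) %% L != 0) stop("sample count is not a multiple of L")
    Tlen <- ncol(data) %/% L
    arr <- array(0, dim = c(nrow(data), L, Tlen))
    for (s in seq_len(L)) {
      arr[, s, ] <- data[, ((s - 1L) * Tlen + 1L):(s * Tlen), drop = FALSE]
    }
    data <- arr
  }
  if (length(dim(data)) != 3L) stop("data must be channels x segments x samples")
  if (dim(data)[1] != length(labels)) stop("one label per channel required")
  if (dim(data)[2] < 2L) stop("at least L = 2 segments are required")
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  structure(list(labels = labels, fs = fs, L = dim(data)[2], T = dim(data)[3],
                 data = data),
            class = "segmented_recording")
}

#' @export
print.segmented_recording <- function(x, ...) {
  cat("<segmented_recording> ", length(x$labels), " channels, L = ", x$L,
      " segments x ", x$T, " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Magnitude-squared coherence per frequency bin
#'
#' Estimates, for every channel pair and frequency bin,
#' `c(x, y) = |f_xy|^2 / (f_xx f_yy)` where the cross- and auto-spectra
#' `f` are averages of the per-segment (cross-)periodograms. Each segment is
#' detrended by mean removal, Hann-tapered, and Fourier transformed; there is
#' no overlap between segments (they are experimentally defined epochs), so
#' the averaged-segment count equals the recording's `L` and the analytic
#' null threshold [significance_threshold()] applies. The one-sided
#' frequency axis is `k * fs / T` for `k = 1 .. floor(T/2)` (the DC bin is
#' dropped: mean removal zeroes it).
#'
#' By the Cauchy-Schwarz inequality the estimates lie in `[0, 1]` up to
#' floating-point rounding, which is clamped.
#'
#' @param recording a [segmented_recording()].
#' @return An object of class `spectral_coherence`: list with `freqs` (Hz),
#'   `coh` (array `channels x channels x bins`, zero diagonal), `labels`,
#'   `L`, `fs`.
#' @export
segment_coherence <- function(recording) {
  stopifnot(inherits(recording, "segmented_recording"))
  n <- length(recording$labels)
  L <- recording$L
  Tlen <- recording$T
  flat <- matrix(recording$data, nrow = n)
  vzero <- apply(flat, 1, stats::var) == 0
  if (any(vzero)) {
    stop("zero-variance channel(s): ",
         paste(recording$labels[vzero], collapse = ", "))
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, Tlen - 1) / Tlen) # Hann
  bins <- seq_len(Tlen %/% 2L)
  nb <- length(bins)
  S <- array(0 + 0i, dim = c(n, n, nb))
  for (s in seq_len(L)) {
    seg <- recording$data[, s, , drop = TRUE]
    if (n == 1L) seg <- matrix(seg, nrow = 1L)
    seg <- seg - rowMeans(seg)
    F <- stats::mvfft(t(seg * rep(taper, each = n)))[bins + 1L, , drop = FALSE]
    for (k in seq_len(nb)) {
      S[, , k] <- S[, , k] + outer(F[k, ], Conj(F[k, ]))
    }
  }
  S <- S / L
  coh <- array(0, dim = c(n, n, nb),
               dimnames = list(recording$labels, recording$labels, NULL))
  for (k in seq_len(nb)) {
    Sk <- matrix(S[, , k], n, n)
    auto <- Re(diag(Sk))
    ck <- Mod(Sk)^2 / outer(auto, auto)
    diag(ck) <- 0
    coh[, , k] <- pmin(pmax(ck, 0), 1)
  }
  structure(list(freqs = bins * recording$fs / Tlen, coh = coh,
                 labels = recording$labels, L = L, fs = recording$fs),
            class = "spectral_coherence")
}

#' @export
print.spectral_coherence <- function(x, ...) {
  cat("<spectral_coherence> ", length(x$labels), " channels, ",
      length(x$freqs), " bins (", format(min(x$freqs)), "-",
      format(max(x$freqs)), " Hz), L = ", x$L, "\n", sep = "")
  invisible(x)
}

#' Collapse bin coherences to a per-band coherence network
#'
#' Averages the per-bin coherences over all bins with `lo <= freq <= hi`
#' (averaging is over bin coherences, not spectra) and attaches a layout and
#' significance threshold to form a [coherence_network()].
#'
#' @param spectral a [segment_coherence()] result.
#' @param band numeric length-2, band limits in Hz (inclusive).
#' @param layout an [electrode_layout()] whose labels match the channels.
#' @param theta significance threshold; defaults to
#'   `significance_threshold(p, L)` with the recording's `L`.
#' @param p tail probability used for the default `theta`.
#' @return A [coherence_network()].
#' @export
band_coherence <- function(spectral, band, layout, theta = NULL, p = 0.01) {
  stopifnot(inherits(spectral, "spectral_coherence"),
            inherits(layout, "electrode_layout"))
  if (length(band) != 2L || band[1] > band[2]) {
    stop("band must be c(lo, hi) with lo <= hi")
  }
  sel <- which(spectral$freqs >= band[1] & spectral$freqs <= band[2])
  if (length(sel) == 0L) {
    stop("band [", band[1], ", ", band[2], "] Hz contains no frequency bin")
  }
  M <- apply(spectral$coh[, , sel, drop = FALSE], c(1, 2), mean)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  if (is.null(theta)) theta <- significance_threshold(p, spectral$L)
  if (!setequal(layout$label, spectral$labels)) {
    stop("layout labels do not match recording channels; difference: ",
         paste(c(setdiff(layout$label, spectral$labels),
                 setdiff(spectral$labels, layout$label)), collapse = ", "))
  }
  coherence_network(layout, M[layout$label, layout$label], theta)
}

#' Read / write segmented recordings
#'
#' A recording is stored as a delimited-text matrix (`channels x (L * T)`,
#' one row per channel, no header) plus a JSON manifest with fields
#' `labels`, `fs`, `L`, `T`.
#'
#' @param data_path path of the sample matrix.
#' @param manifest_path path of the JSON manifest; defaults to
#'   `data_path` with extension replaced by `.json`.
#' @return `read_recording()` returns a [segmented_recording()];
#'   `write_recording()` returns `data_path` invisibly.
#' @export
read_recording <- function(data_path, manifest_path = NULL) {
  if (is.null(manifest_path)) {
    manifest_path <- paste0(sub("\\.[^.]*$", "", data_path), ".json")
  }
  if (!file.exists(data_path)) stop("recording file not found: ", data_path)
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  M <- as.matrix(utils::read.table(data_path, header = FALSE, sep = ","))
  if (nrow(M) != length(man$labels) || ncol(M) != man$L * man$T) {
    stop("recording matrix does not match manifest dimensions")
  }
  segmented_recording(M, man$labels, man$fs, L = man$L)
}

#' @param recording a [segmented_recording()].
#' @rdname read_recording
#' @export
write_recording <- function(recording, data_path, manifest_path = NULL) {
  stopifnot(inherits(recording, "segmented_recording"))
  if (is.null(manifest_path)) {
    manifest_path <- paste0(sub("\\.[^.]*$", "", data_path), ".json")
  }
  n <- length(recording$labels)
  flat <- matrix(0, n, recording$L * recording$T)
  for (s in seq_len(recording$L)) {
    flat[, ((s - 1L) * recording$T + 1L):(s * recording$T)] <-
      recording$data[, s, ]
  }
  utils::write.table(flat, data_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(labels = recording$labels, fs = recording$fs,
                            L = recording$L, T = recording$T),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}
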