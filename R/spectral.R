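# Welch cross-spectral density estimation, band-integrated cross-power
# matrices, Fisher-discriminant-ratio band selection and feature scaling.

#' EEG frequency band
#'
#' The three clinically named bands are fixed at theta 4-7 Hz, alpha
#' 8-13 Hz and beta 14-30 Hz; `band("custom", lb, ub)` builds any other.
#'
#' @param name `"theta"`, `"alpha"`, `"beta"` or `"custom"`.
#' @param lb,ub band edges in Hz (required for `"custom"`, fixed otherwise).
#' @return a `freq_band` list with elements `name`, `lb`, `ub`.
#' @export
band <- function(name = c("theta", "alpha", "beta", "custom"),
                 lb = NULL, ub = NULL) {
  name <- match.arg(name)
  edges <- switch(name,
    theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30),
    custom = c(lb, ub))
  if (length(edges) != 2L || !all(is.finite(edges)) ||
      edges[1L] <= 0 || edges[1L] >= edges[2L]) {
    stop_rsae("band edges must satisfy 0 < lb < ub")
  }
  structure(list(name = name, lb = edges[1L], ub = edges[2L]),
            class = "freq_band")
}

#' The three named candidate bands
#' @return list of `freq_band` objects (theta, alpha, beta).
#' @export
named_bands <- function() {
  list(band("theta"), band("alpha"), band("beta"))
}

#' Welch estimation parameters
#'
#' @param subwindow_s Welch sub-window length in seconds (default 1).
#' @param overlap_frac overlap fraction between sub-windows (default 0.5).
#' @param taper `"hann"` or `"rect"`.
#' @return a plain list.
#' @export
welch_params <- function(subwindow_s = 1, overlap_frac = 0.5,
                         taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  stopifnot(subwindow_s > 0, overlap_frac >= 0, overlap_frac < 1)
  list(subwindow_s = subwindow_s, overlap_frac = overlap_frac, taper = taper)
}

taper_window <- function(kind, m) {
  switch(kind,
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L)),
    rect = rep(1, m),
    stop_rsae("unknown taper: ", kind))
}

# Tapered sub-window FFTs for every channel of an N x L matrix.
# Returns one-sided frequency grid plus a complex array
# (n_freq x n_subwindows x n_channels) already scaled so that
# mean_k(Z[f,k,i] * Conj(Z[f,k,j])) is the one-sided CSD estimate.
welch_ffts <- function(data, fs, welch) {
  m <- round(welch$subwindow_s * fs)
  L <- ncol(data)
  if (m > L) stop_rsae("Welch sub-window longer than the signal")
  hop <- max(1L, round(m * (1 - welch$overlap_frac)))
  starts <- seq(1L, L - m + 1L, by = hop)
  w <- taper_window(welch$taper, m)
  u <- sum(w^2)
  nch <- nrow(data)
  seg <- matrix(0, m, length(starts) * nch)
  col <- 0L
  for (i in seq_len(nch)) {
    for (s in starts) {
      col <- col + 1L
      x <- data[i, s:(s + m - 1L)]
      seg[, col] <- (x - mean(x)) * w
    }
  }
  Z <- mvfft(seg)
  nf <- floor(m / 2) + 1L
  freq <- (seq_len(nf) - 1L) * fs / m
  # one-sided scaling: double interior bins; 1/(fs * sum(w^2)) density norm
  sc <- sqrt(rep(2 / (fs * u), nf))
  sc[1L] <- sqrt(1 / (fs * u))
  if (m %% 2L == 0L) sc[nf] <- sqrt(1 / (fs * u))
  Z <- Z[seq_len(nf), , drop = FALSE] * sc
  dim(Z) <- c(nf, length(starts), nch)
  list(freq = freq, Z = Z, n_sub = length(starts))
}

#' Welch cross-spectral density of two signals
#'
#' Averaged over tapered, mean-removed, overlapping sub-windows.
#' `cross_spectral_density(x, x, ...)` is the (real, nonnegative) one-sided
#' power spectral density of `x`; swapping the arguments conjugates the
#' estimate.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param welch a [welch_params()] list.
#' @return list with `freq` (Hz, one-sided grid) and `csd`
#'   (complex, units uV^2/Hz).
#' @export
cross_spectral_density <- function(x, y, fs, welch = welch_params()) {
  if (length(x) != length(y)) stop_rsae("x and y must have equal length")
  wf <- welch_ffts(rbind(x, y), fs, welch)
  csd <- rowMeans(wf$Z[, , 1L, drop = FALSE] *
                    Conj(wf$Z[, , 2L, drop = FALSE]), dims = 1L)
  if (identical(x, y)) csd <- Re(csd) + 0i
  list(freq = wf$freq, csd = csd)
}

# Trapezoidal band integral; a band containing a single grid bin degrades
# to value * bandwidth.
band_integral <- function(freq, values, lb, ub) {
  idx <- which(freq >= lb & freq <= ub)
  if (length(idx) == 0L) stop_rsae("no frequency bins inside the band")
  if (length(idx) == 1L) return(values[idx] * (ub - lb))
  pracma::trapz(freq[idx], values[idx])
}

#' Band-integrated cross-power matrix of one segment
#'
#' Entry (i, j) integrates the Welch cross-spectral density of channels i
#' and j over `[lb, ub]`.  By default the magnitude `|P_ij(w)|` is
#' integrated, giving a symmetric nonnegative matrix whose diagonal holds
#' each channel's in-band power; `part = "real"` integrates the co-spectrum
#' instead.
#'
#' @param seg an `eeg_segment` or a channels x samples matrix.
#' @param band a [band()] object.
#' @param fs sampling rate in Hz.
#' @param welch a [welch_params()] list.
#' @param part `"magnitude"` (default) or `"real"`.
#' @return a `cross_power_matrix`: N x N matrix with attribute `band`.
#' @export
cross_power_matrix <- function(seg, band, fs, welch = welch_params(),
                               part = c("magnitude", "real")) {
  part <- match.arg(part)
  data <- if (inherits(seg, "eeg_segment")) seg$data else seg
  if (band$ub >= fs / 2) stop_rsae("band upper edge must be below Nyquist (fs/2)")
  wf <- welch_ffts(data, fs, welch)
  m <- cpm_from_ffts(wf, band, part)
  structure(m, band = band, class = c("cross_power_matrix", class(m)))
}

cpm_from_ffts <- function(wf, band, part = "magnitude") {
  idx <- which(wf$freq >= band$lb & wf$freq <= band$ub)
  if (length(idx) == 0L) stop_rsae("no frequency bins inside the band")
  nch <- dim(wf$Z)[3L]
  P <- array(0, dim = c(length(idx), nch, nch))
  for (q in seq_along(idx)) {
    Zf <- matrix(wf$Z[idx[q], , ], ncol = nch)   # n_sub x nch
    S <- crossprod(Conj(Zf), Zf) / wf$n_sub       # nch x nch CSD at this bin
    P[q, , ] <- if (part == "magnitude") Mod(S) else Re(S)
  }
  f <- wf$freq[idx]
  if (length(idx) == 1L) {
    m <- P[1L, , ] * (band$ub - band$lb)
  } else {
    df <- diff(f)
    wts <- c(df[1L] / 2, (df[-1L] + df[-length(df)]) / 2, df[length(df)] / 2)
    m <- apply(P * wts, c(2L, 3L), sum)
  }
  (m + t(m)) / 2                                  # enforce exact symmetry
}

#' Cross-power feature matrices for many segments and bands
#'
#' Shares one FFT pass per segment across all candidate bands, which is the
#' fast path used by [select_band()] and the experiment pipeline.
#'
#' @param segments list of `eeg_segment` objects.
#' @param bands list of [band()] objects.
#' @param fs sampling rate in Hz.
#' @param welch a [welch_params()] list.
#' @param part `"magnitude"` or `"real"`.
#' @return named list (one element per band) of n_segments x N^2 feature
#'   matrices, rows in segment order (row-major matrix flattening).
#' @export
cross_power_features <- function(segments, bands, fs, welch = welch_params(),
                                 part = "magnitude") {
  stopifnot(length(segments) > 0L, length(bands) > 0L)
  nch <- nrow(segments[[1L]]$data)
  out <- lapply(bands, function(b) matrix(0, length(segments), nch^2))
  names(out) <- vapply(bands, band_id, character(1L))
  for (s in seq_along(segments)) {
    wf <- welch_ffts(segments[[s]]$data, fs, welch)
    for (k in seq_along(bands)) {
      out[[k]][s, ] <- vectorize_cpm(cpm_from_ffts(wf, bands[[k]], part))
    }
  }
  out
}

band_id <- function(b) {
  if (b$name == "custom") sprintf("custom_%g_%g", b$lb, b$ub) else b$name
}

#' Fisher's discriminant ratio of two scalar samples
#'
#' `C = (mean_s - mean_n)^2 / (var_s + var_n)` with population (1/n)
#' variances; dimensionless, zero iff the means coincide.
#'
#' @param seizure_samples,nonseizure_samples numeric vectors (length >= 2).
#' @return nonnegative scalar.
#' @export
fdr_score <- function(seizure_samples, nonseizure_samples) {
  if (length(seizure_samples) < 2L || length(nonseizure_samples) < 2L) {
    stop_rsae("each sample set needs at least 2 values")
  }
  pvar <- function(x) mean((x - mean(x))^2)
  denom <- pvar(seizure_samples) + pvar(nonseizure_samples)
  if (denom <= 0) stop_rsae("both sample sets are constant; FDR undefined")
  (mean(seizure_samples) - mean(nonseizure_samples))^2 / denom
}

#' Select the most discriminative frequency band on the training split
#'
#' For every candidate band all cross-power matrix entries of all seizure
#' training segments are pooled into one scalar sample (likewise
#' nonseizure) and scored with [fdr_score()]; the band with the highest
#' score wins, ties going to the lowest lower edge.  `mode = "per_entry"`
#' instead scores each of the N^2 matrix entries separately and averages
#' the scores.
#'
#' @param train_segments labelled list of `eeg_segment` objects containing
#'   both classes.
#' @param candidates list of [band()] objects (default the three named
#'   bands).
#' @param fs sampling rate in Hz.
#' @param welch a [welch_params()] list.
#' @param mode `"pooled"` (default) or `"per_entry"`.
#' @return the winning [band()]; attribute `"scores"` holds all FDR values.
#' @export
select_band <- function(train_segments, candidates = named_bands(), fs,
                        welch = welch_params(),
                        mode = c("pooled", "per_entry")) {
  mode <- match.arg(mode)
  if (length(candidates) == 0L) stop_rsae("empty candidate band list")
  labels <- segment_labels(train_segments)
  if (!all(c("seizure", "nonseizure") %in% labels)) {
    stop_rsae("train_segments must contain both classes")
  }
  feats <- cross_power_features(train_segments, candidates, fs, welch)
  scores <- vapply(feats, function(f) {
    s <- f[labels == "seizure", , drop = FALSE]
    n <- f[labels == "nonseizure", , drop = FALSE]
    if (mode == "pooled") {
      fdr_score(as.vector(s), as.vector(n))
    } else {
      mean(vapply(seq_len(ncol(f)), function(j) {
        tryCatch(fdr_score(s[, j], n[, j]), error = function(e) 0)
      }, numeric(1L)))
    }
  }, numeric(1L))
  lbs <- vapply(candidates, function(b) b$lb, numeric(1L))
  best <- order(-scores, lbs)[1L]
  structure(candidates[[best]], scores = scores)
}

#' Fit a log1p + min-max feature scaler on training features
#'
#' Stores per-feature minimum and range of `log(1 + value)` over the
#' training rows.  [apply_scaler()] maps `log(1 + value)` affinely into
#' `[0, 1]` and clips; features constant on the training set get range 1,
#' so they scale to 0 rather than NaN.
#'
#' @param train_features n x p matrix of nonnegative features.
#' @return a `feature_scaler` with `offset` and `range` vectors.
#' @export
fit_scaler <- function(train_features) {
  train_features <- as.matrix(train_features)
  if (nrow(train_features) == 0L) stop_rsae("cannot fit a scaler on zero rows")
  lx <- log1p(train_features)
  offset <- apply(lx, 2L, min)
  range <- apply(lx, 2L, max) - offset
  range[!is.finite(range) | range <= 0] <- 1
  structure(list(offset = offset, range = range), class = "feature_scaler")
}

#' Apply a fitted feature scaler
#'
#' @param scaler a [fit_scaler()] result (never modified).
#' @param features n x p matrix on the raw feature scale.
#' @return n x p matrix with all entries in `[0, 1]`.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  features <- as.matrix(features)
  if (ncol(features) != length(scaler$offset)) {
    stop_rsae("feature width (", ncol(features),
              ") does not match the fitted scaler (", length(scaler$offset), ")")
  }
  scaled <- sweep(sweep(log1p(features), 2L, scaler$offset), 2L,
                  scaler$range, "/")
  pmin(pmax(scaled, 0), 1)
}

#' Flatten a cross-power matrix to a feature vector
#'
#' Row-major order, length N^2 (e.g. 784 for 28 channels);
#' [unvectorize_cpm()] is its inverse.
#'
#' @param m N x N matrix.
#' @return numeric vector of length `N^2`.
#' @export
vectorize_cpm <- function(m) {
  as.vector(t(m))
}

#' @rdname vectorize_cpm
#' @param v numeric vector of square length.
#' @export
unvectorize_cpm <- function(v) {
  n <- sqrt(length(v))
  if (n != round(n)) stop_rsae("feature vector length is not a perfect square")
  matrix(v, n, n, byrow = TRUE)
}
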