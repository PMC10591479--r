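#' Spectral band window
#' @param lo,hi window bounds in cm^-1, `lo < hi`. The published analysis
#'   windows are 16,892-17,094 cm^-1 (outer-wall peak, experiment) and
#'   15,324-18,550 cm^-1 (simulated spectra).
#' @return An object of class `band_window`.
#' @export
band_window <- function(lo, hi) {
  if (!(lo < hi)) stop("band window requires lo < hi")
  structure(list(lo = lo, hi = hi), class = "band_window")
}

#' Band-averaged OD, LD and reduced LD
#'
#' Arithmetic mean of `A_iso` and `LD` over the grid points inside the
#' window (endpoints inclusive; the grid is not resampled). The reduced LD
#' is the ratio of the band means, `ld_r = mean(LD) / mean(A_iso)` (ratio of
#' means, not mean of pointwise ratios); set `pointwise = TRUE` for the mean
#' of pointwise `LD_r` over the window instead.
#'
#' @param spectrum an `exciton_spectrum`.
#' @param window a [band_window()]; `NULL` averages the full grid.
#' @param pointwise average pointwise `LD_r` instead of taking the ratio of
#'   band means.
#' @return Named list `od`, `ld`, `ld_r`.
#' @export
band_average <- function(spectrum, window = NULL, pointwise = FALSE) {
  sel <- if (is.null(window)) rep(TRUE, nrow(spectrum)) else
    spectrum$wavenumber >= window$lo & spectrum$wavenumber <= window$hi
  if (!any(sel)) stop("band window does not overlap the spectrum grid")
  od <- mean(spectrum$A_iso[sel])
  ld <- mean(spectrum$LD[sel])
  ld_r <- if (pointwise) mean(spectrum$LD_r[sel], na.rm = TRUE)
          else if (od > 0) ld / od
          else if (abs(ld) < .Machine$double.eps) 0
          else NA_real_
  list(od = od, ld = ld, ld_r = ld_r)
}

#' OD/LD/LD_r time series of a frame trajectory
#'
#' Computes the full polarized spectrum of every frame and reduces it to the
#' band-averaged observables, one row per frame in input order. With a fixed
#' `params$seed` the result is deterministic (all frames share the disorder
#' seed, so differences between frames are purely structural).
#'
#' @param frames list of [molecule_frame()]s (e.g. from
#'   [simulate_assembly()]).
#' @param params an [exciton_params()].
#' @param window a [band_window()] (`NULL` = full grid).
#' @param grid wavenumber grid (default [default_grid()]).
#' @param t time coordinates; defaults to the `t` attribute of `frames` or
#'   `0:(n-1)`.
#' @param couplings logical, passed to the spectrum computation.
#' @return data.frame with columns `t`, `n_molecules`, `od`, `ld`, `ld_r`.
#' @export
spectra_timeseries <- function(frames, params, window = NULL, grid = NULL,
                               t = NULL, couplings = TRUE) {
  if (length(frames) < 1L) stop("need at least one frame")
  grid <- grid %||% default_grid(params)
  t <- t %||% attr(frames, "t") %||% (seq_along(frames) - 1)
  rows <- lapply(seq_along(frames), function(i) {
    sp <- full_spectrum(frames[[i]], params, grid = grid,
                        couplings = couplings)
    ba <- band_average(sp, window)
    data.frame(t = t[i], n_molecules = n_molecules(frames[[i]]),
               od = ba$od, ld = ba$ld, ld_r = ba$ld_r)
  })
  do.call(rbind, rows)
}

#' Locate the peak of a spectrum component
#'
#' Grid argmax of the chosen component, optionally restricted to a window;
#' ties are broken towards the lower wavenumber.
#'
#' @param spectrum an `exciton_spectrum` (or data.frame with `wavenumber`).
#' @param component column to search (default `"A_iso"`).
#' @param window optional [band_window()] restricting the search.
#' @return Named list `wavenumber`, `height`.
#' @export
find_peak <- function(spectrum, component = "A_iso", window = NULL) {
  sel <- if (is.null(window)) rep(TRUE, nrow(spectrum)) else
    spectrum$wavenumber >= window$lo & spectrum$wavenumber <= window$hi
  if (!any(sel)) stop("band window does not overlap the spectrum grid")
  y <- spectrum[[component]][sel]
  x <- spectrum$wavenumber[sel]
  if (all(!is.finite(y)) || all(y == 0, na.rm = TRUE))
    stop("no peak: spectrum component is zero everywhere in the window")
  i <- which.max(y)   # first maximum = lowest wavenumber on an ascending grid
  list(wavenumber = x[i], height = y[i])
}

#' Write a time series as TSV
#' @param ts data.frame from [spectra_timeseries()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param path file path.
#' @export
read_timeseries <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
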