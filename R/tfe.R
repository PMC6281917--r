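# Time-frequency-energy (TFE) distributions: per-band ridges of
# (time, instantaneous frequency, squared instantaneous amplitude).

#' Time-frequency-energy ridges of a FIBF set
#'
#' For every band component the instantaneous amplitude and phase are taken
#' in polar form, the instantaneous frequency estimated by finite phase
#' differences, and the energy defined as the squared amplitude. The result
#' is the long-form ridge set whose scatter `{t, f_hz, energy}` is the TFE
#' distribution of the signal.
#'
#' @param fset an `fq_fibf_set` from [fdm_decompose()].
#' @param method finite-difference method for the instantaneous frequency
#'   (see [inst_frequency()]).
#' @return An object of class `fq_tfe`: a data frame with columns
#'   `component`, `band_lo_hz`, `band_hi_hz`, `n`, `t`, `f_hz`, `energy`,
#'   with the sampling rate in attribute `fs`.
#' @examples
#' x <- unit_sample(N = 1000, n0 = 499, fs = 100)
#' plan <- select_bands(1000, 100, M = 1, strategy = "equal")
#' r <- tfe_ridges(fdm_decompose(x, plan))
#' r$t[which.max(r$energy)]  # energy localized at t = 4.99 s
#' @export
tfe_ridges <- function(fset, method = c("cfd", "ffd", "bfd")) {
  method <- match.arg(method)
  stopifnot(inherits(fset, "fq_fibf_set"))
  fs <- if (is.null(fset$fs)) fset$plan$fs else fset$fs
  plan <- fset$plan
  lo_hz <- unname(.bin_to_hz(plan$bands[, 1] - 1L, plan$N, fs, plan$basis))
  hi_hz <- unname(.bin_to_hz(plan$bands[, 2], plan$N, fs, plan$basis))
  rows <- lapply(seq_along(fset$components), function(i) {
    d <- inst_descriptors(fset$components[[i]], method = method, fs = fs)
    data.frame(component = i, band_lo_hz = lo_hz[i], band_hi_hz = hi_hz[i],
               n = d$n, t = d$t, f_hz = d$f_hz, energy = d$ia^2)
  })
  out <- do.call(rbind, rows)
  attr(out, "fs") <- fs
  class(out) <- c("fq_tfe", "data.frame")
  out
}

#' Rasterize TFE ridges onto a time-frequency grid
#'
#' Accumulates ridge energy onto a matrix of `n_freq_bins` frequency rows
#' (spanning `[0, fs/2]`) by time columns, assigning each ridge point to its
#' nearest frequency bin. Total energy is conserved exactly.
#'
#' @param ridges an `fq_tfe` from [tfe_ridges()].
#' @param n_freq_bins number of frequency rows (`>= 2`).
#' @return numeric matrix `[n_freq_bins, n_times]` with `dimnames` giving the
#'   bin centre frequencies (Hz) and times (s).
#' @export
tfe_grid <- function(ridges, n_freq_bins = 64) {
  stopifnot(inherits(ridges, "fq_tfe"), n_freq_bins >= 2)
  fs <- attr(ridges, "fs")
  nyq <- fs / 2
  times <- sort(unique(ridges$n))
  grid <- matrix(0, n_freq_bins, length(times))
  f_idx <- pmin(pmax(1L, as.integer(round(ridges$f_hz / nyq * (n_freq_bins - 1)) + 1L)),
                n_freq_bins)
  t_idx <- match(ridges$n, times)
  for (j in seq_len(nrow(ridges)))
    grid[f_idx[j], t_idx[j]] <- grid[f_idx[j], t_idx[j]] + ridges$energy[j]
  dimnames(grid) <- list(
    f_hz = format(seq(0, nyq, length.out = n_freq_bins), digits = 6),
    t = format(times / fs, digits = 6))
  grid
}

#' Write TFE ridges (or a grid) to CSV
#'
#' @param x an `fq_tfe` data frame or a matrix from [tfe_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tfe_csv <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.csv(as.data.frame(x), path, row.names = TRUE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
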