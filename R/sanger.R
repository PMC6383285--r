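#' Editing level from Sanger chromatogram peak heights
#'
#' The editing level at a site is the minor-peak fraction
#' minor/(major+minor). The base-calling software reports a minor peak only
#' when its height is at least 5% of the major peak's, so the detection
#' threshold on the level scale is 5/(100+5) = 0.048; levels are reported
#' for every peak pair, with `detected = FALSE` below the threshold.
#'
#' @param major_height,minor_height numeric vectors of peak heights
#'   (arbitrary fluorescence units); `major_height > 0`,
#'   `minor_height >= 0`.
#' @param min_minor_ratio minimum minor/major height ratio for detection
#'   (default 0.05; the boundary counts as detected).
#' @return data.frame with `level` and `detected` columns.
#' @export
editing_from_peaks <- function(major_height, minor_height,
                               min_minor_ratio = 0.05) {
  if (any(major_height <= 0)) stop("major peak height must be positive")
  if (any(minor_height < 0)) stop("minor peak height must be >= 0")
  data.frame(
    level = minor_height / (major_height + minor_height),
    detected = minor_height >= min_minor_ratio * major_height
  )
}

#' Minimum reportable editing level implied by the minor-peak rule
#'
#' A minor peak at exactly `min_minor_ratio` times the major peak gives
#' level r/(1+r) — 0.048 at the default 5% rule.
#'
#' @inheritParams editing_from_peaks
#' @return numeric scalar.
#' @export
sanger_detection_threshold <- function(min_minor_ratio = 0.05) {
  min_minor_ratio / (1 + min_minor_ratio)
}

#' Quantify a Sanger peak table
#'
#' Applies [editing_from_peaks()] to each row of a peak table from
#' [read_peak_table()].
#'
#' @param peaks peak-pair data.frame.
#' @inheritParams editing_from_peaks
#' @return the input with `level` and `detected` columns added.
#' @export
quantify_peaks <- function(peaks, min_minor_ratio = 0.05) {
  cbind(peaks, editing_from_peaks(peaks$major_height, peaks$minor_height,
                                  min_minor_ratio = min_minor_ratio))
}
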