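#' Normalize a plus-strand flanking window to the edited strand
#'
#' Candidate sites are recorded on the reference plus strand, so minus-strand
#' C>U events appear as G>A and minus-strand A>I events as T>C. This
#' function reverse-complements the plus-strand window for those classes so
#' that every returned window reads 5' to 3' on the edited strand with the
#' edited C (or A) at the center.
#'
#' @param ref,alt the site's plus-strand alleles (one of the four canonical
#'   pairs C>T, G>A, A>G, T>C).
#' @param window plus-strand window, odd length, center base equal to `ref`.
#' @return list with `window` (edited-strand sequence), `edited_strand`
#'   ("plus"/"minus") and `class` ("C2U"/"A2I").
#' @export
to_edited_strand <- function(ref, alt, window) {
  stopifnot(length(ref) == 1L, length(alt) == 1L, length(window) == 1L)
  window <- toupper(window)
  cls <- editing_class(ref, alt)
  if (is.na(cls)) {
    stop("non-canonical substitution ", ref, ">", alt,
         "; expected C>T, G>A, A>G or T>C")
  }
  n <- nchar(window)
  if (n %% 2L == 0L) stop("window length must be odd")
  center <- substr(window, (n + 1L) %/% 2L, (n + 1L) %/% 2L)
  if (center != ref) {
    stop("window center base ", center, " disagrees with site ref ", ref,
         " (coordinate convention error?)")
  }
  strand <- editing_strand(ref, alt)
  out <- if (strand == "minus") revcomp(window) else window
  list(window = out, edited_strand = strand, class = cls)
}

#' The -1 dinucleotide filter for C>U events
#'
#' APOBEC3 cytidine deaminases edit cytidines in a pyrimidine dinucleotide
#' context: A3G prefers CC and the other family members TC. A candidate C>U
#' site passes when the base immediately 5' of the edited C, on the edited
#' strand, is C or T. An N at the -1 position fails (conservative).
#'
#' @param window character vector of edited-strand windows (center base C).
#' @return logical vector: TRUE when position -1 is C or T.
#' @export
minus_one_filter <- function(window) {
  vapply(window, function(w) {
    n <- nchar(w)
    if (n %% 2L == 0L) stop("window length must be odd")
    e <- (n + 1L) %/% 2L
    if (substr(w, e, e) != "C") {
      stop("minus_one_filter applies to C2U contexts (center C)")
    }
    substr(w, e - 1L, e - 1L) %in% c("C", "T")
  }, logical(1), USE.NAMES = FALSE)
}

#' Position frequency matrix of flanking windows
#'
#' Tabulates per-position base frequencies across a set of same-length
#' edited-strand windows, the numeric counterpart of a sequence logo. N
#' symbols are excluded from each position's denominator, matching logo
#' semantics of observed residues; the center column is degenerate (all C
#' for C>U contexts).
#'
#' @param windows character vector of edited-strand windows, all the same
#'   odd length 2k+1.
#' @return list of class `pfm`: `freq` (a (2k+1) x 4 matrix of relative
#'   frequencies, rows named by position -k..k, columns A/C/G/T), `counts`
#'   (same shape, integer counts), `n_obs` (non-N observations per
#'   position), `k`.
#' @export
build_pfm <- function(windows) {
  stopifnot(length(windows) >= 1L)
  lens <- unique(nchar(windows))
  if (length(lens) != 1L || lens %% 2L == 0L) {
    stop("all windows must share one odd length")
  }
  k <- (lens - 1L) %/% 2L
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  bases <- c("A", "C", "G", "T")
  counts <- t(apply(mat, 2, function(col) {
    tabulate(factor(col[col != "N"], levels = bases), nbins = 4L)
  }))
  n_obs <- rowSums(counts)
  freq <- counts / ifelse(n_obs > 0, n_obs, 1)
  dimnames(counts) <- dimnames(freq) <- list(as.character(-k:k), bases)
  structure(list(freq = freq, counts = counts, n_obs = n_obs, k = k),
            class = "pfm")
}

#' Write a position frequency matrix as TSV
#'
#' Rows are positions -k..k relative to the edited base, columns the four
#' bases plus the per-position number of non-N observations.
#'
#' @param pfm object from [build_pfm()].
#' @param path output file.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = rownames(pfm$freq), pfm$freq,
                   n_obs = pfm$n_obs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
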