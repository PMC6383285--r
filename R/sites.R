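#' Canonical site keys and small sequence utilities
#'
#' Sites are identified throughout the package by the key
#' `"chrom:pos:ref>alt"` with 1-based positions. Positional keys
#' (`"chrom:pos"`) are used for cross-study overlap where alleles are not
#' recorded.
#'
#' @param chrom character vector of contig names.
#' @param pos 1-based integer positions.
#' @param ref,alt single-base alleles in A/C/G/T.
#' @return character vector of site keys.
#' @export
site_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' @rdname site_key
#' @export
pos_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character vectors over A/C/G/T/N (case-insensitive,
#' returned uppercase). N maps to N.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Classify a ref>alt substitution into an editing class
#'
#' C>T and G>A mismatches are plus- and minus-strand representations of
#' C-to-U editing; A>G and T>C are the two strands of A-to-I editing. All
#' other substitutions are non-canonical.
#'
#' @param ref,alt character vectors of single bases.
#' @return character vector: "C2U", "A2I", or NA for non-canonical pairs.
#' @export
editing_class <- function(ref, alt) {
  if (length(ref) == 0L) return(character(0))
  key <- paste0(ref, ">", alt)
  out <- rep(NA_character_, length(key))
  out[key %in% c("C>T", "G>A")] <- "C2U"
  out[key %in% c("A>G", "T>C")] <- "A2I"
  out
}

#' @rdname editing_class
#' @return for `editing_strand`: "plus" when the edited base is on the
#'   reference plus strand (C>T, A>G), "minus" for G>A and T>C, NA otherwise.
#' @export
editing_strand <- function(ref, alt) {
  if (length(ref) == 0L) return(character(0))
  key <- paste0(ref, ">", alt)
  out <- rep(NA_character_, length(key))
  out[key %in% c("C>T", "A>G")] <- "plus"
  out[key %in% c("G>A", "T>C")] <- "minus"
  out
}

# shared base-pair rule; wobble adds G:T/T:G (DNA alphabet stands in for G:U)
.wc_pair <- function(x, y, wobble = FALSE) {
  p <- paste0(x, y)
  ok <- p %in% c("AT", "TA", "GC", "CG")
  if (wobble) ok <- ok | p %in% c("GT", "TG")
  ok & !grepl("N", p, fixed = TRUE)
}
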