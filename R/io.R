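#' Read a per-sample site counts table
#'
#' The long-format tab-separated table carries one row per site x sample:
#' mandatory columns `chrom`, `pos`, `ref`, `alt`, `sample_id`, `donor_id`,
#' `condition` (normoxia/hypoxia), `ref_count`, `alt_count`; optional
#' annotation columns (`gene`, `region`, `aa_effect`, `flank`, ...) are
#' preserved untouched.
#'
#' @param path tab-separated file with a header line.
#' @return data.frame with typed columns and a `site_id` key column added.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  mandatory <- c("chrom", "pos", "ref", "alt", "sample_id", "donor_id",
                 "condition", "ref_count", "alt_count")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0L) {
    stop("site table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("pos", "ref_count", "alt_count")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]])) {
      stop("non-integer values in column ", col)
    }
    df[[col]] <- v
  }
  if (any(df$ref_count < 0 | df$alt_count < 0, na.rm = TRUE)) {
    stop("negative read counts")
  }
  if (any(df$pos < 1, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  bad <- setdiff(unique(df$condition), c("normoxia", "hypoxia"))
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  df$site_id <- site_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' @rdname read_site_table
#' @param df a site counts data.frame.
#' @export
write_site_table <- function(df, path) {
  out <- df[setdiff(names(df), "site_id")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the flanking window around a site from a reference genome
#'
#' Returns the 2k+1 base window on the reference plus strand centered on the
#' site, uppercase; windows truncated at contig edges are padded with N. The
#' center base is checked against the site's ref allele to catch coordinate
#' convention bugs (positions are 1-based inclusive throughout).
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param chrom contig name.
#' @param pos 1-based position.
#' @param ref expected reference base at `pos` (checked; use NULL to skip).
#' @param k flank width on each side (default 15).
#' @return character string of length 2k+1.
#' @export
extract_flank <- function(genome, chrom, pos, ref = NULL, k = 15L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  idx <- match(chrom, nm)
  if (is.na(idx)) stop("contig ", chrom, " absent from genome")
  contig <- genome[[idx]]
  len <- length(contig)
  if (pos < 1L || pos > len) stop("position ", pos, " outside contig ", chrom)
  lo <- max(1L, pos - k)
  hi <- min(len, pos + k)
  core <- toupper(as.character(Biostrings::subseq(contig, lo, hi)))
  window <- paste0(strrep("N", lo - (pos - k)), core, strrep("N", (pos + k) - hi))
  if (!is.null(ref)) {
    center <- substr(window, k + 1L, k + 1L)
    if (center != toupper(ref)) {
      stop("center base ", center, " at ", chrom, ":", pos,
           " disagrees with site ref ", ref)
    }
  }
  window
}

#' Read a known-SNP blacklist (VCF or TSV)
#'
#' Only CHROM/POS/REF/ALT are consumed from a VCF; multi-allelic records are
#' expanded to one key per alternate allele. A plain TSV needs at least
#' chrom and pos columns; when ref/alt columns are absent the entries match
#' any allele at that position.
#'
#' @param path a `.vcf` file or a tab-separated table (header optional for
#'   VCF; a TSV is assumed headerless with columns chrom, pos[, ref, alt]).
#' @return data.frame of class `site_set` with columns `chrom`, `pos`,
#'   `ref`, `alt` (NA when positional-only), `key`.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(.site_set(character(), integer()))
  fields <- strsplit(lines, "\t")
  ncol_min <- min(lengths(fields))
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE)
  if (is_vcf && ncol_min < 5L) {
    stop("VCF blacklist records need CHROM POS ID REF ALT (line ",
         which(lengths(fields) < 5L)[1], ")")
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("unparseable position at line ", i, ": ", lines[i])
    if (is_vcf) {
      alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
      data.frame(chrom = f[1], pos = pos, ref = f[4], alt = alts,
                 stringsAsFactors = FALSE)
    } else if (length(f) >= 4L) {
      data.frame(chrom = f[1], pos = pos, ref = f[3], alt = f[4],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = f[1], pos = pos, ref = NA_character_,
                 alt = NA_character_, stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  .site_set(df$chrom, df$pos, df$ref, df$alt)
}

#' Read a site set (BED or 1-based TSV)
#'
#' BED input is 0-based half-open and converted to 1-based positions at the
#' boundary (intervals are expanded to per-position keys); TSV input is
#' taken as 1-based chrom/pos. Duplicate keys are collapsed.
#'
#' @param path input file.
#' @param format "bed" or "tsv" — the coordinate convention must be
#'   declared, never guessed.
#' @return `site_set` data.frame with positional keys.
#' @export
read_site_set <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (length(lines) == 0L) return(.site_set(character(), integer()))
  fields <- strsplit(lines, "[\t ]+")
  if (format == "bed") {
    rows <- lapply(fields, function(f) {
      start <- as.integer(f[2]); end <- as.integer(f[3])
      if (is.na(start) || is.na(end) || end <= start) {
        stop("bad BED interval: ", paste(f, collapse = " "))
      }
      data.frame(chrom = f[1], pos = (start + 1L):end,
                 stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(fields, function(f) {
      pos <- as.integer(f[2])
      if (is.na(pos)) stop("bad TSV site row: ", paste(f, collapse = " "))
      data.frame(chrom = f[1], pos = pos, stringsAsFactors = FALSE)
    })
  }
  df <- do.call(rbind, rows)
  .site_set(df$chrom, df$pos)
}

#' Read a Sanger peak-height table
#'
#' Comma-separated columns: `site`, `label`, `major_base`, `major_height`,
#' `minor_base`, `minor_height`. Rows where the minor peak exceeds the major
#' are swapped with a warning.
#'
#' @param path CSV file.
#' @return data.frame of peak pairs.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site", "major_base", "major_height", "minor_base",
              "minor_height")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("peak table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$major_height <= 0)) stop("major peak heights must be positive")
  if (any(df$minor_height < 0)) stop("minor peak heights must be >= 0")
  swap <- df$minor_height > df$major_height
  if (any(swap)) {
    warning(sum(swap), " row(s) had minor > major peak; bases swapped")
    tmpb <- df$major_base[swap]; tmph <- df$major_height[swap]
    df$major_base[swap] <- df$minor_base[swap]
    df$major_height[swap] <- df$minor_height[swap]
    df$minor_base[swap] <- tmpb
    df$minor_height[swap] <- tmph
  }
  df
}

#' Write a minimal site-only VCF (CHROM POS ID REF ALT)
#'
#' @param df data.frame with chrom, pos, ref, alt (and optional id).
#' @param path output path.
#' @export
write_blacklist_vcf <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT"), con)
  id <- if ("id" %in% names(df)) df$id else rep(".", nrow(df))
  if (nrow(df) > 0L) {
    writeLines(paste(df$chrom, df$pos, id, df$ref, df$alt, sep = "\t"), con)
  }
  invisible(path)
}

.site_set <- function(chrom, pos, ref = NULL, alt = NULL) {
  if (is.null(ref)) ref <- rep(NA_character_, length(chrom))
  if (is.null(alt)) alt <- rep(NA_character_, length(chrom))
  key <- ifelse(is.na(ref) | is.na(alt),
                pos_key(chrom, pos), site_key(chrom, pos, ref, alt))
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   key = key, stringsAsFactors = FALSE)
  df <- df[!duplicated(df$key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("site_set", class(df))
  df
}
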