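#' Run the full editing-detection filter cascade
#'
#' Applies, in order: the canonical-substitution filter (C>T/G>A and
#' A>G/T>C only), known-SNP blacklist removal, the 5%-in-any-sample
#' prevalence filter, the paired binomial GLM with BH FDR and direction
#' classification, and — for C>U events only — the -1 C/T dinucleotide
#' filter and the stem-loop + exon/UTR structural filter. A>I events stop
#' after direction classification. Every stage's output site set is a
#' subset of its input (asserted), and identical inputs give identical
#' outputs (no hidden randomness).
#'
#' @param counts long-format counts data.frame (see [read_site_table()]);
#'   `region` and `aa_effect` columns are used when present.
#' @param flanks data.frame with `chrom`, `pos`, `ref`, `alt`, `flank`
#'   (plus-strand windows), or NULL to skip the context/structure stages.
#' @param blacklist a `site_set`, a data.frame with chrom/pos[/ref/alt], or
#'   NULL.
#' @param min_level prevalence threshold (default 0.05, inclusive).
#' @param alpha FDR threshold (default 0.05, strict).
#' @param wobble treat G:T as complementary in the stem-loop predicate.
#' @param test,fdr_family passed to [edit_test_all()].
#' @return list of class `cascade_result`:
#'   `results` — one row per site reaching the GLM stage, with test
#'   results, per-stage pass flags, and `retained` (final C>U call);
#'   `report` — per-stage data.frame (stage, sites_in, sites_out,
#'   hypoxia_higher, normoxia_higher);
#'   `pfm` — list of position frequency matrices of retained C>U contexts
#'   by direction (NULL when empty);
#'   `class_summary` — see [summarize_by_class()].
#' @export
run_cascade <- function(counts, flanks = NULL, blacklist = NULL,
                        min_level = 0.05, alpha = 0.05, wobble = FALSE,
                        test = "wald", fdr_family = "joint") {
  if (!"site_id" %in% names(counts)) {
    counts$site_id <- site_key(counts$chrom, counts$pos, counts$ref,
                               counts$alt)
  }
  n_sites <- function(df) length(unique(df$site_id))
  report <- list()
  note_stage <- function(name, n_in, n_out, hyp = NA_integer_,
                         norm = NA_integer_) {
    stopifnot(n_out <= n_in)  # cascade monotonicity
    report[[length(report) + 1L]] <<- data.frame(
      stage = name, sites_in = n_in, sites_out = n_out,
      hypoxia_higher = hyp, normoxia_higher = norm,
      stringsAsFactors = FALSE)
  }

  n0 <- n_sites(counts)
  s1 <- filter_canonical(counts)
  note_stage("canonical", n0, n_sites(s1))
  s2 <- remove_blacklisted(s1, blacklist)
  note_stage("blacklist", n_sites(s1), n_sites(s2))
  s3 <- filter_prevalence(s2, min_level = min_level)
  note_stage("prevalence", n_sites(s2), n_sites(s3))

  if (n_sites(s3) == 0L) {
    note_stage("glm_fdr", 0L, 0L, 0L, 0L)
    note_stage("minus_one", 0L, 0L, 0L, 0L)
    note_stage("stemloop_exon_utr", 0L, 0L, 0L, 0L)
    return(structure(list(results = NULL,
                          report = do.call(rbind, report),
                          pfm = NULL, class_summary = NULL),
                     class = "cascade_result"))
  }

  res <- edit_test_all(s3, alpha = alpha, test = test, family = fdr_family)
  site_info <- s3[!duplicated(s3$site_id),
                  intersect(c("site_id", "chrom", "pos", "ref", "alt",
                              "gene", "region", "aa_effect", "class",
                              "strand"), names(s3))]
  res <- merge(site_info, res[setdiff(names(res), "class")], by = "site_id",
               sort = FALSE)
  sig <- res$direction != "ns"
  note_stage("glm_fdr", n_sites(s3), sum(sig),
             sum(res$direction == "hypoxia_higher"),
             sum(res$direction == "normoxia_higher"))

  res$pass_minus_one <- NA
  res$stemloop_qualifies <- NA
  res$retained <- NA
  res$edited_window <- NA_character_

  c2u_sig <- which(sig & res$class == "C2U")
  if (length(c2u_sig) > 0L && !is.null(flanks)) {
    if (!"site_id" %in% names(flanks)) {
      flanks$site_id <- site_key(flanks$chrom, flanks$pos, flanks$ref,
                                 flanks$alt)
    }
    fl <- flanks$flank[match(res$site_id[c2u_sig], flanks$site_id)]
    if (anyNA(fl)) {
      stop("no flank available for site(s) ",
           paste(res$site_id[c2u_sig][is.na(fl)], collapse = ", "))
    }
    win <- vapply(c2u_sig, function(i) {
      to_edited_strand(res$ref[i], res$alt[i],
                       flanks$flank[match(res$site_id[i], flanks$site_id)]
                       )$window
    }, "")
    res$edited_window[c2u_sig] <- win
    res$pass_minus_one[c2u_sig] <- minus_one_filter(win)
    after_m1 <- c2u_sig[res$pass_minus_one[c2u_sig]]
    note_stage("minus_one", length(c2u_sig), length(after_m1),
               sum(res$direction[after_m1] == "hypoxia_higher"),
               sum(res$direction[after_m1] == "normoxia_higher"))

    if (length(after_m1) > 0L) {
      qual <- vapply(res$edited_window[after_m1], function(w) {
        stemloop_predicate(w, wobble = wobble)$qualifies
      }, logical(1), USE.NAMES = FALSE)
      res$stemloop_qualifies[after_m1] <- qual
      in_exon_utr <- if ("region" %in% names(res)) {
        res$region[after_m1] %in% c("exonic", "UTR5", "UTR3")
      } else rep(TRUE, length(after_m1))
      keep <- after_m1[qual & in_exon_utr]
    } else {
      keep <- integer(0)
    }
    res$retained[c2u_sig] <- FALSE
    res$retained[keep] <- TRUE
    note_stage("stemloop_exon_utr", length(after_m1), length(keep),
               sum(res$direction[keep] == "hypoxia_higher"),
               sum(res$direction[keep] == "normoxia_higher"))
  } else {
    note_stage("minus_one", length(c2u_sig), 0L, 0L, 0L)
    note_stage("stemloop_exon_utr", 0L, 0L, 0L, 0L)
  }

  pfm <- NULL
  retained_idx <- which(res$retained %in% TRUE)
  if (length(retained_idx) > 0L) {
    pfm <- lapply(split(retained_idx, res$direction[retained_idx]),
                  function(i) build_pfm(res$edited_window[i]))
  }
  cs <- summarize_by_class(res, s3)

  structure(list(results = res, report = do.call(rbind, report),
                 pfm = pfm, class_summary = cs),
            class = "cascade_result")
}

#' Summarize retained sites by mutational-impact class
#'
#' Groups the finally retained C>U sites by predicted impact — missense,
#' stopgain, synonymous for exonic sites; UTR otherwise — and reports the
#' per-class site count and mean editing level in each condition (mean over
#' sites of the per-site mean sample level).
#'
#' @param results the per-site results of [run_cascade()] (needs `retained`,
#'   `region`, `aa_effect`).
#' @param counts the long-format counts the cascade consumed.
#' @return data.frame: `impact_class`, `n_sites`, `mean_level_normoxia`,
#'   `mean_level_hypoxia`; NULL when annotation columns are absent or
#'   nothing was retained.
#' @export
summarize_by_class <- function(results, counts) {
  if (is.null(results) ||
      !all(c("region", "aa_effect", "retained") %in% names(results))) {
    return(NULL)
  }
  kept <- results[results$retained %in% TRUE, , drop = FALSE]
  if (nrow(kept) == 0L) return(NULL)
  kept$impact_class <- ifelse(kept$region %in% c("UTR5", "UTR3"), "UTR",
                              kept$aa_effect)
  lev <- counts
  lev$level <- editing_level(lev$ref_count, lev$alt_count)
  site_means <- stats::aggregate(level ~ site_id + condition, data = lev,
                                 FUN = mean, na.rm = TRUE)
  rows <- lapply(split(kept, kept$impact_class), function(g) {
    m <- site_means[site_means$site_id %in% g$site_id, ]
    data.frame(
      impact_class = g$impact_class[1], n_sites = nrow(g),
      mean_level_normoxia =
        mean(m$level[m$condition == "normoxia"], na.rm = TRUE),
      mean_level_hypoxia =
        mean(m$level[m$condition == "hypoxia"], na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the manual context/structure filters to a site table
#'
#' Runs the -1 C/T dinucleotide filter and the stem-loop + exon/UTR filter
#' on a table of C>U sites with flanks, independently of the statistical
#' stages — the form in which curated site lists are re-screened. When an
#' expected retained-site list is supplied, the per-site disagreements
#' (expected-but-dropped and retained-but-unexpected) are listed.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`, `flank`
#'   (plus strand) and optionally `region`.
#' @param expected optional character vector of site keys expected to
#'   survive the filters.
#' @param wobble passed to [stemloop_predicate()].
#' @return list: `sites` (input with `pass_minus_one`,
#'   `stemloop_qualifies`, `in_exon_utr`, `retained` columns), `n_retained`,
#'   and when `expected` is given, `missing` and `extra` key vectors.
#' @export
manual_filters <- function(sites, expected = NULL, wobble = FALSE) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "flank") %in% names(sites)))
  if (!"site_id" %in% names(sites)) {
    sites$site_id <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  }
  win <- vapply(seq_len(nrow(sites)), function(i) {
    to_edited_strand(sites$ref[i], sites$alt[i], sites$flank[i])$window
  }, "")
  sites$pass_minus_one <- minus_one_filter(win)
  sites$stemloop_qualifies <- vapply(win, function(w) {
    stemloop_predicate(w, wobble = wobble)$qualifies
  }, logical(1), USE.NAMES = FALSE)
  sites$in_exon_utr <- if ("region" %in% names(sites)) {
    sites$region %in% c("exonic", "UTR5", "UTR3")
  } else TRUE
  sites$retained <- sites$pass_minus_one & sites$stemloop_qualifies &
    sites$in_exon_utr
  out <- list(sites = sites, n_retained = sum(sites$retained))
  if (!is.null(expected)) {
    retained_keys <- sites$site_id[sites$retained]
    out$missing <- setdiff(expected, retained_keys)
    out$extra <- setdiff(retained_keys, expected)
  }
  out
}

#' Serialize a cascade filter report as JSON
#'
#' @param result a `cascade_result` (or its `report` data.frame).
#' @param path output file.
#' @export
write_report_json <- function(result, path) {
  report <- if (inherits(result, "cascade_result")) result$report else result
  jsonlite::write_json(report, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
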