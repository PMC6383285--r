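#' Configuration for the synthetic paired editing dataset
#'
#' The generator emulates the study design the analysis assumes: a small
#' cohort of donors each contributing one normoxia and one hypoxia sample,
#' with candidate sites drawn from six truth classes — condition-responsive
#' edited sites (either direction), heterozygous and homozygous SNP
#' contaminants, sub-threshold noise sites, and constitutively edited null
#' sites. Alternate-base counts are binomial with a logit-linear mean:
#' baseline + donor random intercept + condition effect.
#'
#' @param n_donors donors, each sampled in both conditions (default 3).
#' @param depth_range integer pair, uniform read depth per site x sample.
#' @param n_edited_up_hypoxia,n_edited_up_normoxia,n_snp_het,n_snp_hom,n_noise,n_null
#'   sites per truth class.
#' @param baseline_logit normoxia editing log-odds (default logit(0.02)).
#' @param effect_logit condition shift on the logit scale (default 2.0,
#'   lifting ~2% baseline editing to the ~10-30% range under stress).
#' @param donor_sd donor random-intercept standard deviation (default 0.3).
#' @param planted_stemloop_frac fraction of edited sites built on a planted
#'   qualifying stem-loop (default 1).
#' @param minus_one_c_frac fraction of edited sites with C at the -1
#'   position (the A3G-preferred CC context); the rest get T (default 0.8).
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 3L, depth_range = c(20L, 200L),
                       n_edited_up_hypoxia = 60L, n_edited_up_normoxia = 20L,
                       n_snp_het = 20L, n_snp_hom = 10L,
                       n_noise = 40L, n_null = 60L,
                       baseline_logit = stats::qlogis(0.02),
                       effect_logit = 2.0, donor_sd = 0.3,
                       planted_stemloop_frac = 1.0, minus_one_c_frac = 0.8,
                       seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              depth_range = as.integer(depth_range),
              n_edited_up_hypoxia = as.integer(n_edited_up_hypoxia),
              n_edited_up_normoxia = as.integer(n_edited_up_normoxia),
              n_snp_het = as.integer(n_snp_het),
              n_snp_hom = as.integer(n_snp_hom),
              n_noise = as.integer(n_noise), n_null = as.integer(n_null),
              baseline_logit = baseline_logit, effect_logit = effect_logit,
              donor_sd = donor_sd,
              planted_stemloop_frac = planted_stemloop_frac,
              minus_one_c_frac = minus_one_c_frac, seed = as.integer(seed))
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  stopifnot(all(counts >= 0), cfg$n_donors >= 1,
            length(cfg$depth_range) == 2,
            cfg$depth_range[1] >= 1,
            cfg$depth_range[1] <= cfg$depth_range[2],
            cfg$planted_stemloop_frac >= 0, cfg$planted_stemloop_frac <= 1,
            cfg$minus_one_c_frac >= 0, cfg$minus_one_c_frac <= 1,
            cfg$donor_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a flanking window with or without a planted stem-loop
#'
#' With `plant = TRUE`, builds a window whose center C closes a tri- or
#' tetra-loop with the requested stem geometry, then verifies with
#' [stemloop_predicate()] that the predicate actually returns the requested
#' loop length and defect type (random filler can occasionally create a
#' preferred alternative structure, in which case the window is resampled).
#' With `plant = FALSE`, rejection-samples random windows until the
#' predicate fails. Uses the session RNG.
#'
#' @param plant logical.
#' @param loop_len 3 or 4.
#' @param stem_len paired positions; >= 2 for `defect = "none"`, >= 4
#'   otherwise.
#' @param defect "none", "mismatch" or "bulge".
#' @param k flank width (window length 2k+1, default 15).
#' @param minus_one NULL, "C" or "T": force the -1 base.
#' @param max_tries rejection-sampling cap; exceeding it errors (signals
#'   mis-set parameters).
#' @return character window of length 2k+1, center C, edited-strand sense.
#' @export
synth_flank <- function(plant, loop_len = 3L, stem_len = 2L,
                        defect = c("none", "mismatch", "bulge"),
                        k = 15L, minus_one = NULL, max_tries = 500L) {
  defect <- match.arg(defect)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- 2L * k + 1L
  e <- k + 1L
  if (plant) {
    stopifnot(loop_len %in% c(3L, 4L))
    if (defect == "none" && stem_len < 2L) stop("perfect stem needs >= 2 bp")
    if (defect != "none" && stem_len < 4L) stop("defective stem needs >= 4 bp")
    if (stem_len + loop_len + (defect == "bulge") > k) {
      stop("stem does not fit in the window: reduce stem_len or raise k")
    }
  }

  for (try in seq_len(max_tries)) {
    w <- sample(bases, n, replace = TRUE)
    w[e] <- "C"
    if (!is.null(minus_one)) w[e - 1L] <- minus_one

    if (!plant) {
      window <- paste(w, collapse = "")
      if (!stemloop_predicate(window)$qualifies) return(window)
      next
    }

    off <- if (defect == "mismatch") sample(2:(stem_len - 1L), 1L) else NA
    j <- if (defect == "bulge") sample(seq_len(stem_len - 1L), 1L) else NA
    arm <- if (defect == "bulge") sample(c("five_prime", "three_prime"), 1L)
      else NA
    for (i in seq_len(stem_len)) {
      s5 <- if (defect == "bulge" && arm == "five_prime" && i > j) 1L else 0L
      s3 <- if (defect == "bulge" && arm == "three_prime" && i > j) 1L else 0L
      i5 <- e - loop_len - i + 1L - s5
      i3 <- e + i + s3
      w[i3] <- sample(bases, 1L)
      if (defect == "mismatch" && i == off) {
        w[i5] <- sample(setdiff(bases, comp[[w[i3]]]), 1L)
      } else {
        w[i5] <- comp[[w[i3]]]
      }
    }
    # stop random filler from extending the stem past the planted length
    out5 <- e - loop_len - stem_len - (defect == "bulge" &&
                                         identical(arm, "five_prime"))
    out3 <- e + stem_len + 1L + (defect == "bulge" &&
                                   identical(arm, "three_prime"))
    if (out5 >= 1L && out3 <= n) {
      w[out5] <- sample(setdiff(bases, comp[[w[out3]]]), 1L)
    }

    window <- paste(w, collapse = "")
    call <- stemloop_predicate(window)
    ok <- call$qualifies && call$loop_len == loop_len &&
      identical(call$defect, defect) && call$stem_len >= stem_len
    if (ok) return(window)
  }
  stop("synth_flank: rejection sampling exceeded ", max_tries,
       " tries (mis-set parameters?)")
}

#' Simulate donor-paired binomial counts for one site
#'
#' Draws, for every donor x condition, a depth uniform over the configured
#' range and an alternate-base count Binomial(depth, p), where logit(p) =
#' baseline + donor intercept + effect for the stress condition of edited
#' classes; p ~ 0.5 for heterozygous SNPs, ~1 for homozygous SNPs, uniform
#' below 0.04 for noise sites, and the baseline for null sites. Uses the
#' session RNG.
#'
#' @param config a [sim_config()].
#' @param class one of `edited_up_hypoxia`, `edited_up_normoxia`, `snp_het`,
#'   `snp_hom`, `noise`, `null`.
#' @param effect_logit condition shift for edited classes (defaults to the
#'   config value).
#' @return data.frame: `donor_id`, `condition`, `ref_count`, `alt_count`.
#' @export
synth_site_counts <- function(config, class,
                              effect_logit = config$effect_logit) {
  classes <- c("edited_up_hypoxia", "edited_up_normoxia", "snp_het",
               "snp_hom", "noise", "null")
  stopifnot(class %in% classes)
  donors <- sprintf("D%d", seq_len(config$n_donors))
  u <- stats::rnorm(config$n_donors, 0, config$donor_sd)
  p_noise <- stats::runif(1, 0, 0.04)
  grid <- expand.grid(donor_id = donors,
                      condition = c("normoxia", "hypoxia"),
                      stringsAsFactors = FALSE)
  p <- mapply(function(donor, cond) {
    d <- match(donor, donors)
    switch(class,
      edited_up_hypoxia = stats::plogis(config$baseline_logit + u[d] +
                                          effect_logit * (cond == "hypoxia")),
      edited_up_normoxia = stats::plogis(config$baseline_logit + u[d] +
                                           effect_logit * (cond == "normoxia")),
      snp_het = 0.5,
      snp_hom = 0.995,
      noise = p_noise,
      null = stats::plogis(config$baseline_logit + u[d]))
  }, grid$donor_id, grid$condition)
  depth <- config$depth_range[1] +
    sample.int(config$depth_range[2] - config$depth_range[1] + 1L,
               nrow(grid), replace = TRUE) - 1L
  alt <- stats::rbinom(nrow(grid), depth, p)
  data.frame(donor_id = grid$donor_id, condition = grid$condition,
             ref_count = depth - alt, alt_count = alt,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Emits the four tables the pipeline consumes — long-format counts,
#' plus-strand flanks, a SNP blacklist, and a per-site truth table — with
#' the statistical structure of the paired normoxia/hypoxia design.
#' Deterministic given the config (which includes the seed).
#'
#' Edited sites are C>U class (randomly on either strand, so G>A rows
#' exercise the strand normalization), carry exon/UTR region labels, and a
#' configurable fraction sit on planted qualifying stem-loops with a C or T
#' at -1. SNP classes are emitted in the blacklist. Null sites mix C>U and
#' A>I classes at the editing baseline in both conditions.
#'
#' @param config a [sim_config()].
#' @return list of class `synth_dataset`: `counts`, `flanks`, `blacklist`,
#'   `truth` data.frames plus the `config`.
#' @export
synth_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- 15L
  specs <- c(edited_up_hypoxia = config$n_edited_up_hypoxia,
             edited_up_normoxia = config$n_edited_up_normoxia,
             snp_het = config$n_snp_het, snp_hom = config$n_snp_hom,
             noise = config$n_noise, null = config$n_null)

  sites <- list(); counts <- list(); flanks <- list(); truth <- list()
  idx <- 0L
  for (cls in names(specs)) {
    for (i in seq_len(specs[[cls]])) {
      idx <- idx + 1L
      chrom <- "chr1"
      pos <- 1000L * idx
      edited <- cls %in% c("edited_up_hypoxia", "edited_up_normoxia")
      if (cls == "null" && stats::runif(1) < 0.35) {
        # constitutive A>I background
        strand <- sample(c("plus", "minus"), 1L)
        ra <- if (strand == "plus") c("A", "G") else c("T", "C")
      } else {
        strand <- sample(c("plus", "minus"), 1L)
        ra <- if (strand == "plus") c("C", "T") else c("G", "A")
      }
      cls2u <- editing_class(ra[1], ra[2]) == "C2U"

      if (edited) {
        region <- sample(c("exonic", "UTR3", "UTR5"), 1L,
                         prob = c(0.6, 0.25, 0.15))
        aa <- if (region == "exonic") {
          sample(c("missense", "synonymous", "stopgain"), 1L,
                 prob = c(0.5, 0.35, 0.15))
        } else "none"
        planted <- stats::runif(1) < config$planted_stemloop_frac
        m1 <- if (stats::runif(1) < config$minus_one_c_frac) "C" else "T"
        if (planted) {
          loop <- sample(c(3L, 4L), 1L)
          defect <- sample(c("none", "mismatch", "bulge"), 1L,
                           prob = c(0.6, 0.2, 0.2))
          stem <- if (defect == "none") sample(2:5, 1L) else sample(4:6, 1L)
          fl <- synth_flank(TRUE, loop, stem, defect, k = k, minus_one = m1)
        } else {
          loop <- NA_integer_; defect <- NA_character_; stem <- NA_integer_
          fl <- synth_flank(FALSE, k = k, minus_one = m1)
        }
        flank_plus <- if (strand == "minus") revcomp(fl) else fl
      } else {
        region <- sample(c("exonic", "UTR3", "intronic", "intergenic"), 1L)
        aa <- if (region == "exonic") sample(c("missense", "synonymous"), 1L)
          else "none"
        planted <- FALSE
        loop <- NA_integer_; defect <- NA_character_; stem <- NA_integer_
        m1 <- NA_character_
        flank_plus <- paste(sample(c("A", "C", "G", "T"), 2L * k + 1L,
                                   replace = TRUE), collapse = "")
        substr(flank_plus, k + 1L, k + 1L) <- ra[1]
      }

      obs <- synth_site_counts(config, cls)
      sid <- site_key(chrom, pos, ra[1], ra[2])
      site_cols <- data.frame(chrom = chrom, pos = pos, ref = ra[1],
                              alt = ra[2], gene = sprintf("GENE%04d", idx),
                              region = region, aa_effect = aa,
                              stringsAsFactors = FALSE)
      counts[[idx]] <- cbind(site_cols[rep(1L, nrow(obs)), ],
                             sample_id = paste(obs$donor_id, obs$condition,
                                               sep = "_"),
                             obs, site_id = sid, row.names = NULL)
      flanks[[idx]] <- cbind(site_cols[, c("chrom", "pos", "ref", "alt")],
                             flank = flank_plus, site_id = sid)
      truth[[idx]] <- data.frame(
        site_id = sid, class = cls,
        true_effect_logit = switch(cls,
          edited_up_hypoxia = config$effect_logit,
          edited_up_normoxia = -config$effect_logit, 0),
        strand = strand, editing_class = if (cls2u) "C2U" else "A2I",
        planted = planted, planted_loop_len = loop,
        planted_stem_len = stem, planted_defect = defect,
        minus_one = m1, stringsAsFactors = FALSE)
    }
  }

  counts <- do.call(rbind, counts)
  flanks <- do.call(rbind, flanks)
  truth <- do.call(rbind, truth)
  snp <- truth$class %in% c("snp_het", "snp_hom")
  blacklist_df <- flanks[flanks$site_id %in% truth$site_id[snp],
                         c("chrom", "pos", "ref", "alt")]
  blacklist_df$id <- sprintf("sim_snp_%d", seq_len(nrow(blacklist_df)))
  structure(list(counts = counts, flanks = flanks,
                 blacklist = blacklist_df, truth = truth, config = config),
            class = "synth_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits `counts.tsv`, `flanks.tsv`, `truth.tsv` (tab-separated) and
#' `blacklist.vcf`; the tables round-trip through the package readers.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_site_table(ds$counts, file.path(dir, "counts.tsv"))
  utils::write.table(ds$flanks[setdiff(names(ds$flanks), "site_id")],
                     file.path(dir, "flanks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_blacklist_vcf(ds$blacklist, file.path(dir, "blacklist.vcf"))
  invisible(dir)
}
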