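#' Per-sample editing level
#'
#' The editing level at a site in one sample is the fraction of reads
#' carrying the alternate base, alt/(ref+alt). Undefined (NA) when the site
#' has no coverage in that sample.
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @return numeric vector in [0, 1], NA where ref+alt == 0.
#' @export
editing_level <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  ifelse(total > 0, alt_count / total, NA_real_)
}

#' Keep only canonical editing substitution classes
#'
#' Retains C>T/G>A (the two strand representations of C-to-U editing) and
#' A>G/T>C (A-to-I); all other DNA-RNA mismatch classes are dropped. Adds
#' `class` ("C2U"/"A2I") and `strand` ("plus"/"minus") columns.
#'
#' @param df data.frame with `ref` and `alt` columns.
#' @return the canonical subset of `df`, annotated.
#' @export
filter_canonical <- function(df) {
  cls <- editing_class(df$ref, df$alt)
  out <- df[!is.na(cls), , drop = FALSE]
  out$class <- cls[!is.na(cls)]
  out$strand <- editing_strand(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' Prevalence filter: at least 5% editing level in any sample
#'
#' A site is kept when any single sample reaches the minimum editing level
#' (inclusive, >=). Samples with zero coverage are excluded from the check.
#'
#' @param df long-format counts data.frame (one row per site x sample) with
#'   `site_id`, `ref_count`, `alt_count`.
#' @param min_level minimum per-sample editing level (default 0.05).
#' @return the subset of `df` at sites passing the filter.
#' @export
filter_prevalence <- function(df, min_level = 0.05) {
  lev <- editing_level(df$ref_count, df$alt_count)
  ok <- tapply(lev, df$site_id, function(x) any(x >= min_level, na.rm = TRUE))
  keep <- names(ok)[ok]
  out <- df[df$site_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove blacklisted (known SNP) sites
#'
#' Drops every site whose (chrom, pos, ref, alt) key — or position, for
#' positional-only blacklist entries — appears in the blacklist.
#'
#' @param df data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param blacklist a `site_set` from [read_blacklist()] (or NULL for none).
#' @return the subset of `df` not in the blacklist.
#' @export
remove_blacklisted <- function(df, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) return(df)
  if (!"key" %in% names(blacklist)) {
    if (!"ref" %in% names(blacklist)) blacklist$ref <- NA_character_
    if (!"alt" %in% names(blacklist)) blacklist$alt <- NA_character_
    blacklist$key <- ifelse(
      is.na(blacklist$ref) | is.na(blacklist$alt),
      pos_key(blacklist$chrom, blacklist$pos),
      site_key(blacklist$chrom, blacklist$pos, blacklist$ref, blacklist$alt))
  }
  allelic <- blacklist$key[!is.na(blacklist$ref)]
  positional <- pos_key(blacklist$chrom[is.na(blacklist$ref)],
                        blacklist$pos[is.na(blacklist$ref)])
  hit <- site_key(df$chrom, df$pos, df$ref, df$alt) %in% allelic |
    pos_key(df$chrom, df$pos) %in% positional
  out <- df[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired binomial GLM test of the condition effect at one site
#'
#' Alternate-base counts are modeled as binomial; the log odds of editing
#' are regressed on condition (hypoxia vs normoxia) with donor fixed
#' effects, so the condition coefficient is the within-donor log odds ratio.
#' The default p-value is a two-sided Wald test on that coefficient; a
#' likelihood-ratio test is available via `test = "lrt"`.
#'
#' Complete separation (a zero cell in the condition-collapsed 2x2 table of
#' alt/ref counts) makes the MLE infinite; in that case the Haldane-Anscombe
#' correction adds 0.5 to each collapsed cell and the log OR and its
#' asymptotic standard error are computed from the corrected table, flagged
#' `"haldane"`.
#'
#' @param obs data.frame of one site's observations: `donor_id`,
#'   `condition` ("normoxia"/"hypoxia"), `ref_count`, `alt_count`.
#' @param test "wald" (default) or "lrt".
#' @return list: `log_or` (hypoxia vs normoxia), `se`, `p_value`, `flag`
#'   ("" or "haldane").
#' @export
glm_condition_test <- function(obs, test = c("wald", "lrt")) {
  test <- match.arg(test)
  obs <- obs[obs$ref_count + obs$alt_count > 0, , drop = FALSE]
  if (nrow(obs) == 0L) stop("all observations have zero coverage")
  obs$condition <- factor(obs$condition, levels = c("normoxia", "hypoxia"))
  paired <- intersect(obs$donor_id[obs$condition == "normoxia"],
                      obs$donor_id[obs$condition == "hypoxia"])
  if (length(paired) == 0L) stop("no donor observed in both conditions")

  a <- sum(obs$alt_count[obs$condition == "hypoxia"])
  b <- sum(obs$ref_count[obs$condition == "hypoxia"])
  cc <- sum(obs$alt_count[obs$condition == "normoxia"])
  d <- sum(obs$ref_count[obs$condition == "normoxia"])
  if (min(a, b, cc, d) == 0L) {
    log_or <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5)))
    se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (cc + 0.5) + 1 / (d + 0.5))
    p <- 2 * stats::pnorm(-abs(log_or / se))
    return(list(log_or = log_or, se = se, p_value = p, flag = "haldane"))
  }

  form <- if (length(unique(obs$donor_id)) > 1L) {
    cbind(alt_count, ref_count) ~ condition + donor_id
  } else {
    cbind(alt_count, ref_count) ~ condition
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = obs))
  co <- summary(fit)$coefficients
  log_or <- co["conditionhypoxia", "Estimate"]
  se <- co["conditionhypoxia", "Std. Error"]
  if (test == "wald") {
    p <- 2 * stats::pnorm(-abs(log_or / se))
  } else {
    null_form <- if (length(unique(obs$donor_id)) > 1L) {
      cbind(alt_count, ref_count) ~ donor_id
    } else {
      cbind(alt_count, ref_count) ~ 1
    }
    fit0 <- suppressWarnings(stats::glm(null_form, family = stats::binomial(),
                                        data = obs))
    lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(fit0)))
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  list(log_or = log_or, se = se, p_value = p, flag = "")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH q-values controlling the false discovery rate across
#' one family of per-site tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify per-site test results by direction
#'
#' A site is called `hypoxia_higher` when its condition log odds ratio is
#' positive and its FDR q-value is below `alpha` (strict <), and
#' `normoxia_higher` for a negative log OR; otherwise `ns`.
#'
#' @param results data.frame with `log_or` and `q_value` columns.
#' @param alpha FDR threshold (default 0.05).
#' @return `results` with a `direction` column added.
#' @export
classify_direction <- function(results, alpha = 0.05) {
  dir <- rep("ns", nrow(results))
  sig <- !is.na(results$q_value) & results$q_value < alpha
  dir[sig & results$log_or > 0] <- "hypoxia_higher"
  dir[sig & results$log_or < 0] <- "normoxia_higher"
  results$direction <- dir
  results
}

#' Run the paired GLM across all sites of a counts table
#'
#' Fits [glm_condition_test()] per site, applies [bh_adjust()] across the
#' whole family (C>U and A>I jointly by default, per class with
#' `family = "per_class"`), and classifies directions.
#'
#' @param counts long-format counts data.frame with `site_id`, `donor_id`,
#'   `condition`, `ref_count`, `alt_count` and (if present) `class`.
#' @param alpha FDR threshold for direction classification.
#' @param test passed to [glm_condition_test()].
#' @param family "joint" (one BH family) or "per_class" (separate BH within
#'   C2U and A2I).
#' @return data.frame: one row per site with `site_id`, `class`, `log_or`,
#'   `se`, `p_value`, `q_value`, `direction`, `flag`.
#' @export
edit_test_all <- function(counts, alpha = 0.05, test = "wald",
                          family = c("joint", "per_class")) {
  family <- match.arg(family)
  ids <- unique(counts$site_id)
  fits <- lapply(ids, function(id) {
    obs <- counts[counts$site_id == id, , drop = FALSE]
    r <- glm_condition_test(obs, test = test)
    data.frame(site_id = id,
               class = if ("class" %in% names(obs)) obs$class[1] else NA,
               log_or = r$log_or, se = r$se, p_value = r$p_value,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, fits)
  if (family == "per_class" && !all(is.na(res$class))) {
    res$q_value <- NA_real_
    for (cl in unique(res$class)) {
      i <- res$class == cl
      res$q_value[i] <- bh_adjust(res$p_value[i])
    }
  } else {
    res$q_value <- bh_adjust(res$p_value)
  }
  classify_direction(res, alpha = alpha)
}
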