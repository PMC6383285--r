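test_that("editing levels and the inclusive 5% prevalence rule", {
  expect_equal(editing_level(50, 0), 0)
  expect_equal(editing_level(95, 5), 0.05)
  expect_equal(editing_level(80, 20), 0.20)
  expect_true(is.na(editing_level(0, 0)))

  counts <- data.frame(
    site_id = rep(c("s1", "s2"), each = 6),
    ref_count = c(98, 98, 949, 99, 100, 100,   971, 971, 971, 971, 971, 971),
    alt_count = c(2, 2, 51, 1, 0, 0,           49, 49, 49, 49, 49, 49))
  # s1 has one sample at exactly 51/1000 = 0.051 -> kept by the any-sample
  # rule; s2 sits at 0.048 everywhere -> removed
  kept <- filter_prevalence(counts, min_level = 0.05)
  expect_equal(unique(kept$site_id), "s1")
  # a site with a sample at exactly the threshold is kept (inclusive >=)
  at <- data.frame(site_id = "s", ref_count = 95, alt_count = 5)
  expect_equal(nrow(filter_prevalence(at)), 1L)
})

test_that("canonical filter keeps the four strand representations only", {
  df <- data.frame(ref = c("C", "G", "A", "T", "C", "G"),
                   alt = c("T", "A", "G", "C", "G", "T"))
  out <- filter_canonical(df)
  expect_equal(nrow(out), 4L)
  expect_equal(out$class, c("C2U", "C2U", "A2I", "A2I"))
  expect_equal(out$strand, c("plus", "minus", "plus", "minus"))
})

test_that("blacklist removal is a set difference on site keys", {
  df <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   ref = "C", alt = "T",
                   site_id = site_key("chr1", c(100, 200, 300), "C", "T"))
  expect_equal(remove_blacklisted(df, NULL), df)
  bl <- data.frame(chrom = "chr1", pos = c(100L, 300L), ref = "C", alt = "T")
  expect_equal(remove_blacklisted(df, bl)$pos, 200L)
  # allele-specific: a different alt at the same position is not removed
  bl2 <- data.frame(chrom = "chr1", pos = 200L, ref = "C", alt = "G")
  expect_equal(nrow(remove_blacklisted(df, bl2)), 3L)
  # positional-only entries remove any allele
  bl3 <- data.frame(chrom = "chr1", pos = 200L)
  expect_equal(remove_blacklisted(df, bl3)$pos, c(100L, 300L))
})

test_that("paired GLM recovers the collapsed log odds ratio", {
  # symmetric site: no condition effect
  sym <- glm_condition_test(paired_obs(10, 90, 10, 90))
  expect_equal(sym$log_or, 0, tolerance = 1e-8)
  expect_equal(sym$p_value, 1, tolerance = 1e-6)

  # 3 donors, hypoxia 30/70 vs normoxia 2/98: log OR = ln(21)
  r <- glm_condition_test(paired_obs(30, 70, 2, 98))
  expect_equal(r$log_or, log(21), tolerance = 1e-6)
  expect_lt(r$p_value, 1e-6)
  # independent grid-search ML oracle on the collapsed counts
  expect_equal(r$log_or, grid_ml_log_or(90, 210, 6, 294), tolerance = 0.01)
  # Fisher exact on the collapsed table agrees on significance
  expect_lt(fisher_exact_2x2(90, 210, 6, 294)$p_value, 1e-6)
})

test_that("separation triggers the flagged Haldane-corrected estimate", {
  r <- glm_condition_test(paired_obs(10, 90, 0, 100))
  expect_equal(r$flag, "haldane")
  expect_equal(r$log_or,
               log((30 + 0.5) * (300 + 0.5) / ((270 + 0.5) * (0 + 0.5))),
               tolerance = 1e-10)
  expect_true(is.finite(r$p_value) && r$p_value > 0)
  expect_error(glm_condition_test(paired_obs(0, 0, 0, 0)), "zero coverage")
  unpaired <- data.frame(donor_id = c("D1", "D2"),
                         condition = c("hypoxia", "normoxia"),
                         alt_count = c(5, 5), ref_count = c(95, 95))
  expect_error(glm_condition_test(unpaired), "both conditions")
})

test_that("condition label swap negates the log OR; donor relabeling is inert", {
  set.seed(77)
  for (i in 1:20) {
    obs <- paired_obs(rbinom(1, 100, 0.2) + 1, 80, rbinom(1, 100, 0.05) + 1, 95)
    obs$alt_count <- obs$alt_count + rpois(nrow(obs), 2)  # donor variation
    r1 <- glm_condition_test(obs)
    swapped <- obs
    swapped$condition <- ifelse(obs$condition == "hypoxia", "normoxia",
                                "hypoxia")
    r2 <- glm_condition_test(swapped)
    expect_equal(r2$log_or, -r1$log_or, tolerance = 1e-6)
    expect_equal(r2$p_value, r1$p_value, tolerance = 1e-6)
    relabeled <- obs
    relabeled$donor_id <- chartr("123", "312", obs$donor_id)
    r3 <- glm_condition_test(relabeled)
    expect_equal(r3$log_or, r1$log_or, tolerance = 1e-8)
    expect_equal(r3$p_value, r1$p_value, tolerance = 1e-8)
  }
})

test_that("Wald and LRT p-values broadly agree away from boundaries", {
  r_w <- glm_condition_test(paired_obs(20, 80, 5, 95), test = "wald")
  r_l <- glm_condition_test(paired_obs(20, 80, 5, 95), test = "lrt")
  expect_equal(r_w$log_or, r_l$log_or)
  expect_equal(log10(r_w$p_value), log10(r_l$p_value), tolerance = 0.5)
})

test_that("BH adjustment is the standard step-up procedure", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p within one family
  set.seed(5)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("direction calls need both sign and FDR significance", {
  res <- data.frame(log_or = c(1.2, -1.2, 2.0, 0.5),
                    q_value = c(0.01, 0.01, 0.20, NA))
  out <- classify_direction(res, alpha = 0.05)
  expect_equal(out$direction,
               c("hypoxia_higher", "normoxia_higher", "ns", "ns"))
})

test_that("noise-site removal by the prevalence filter matches the binomial tail", {
  # exact oracle: p ~ U(0, 0.04), 6 samples at depth 200; a site is removed
  # iff every sample draws alt <= 9 (level < 5%)
  oracle <- integrate(function(p) pbinom(9, 200, p)^6, 0, 0.04)$value / 0.04
  set.seed(31)
  cfg <- sim_config(depth_range = c(200L, 200L))
  removed <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    obs <- synth_site_counts(cfg, "noise")
    obs$site_id <- "s"
    removed <- removed + (nrow(filter_prevalence(obs)) == 0L)
  }
  expect_lt(abs(removed / n_rep - oracle), 0.07)  # ~3.4 sigma at n = 400
})
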