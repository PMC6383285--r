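test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_noise = -1))
  expect_error(sim_config(depth_range = c(100L, 20L)))
  expect_error(sim_config(planted_stemloop_frac = 1.5))
})

test_that("planted flanks qualify and rejection-sampled ones never do", {
  set.seed(101)
  # every planted geometry family
  grid <- expand.grid(loop = c(3L, 4L), stem = c(2L, 4L, 6L),
                      defect = c("none", "mismatch", "bulge"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$defect == "none" | grid$stem >= 4L, ]
  for (i in seq_len(nrow(grid))) {
    fl <- synth_flank(TRUE, grid$loop[i], grid$stem[i], grid$defect[i])
    call <- stemloop_predicate(fl)
    expect_true(call$qualifies)
    expect_equal(call$loop_len, grid$loop[i])
    expect_equal(call$defect, grid$defect[i])
    expect_gte(call$stem_len, grid$stem[i])
    # the oracle confirms the planted geometry exists in the window
    geoms <- enumerate_structures(fl)
    expect_true(any(geoms$loop_len == grid$loop[i] &
                      geoms$defect == grid$defect[i]))
  }
  negatives <- replicate(50, synth_flank(FALSE))
  expect_false(any(vapply(negatives, function(w)
    stemloop_predicate(w)$qualifies, logical(1))))
  # an exhausted retry cap errors rather than looping forever
  expect_error(synth_flank(FALSE, max_tries = 0), "tries")
  expect_error(synth_flank(TRUE, 4, 20, "none"), "fit")
})

test_that("site counts match their class construction", {
  cfg <- sim_config(depth_range = c(400L, 400L))
  set.seed(102)
  hom <- synth_site_counts(cfg, "snp_hom")
  expect_true(all(hom$ref_count <= 6))  # p ~ 0.995
  het <- do.call(rbind, replicate(30, synth_site_counts(cfg, "snp_het"),
                                  simplify = FALSE))
  expect_equal(mean(editing_level(het$ref_count, het$alt_count)), 0.5,
               tolerance = 0.02)
  # null: alt fraction equal in distribution across conditions
  nul <- do.call(rbind, replicate(100, synth_site_counts(cfg, "null"),
                                  simplify = FALSE))
  lev <- editing_level(nul$ref_count, nul$alt_count)
  expect_lt(abs(mean(lev[nul$condition == "hypoxia"]) -
                  mean(lev[nul$condition == "normoxia"])), 0.005)
  expect_error(synth_site_counts(cfg, "not_a_class"))
})

test_that("moment check: mean alt fraction approaches the class p with depth", {
  cfg <- sim_config(depth_range = c(2000L, 2000L), donor_sd = 0)
  set.seed(103)
  ed <- do.call(rbind, replicate(60, synth_site_counts(cfg, "edited_up_hypoxia"),
                                 simplify = FALSE))
  lev <- editing_level(ed$ref_count, ed$alt_count)
  expect_equal(mean(lev[ed$condition == "normoxia"]), 0.02, tolerance = 0.1)
  expect_equal(mean(lev[ed$condition == "hypoxia"]),
               plogis(qlogis(0.02) + 2), tolerance = 0.05)
})

test_that("synth_dataset is deterministic and covers every site once", {
  cfg <- sim_config(n_edited_up_hypoxia = 4L, n_edited_up_normoxia = 2L,
                    n_snp_het = 2L, n_snp_hom = 2L, n_noise = 3L,
                    n_null = 3L, seed = 17L)
  ds1 <- synth_dataset(cfg)
  ds2 <- synth_dataset(cfg)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$flanks, ds2$flanks)
  expect_identical(ds1$truth, ds2$truth)
  # truth covers every emitted site exactly once
  expect_setequal(ds1$truth$site_id, unique(ds1$counts$site_id))
  expect_false(any(duplicated(ds1$truth$site_id)))
  # paired design: each donor once per condition at every site
  tab <- table(ds1$counts$site_id, ds1$counts$donor_id, ds1$counts$condition)
  expect_true(all(tab == 1))
  # snp classes appear in the emitted blacklist
  snp_ids <- ds1$truth$site_id[grepl("^snp", ds1$truth$class)]
  bl_keys <- site_key(ds1$blacklist$chrom, ds1$blacklist$pos,
                      ds1$blacklist$ref, ds1$blacklist$alt)
  expect_setequal(bl_keys, snp_ids)
  # flank center equals the plus-strand ref base
  expect_equal(substr(ds1$flanks$flank, 16, 16), ds1$flanks$ref)
  # planted structures qualify on the edited strand
  planted <- ds1$truth$site_id[ds1$truth$planted]
  for (sid in planted) {
    i <- match(sid, ds1$flanks$site_id)
    win <- to_edited_strand(ds1$flanks$ref[i], ds1$flanks$alt[i],
                            ds1$flanks$flank[i])$window
    expect_true(stemloop_predicate(win)$qualifies)
  }
})
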