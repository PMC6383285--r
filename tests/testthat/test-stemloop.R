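test_that("hand-checked hairpin geometries are called correctly", {
  # 5'-G C A A C G C-3': tri-loop AAC ending at the edited C, closed by a
  # perfect 2-bp stem (C:G, G:C); filler As cannot extend the stem
  w <- paste0(strrep("A", 11), "GCAACGC", strrep("A", 13))
  call <- stemloop_predicate(w)
  expect_true(call$qualifies)
  expect_equal(call$loop_len, 3L)
  expect_equal(call$stem_len, 2L)
  expect_equal(call$defect, "none")

  # 5'-GATC TTAC GCTC-3': tetra-loop TTAC ending at the edited C; pairs
  # C:G, T:C (mismatch), A:T, G:C -> 4-bp stem, single interior mismatch
  # at offset 2
  w2 <- paste0(strrep("A", 8), "GATCTTACGCTC", strrep("A", 11))
  call2 <- stemloop_predicate(w2)
  expect_true(call2$qualifies)
  expect_equal(call2$loop_len, 4L)
  expect_equal(call2$stem_len, 4L)
  expect_equal(call2$defect, "mismatch")
  expect_equal(call2$defect_offset, 2L)
  # cross-validated against the enumeration oracle
  geoms <- enumerate_structures(w2)
  expect_true(any(geoms$loop_len == 4 & geoms$stem_len == 4 &
                    geoms$defect == "mismatch" & geoms$defect_offset == 2))

  # poly-A window: no pairing possible
  expect_false(stemloop_predicate(strrep("A", 15) |>
                                    paste0("C", strrep("A", 15)))$qualifies)
})

test_that("predicate validates its input window", {
  expect_error(stemloop_predicate(paste0(strrep("A", 15), "G",
                                         strrep("A", 15))), "center")
  expect_error(stemloop_predicate("ACACA"), "odd length")
  expect_error(stemloop_predicate(paste0(strrep("A", 15), "C",
                                         strrep("A", 14), "X")), "A/C/G/T/N")
})

test_that("all-N flanks and terminal defects never qualify", {
  w <- paste0(strrep("N", 15), "C", strrep("N", 15))
  expect_false(stemloop_predicate(w)$qualifies)
  expect_equal(nrow(enumerate_structures(w)), 0L)

  # a mismatch at the loop-closing pair or at the outermost pair must not
  # count: stem GGG / loop AAC / arm CCT gives pairs G:C, G:C, G:T(bad) --
  # perfect stem of 2, never a 3-bp defective stem
  w2 <- paste0(strrep("A", 10), "GGGAACCCT", strrep("A", 12))
  call <- stemloop_predicate(w2)
  expect_true(call$qualifies)
  expect_equal(call$defect, "none")
  expect_equal(call$stem_len, 2L)
  geoms <- enumerate_structures(w2)
  expect_false(any(geoms$defect != "none" & geoms$stem_len < 4))
})

test_that("G:T pairs count only under the wobble option", {
  # stem arm GG / loop AAC / arm TC: pairs G:T, G:C -- with strict
  # complementarity pair 1 fails; with wobble it is a perfect 2-bp stem
  w <- paste0(strrep("A", 11), "GGAACTC", strrep("A", 13))
  expect_false(stemloop_predicate(w)$qualifies)
  call <- stemloop_predicate(w, wobble = TRUE)
  expect_true(call$qualifies)
  expect_equal(call$stem_len, 2L)
})

test_that("predicate agrees with the enumeration oracle on random windows", {
  set.seed(401)
  for (i in 1:500) {
    w <- random_c_window()
    expect_equal(stemloop_predicate(w)$qualifies,
                 nrow(enumerate_structures(w)) > 0,
                 info = w)
  }
  # the preferred call is always among the enumerated geometries
  set.seed(402)
  n_checked <- 0
  while (n_checked < 50) {
    w <- random_c_window()
    call <- stemloop_predicate(w)
    if (!call$qualifies) next
    n_checked <- n_checked + 1
    geoms <- enumerate_structures(w)
    hit <- geoms$loop_len == call$loop_len &
      geoms$stem_len == call$stem_len &
      geoms$defect == call$defect &
      (is.na(call$defect_offset) |
         (!is.na(geoms$defect_offset) &
            geoms$defect_offset == call$defect_offset))
    expect_true(any(hit), info = w)
  }
})

test_that("appending flanking bases never flips a qualifying call to false", {
  set.seed(403)
  n_pos <- 0
  while (n_pos < 40) {
    w <- random_c_window(k = 8)
    if (!stemloop_predicate(w)$qualifies) next
    n_pos <- n_pos + 1
    pad <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
    w2 <- paste0(pad, w, pad)
    expect_true(stemloop_predicate(w2)$qualifies, info = w)
  }
})

test_that("stemloop_screen annotates a flank table row-wise", {
  flanks <- data.frame(
    site = c("a", "b"),
    flank = c(paste0(strrep("A", 11), "GCAACGC", strrep("A", 13)),
              paste0(strrep("A", 15), "C", strrep("A", 15))),
    stringsAsFactors = FALSE)
  out <- stemloop_screen(flanks)
  expect_equal(out$qualifies, c(TRUE, FALSE))
  expect_equal(out$site, flanks$site)
})
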