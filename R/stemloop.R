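#' Stem-loop structural predicate for APOBEC3 substrate selection
#'
#' Decides whether the edited C at the center of a flanking-sequence window
#' sits at the 3' end of a putative tri- or tetra-loop hairpin closed by a
#' qualifying stem. The stem qualifies when it has at least 2 consecutive
#' Watson-Crick base pairs with perfect complementarity, or at least 4 pair
#' positions whose complementarity is imperfect by exactly one single-base
#' mismatch or one single-base bulge on one arm.
#'
#' Geometry: with the edited base at index `e` (window center) and loop
#' length `L` in {3, 4}, the loop occupies `window[e-L+1 .. e]`. Pair `i`
#' (i = 1, 2, ...) pairs `window[e-L-i+1]` on the 5' arm with `window[e+i]`
#' on the 3' arm; a bulge shifts one arm outward by one position for all
#' pairs beyond the bulge. Conventions (see the methods vignette for
#' rationale): the loop-closing pair (pair 1) and the outermost counted pair
#' must be true Watson-Crick pairs, so defects are strictly interior; at
#' most one defect is allowed; G:T (G:U) wobble pairs are non-complementary
#' unless `wobble = TRUE`; any pair involving N is non-complementary.
#'
#' When several geometries qualify, the returned call is the first under the
#' preference order: perfect stems before defective ones; loop length 3
#' before 4; longer stems within a category; mismatch before bulge; smaller
#' defect offset; 5' bulge before 3'.
#'
#' @param window a single character string over A/C/G/T/N of odd length
#'   >= 17 (k >= 8), with the edited C at the center, written 5' to 3' on
#'   the edited strand.
#' @param wobble logical; treat G:T as complementary (default FALSE).
#' @return A one-row data.frame (class `stemloop_call`) with columns
#'   `qualifies` (logical), `loop_len`, `stem_len` (number of paired
#'   positions), `defect` ("none", "mismatch", "bulge" or NA),
#'   `defect_offset` (pair index from the loop-closing pair), and
#'   `bulge_arm` ("five_prime"/"three_prime" or NA). When no geometry
#'   qualifies, `qualifies` is FALSE and the geometry columns are NA.
#' @seealso [enumerate_structures()] for the exhaustive enumeration of all
#'   qualifying geometries, [stemloop_screen()] for a table of windows.
#' @examples
#' # perfect 2-bp stem closing a tri-loop: 5'-G C A A C G C-3', the loop
#' # "AAC" ending at the window center
#' w <- paste0(strrep("A", 11), "GCAACGC", strrep("A", 13))
#' stemloop_predicate(w)
#' @export
stemloop_predicate <- function(window, wobble = FALSE) {
  w <- .check_window(window)
  n <- length(w)
  e <- (n + 1L) %/% 2L

  best <- NULL
  for (L in c(3L, 4L)) {
    # match vector under the unbulged alignment
    K <- min(e - L, n - e)
    if (K < 2L) next
    m <- .wc_pair(w[e - L - seq_len(K) + 1L], w[e + seq_len(K)], wobble)

    # perfect: maximal all-WC prefix
    run1 <- .prefix_run(m)
    if (run1 >= 2L) {
      best <- .better_call(best, list(
        category = 0L, loop_len = L, stem_len = run1,
        defect = "none", defect_offset = NA_integer_, bulge_arm = NA_character_
      ))
    }

    # single interior mismatch in a stem of >= 4 pair positions
    for (s in seq_len(K)) {
      if (s < 4L) next
      bad <- which(!m[seq_len(s)])
      if (length(bad) == 1L && bad >= 2L && bad <= s - 1L) {
        best <- .better_call(best, list(
          category = 1L, loop_len = L, stem_len = s,
          defect = "mismatch", defect_offset = bad, bulge_arm = NA_character_
        ))
      }
    }

    # single bulge between counted pairs j and j+1 on one arm
    for (arm in c("five_prime", "three_prime")) {
      Kb <- if (arm == "five_prime") min(e - L - 1L, n - e) else
        min(e - L, n - e - 1L)
      if (Kb < 4L) next
      for (j in seq_len(min(run1, Kb - 1L))) {
        # pairs 1..j unbulged (all WC by j <= run1); extend past the bulge
        i <- j + 1L
        run2 <- 0L
        while (i <= Kb) {
          i5 <- if (arm == "five_prime") e - L - i else e - L - i + 1L
          i3 <- if (arm == "three_prime") e + i + 1L else e + i
          if (!.wc_pair(w[i5], w[i3], wobble)) break
          run2 <- run2 + 1L
          i <- i + 1L
        }
        s <- j + run2
        if (run2 >= 1L && s >= 4L) {
          best <- .better_call(best, list(
            category = 1L, loop_len = L, stem_len = s,
            defect = "bulge", defect_offset = j, bulge_arm = arm
          ))
        }
      }
    }
  }

  if (is.null(best)) {
    call <- data.frame(
      qualifies = FALSE, loop_len = NA_integer_, stem_len = NA_integer_,
      defect = NA_character_, defect_offset = NA_integer_,
      bulge_arm = NA_character_, stringsAsFactors = FALSE
    )
  } else {
    call <- data.frame(
      qualifies = TRUE, loop_len = best$loop_len, stem_len = best$stem_len,
      defect = best$defect, defect_offset = best$defect_offset,
      bulge_arm = best$bulge_arm, stringsAsFactors = FALSE
    )
  }
  class(call) <- c("stemloop_call", class(call))
  call
}

#' Exhaustively enumerate all qualifying stem-loop geometries
#'
#' Brute-force enumeration of every (loop length, defect type, defect
#' position, stem length) combination that fits in the window, validating
#' each candidate geometry pair-by-pair. Serves as the independent oracle
#' for [stemloop_predicate()]: the predicate qualifies if and only if this
#' list is non-empty.
#'
#' @inheritParams stemloop_predicate
#' @return data.frame with one row per qualifying geometry (columns
#'   `loop_len`, `stem_len`, `defect`, `defect_offset`, `bulge_arm`);
#'   zero rows when nothing qualifies.
#' @export
enumerate_structures <- function(window, wobble = FALSE) {
  w <- .check_window(window)
  n <- length(w)
  e <- (n + 1L) %/% 2L
  rows <- list()
  add <- function(L, s, defect, off, arm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      loop_len = L, stem_len = s, defect = defect,
      defect_offset = off, bulge_arm = arm, stringsAsFactors = FALSE
    )
  }
  pair_ok <- function(i5, i3) {
    i5 >= 1L && i3 <= n && .wc_pair(w[i5], w[i3], wobble)
  }

  for (L in c(3L, 4L)) {
    K <- min(e - L, n - e)
    # perfect stems of every length s >= 2
    if (K >= 2L) {
      for (s in 2:K) {
        ok <- all(vapply(seq_len(s), function(i)
          pair_ok(e - L - i + 1L, e + i), logical(1)))
        if (ok) add(L, s, "none", NA_integer_, NA_character_)
      }
    }
    # one interior mismatch, s >= 4
    if (K >= 4L) {
      for (s in 4:K) {
        for (off in 2:(s - 1L)) {
          ok <- TRUE
          for (i in seq_len(s)) {
            hit <- pair_ok(e - L - i + 1L, e + i)
            if (i == off) hit <- !hit
            if (!hit) { ok <- FALSE; break }
          }
          if (ok) add(L, s, "mismatch", off, NA_character_)
        }
      }
    }
    # one bulge on one arm between pairs j and j+1, s >= 4
    for (arm in c("five_prime", "three_prime")) {
      Kb <- if (arm == "five_prime") min(e - L - 1L, n - e) else
        min(e - L, n - e - 1L)
      if (Kb < 4L) next
      for (s in 4:Kb) {
        for (j in seq_len(s - 1L)) {
          ok <- TRUE
          for (i in seq_len(s)) {
            shift5 <- if (arm == "five_prime" && i > j) 1L else 0L
            shift3 <- if (arm == "three_prime" && i > j) 1L else 0L
            if (!pair_ok(e - L - i + 1L - shift5, e + i + shift3)) {
              ok <- FALSE; break
            }
          }
          if (ok) add(L, s, "bulge", j, arm)
        }
      }
    }
  }

  if (length(rows) == 0L) {
    return(data.frame(
      loop_len = integer(), stem_len = integer(), defect = character(),
      defect_offset = integer(), bulge_arm = character(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Apply the stem-loop predicate to a table of flanking windows
#'
#' @param flanks data.frame with a `flank` column of edited-strand windows
#'   (see [to_edited_strand()]); other columns are carried through.
#' @param wobble passed to [stemloop_predicate()].
#' @return the input with the `stemloop_call` columns bound on.
#' @export
stemloop_screen <- function(flanks, wobble = FALSE) {
  stopifnot(is.data.frame(flanks), "flank" %in% names(flanks))
  calls <- do.call(rbind, lapply(flanks$flank, function(w) {
    as.data.frame(stemloop_predicate(w, wobble = wobble))
  }))
  cbind(flanks, calls)
}

.check_window <- function(window) {
  stopifnot(is.character(window), length(window) == 1L, !is.na(window))
  w <- strsplit(toupper(window), "")[[1]]
  n <- length(w)
  if (n %% 2L == 0L || n < 17L) {
    stop("window must have odd length >= 17 (k >= 8), got ", n)
  }
  if (!all(w %in% c("A", "C", "G", "T", "N"))) {
    stop("window contains characters outside A/C/G/T/N")
  }
  if (w[(n + 1L) %/% 2L] != "C") {
    stop("center base must be C (edited strand), got ", w[(n + 1L) %/% 2L])
  }
  w
}

.prefix_run <- function(m) {
  r <- 0L
  for (x in m) {
    if (!x) break
    r <- r + 1L
  }
  r
}

# preference: perfect < defective; loop 3 < 4; longer stem; mismatch < bulge;
# smaller offset; 5' arm first
.better_call <- function(cur, cand) {
  rank <- function(c_) {
    list(
      c_$category,
      c_$loop_len,
      -c_$stem_len,
      if (identical(c_$defect, "bulge")) 1L else 0L,
      if (is.na(c_$defect_offset)) 0L else c_$defect_offset,
      if (identical(c_$bulge_arm, "three_prime")) 1L else 0L
    )
  }
  if (is.null(cur)) return(cand)
  a <- rank(cand); b <- rank(cur)
  for (i in seq_along(a)) {
    if (a[[i]] < b[[i]]) return(cand)
    if (a[[i]] > b[[i]]) return(cur)
  }
  cur
}
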