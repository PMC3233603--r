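library(tibble)

toy_pairs <- function() {
  # crafted 20-pair candidate list over a 50-column toy family
  tibble(
    i = c(3, 3, 1, 10, 12, 2, 5, 40, 8, 15, 20, 22, 30, 31, 7, 9, 11, 25, 18, 6),
    j = c(8, 9, 30, 40, 18, 7, 45, 46, 14, 22, 26, 29, 44, 38, 13, 16, 48, 33, 24, 12),
    di = seq(2, 0.1, length.out = 20)
  )
}

test_that("minimum-separation filter retains exactly |i-j| > minsep", {
  pairs <- tibble(i = c(3, 3), j = c(8, 9), di = c(1, 1))
  out <- filter_min_separation(pairs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$j, 9)
  expect_equal(nrow(filter_min_separation(pairs[0, ])), 0L)

  toy <- toy_pairs()
  out2 <- filter_min_separation(toy)
  # brute-force count on the fixture
  expect_equal(nrow(out2), sum(toy$j - toy$i > 5))
  expect_true(all(out2$j - out2$i > 5))
})

test_that("conservation filter removes pairs touching near-invariant columns", {
  # column 2 is 95% A (19/20 rows), column 5 fully conserved
  set.seed(2)
  mat <- matrix(sample.int(20, 20 * 6, replace = TRUE), 20, 6)
  mat[, 2] <- 1L; mat[1, 2] <- 2L
  mat[, 5] <- 3L
  aln <- alignment(mat)
  cons <- conservation_fraction(aln)
  expect_equal(cons[2], 0.95)
  expect_equal(cons[5], 1)

  pairs <- tibble(i = c(1, 2, 3, 1, 4), j = c(3, 4, 5, 6, 6),
                  di = c(5, 4, 3, 2, 1))
  out <- filter_conservation(pairs, cons, threshold = 0.9)
  # brute-force: remove any pair touching columns 2 or 5
  oracle <- pairs[!(pairs$i %in% c(2, 5) | pairs$j %in% c(2, 5)), ]
  expect_tibble_equal_pairs(out, oracle)

  # threshold 1.0: only the fully conserved column is caught by > comparison
  out2 <- filter_conservation(pairs, cons, threshold = 1.0)
  expect_equal(nrow(out2), nrow(pairs))
})

test_that("cysteine exclusivity keeps one partner per cysteine, by rank", {
  letters_row <- rep("A", 80)
  letters_row[c(5, 40, 70)] <- "C"
  ref <- paste(letters_row, collapse = "")
  aln <- aln_from_letters(c(ref, ref))
  pairs <- tibble(i = c(5, 5, 40), j = c(40, 70, 70), di = c(0.9, 0.4, 0.2))
  out <- filter_cysteine_exclusivity(pairs, aln)
  # greedy: (5,40) taken, (5,70) reuses 5, (40,70) reuses 40 -> 1 survivor
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$i, out$j), c(5, 40))

  # non-cysteine pairs pass untouched
  pairs2 <- tibble(i = c(1, 2), j = c(20, 30), di = c(1, 1))
  expect_equal(nrow(filter_cysteine_exclusivity(pairs2, aln)), 2L)
})

test_that("same-segment pairs conflict with predicted secondary structure", {
  ss <- ss_track(c(rep("H", 10), rep("C", 5), rep("E", 5), rep("C", 5),
                   rep("E", 5)))
  pairs <- tibble(i = c(2, 2, 16, 16, 12), j = c(8, 18, 19, 27, 14),
                  di = 5:1)
  out <- filter_ss_conflict(pairs, ss)
  # removed: (2,8) same helix, (16,19) same strand; coil pairs pass
  expect_tibble_equal_pairs(out, tibble(i = c(2, 16, 12), j = c(18, 27, 14)))
})

test_that("filters are order-independent apart from the rank-greedy cysteine rule", {
  set.seed(6)
  mat <- matrix(sample.int(20, 30 * 50, replace = TRUE), 30, 50)
  mat[, 7] <- 1L
  aln <- alignment(mat)
  cons <- conservation_fraction(aln)
  ss <- ss_track(c(rep("H", 12), rep("C", 10), rep("E", 8), rep("C", 20)))
  toy <- toy_pairs()
  f1 <- function(p) filter_min_separation(p)
  f2 <- function(p) filter_ss_conflict(p, ss)
  f3 <- function(p) filter_conservation(p, cons, 0.9)
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  results <- lapply(perms, function(ord) {
    out <- toy
    for (k in ord) out <- list(f1, f2, f3)[[k]](out)
    out
  })
  expect_tibble_equal_pairs(results[[1]], results[[2]])
  expect_tibble_equal_pairs(results[[1]], results[[3]])
})

test_that("select_eics returns ranked survivors with an audit trail", {
  expect_error(select_eics(toy_pairs(), n_c = 0))

  # no filters that remove anything: top-n by DI with (i,j) tie-break
  tied <- tibble(i = c(2, 1, 1), j = c(30, 40, 20), di = c(1, 1, 1))
  out <- select_eics(tied, n_c = 3, filters = character(0))
  expect_equal(out$i, c(1, 1, 2))
  expect_equal(out$j, c(20, 40, 30))

  ss <- ss_track(c(rep("H", 10), rep("C", 40)))
  set.seed(3)
  mat <- matrix(sample.int(20, 20 * 50, replace = TRUE), 20, 50)
  aln <- alignment(mat)
  toy <- toy_pairs()
  eics <- select_eics(toy, n_c = 5, ss = ss, aln = aln)
  # oracle recomputation by explicit set difference
  surv <- filter_min_separation(toy)
  surv <- filter_ss_conflict(surv, ss)
  surv <- filter_conservation(surv, conservation_fraction(aln), 0.9)
  surv <- filter_cysteine_exclusivity(surv, aln)
  expect_equal(eics$i, surv$i[1:5])
  expect_equal(eics$j, surv$j[1:5])
  audit <- eic_audit(eics)
  expect_true(all(c("i", "j", "rule") %in% names(audit)))
  expect_equal(nrow(audit), nrow(toy) - nrow(surv))

  # fewer survivors than requested: all returned, warning + flag
  expect_warning(short <- select_eics(toy, n_c = 1000), "survive")
  expect_true(attr(short, "short"))
})

test_that("EIC sets are prefix-monotone in n_c", {
  toy <- toy_pairs()
  a <- select_eics(toy, n_c = 5, filters = "min_separation")
  b <- select_eics(toy, n_c = 15, filters = "min_separation")
  expect_equal(a$i, b$i[seq_len(nrow(a))])
  expect_equal(a$j, b$j[seq_len(nrow(a))])
  expect_equal(a$di, b$di[seq_len(nrow(a))])
})

test_that("the N_C grid runs from 30 to L in steps of 10", {
  expect_equal(nc_grid(71), seq(30, 70, 10))
  expect_equal(nc_grid(160), seq(30, 160, 10))
  expect_equal(nc_grid(25), 20)
})

test_that("secondary-structure tracks parse from both dialects", {
  f <- withr::local_tempfile(fileext = ".ss")
  writeLines(c("# pos state conf", "1 H 0.9", "2 H 0.8", "3 C 0.5",
               "4 E 0.7"), f)
  ss <- read_ss_track(f)
  expect_equal(ss$state, c("H", "H", "C", "E"))
  expect_equal(ss$confidence, c(0.9, 0.8, 0.5, 0.7))

  f2 <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("1 M C 0.9 0.1 0.0", "2 K H 0.1 0.8 0.1",
               "3 V E 0.0 0.2 0.8"), f2)
  ss2 <- read_ss_track(f2)
  expect_equal(ss2$state, c("C", "H", "E"))
  expect_equal(ss2$confidence, c(0.9, 0.8, 0.8))

  segs <- ss_segments(ss_track(c("H", "H", "H", "C", "E", "E")))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$length, c(3L, 2L))
})
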