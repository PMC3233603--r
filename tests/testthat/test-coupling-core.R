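test_that("frequency counting matches direct counts and pseudocount limits", {
  # one sequence, lambda = 0: indicator frequencies
  one <- aln_from_letters("ACD")
  w1 <- compute_weights(one)
  ft <- suppressWarnings(count_frequencies(w1, lambda = 0))
  expect_equal(ft$fi[1, ], as.numeric(1:21 == 1))
  expect_equal(ft$fi[2, ], as.numeric(1:21 == 2))

  # two equally weighted sequences AC and AD: fi(2,C) = fi(2,D) = 0.5
  two <- aln_from_letters(c("AC", "AD"))
  ft2 <- suppressWarnings(count_frequencies(compute_weights(two), lambda = 0))
  expect_equal(ft2$fi[2, encode_residue("C")], 0.5)
  expect_equal(ft2$fi[2, encode_residue("D")], 0.5)

  # lambda -> infinity: uniform
  big <- count_frequencies(compute_weights(two), lambda = 1e9)
  expect_equal(big$fi, matrix(1 / 21, 2, 21), tolerance = 1e-6)
  expect_equal(max(abs(fij_block_test(big, 1, 2) - 1 / 441)), 0,
               tolerance = 1e-6)
})

test_that("frequency tables satisfy normalization and marginal consistency", {
  aln <- random_alignment(40, 6, seed = 8)
  ft <- count_frequencies(compute_weights(aln))
  expect_equal(rowSums(ft$fi), rep(1, 6), tolerance = 1e-9)
  for (i in 1:5) for (j in (i + 1):6) {
    blk <- fij_block_test(ft, i, j)
    expect_equal(sum(blk), 1, tolerance = 1e-9)
    expect_equal(rowSums(blk), ft$fi[i, ], tolerance = 1e-9)
    expect_equal(colSums(blk), ft$fi[j, ], tolerance = 1e-9)
    expect_equal(blk, t(fij_block_test(ft, j, i)), tolerance = 1e-12)
  }
})

test_that("pair-excess matrix equals hand arithmetic and is symmetric", {
  # L=2, q=2 system with fij diag (0.4, 0.4), off-diag (0.1, 0.1)
  fi <- matrix(0.5, 2, 2)
  fij <- array(0, c(2, 2, 2, 2))
  fij[1, 2, , ] <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  fij[2, 1, , ] <- t(fij[1, 2, , ])
  ft <- freq_tables_from_marginals(fi, fij)
  C <- pair_excess_matrix(ft)
  expect_equal(C[1, 2], 0.4 - 0.25)
  expect_equal(C, t(C), tolerance = 1e-12)

  # independent columns at exact product frequencies: off-diagonal zero
  fi2 <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  fij2 <- array(0, c(2, 2, 2, 2))
  fij2[1, 2, , ] <- outer(fi2[1, ], fi2[2, ])
  fij2[2, 1, , ] <- t(fij2[1, 2, , ])
  C2 <- pair_excess_matrix(freq_tables_from_marginals(fi2, fij2))
  expect_equal(C2[1, 2], 0, tolerance = 1e-12)

  # symmetry on a random fixture
  aln <- random_alignment(30, 5, seed = 4)
  Cr <- pair_excess_matrix(count_frequencies(compute_weights(aln)))
  expect_equal(Cr, t(Cr), tolerance = 1e-12)
})

test_that("coupling inversion matches the closed-form 2x2 solution", {
  fi <- matrix(0.5, 2, 2)
  fij <- array(0, c(2, 2, 2, 2))
  fij[1, 2, , ] <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  fij[2, 1, , ] <- t(fij[1, 2, , ])
  ft <- freq_tables_from_marginals(fi, fij)
  C <- pair_excess_matrix(ft)
  cm <- invert_for_couplings(C)
  # hand 2x2 inversion: C = [[0.25, 0.15], [0.15, 0.25]],
  # (C^-1)_12 = -0.15/det, e_12 = +0.15/det
  det2 <- 0.25 * 0.25 - 0.15 * 0.15
  expect_equal(eij_block(cm, 1, 2)[1, 1], 0.15 / det2, tolerance = 1e-9)
  # gap-state entries zero in the stored gauge
  expect_equal(eij_block(cm, 1, 2)[2, ], c(0, 0))
  expect_equal(eij_block(cm, 1, 2)[, 2], c(0, 0))

  # independent columns -> all couplings zero
  aln <- random_alignment(50, 4, seed = 6)
  ftr <- count_frequencies(compute_weights(aln))
  blockdiag <- ftr
  # exact product fij makes C block-diagonal
  fiX <- ftr$fi
  fijX <- array(0, c(4, 4, 21, 21))
  for (i in 1:4) for (j in 1:4) if (i != j)
    fijX[i, j, , ] <- outer(fiX[i, ], fiX[j, ])
  cm0 <- invert_for_couplings(pair_excess_matrix(
    freq_tables_from_marginals(fiX, fijX)))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(max(abs(eij_block(cm0, i, j))), 0, tolerance = 1e-7)
  }

  # e symmetric under (i,j,A,B) -> (j,i,B,A)
  cmr <- invert_for_couplings(pair_excess_matrix(ftr))
  expect_equal(eij_block(cmr, 1, 3), t(eij_block(cmr, 3, 1)),
               tolerance = 1e-10)
})

test_that("singular pair-excess matrix raises an inversion error", {
  dup <- alignment(matrix(rep(c(1:5), each = 3), nrow = 3))
  suppressWarnings(ft <- count_frequencies(compute_weights(dup), lambda = 0))
  expect_error(invert_for_couplings(pair_excess_matrix(ft)),
               class = "dcafold_inversion")
})

test_that("pair-field fitting reproduces marginals; zero coupling gives product", {
  fi_i <- c(0.5, 0.3, 0.2)
  fi_j <- c(0.1, 0.6, 0.3)
  pd0 <- fit_pair_fields(matrix(0, 3, 3), fi_i, fi_j)
  expect_equal(pd0$pdir, outer(fi_i, fi_j), tolerance = 1e-6)
  expect_lt(pd0$tol_achieved, 1e-4)
  expect_equal(direct_information(pd0, fi_i, fi_j), 0, tolerance = 1e-8)

  # q=2 diagonal-favoring coupling, uniform marginals: brute-force oracle
  e <- matrix(c(1, 0, 0, 1), 2, 2)
  pd <- fit_pair_fields(e, c(0.5, 0.5), c(0.5, 0.5))
  # oracle: symmetric 2x2 solve - P ~ exp(e + hi + hj), marginals 1/2 force
  # hi = hj by symmetry; root-find the field
  f <- function(h) {
    P <- exp(e + h * outer(c(1, -1), c(0, 0), "+") )
    P
  }
  # independent root-finding on the single free parameter a = exp(2h1')
  g <- function(a) {
    P <- matrix(c(exp(1) * a, 1, 1, exp(1) / a), 2, 2)
    P <- P / sum(P)
    rowSums(P)[1] - 0.5
  }
  a <- stats::uniroot(g, c(0.01, 100))$root
  P_oracle <- matrix(c(exp(1) * a, 1, 1, exp(1) / a), 2, 2)
  P_oracle <- P_oracle / sum(P_oracle)
  expect_equal(pd$pdir, P_oracle, tolerance = 1e-3)
  expect_gt(sum(diag(pd$pdir)), 0.5)

  # any converged output matches its marginals within tol
  set.seed(12)
  for (k in 1:5) {
    q <- sample(3:6, 1)
    e <- matrix(rnorm(q * q, sd = 0.5), q, q)
    fa <- prop.table(runif(q) + 0.1)
    fb <- prop.table(runif(q) + 0.1)
    pd <- fit_pair_fields(e, fa, fb)
    expect_lt(max(abs(rowSums(pd$pdir) - fa)), 1e-4)
    expect_lt(max(abs(colSums(pd$pdir) - fb)), 1e-4)
    expect_true(all(pd$pdir > 0))
  }
})

test_that("direct and mutual information match textbook values and oracles", {
  # DI of a perfectly correlated binary direct distribution = ln 2
  pd <- structure(list(pdir = diag(c(0.5, 0.5))), class = "pair_direct")
  expect_equal(direct_information(pd, c(0.5, 0.5), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)

  # MI: perfectly correlated binary columns at lambda 0
  aln <- aln_from_letters(c("AA", "CC"))
  ft <- count_frequencies(compute_weights(aln), lambda = 0)
  expect_equal(mutual_information(ft, 1, 2), log(2), tolerance = 1e-12)

  # independent product table -> MI 0
  fi2 <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  fij2 <- array(0, c(2, 2, 2, 2))
  fij2[1, 2, , ] <- outer(fi2[1, ], fi2[2, ])
  fij2[2, 1, , ] <- t(fij2[1, 2, , ])
  ft2 <- freq_tables_from_marginals(fi2, fij2)
  expect_equal(mutual_information(ft2, 1, 2), 0, tolerance = 1e-12)

  # three-state hand table vs brute-force double-sum oracle
  tab <- matrix(c(0.2, 0.05, 0.05, 0.05, 0.3, 0.05, 0.05, 0.05, 0.2), 3, 3)
  fi3 <- rbind(rowSums(tab), colSums(tab))
  fij3 <- array(0, c(2, 2, 3, 3))
  fij3[1, 2, , ] <- tab
  fij3[2, 1, , ] <- t(tab)
  ft3 <- freq_tables_from_marginals(fi3, fij3)
  expect_equal(mutual_information(ft3, 1, 2),
               oracle_mi(tab, fi3[1, ], fi3[2, ]), tolerance = 1e-12)
})

test_that("score table is symmetric in construction and order-invariant", {
  aln <- random_alignment(60, 8, q = 6, seed = 10)
  # recode into q=21 space is unnecessary: q carried by the alignment
  w <- compute_weights(aln)
  st <- score_all_pairs(w)
  expect_equal(st$di, t(st$di), tolerance = 1e-10)
  expect_equal(st$mi, t(st$mi), tolerance = 1e-10)
  expect_true(all(st$di >= -1e-10))

  perm <- sample(60)
  alnp <- alignment(aln$matrix[perm, , drop = FALSE])
  stp <- score_all_pairs(compute_weights(alnp))
  expect_equal(stp$di, st$di, tolerance = 1e-9)
  expect_equal(stp$mi, st$mi, tolerance = 1e-9)
})

test_that("identical sequences yield a featureless, uniform DI landscape", {
  # fully conserved alignment: the pseudocount mixture induces an identical
  # apparent coupling at every pair (the reason conserved columns are
  # filtered before contact selection), so no pair is distinguished
  set.seed(20)
  aln <- alignment(matrix(rep(sample.int(20, 10), each = 6), nrow = 6))
  st <- suppressWarnings(score_all_pairs(compute_weights(aln)))
  vals <- st$di[upper.tri(st$di)]
  expect_lt(diff(range(vals)), 1e-8)
  cons <- conservation_fraction(aln)
  survivors <- filter_conservation(tidy(st), cons, 0.9)
  expect_equal(nrow(survivors), 0L)
})

test_that("DI suppresses transitive correlations that MI reports", {
  pm <- chain_potts(L = 3, q = 3, strength = 1, seed = 42)
  marg <- enumerate_marginals(pm)
  ft <- freq_tables_from_marginals(marg$fi, marg$fij, lambda = 0.01)
  st <- score_from_freqs(ft)
  expect_lt(st$di[1, 3], min(st$di[1, 2], st$di[2, 3]))
  expect_lt(st$di[1, 3], 0.05 * st$di[1, 2])
  expect_gt(st$mi[1, 3], 0.01)
})

test_that("mean-field couplings recover planted sign structure on exact marginals", {
  # weak couplings: inferred e correlates with planted e on coupled pairs
  pm <- chain_potts(L = 4, q = 3, strength = 0.3, seed = 15)
  marg <- enumerate_marginals(pm)
  ft <- freq_tables_from_marginals(marg$fi, marg$fij, lambda = 0.01)
  cm <- invert_for_couplings(pair_excess_matrix(ft))
  for (key in names(pm$couplings)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    planted <- pm$couplings[[key]][1:2, 1:2]
    inferred <- eij_block(cm, ij[1], ij[2])[1:2, 1:2]
    # same zero-q gauge: compare double-centered blocks
    ctr <- function(m) sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) +
      mean(m)
    expect_gt(cor(as.numeric(ctr(planted)), as.numeric(ctr(inferred))), 0.8)
  }
})

test_that("DI ranking is gauge-invariant under row/column shifts of couplings", {
  pm <- chain_potts(L = 4, q = 3, strength = 0.8, seed = 33)
  marg1 <- enumerate_marginals(pm)
  # shift a constant onto one row of the (1,2) coupling: gauge-equivalent
  # to a field change, so the coupled/uncoupled DI separation must persist
  pm2 <- pm
  pm2$couplings[["1_2"]][2, ] <- pm2$couplings[["1_2"]][2, ] + 1.5
  marg2 <- enumerate_marginals(pm2)
  st1 <- score_from_freqs(freq_tables_from_marginals(marg1$fi, marg1$fij,
                                                     lambda = 0.01))
  st2 <- score_from_freqs(freq_tables_from_marginals(marg2$fi, marg2$fij,
                                                     lambda = 0.01))
  planted <- c("1 2", "2 3", "3 4")
  for (st in list(st1, st2)) {
    tt <- tidy(st)
    top <- paste(tt$i, tt$j)[seq_along(planted)]
    expect_setequal(top, planted)
  }
})

test_that("oversized alignments are refused with a resource error", {
  ft <- structure(list(L = 400L, q = 21L), class = "freq_tables")
  expect_error(pair_excess_matrix(ft), class = "dcafold_resource")
})
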