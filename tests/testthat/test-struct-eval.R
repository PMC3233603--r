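library(tibble)

test_that("reference contact maps follow the min-heavy-atom rule", {
  # two-residue toy: closest atoms at 4.9 A -> contact; 5.1 A -> none
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, list(matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3, byrow = TRUE),
                        matrix(c(6.4, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)))
  cm <- contacts_from_reference(f)
  expect_equal(nrow(cm), 1L)          # 6.4 - 1.5 = 4.9
  expect_equal(cm$dist, 4.9, tolerance = 1e-6)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f2, list(matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3, byrow = TRUE),
                         matrix(c(6.6, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(nrow(contacts_from_reference(f2)), 0L)
})

test_that("contact maps equal a brute-force all-atom double loop", {
  set.seed(9)
  res <- lapply(1:5, function(r)
    matrix(rnorm(9, mean = 4 * r, sd = 2), 3, 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, res)
  cm <- contacts_from_reference(f, threshold = 6)
  oracle <- list()
  for (a in 1:4) for (b in (a + 1):5) {
    mind <- Inf
    for (x in 1:3) for (y in 1:3) {
      mind <- min(mind, sqrt(sum((res[[a]][x, ] - res[[b]][y, ])^2)))
    }
    if (mind < 6) oracle[[length(oracle) + 1L]] <- c(a, b)
  }
  expect_equal(nrow(cm), length(oracle))
  expect_setequal(paste(cm$i, cm$j),
                  vapply(oracle, function(p) paste(p[1], p[2]), ""))
})

test_that("contact metrics match brute-force recomputation", {
  obs <- structure(tibble(i = c(1, 5, 10, 3), j = c(20, 30, 40, 25),
                          dist = 4, sep = c(19, 25, 30, 22)),
                   class = c("contact_map", class(tibble())))
  # predicted subset of observed -> tp 1, fp_severity 0
  pred_in <- tibble(i = c(1, 10), j = c(20, 40))
  expect_equal(true_positive_rate(pred_in, obs, 2), 1.0)
  expect_equal(fp_severity(pred_in, obs, 2), 0)
  # disjoint -> tp 0
  pred_out <- tibble(i = c(2, 6), j = c(9, 35))
  expect_equal(true_positive_rate(pred_out, obs, 2), 0)
  # crafted: 13 hits of 20
  hits <- tibble(i = rep(1, 13), j = rep(20, 13))
  misses <- tibble(i = 2:8, j = c(50, 51, 52, 53, 54, 55, 56))
  both <- dplyr::bind_rows(hits, misses)
  expect_equal(true_positive_rate(both, obs, 20), 13 / 20)

  # single prediction (10,20), nearest observed (10,22) -> 2.0
  obs2 <- structure(tibble(i = 10, j = 22, dist = 4, sep = 12),
                    class = c("contact_map", class(tibble())))
  expect_equal(fp_severity(tibble(i = 10, j = 20), obs2, 1), 2.0)
  # spread: one observed contact, nearest prediction 5 units away
  expect_equal(contact_spread(tibble(i = 10, j = 27), obs2, 1), 5.0)
  # predicted superset of observed -> spread 0
  expect_equal(contact_spread(dplyr::bind_rows(obs2, pred_out), obs2, 3), 0)

  # random fixture vs O(P*O) oracle
  set.seed(31)
  P <- tibble(i = sample(1:30, 15), j = sample(31:60, 15))
  O <- structure(tibble(i = sample(1:30, 12), j = sample(31:60, 12),
                        dist = 4, sep = 20),
                 class = c("contact_map", class(tibble())))
  fp_o <- mean(apply(P, 1, function(p)
    min(sqrt((O$i - p[1])^2 + (O$j - p[2])^2))))
  expect_equal(fp_severity(P, O, 15), fp_o)
  sp_o <- mean(apply(O[, 1:2], 1, function(o)
    min(sqrt((P$i - o[1])^2 + (P$j - o[2])^2))))
  expect_equal(contact_spread(P, O, 15), sp_o)

  expect_error(fp_severity(P, O[0, ], 5), "empty")
  # fp_severity(X, X) = spread(X, X) = 0
  expect_equal(fp_severity(O, O, 12), 0)
  expect_equal(contact_spread(O, O, 12), 0)
})

test_that("tp_rate over sorted all-hits-first predictions is non-increasing in n_c", {
  obs <- structure(tibble(i = 1:8, j = 21:28, dist = 4, sep = 20),
                   class = c("contact_map", class(tibble())))
  pred <- tibble(i = c(1:8, 9:12), j = c(21:28, 50:53))
  rates <- vapply(c(2, 4, 8, 10, 12),
                  function(nc) true_positive_rate(pred, obs, nc), numeric(1))
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("Kabsch superposition is exact, proper, and matches oracles", {
  set.seed(14)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(p, p), 0, tolerance = 1e-12)

  R <- dcafold:::rotation_matrix(c(1, -2, 0.5), 0.9)
  q <- p %*% R + matrix(c(3, 4, 5), 10, 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(p, q), 0, tolerance = 1e-9)

  # reflection must NOT be absorbed (proper rotation only)
  mir <- p %*% diag(c(1, 1, -1))
  expect_gt(kabsch_rmsd(p[1:4, ], mir[1:4, ]), 1e-3)

  # cross-check against an independent superposition implementation
  set.seed(15)
  a <- matrix(rnorm(24), 8, 3); b <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_rmsd(a, b),
               as.numeric(bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)),
                                      fit = TRUE)),
               tolerance = 1e-4)

  # grid-search oracle on a small 4-point problem
  set.seed(16)
  x <- matrix(rnorm(12), 4, 3); y <- matrix(rnorm(12), 4, 3)
  grid <- seq(0, 2 * pi, length.out = 25)[-25]
  best <- Inf
  for (a1 in grid) for (a2 in seq(0, pi, length.out = 13)) for (a3 in grid) {
    R <- dcafold:::rotation_matrix(c(0, 0, 1), a1) %*%
      dcafold:::rotation_matrix(c(0, 1, 0), a2) %*%
      dcafold:::rotation_matrix(c(0, 0, 1), a3)
    xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
    best <- min(best, sqrt(mean(rowSums((xc %*% R - yc)^2))))
  }
  expect_equal(kabsch_rmsd(x, y), best, tolerance = 0.02)
  expect_lte(kabsch_rmsd(x, y), best + 1e-9)

  # degenerate collinear input still returns a finite value
  lin <- cbind(1:5, 0, 0)
  expect_true(is.finite(kabsch_rmsd(lin, lin + 1)))
})

test_that("trimmed RMSD rejects outliers and respects the retention floor", {
  set.seed(17)
  p <- matrix(rnorm(60), 20, 3) * 4
  tr0 <- trimmed_rmsd(p, p)
  expect_equal(tr0$rmsd, 0, tolerance = 1e-12)
  expect_equal(tr0$n_used, 20L)

  q <- p
  q[c(3, 11, 17), ] <- q[c(3, 11, 17), ] + 40
  tr <- trimmed_rmsd(p, q)
  expect_equal(tr$n_used, 17L)
  expect_setequal(setdiff(1:20, tr$used), c(3, 11, 17))
  expect_lt(tr$rmsd, 1e-6)

  # all-noise pair: trimming floor triggers the flag or keeps everything
  set.seed(18)
  a <- matrix(rnorm(45), 15, 3) * 10
  b <- matrix(rnorm(45), 15, 3) * 10
  tra <- trimmed_rmsd(a, b, max_cycles = 20, sigma_cut = 0.5)
  expect_true(tra$flagged)
})

test_that("TM-score and GDT-TS behave like their definitions", {
  h <- helix_hairpin(n_helix = 12, n_turn = 4)$ca
  expect_equal(tm_score(h, h), 1.0, tolerance = 1e-9)
  expect_equal(gdt_ts(h, h), 100, tolerance = 1e-9)

  R <- dcafold:::rotation_matrix(c(1, 1, 0), 2)
  moved <- h %*% R + matrix(c(10, 0, -4), nrow(h), 3, byrow = TRUE)
  expect_equal(tm_score(moved, h), 1.0, tolerance = 1e-6)

  set.seed(19)
  noisy <- h + matrix(rnorm(length(h), sd = 2), nrow(h), 3)
  tm <- tm_score(noisy, h)
  expect_true(tm > 0 && tm <= 1)
  g <- gdt_ts(noisy, h)
  expect_true(g >= 0 && g <= 100)

  # small fixture vs exhaustive fragment-seed oracle: every contiguous
  # window superposition, scored over all residues
  p <- noisy[1:14, ]; q <- h[1:14, ]
  d0 <- 0.5   # Lref <= 15 floor
  oracle <- 0
  for (w in 3:14) for (s in 1:(14 - w + 1)) {
    sub <- s:(s + w - 1)
    fit <- kabsch_superpose(p[sub, , drop = FALSE], q[sub, , drop = FALSE])
    allp <- sweep(sweep(p, 2, colMeans(p[sub, , drop = FALSE])) %*% t(fit$R),
                  2, colMeans(q[sub, , drop = FALSE]), "+")
    d <- sqrt(rowSums((allp - q)^2))
    oracle <- max(oracle, mean(1 / (1 + (d / d0)^2)))
  }
  expect_gte(tm_score(p, q) + 0.01, oracle)
})

test_that("model-side contacts use the labelled C-beta proxy definition", {
  hh <- helix_hairpin(n_helix = 10, n_turn = 4)
  m <- dcafold:::new_fold_model(hh$ca)
  cm <- contacts_from_model(m, threshold = 8, min_sep = 5)
  expect_equal(attr(cm, "definition"), "cb_proxy")
  d <- as.matrix(dist(m$cb))
  oracle <- sum(upper.tri(d) & d < 8 & (col(d) - row(d)) > 5)
  expect_equal(nrow(cm), oracle)
})

test_that("evaluation reports bundle contact and structure metrics", {
  hh <- helix_hairpin(n_helix = 10, n_turn = 4)
  m <- dcafold:::new_fold_model(hh$ca)
  obs <- contacts_from_model(m, threshold = 8, min_sep = 5)
  pred <- as_tibble(obs)[, c("i", "j")]
  rep <- evaluate_prediction(pred, obs, model = m, reference = hh$ca,
                             nc_values = c(2, 5))
  expect_equal(rep$tp_rate, c(1, 1))
  sm <- structure_metrics(rep)
  expect_equal(sm$ca_rmsd, 0, tolerance = 1e-9)
  expect_equal(sm$tm, 1, tolerance = 1e-9)
  expect_equal(sm$gdt_ts, 100, tolerance = 1e-9)
})
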