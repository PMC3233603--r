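# shared fixtures and independent oracles, built in code at test time

# alignment from a character matrix of residue letters
aln_from_letters <- function(rows, ...) {
  mat <- do.call(rbind, lapply(rows, function(s) encode_residue(strsplit(s, "")[[1]])))
  alignment(mat, ...)
}

# random integer alignment
random_alignment <- function(m, l, q = 21, seed = 1) {
  set.seed(seed)
  alignment(matrix(sample.int(q, m * l, replace = TRUE), m, l))
}

# chain-topology Potts model with couplings on consecutive pairs
chain_potts <- function(L = 5, q = 3, strength = 1, seed = 42) {
  set.seed(seed)
  cps <- list()
  for (i in seq_len(L - 1)) {
    g <- matrix(rnorm(q * q), q, q)
    cps[[paste0(i, "_", i + 1)]] <- strength * (g + t(g)) / 2
  }
  potts_model(L, q, couplings = cps)
}

# planted-contact model on random long-range pairs
planted_potts <- function(L, q, n_pairs, strength = 1, seed = 7,
                          min_sep = 5) {
  set.seed(seed)
  z <- matrix(0, L, L)
  allp <- which(upper.tri(z) & (col(z) - row(z)) > min_sep, arr.ind = TRUE)
  sel <- allp[sample(nrow(allp), n_pairs), , drop = FALSE]
  sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
  cps <- list()
  for (k in seq_len(n_pairs)) {
    g <- matrix(rnorm(q * q), q, q)
    cps[[paste0(sel[k, 1], "_", sel[k, 2])]] <- strength * (g + t(g)) / 2
  }
  list(model = potts_model(L, q, couplings = cps),
       pairs = tibble::tibble(i = sel[, 1], j = sel[, 2]))
}

# brute-force mutual information of two columns from a frequency table
oracle_mi <- function(fij, fi, fj) {
  s <- 0
  for (a in seq_along(fi)) for (b in seq_along(fj)) {
    if (fij[a, b] > 0) s <- s + fij[a, b] * log(fij[a, b] / (fi[a] * fj[b]))
  }
  s
}

# brute-force pairwise-identity weights
oracle_weights <- function(mat, theta) {
  m <- nrow(mat)
  n <- integer(m)
  for (s in seq_len(m)) {
    for (t in seq_len(m)) {
      if (mean(mat[s, ] == mat[t, ]) >= theta) n[s] <- n[s] + 1L
    }
  }
  1 / n
}

# Fox 3-coloring count of a knot diagram: independent knottedness oracle.
# crossings: list of (under_pos, over_pos) as produced by the package's
# projection; arcs delimited by underpasses. The unknot admits 3 colorings,
# the trefoil 9.
count_three_colorings <- function(coords, closed = TRUE) {
  P <- coords
  cr <- dcafold:::find_crossings(P)
  n <- length(cr)
  if (n == 0) return(3L)
  under <- vapply(cr, `[[`, numeric(1), "under_pos")
  over <- vapply(cr, `[[`, numeric(1), "over_pos")
  ord <- order(under)
  us <- under[ord]
  arc_of <- function(pos) {
    idx <- findInterval(pos, us)
    ifelse(idx == 0, n, idx)
  }
  cols <- as.matrix(do.call(expand.grid, rep(list(0:2), n)))
  ok <- rep(TRUE, nrow(cols))
  for (r in seq_len(n)) {
    k_in <- if (r == 1) n else r - 1
    k_out <- r
    i_over <- arc_of(over[ord[r]])
    ok <- ok & ((2 * cols[, i_over] - cols[, k_in] - cols[, k_out]) %% 3 == 0)
  }
  sum(ok)
}

# small PDB text written through bio3d, with atoms at given coordinates
write_toy_pdb <- function(path, res_atoms) {
  xyz <- numeric(0); resno <- integer(0); elety <- character(0)
  for (r in seq_along(res_atoms)) {
    at <- res_atoms[[r]]
    for (k in seq_len(nrow(at))) {
      xyz <- c(xyz, at[k, ])
      resno <- c(resno, r)
      elety <- c(elety, c("N", "CA", "C", "O", "CB", "CG")[min(k, 6)])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno,
                   resid = rep("ALA", length(resno)), elety = elety,
                   chain = "A")
  path
}

expect_tibble_equal_pairs <- function(a, b) {
  expect_setequal(paste(a$i, a$j), paste(b$i, b$j))
}

fij_block_test <- function(ft, i, j) dcafold:::fij_block(ft, i, j)
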