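#' Pseudocounted frequency tables from a weighted alignment
#'
#' Single-column and pair-column amino-acid frequencies with uniform
#' pseudocount mass `lambda`:
#' \deqn{f_i(A) = (\lambda/q + \sum_s w_s [A_i^s = A]) / (\lambda + M_{eff})}
#' \deqn{f_{ij}(A,B) = (\lambda/q^2 + \sum_s w_s [A_i^s=A][A_j^s=B]) / (\lambda + M_{eff})}
#' The diagonal blocks (`i = j`) are set to `f_i(A) [A = B]`, so the
#' pair-excess matrix's diagonal blocks are the single-site covariances —
#' the convention under which the mean-field inversion is well posed.
#'
#' @param walign A `weighted_alignment` from [compute_weights()].
#' @param lambda Pseudocount mass; the default `meff` gives equal weight to
#'   data and prior, the standard mean-field choice that guarantees
#'   invertibility.
#' @return A `freq_tables` object: `fi` (`L x q`), `fij` (an `Lq x Lq`
#'   matrix of `q x q` blocks), `lambda`, `meff`, `L`, `q`.
#' @export
count_frequencies <- function(walign, lambda = NULL) {
  stopifnot(inherits(walign, "weighted_alignment"))
  lambda <- lambda %||% walign$meff
  stopifnot(lambda >= 0, walign$meff > 0)
  mat <- walign$alignment$matrix
  q <- walign$alignment$q
  L <- ncol(mat)
  w <- walign$weights
  denom <- lambda + walign$meff
  X <- one_hot(mat, q)
  fi_flat <- as.numeric(Matrix::crossprod(X, w))
  fi <- matrix((lambda / q + fi_flat) / denom, L, q, byrow = TRUE)
  Fbig <- as.matrix(Matrix::crossprod(X, X * w))
  Fbig <- (lambda / q^2 + Fbig) / denom
  for (i in seq_len(L)) {
    blk <- (i - 1L) * q + seq_len(q)
    Fbig[blk, blk] <- diag(fi[i, ], q, q)
  }
  if (lambda == 0 && any(apply(fi, 1L, max) >= 1 - 1e-12)) {
    warn("lambda = 0 with fully conserved column(s): coupling inversion will fail")
  }
  new_freq_tables(fi, Fbig, lambda, walign$meff, L, q)
}

new_freq_tables <- function(fi, fij, lambda, meff, L, q) {
  structure(list(fi = fi, fij = fij, lambda = lambda, meff = meff,
                 L = L, q = q),
            class = "freq_tables")
}

#' @export
print.freq_tables <- function(x, ...) {
  cat(sprintf("<freq_tables> L = %d, q = %d, lambda = %.3g, Meff = %.3g\n",
              x$L, x$q, x$lambda, x$meff))
  invisible(x)
}

#' Frequency tables from externally supplied (e.g. exact) marginals
#'
#' Applies the same pseudocount formula as [count_frequencies()], with the
#' empirical counts replaced by `meff` times the supplied marginals. With
#' `lambda = 0` the marginals pass through unchanged. Used to run the
#' inverse pipeline on exact Boltzmann marginals from
#' [enumerate_marginals()].
#'
#' @param fi `L x q` single-site marginals.
#' @param fij Array `L x L x q x q` of pair marginals (diagonal ignored).
#' @param lambda Pseudocount mass.
#' @param meff Nominal effective count for the data term (default 1).
#' @return A `freq_tables` object.
#' @export
freq_tables_from_marginals <- function(fi, fij, lambda = 0, meff = 1) {
  L <- nrow(fi); q <- ncol(fi)
  denom <- lambda + meff
  fi_pc <- (lambda / q + meff * fi) / denom
  Fbig <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) {
    bi <- (i - 1L) * q + seq_len(q)
    for (j in seq_len(L)) {
      bj <- (j - 1L) * q + seq_len(q)
      if (i == j) {
        Fbig[bi, bj] <- diag(fi_pc[i, ], q, q)
      } else {
        Fbig[bi, bj] <- (lambda / q^2 + meff * fij[i, j, , ]) / denom
      }
    }
  }
  new_freq_tables(fi_pc, Fbig, lambda, meff, L, q)
}

fij_block <- function(freqs, i, j) {
  q <- freqs$q
  freqs$fij[(i - 1L) * q + seq_len(q), (j - 1L) * q + seq_len(q)]
}

#' Modal column frequency (conservation) of an alignment
#'
#' Raw, unweighted per-column frequency of the most common state (gap
#' included), used by the conservation filter.
#'
#' @param aln An [alignment] or `weighted_alignment`.
#' @return Numeric vector of length `L`.
#' @export
conservation_fraction <- function(aln) {
  if (inherits(aln, "weighted_alignment")) aln <- aln$alignment
  apply(aln$matrix, 2L, function(col) max(tabulate(col, aln$q)) / length(col))
}

# columns of the Lq x Lq grid that correspond to states 1..q-1
restricted_index <- function(L, q) {
  which(rep(seq_len(q), L) != q)
}

#' Pair-excess (covariance) matrix restricted to q-1 states
#'
#' `C` holds blocks \eqn{C_{ij}(A,B) = f_{ij}(A,B) - f_i(A) f_j(B)} for
#' states `A, B` in `1..q-1`; dropping the gap state fixes the gauge and
#' makes the matrix invertible for `lambda > 0`. Dense of order
#' `(L(q-1))^2`; lengths above 300 columns (at q = 21) are refused with a
#' resource error rather than silently thrashing memory.
#'
#' @param freqs A `freq_tables`.
#' @return Symmetric `L(q-1) x L(q-1)` matrix with attributes `L`, `q`.
#' @export
pair_excess_matrix <- function(freqs) {
  L <- freqs$L; q <- freqs$q
  n <- L * (q - 1L)
  if (n > 6000L) {
    abort(sprintf(
      "pair-excess matrix would be %d x %d; lengths above %d columns are not supported in memory",
      n, n, floor(6000 / (q - 1))), class = "dcafold_resource")
  }
  fi_flat <- as.numeric(t(freqs$fi))           # position-major, state within
  keep <- restricted_index(L, q)
  C <- freqs$fij[keep, keep] - tcrossprod(fi_flat[keep])
  attr(C, "L") <- L
  attr(C, "q") <- q
  C
}

#' Mean-field couplings by inversion of the pair-excess matrix
#'
#' The maximum-entropy pair couplings in mean-field approximation are
#' \eqn{e_{ij}(A,B) = -(C^{-1})_{ij}(A,B)} on the `q-1` restricted states;
#' entries involving the gap state are exactly zero in the stored gauge,
#' and diagonal (`i = i`) blocks are discarded.
#'
#' @param C Pair-excess matrix from [pair_excess_matrix()].
#' @return A `coupling_model`: `eij` (`Lq x Lq`, zero-extended), `L`, `q`,
#'   `gauge`.
#' @export
invert_for_couplings <- function(C) {
  L <- attr(C, "L"); q <- attr(C, "q")
  Cinv <- tryCatch(solve(C), error = function(e) {
    abort(paste0("pair-excess matrix is singular or ill-conditioned (",
                 conditionMessage(e),
                 "); increase the pseudocount lambda"),
          class = "dcafold_inversion")
  })
  E <- matrix(0, L * q, L * q)
  keep <- restricted_index(L, q)
  E[keep, keep] <- -Cinv
  for (i in seq_len(L)) {
    blk <- (i - 1L) * q + seq_len(q)
    E[blk, blk] <- 0
  }
  structure(list(eij = E, L = L, q = q, gauge = "zero-gap-state"),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("<coupling_model> L = %d, q = %d, gauge: %s\n",
              x$L, x$q, x$gauge))
  invisible(x)
}

#' Extract one coupling block e_ij
#' @param cm A `coupling_model`.
#' @param i,j Positions.
#' @export
eij_block <- function(cm, i, j) {
  q <- cm$q
  cm$eij[(i - 1L) * q + seq_len(q), (j - 1L) * q + seq_len(q)]
}

#' Two-site direct distribution with marginal-compatible fields
#'
#' For a coupling block `e`, finds fields \eqn{\tilde h_i, \tilde h_j} such
#' that \eqn{P^{Dir}(A,B) = \exp(e(A,B) + \tilde h_i(A) + \tilde h_j(B)) / Z_{ij}}
#' reproduces the single-site marginals. Solved by alternating
#' multiplicative marginal-matching updates to a fixed point.
#'
#' @param eij_block `q x q` coupling block.
#' @param fi_i,fi_j Strictly positive marginal q-vectors.
#' @param tol Convergence tolerance on the max marginal mismatch.
#' @param max_iter Iteration cap.
#' @return A `pair_direct` object: `pdir`, `hti`, `htj`, `zij`,
#'   `tol_achieved`, `iterations`.
#' @export
fit_pair_fields <- function(eij_block, fi_i, fi_j, tol = 1e-4,
                            max_iter = 500L) {
  stopifnot(all(fi_i > 0), all(fi_j > 0))
  q <- length(fi_i)
  W <- exp(eij_block)
  mu_i <- rep(1 / q, q)
  mu_j <- rep(1 / q, q)
  mismatch <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu_i <- fi_i / as.numeric(W %*% mu_j);  mu_i <- mu_i / sum(mu_i)
    mu_j <- fi_j / as.numeric(crossprod(W, mu_i)); mu_j <- mu_j / sum(mu_j)
    P <- W * outer(mu_i, mu_j)
    P <- P / sum(P)
    mismatch <- max(abs(rowSums(P) - fi_i), abs(colSums(P) - fi_j))
    if (mismatch <= tol) break
  }
  if (mismatch > tol) {
    abort(sprintf(
      "pair-field iteration did not converge: residual %.3g after %d iterations",
      mismatch, it), class = "dcafold_convergence")
  }
  zij <- sum(W * outer(mu_i, mu_j))
  structure(list(pdir = P, hti = log(mu_i), htj = log(mu_j), zij = zij,
                 tol_achieved = mismatch, iterations = it),
            class = "pair_direct")
}

#' Direct information of a pair
#'
#' Kullback-Leibler divergence (natural log) of the direct two-site
#' distribution from the product of its marginals:
#' \deqn{DI = \sum_{A,B} P^{Dir}(A,B) \ln \frac{P^{Dir}(A,B)}{f_i(A) f_j(B)}}
#'
#' @param pdir A `pair_direct` from [fit_pair_fields()].
#' @param fi_i,fi_j Marginal q-vectors.
#' @return Nonnegative scalar (clipped at 0 beyond -1e-10), in nats.
#' @export
direct_information <- function(pdir, fi_i, fi_j) {
  P <- pdir$pdir
  prod <- outer(fi_i, fi_j)
  nz <- P > 0
  di <- sum(P[nz] * log(P[nz] / prod[nz]))
  if (di < -1e-10) abort(sprintf("negative DI: %.3g", di))
  max(di, 0)
}

#' Mutual information of two columns
#'
#' \deqn{MI = \sum_{A,B} f_{ij}(A,B) \ln \frac{f_{ij}(A,B)}{f_i(A) f_j(B)}}
#' with zero-frequency terms contributing 0; natural log.
#'
#' @param freqs A `freq_tables`.
#' @param i,j Distinct column indices.
#' @return Nonnegative scalar in nats.
#' @export
mutual_information <- function(freqs, i, j) {
  stopifnot(i != j)
  fij <- fij_block(freqs, i, j)
  prod <- outer(freqs$fi[i, ], freqs$fi[j, ])
  nz <- fij > 0
  max(sum(fij[nz] * log(fij[nz] / prod[nz])), 0)
}

#' Score all column pairs with DI and MI
#'
#' Full mean-field pipeline: pseudocounted frequencies, pair-excess matrix,
#' coupling inversion, per-pair direct distributions, DI; plus the local MI
#' baseline. MI uses raw (non-pseudocounted, weighted) frequencies by
#' default.
#'
#' @param walign A `weighted_alignment`.
#' @param lambda Pseudocount mass for the DI branch (default `meff`).
#' @param mi_lambda Pseudocount mass for the MI branch (default 0, raw).
#' @param tol,max_iter Passed to [fit_pair_fields()].
#' @return A `score_table`: symmetric `di` and `mi` matrices plus metadata;
#'   [tidy()] gives the ranked pair list.
#' @export
score_all_pairs <- function(walign, lambda = NULL, mi_lambda = 0,
                            tol = 1e-4, max_iter = 500L) {
  freqs <- count_frequencies(walign, lambda = lambda)
  freqs_mi <- if (identical(mi_lambda, freqs$lambda)) freqs else
    count_frequencies(walign, lambda = mi_lambda)
  st <- score_from_freqs(freqs, freqs_mi, tol = tol, max_iter = max_iter)
  st$column_map <- walign$alignment$column_map
  st$meff <- walign$meff
  st
}

#' Score pairs from prepared frequency tables
#'
#' The matrix-inversion half of [score_all_pairs()], callable directly on
#' exact marginals (see [freq_tables_from_marginals()]).
#'
#' @param freqs `freq_tables` for the DI branch (must have `lambda > 0` or
#'   nonsingular covariance).
#' @param freqs_mi `freq_tables` for the MI branch (default: same).
#' @param tol,max_iter Passed to [fit_pair_fields()].
#' @return A `score_table`.
#' @export
score_from_freqs <- function(freqs, freqs_mi = freqs, tol = 1e-4,
                             max_iter = 500L) {
  L <- freqs$L; q <- freqs$q
  C <- pair_excess_matrix(freqs)
  cm <- invert_for_couplings(C)
  di <- matrix(0, L, L)
  mi <- matrix(0, L, L)
  worst <- 0
  for (i in seq_len(L - 1L)) {
    for (j in seq((i + 1L), L)) {
      pd <- fit_pair_fields(eij_block(cm, i, j), freqs$fi[i, ], freqs$fi[j, ],
                            tol = tol, max_iter = max_iter)
      worst <- max(worst, pd$tol_achieved)
      di[i, j] <- di[j, i] <- direct_information(pd, freqs$fi[i, ],
                                                 freqs$fi[j, ])
      mi[i, j] <- mi[j, i] <- mutual_information(freqs_mi, i, j)
    }
  }
  structure(list(di = di, mi = mi, L = L, q = q,
                 lambda = freqs$lambda, meff = freqs$meff,
                 column_map = seq_len(L), couplings = cm,
                 max_marginal_mismatch = worst),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d columns, %d pairs; lambda = %.3g, Meff = %.3g\n",
              x$L, x$L * (x$L - 1L) / 2L, x$lambda, x$meff))
  top <- head(tidy(x), 5L)
  cat("top pairs by DI:\n")
  print(as.data.frame(top))
  invisible(x)
}

#' Ranked pair scores as a tibble
#'
#' @param x A `score_table`.
#' @param ... Unused.
#' @return Tibble with `i`, `j` (focus columns, `i < j`), `ref_i`, `ref_j`
#'   (reference-sequence numbering), `di`, `mi`, sorted by decreasing DI
#'   with lexicographic `(i, j)` tie-break.
#' @export
tidy.score_table <- function(x, ...) {
  idx <- which(upper.tri(x$di), arr.ind = TRUE)
  cmap <- x$column_map %||% seq_len(x$L)
  out <- tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                ref_i = cmap[idx[, 1]], ref_j = cmap[idx[, 2]],
                di = x$di[idx], mi = x$mi[idx])
  arrange(out, desc(.data$di), .data$i, .data$j)
}

#' @export
glance.score_table <- function(x, ...) {
  tibble(L = x$L, q = x$q, n_pairs = x$L * (x$L - 1L) / 2L,
         lambda = x$lambda, meff = x$meff,
         max_marginal_mismatch = x$max_marginal_mismatch)
}

#' Write ranked pair scores as TSV
#' @param x A `score_table`.
#' @param path Output file.
#' @export
write_scores <- function(x, path) {
  write.table(tidy(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
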