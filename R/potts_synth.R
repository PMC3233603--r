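#' Construct a Potts sequence model with a sparse coupling topology
#'
#' The model assigns a sequence \eqn{A_1..A_L} (each position one of `q`
#' states) probability proportional to
#' \eqn{\exp(\sum_{i<j} e_{ij}(A_i,A_j) + \sum_i h_i(A_i))}. Pairs without a
#' coupling entry are exactly zero-coupled.
#'
#' @param L Sequence length.
#' @param q Alphabet size.
#' @param couplings Named list of `q x q` matrices, names `"i_j"` with
#'   `i < j`.
#' @param fields `L x q` matrix of single-site fields (default 0).
#' @param contact_pairs Tibble with columns `i`, `j`: the planted coupled
#'   pair set (defaults to the keys of `couplings`).
#' @return A `potts_model` object.
#' @export
potts_model <- function(L, q, couplings = list(), fields = NULL,
                        contact_pairs = NULL) {
  stopifnot(L >= 1, q >= 2)
  fields <- fields %||% matrix(0, L, q)
  stopifnot(nrow(fields) == L, ncol(fields) == q)
  if (length(couplings)) {
    keys <- do.call(rbind, strsplit(names(couplings), "_"))
    ij <- apply(keys, 2L, as.integer)
    ij <- matrix(ij, ncol = 2L)
    stopifnot(all(ij[, 1] < ij[, 2]), all(ij >= 1), all(ij <= L))
    ok <- vapply(couplings, function(e) all(dim(e) == c(q, q)), logical(1))
    if (!all(ok)) abort("each coupling must be a q x q matrix")
  } else {
    ij <- matrix(integer(), ncol = 2L)
  }
  contact_pairs <- contact_pairs %||%
    tibble(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
  structure(list(L = L, q = q, couplings = couplings, fields = fields,
                 contact_pairs = contact_pairs),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("<potts_model> L = %d, q = %d, %d coupled pairs\n",
              x$L, x$q, length(x$couplings)))
  invisible(x)
}

coupling_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))

#' Retrieve the coupling matrix e_ij(A,B) of a pair (zero if uncoupled)
#' @param model A `potts_model`.
#' @param i,j Positions.
#' @return `q x q` matrix oriented so rows index the state at `min(i,j)`
#'   when `i < j`, transposed otherwise.
#' @export
coupling_block <- function(model, i, j) {
  e <- model$couplings[[coupling_key(i, j)]]
  if (is.null(e)) return(matrix(0, model$q, model$q))
  if (i < j) e else t(e)
}

#' Exact single- and pair-site marginals by state enumeration
#'
#' Sums Boltzmann weights over all `q^L` sequences; feasible for
#' `q^L <= 1e6`. Serves as the ground-truth oracle for the moment-matching
#' constraints the mean-field inversion approximates.
#'
#' @param model A [potts_model].
#' @return List with `fi` (`L x q`) and `fij` (array `L x L x q x q`;
#'   diagonal blocks hold `fi` on the state diagonal).
#' @export
enumerate_marginals <- function(model) {
  L <- model$L; q <- model$q
  n_states <- q^L
  if (n_states > 1e6) {
    abort(sprintf("state space q^L = %g exceeds enumeration limit 1e6",
                  n_states), class = "dcafold_feasibility")
  }
  states <- as.matrix(do.call(expand.grid, rep(list(seq_len(q)), L)))
  colnames(states) <- NULL
  logw <- numeric(n_states)
  for (i in seq_len(L)) logw <- logw + model$fields[i, states[, i]]
  for (key in names(model$couplings)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    e <- model$couplings[[key]]
    logw <- logw + e[cbind(states[, ij[1]], states[, ij[2]])]
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  fi <- matrix(0, L, q)
  for (i in seq_len(L)) {
    fi[i, ] <- vapply(seq_len(q),
                      function(a) sum(w[states[, i] == a]), numeric(1))
  }
  fij <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) {
        fij[i, i, , ] <- diag(fi[i, ], q, q)
      } else if (i < j) {
        tab <- matrix(0, q, q)
        lin <- states[, i] + (states[, j] - 1L) * q
        agg <- rowsum(w, lin)
        tab[as.integer(rownames(agg))] <- agg[, 1]
        fij[i, j, , ] <- tab
        fij[j, i, , ] <- t(tab)
      }
    }
  }
  list(fi = fi, fij = fij)
}

#' Default Gibbs sampler settings
#'
#' @param n_chains Number of parallel chains (default: capped at 200).
#' @param burn_in Sweeps discarded before sampling.
#' @param thin Sweeps between retained samples on each chain.
#' @param seed Integer seed.
#' @export
sampler_config <- function(n_chains = NULL, burn_in = 500L, thin = 10L,
                           seed = 1L) {
  list(n_chains = n_chains, burn_in = as.integer(burn_in),
       thin = as.integer(thin), seed = seed)
}

# one heat-bath sweep over all sites, vectorized across chains
gibbs_sweep <- function(S, model, neighbors) {
  q <- model$q
  n <- nrow(S)
  U <- upper.tri(diag(q), diag = TRUE)
  for (i in seq_len(model$L)) {
    logp <- matrix(model$fields[i, ], n, q, byrow = TRUE)
    for (j in neighbors[[i]]) {
      e <- coupling_block(model, i, j)   # rows: states of i
      logp <- logp + t(e[, S[, j], drop = FALSE])
    }
    p <- exp(logp - apply(logp, 1L, max))
    cum <- p %*% U
    u <- runif(n) * cum[, q]
    S[, i] <- rowSums(cum < u) + 1L
  }
  S
}

#' Sample an alignment from a Potts model by Gibbs sampling
#'
#' Single-site heat-bath resampling in full sweeps across parallel chains.
#' Deterministic for a fixed seed.
#'
#' @param model A [potts_model].
#' @param m Number of sequences to draw.
#' @param config A [sampler_config].
#' @return A `synthetic_family`: list with `model`, `alignment`
#'   ([alignment]), and the recorded `sampler_config`.
#' @export
sample_alignment <- function(model, m, config = sampler_config()) {
  stopifnot(m >= 1)
  L <- model$L; q <- model$q
  n_chains <- config$n_chains %||% min(m, 200L)
  per_chain <- ceiling(m / n_chains)
  neighbors <- vector("list", L)
  for (key in names(model$couplings)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    neighbors[[ij[1]]] <- c(neighbors[[ij[1]]], ij[2])
    neighbors[[ij[2]]] <- c(neighbors[[ij[2]]], ij[1])
  }
  samples <- with_seed(config$seed, {
    S <- matrix(sample.int(q, n_chains * L, replace = TRUE), n_chains, L)
    for (s in seq_len(config$burn_in)) S <- gibbs_sweep(S, model, neighbors)
    out <- vector("list", per_chain)
    for (k in seq_len(per_chain)) {
      if (k > 1L) for (s in seq_len(config$thin))
        S <- gibbs_sweep(S, model, neighbors)
      out[[k]] <- S
    }
    do.call(rbind, out)[seq_len(m), , drop = FALSE]
  })
  aln <- alignment(samples,
                   ids = sprintf("sample_%04d", seq_len(m)),
                   column_map = seq_len(L))
  structure(list(model = model, alignment = aln, sampler_config = config,
                 n_chains = n_chains),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "<synthetic_family> %d sequences from L = %d, q = %d model (%d chains, burn-in %d, thin %d, seed %s)\n",
    n_seq(x$alignment), x$model$L, x$model$q, x$n_chains,
    x$sampler_config$burn_in, x$sampler_config$thin,
    format(x$sampler_config$seed)))
  invisible(x)
}

#' Plant a Potts model on the contact graph of a 3D structure
#'
#' Residue pairs of the structure within `contact_threshold` (C-alpha) and
#' with sequence separation `|i-j| > min_sep` become coupled pairs; each
#' receives an i.i.d. Gaussian `q x q` coupling matrix, symmetrized within
#' the block and scaled by `coupling_strength`.
#'
#' @param struct A structure with C-alpha coordinates (a `fold_model` or an
#'   `L x 3` matrix).
#' @param coupling_strength Standard-deviation scale of the planted
#'   couplings (default 1).
#' @param seed Integer seed; coupling tensors are reproducible.
#' @param q Alphabet size (default 21).
#' @param contact_threshold C-alpha distance cutoff in Angstrom (default 8).
#' @param min_sep Minimum sequence separation (pairs need `|i-j| > min_sep`).
#' @return A [potts_model] with `contact_pairs` the planted topology.
#' @export
plant_from_structure <- function(struct, coupling_strength = 1, seed = 1L,
                                 q = gap_code, contact_threshold = 8,
                                 min_sep = 5L) {
  ca <- if (is.matrix(struct)) struct else struct$ca
  L <- nrow(ca)
  stopifnot(L >= 10)
  d <- as.matrix(dist(ca))
  idx <- which(upper.tri(d) & d < contact_threshold &
                 abs(row(d) - col(d)) > min_sep, arr.ind = TRUE)
  if (nrow(idx) < 2L) {
    abort("structure yields fewer than 2 eligible contact pairs",
          class = "dcafold_degenerate_topology")
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  couplings <- with_seed(seed, {
    out <- list()
    for (k in seq_len(nrow(idx))) {
      g <- matrix(rnorm(q * q), q, q)
      out[[coupling_key(idx[k, 1], idx[k, 2])]] <-
        coupling_strength * (g + t(g)) / 2
    }
    out
  })
  potts_model(L, q, couplings = couplings)
}

#' Serialize / restore a Potts model as JSON
#'
#' Layout: scalars `L`, `q`; `fields` as row-major matrix; `couplings` as a
#' list of records `{i, j, e}` with `e` a `q x q` matrix.
#'
#' @param model A [potts_model].
#' @param path Output file.
#' @export
write_potts_model <- function(model, path) {
  keys <- names(model$couplings)
  recs <- lapply(keys, function(k) {
    ij <- as.integer(strsplit(k, "_")[[1]])
    list(i = ij[1], j = ij[2], e = model$couplings[[k]])
  })
  jsonlite::write_json(
    list(L = model$L, q = model$q, fields = model$fields, couplings = recs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potts_model
#' @export
read_potts_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  q <- x$q
  couplings <- list()
  for (rec in x$couplings) {
    couplings[[coupling_key(rec$i, rec$j)]] <-
      matrix(unlist(rec$e), q, q, byrow = TRUE)
  }
  potts_model(x$L, q, couplings = couplings,
              fields = matrix(unlist(x$fields), x$L, q, byrow = TRUE))
}
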