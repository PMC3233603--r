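#' Restraint-table configuration
#'
#' Distance bounds (Angstrom) used to translate EICs and predicted
#' secondary structure into restraints. EIC restraints act between
#' pseudo-C-beta centers with a generous side-chain allowance; helix and
#' strand restraints encode canonical local geometry; chain restraints pin
#' consecutive C-alpha atoms at the virtual bond length.
#'
#' @param eic_lower,eic_upper C-beta bounds for an EIC (default 3.5-7.0).
#' @param eic_weight Restraint weight for EICs.
#' @param helix_i2,helix_i3,helix_i4 Bounds for helix `d(i,i+2)`,
#'   `d(i,i+3)`, `d(i,i+4)`.
#' @param strand_i2 Bounds for strand `d(i,i+2)`.
#' @param ss_weight Weight for secondary-structure restraints.
#' @param chain_bond Virtual C-alpha bond length (3.8).
#' @param chain_weight Weight for chain-bond restraints.
#' @param cb_offset C-alpha to pseudo-C-beta bond length (1.53).
#' @param clash_dist Soft-sphere repulsion onset (4.0).
#' @export
restraint_config <- function(eic_lower = 3.5, eic_upper = 7.0,
                             eic_weight = 1.0,
                             helix_i2 = c(5.1, 5.9),
                             helix_i3 = c(4.8, 5.6),
                             helix_i4 = c(5.8, 6.6),
                             strand_i2 = c(6.2, 7.0),
                             ss_weight = 1.0,
                             chain_bond = 3.8, chain_weight = 10,
                             cb_offset = 1.53, clash_dist = 4.0) {
  list(eic_lower = eic_lower, eic_upper = eic_upper, eic_weight = eic_weight,
       helix_i2 = helix_i2, helix_i3 = helix_i3, helix_i4 = helix_i4,
       strand_i2 = strand_i2,
       ss_weight = ss_weight, chain_bond = chain_bond,
       chain_weight = chain_weight, cb_offset = cb_offset,
       clash_dist = clash_dist)
}

#' Build distance restraints from EICs and secondary structure
#'
#' One C-beta--C-beta restraint per EIC; helix `d(i,i+3)`/`d(i,i+4)` and
#' strand `d(i,i+2)` restraints for residues inside predicted segments;
#' chain restraints `d(i,i+1)` at the virtual bond length for every
#' consecutive pair.
#'
#' @param eics An `eic_set` (or tibble with `i`, `j`), may be empty or NULL.
#' @param ss Optional [ss_track].
#' @param L Chain length.
#' @param config A [restraint_config].
#' @return Tibble `(i, j, center, lower, upper, weight, origin)`.
#' @export
build_restraints <- function(eics = NULL, ss = NULL, L,
                             config = restraint_config()) {
  out <- list()
  ii <- seq_len(L - 1L)
  out$chain <- tibble(i = ii, j = ii + 1L, center = "CA",
                      lower = config$chain_bond, upper = config$chain_bond,
                      weight = config$chain_weight, origin = "chain")
  if (!is.null(ss)) {
    segs <- ss_segments(ss)
    hx <- filter(segs, .data$state == "H")
    st <- filter(segs, .data$state == "E")
    ss_rows <- list()
    for (k in seq_len(nrow(hx))) {
      s <- hx$start[k]; e <- hx$end[k]
      if (e - s >= 2L) {
        i2 <- s:(e - 2L)
        ss_rows[[length(ss_rows) + 1L]] <-
          tibble(i = i2, j = i2 + 2L, center = "CA",
                 lower = config$helix_i2[1], upper = config$helix_i2[2],
                 weight = config$ss_weight, origin = "ss_local")
      }
      if (e - s >= 3L) {
        i3 <- s:(e - 3L)
        ss_rows[[length(ss_rows) + 1L]] <-
          tibble(i = i3, j = i3 + 3L, center = "CA",
                 lower = config$helix_i3[1], upper = config$helix_i3[2],
                 weight = config$ss_weight, origin = "ss_local")
      }
      if (e - s >= 4L) {
        i4 <- s:(e - 4L)
        ss_rows[[length(ss_rows) + 1L]] <-
          tibble(i = i4, j = i4 + 4L, center = "CA",
                 lower = config$helix_i4[1], upper = config$helix_i4[2],
                 weight = config$ss_weight, origin = "ss_local")
      }
    }
    for (k in seq_len(nrow(st))) {
      s <- st$start[k]; e <- st$end[k]
      if (e - s >= 2L) {
        i2 <- s:(e - 2L)
        ss_rows[[length(ss_rows) + 1L]] <-
          tibble(i = i2, j = i2 + 2L, center = "CA",
                 lower = config$strand_i2[1], upper = config$strand_i2[2],
                 weight = config$ss_weight, origin = "ss_local")
      }
    }
    out$ss <- bind_rows(ss_rows)
  }
  if (!is.null(eics) && nrow(eics)) {
    out$eic <- tibble(i = eics$i, j = eics$j, center = "CB",
                      lower = config$eic_lower, upper = config$eic_upper,
                      weight = config$eic_weight, origin = "eic")
  }
  res <- bind_rows(out)
  stopifnot(all(res$lower <= res$upper), all(res$lower > 0),
            all(res$i != res$j))
  res
}

# effective C-alpha bounds: C-beta restraints widened by one side-chain
# offset (contacting side chains point broadly toward each other), floored
# at the clash distance
ca_effective_restraints <- function(restraints, config) {
  off <- config$cb_offset
  mutate(restraints,
         lower = ifelse(.data$center == "CB",
                        pmax(config$clash_dist, .data$lower - off),
                        .data$lower),
         upper = ifelse(.data$center == "CB", .data$upper + off,
                        .data$upper))
}

#' Triangle-inequality bound smoothing
#'
#' Tightens a full bounds matrix: upper bounds by all-pairs shortest paths,
#' lower bounds by the standard tetrangle-free rule
#' `l_ij >= max(l_ik - u_kj, l_jk - u_ki)`. Never widens a bound. Errors if
#' contradictory input bounds leave `lower > upper` anywhere, naming the
#' worst pair and its tightest path vertex.
#'
#' @param lower,upper `L x L` symmetric bound matrices (Inf allowed in
#'   `upper`).
#' @return List `(lower, upper)` of smoothed matrices.
#' @export
smooth_bounds <- function(lower, upper) {
  L <- nrow(upper)
  U <- upper; B <- lower
  diag(U) <- 0; diag(B) <- 0
  for (k in seq_len(L)) {
    U <- pmin(U, outer(U[, k], U[k, ], "+"))
  }
  for (k in seq_len(L)) {
    cand <- outer(B[, k], U[k, ], "-")     # l_ik - u_kj
    B <- pmax(B, cand, t(cand))
  }
  diag(B) <- 0
  viol <- B - U
  if (max(viol) > 1e-8) {
    w <- which(viol == max(viol), arr.ind = TRUE)[1L, ]
    i <- w[1]; j <- w[2]
    k <- which.min(upper[i, ] + upper[, j])
    abort(sprintf(
      "infeasible restraints: lower(%d,%d) = %.2f exceeds smoothed upper %.2f (tightest path through %d)",
      i, j, B[i, j], U[i, j], k), class = "dcafold_infeasible")
  }
  list(lower = B, upper = U)
}

restraints_to_bounds <- function(restraints, L, config = restraint_config()) {
  eff <- ca_effective_restraints(restraints, config)
  lower <- matrix(0, L, L)
  upper <- matrix(Inf, L, L)
  # generic steric floor for non-adjacent pairs
  lower[abs(row(lower) - col(lower)) > 1L] <- config$clash_dist
  for (k in seq_len(nrow(eff))) {
    i <- eff$i[k]; j <- eff$j[k]
    lower[i, j] <- lower[j, i] <- max(lower[i, j], eff$lower[k])
    upper[i, j] <- upper[j, i] <- min(upper[i, j], eff$upper[k])
  }
  smooth_bounds(lower, upper)
}

new_fold_model <- function(ca, provenance = list(), restraint_energy = NA_real_,
                           sequence = NULL) {
  ca <- as.matrix(ca)
  structure(list(ca = ca, cb = place_cbeta(ca, sequence),
                 provenance = provenance,
                 restraint_energy = restraint_energy),
            class = "fold_model")
}

#' @export
print.fold_model <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<fold_model> %d residues, chirality: %s, restraint energy: %.3g\n",
              nrow(x$ca), p$chirality %||% "?", x$restraint_energy))
  invisible(x)
}

#' Model coordinates as a tibble
#' @param x A `fold_model`.
#' @param ... Unused.
#' @export
tidy.fold_model <- function(x, ...) {
  tibble(residue = seq_len(nrow(x$ca)),
         x = x$ca[, 1], y = x$ca[, 2], z = x$ca[, 3],
         xcb = x$cb[, 1], ycb = x$cb[, 2], zcb = x$cb[, 3])
}

#' @export
glance.fold_model <- function(x, ...) {
  p <- x$provenance
  bonds <- sqrt(rowSums((x$ca[-1, , drop = FALSE] -
                           x$ca[-nrow(x$ca), , drop = FALSE])^2))
  tibble(n_res = nrow(x$ca), n_c = p$n_c %||% NA_integer_,
         replicate = p$replicate %||% NA_integer_,
         chirality = p$chirality %||% NA_character_,
         restraint_energy = x$restraint_energy,
         max_bond_dev = max(abs(bonds - 3.8)))
}

#' Place pseudo-C-beta centers on a C-alpha trace
#'
#' 1.53 A from each C-alpha along the local tetrahedral direction
#' reconstructed from three consecutive C-alpha positions; glycine (and the
#' degenerate chain termini fallback) uses the C-alpha itself when no
#' direction is defined.
#'
#' @param ca `L x 3` coordinates.
#' @param sequence Optional residue codes; glycine positions get
#'   `cb == ca`.
#' @param offset Bond length (default 1.53).
#' @return `L x 3` matrix.
#' @export
place_cbeta <- function(ca, sequence = NULL, offset = 1.53) {
  L <- nrow(ca)
  cb <- ca
  gly <- encode_residue("G")
  for (i in seq_len(L)) {
    tri <- if (i == 1L) c(2L, 1L, 3L) else if (i == L) c(L - 1L, L, L - 2L)
           else c(i - 1L, i, i + 1L)
    v1 <- ca[tri[1], ] - ca[i, ]
    v2 <- ca[tri[3], ] - ca[i, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-9 || n2 < 1e-9) next
    u <- -(v1 / n1 + v2 / n2)
    w <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
    if (nu < 1e-9 || nw < 1e-9) next
    dir <- u / nu + w / nw
    cb[i, ] <- ca[i, ] + offset * dir / sqrt(sum(dir^2))
  }
  if (!is.null(sequence)) cb[sequence == gly, ] <- ca[sequence == gly, ]
  cb
}

#' Metric-matrix embedding of smoothed distance bounds
#'
#' Random metrization within the smoothed bounds (seeded), double-centered
#' Gram matrix, spectral embedding on the top three components. Distance
#' bounds carry no chirality, so both the embedding and its mirror image
#' are returned.
#'
#' @param restraints Restraint tibble from [build_restraints()], or `NULL`
#'   when `bounds` is given.
#' @param L Chain length.
#' @param seed Integer seed for the metrization draw.
#' @param config A [restraint_config].
#' @param bounds Optional pre-smoothed list `(lower, upper)`, bypassing
#'   restraint translation (used for exact-distance reconstruction).
#' @return List of two `fold_model`s, chirality `"plus"` and `"minus"`.
#' @export
embed_structure <- function(restraints = NULL, L, seed = 1L,
                            config = restraint_config(), bounds = NULL) {
  bounds <- bounds %||% restraints_to_bounds(restraints, L, config)
  D <- with_seed(seed, {
    u <- matrix(runif(L * L), L, L)
    m <- bounds$lower + (bounds$upper - bounds$lower) * u
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  D2 <- D^2
  J <- diag(L) - matrix(1 / L, L, L)
  B <- -0.5 * J %*% D2 %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values[1:3], 0)
  X <- ev$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3L, 3L)
  mirror <- X
  mirror[, 3] <- -mirror[, 3]
  list(new_fold_model(X, provenance = list(seed = seed, chirality = "plus")),
       new_fold_model(mirror,
                      provenance = list(seed = seed, chirality = "minus")))
}

# flat-bottom restraint + chain energy and gradient on the C-alpha trace
restraint_terms <- function(restraints, config) {
  eff <- ca_effective_restraints(restraints, config)
  list(i = eff$i, j = eff$j, lower = eff$lower, upper = eff$upper,
       weight = eff$weight)
}

make_objective <- function(L, terms, config) {
  # repulsion pairs |i-j| > 1
  rp <- which(upper.tri(matrix(0, L, L)) &
                (col(matrix(0, L, L)) - row(matrix(0, L, L))) > 1L,
              arr.ind = TRUE)
  ri <- rp[, 1]; rj <- rp[, 2]
  clash <- config$clash_dist
  ti <- terms$i; tj <- terms$j
  tl <- terms$lower; tu <- terms$upper; tw <- terms$weight
  acc <- function(idx, val) {           # scatter-add into length-L vector
    out <- numeric(L)
    s <- rowsum(val, idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  fn <- function(x, w_rep) {
    P <- matrix(x, L, 3L)
    dv <- P[ti, , drop = FALSE] - P[tj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2)) + 1e-12
    e <- sum(tw * (pmax(d - tu, 0)^2 + pmax(tl - d, 0)^2))
    rv <- P[ri, , drop = FALSE] - P[rj, , drop = FALSE]
    rd <- sqrt(rowSums(rv^2)) + 1e-12
    e + w_rep * sum(pmax(clash - rd, 0)^2)
  }
  gr <- function(x, w_rep) {
    P <- matrix(x, L, 3L)
    dv <- P[ti, , drop = FALSE] - P[tj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2)) + 1e-12
    coef <- 2 * tw * (pmax(d - tu, 0) - pmax(tl - d, 0)) / d
    rv <- P[ri, , drop = FALSE] - P[rj, , drop = FALSE]
    rd <- sqrt(rowSums(rv^2)) + 1e-12
    rcoef <- -2 * w_rep * pmax(clash - rd, 0) / rd
    G <- matrix(0, L, 3L)
    for (c in 1:3) {
      G[, c] <- acc(ti, coef * dv[, c]) - acc(tj, coef * dv[, c]) +
        acc(ri, rcoef * rv[, c]) - acc(rj, rcoef * rv[, c])
    }
    as.numeric(G)
  }
  restraint_only <- function(x) {
    P <- matrix(x, L, 3L)
    dv <- P[ti, , drop = FALSE] - P[tj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2)) + 1e-12
    sum(tw * (pmax(d - tu, 0)^2 + pmax(tl - d, 0)^2))
  }
  list(fn = fn, gr = gr, restraint_only = restraint_only)
}

#' Annealing schedule for restraint refinement
#'
#' Outer stages ramp the soft-sphere repulsion weight from `ramp[1]` to
#' `ramp[n]` (default 0.1 to 1.0 over 5 stages), mimicking the role of
#' simulated annealing in resolving steric clashes; each stage runs a
#' bounded quasi-Newton minimization.
#'
#' @param stages Number of outer stages.
#' @param steps Minimizer iterations per stage.
#' @param ramp Repulsion-weight multipliers, length `stages`.
#' @export
anneal_schedule <- function(stages = 5L, steps = 300L,
                            ramp = seq(0.1, 1.0, length.out = stages)) {
  stopifnot(length(ramp) == stages)
  list(stages = stages, steps = steps, ramp = ramp)
}

#' Refine an embedded model against its restraints
#'
#' Gradient-based minimization of the flat-bottom harmonic restraint energy
#' plus soft-sphere C-alpha repulsion and the chain-bond term, with the
#' repulsion weight annealed over outer stages. The best coordinates by
#' full-weight energy are carried across stages, so the reported energy
#' trace is non-increasing. A final bond-projection pass restores the
#' consecutive C-alpha distance invariant (3.8 +/- 0.2 A).
#'
#' @param model A `fold_model` from [embed_structure()].
#' @param restraints Restraint tibble.
#' @param schedule An [anneal_schedule].
#' @param config A [restraint_config].
#' @return The refined `fold_model`, with `restraint_energy` and an
#'   `energy_trace` provenance entry.
#' @export
refine_structure <- function(model, restraints,
                             schedule = anneal_schedule(),
                             config = restraint_config()) {
  L <- nrow(model$ca)
  terms <- restraint_terms(restraints, config)
  obj <- make_objective(L, terms, config)
  x <- as.numeric(model$ca)
  e0 <- obj$fn(x, 1.0)
  best_x <- x
  best_e <- e0
  trace <- numeric(schedule$stages)
  for (s in seq_len(schedule$stages)) {
    w <- schedule$ramp[s]
    fit <- optim(best_x, fn = obj$fn, gr = obj$gr, w_rep = w,
                 method = "L-BFGS-B",
                 control = list(maxit = schedule$steps))
    e_full <- obj$fn(fit$par, 1.0)
    if (e_full > 10 * (e0 + 1)) {
      abort(sprintf("refinement diverged: energy %.3g from initial %.3g",
                    e_full, e0), class = "dcafold_refinement")
    }
    if (e_full <= best_e) {
      best_e <- e_full
      best_x <- fit$par
    }
    trace[s] <- best_e
  }
  P <- project_bonds(matrix(best_x, L, 3L), config$chain_bond)
  out <- new_fold_model(P, provenance = c(model$provenance,
                                          list(energy_trace = trace)))
  out$restraint_energy <- obj$restraint_only(as.numeric(P))
  out
}

# SHAKE-like pass: iteratively nudge consecutive atoms to the bond length
project_bonds <- function(P, bond = 3.8, tol = 0.05, max_pass = 200L) {
  L <- nrow(P)
  for (pass in seq_len(max_pass)) {
    dv <- P[-1, , drop = FALSE] - P[-L, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    if (max(abs(d - bond)) < tol) break
    for (i in seq_len(L - 1L)) {
      v <- P[i + 1L, ] - P[i, ]
      dn <- sqrt(sum(v^2))
      corr <- 0.5 * (dn - bond) / dn
      P[i, ] <- P[i, ] + corr * v
      P[i + 1L, ] <- P[i + 1L, ] - corr * v
    }
  }
  P
}

#' Generate a candidate-structure ensemble over an N_C grid
#'
#' For each N_C bin, `n_per_bin` refined models from fresh metrization
#' seeds; both chiral images are refined and the better-handed one (by
#' [handedness_score()]) is kept, falling back to lower restraint energy
#' when handedness is undecided.
#'
#' @param eics_by_nc Named list of `eic_set`s keyed by N_C (as produced by
#'   repeated [select_eics()] calls over [nc_grid()]).
#' @param ss An [ss_track] (used for restraints and chirality selection).
#' @param L Chain length.
#' @param n_per_bin Models per bin (default 20).
#' @param seed Master seed; the ensemble is reproducible bit-for-bit.
#' @param config A [restraint_config].
#' @param schedule An [anneal_schedule].
#' @return List of `fold_model`s; `summary` attribute tabulates provenance.
#' @export
generate_ensemble <- function(eics_by_nc, ss, L, n_per_bin = 20L, seed = 1L,
                              config = restraint_config(),
                              schedule = anneal_schedule()) {
  stopifnot(length(eics_by_nc) >= 1L)
  models <- list()
  for (b in seq_along(eics_by_nc)) {
    n_c <- as.integer(names(eics_by_nc)[[b]])
    restraints <- build_restraints(eics_by_nc[[b]], ss, L, config)
    for (r in seq_len(n_per_bin)) {
      s <- derive_seed(seed, b * 1000L + r)
      pair <- embed_structure(restraints, L, seed = s, config = config)
      refined <- lapply(pair, refine_structure, restraints = restraints,
                        schedule = schedule, config = config)
      scores <- vapply(refined, function(m)
        handedness_score(m, ss)$combined, numeric(1))
      pick <- if (abs(scores[1] - scores[2]) > 1e-9) which.max(scores) else
        which.min(vapply(refined, `[[`, numeric(1), "restraint_energy"))
      m <- refined[[pick]]
      m$provenance$n_c <- n_c
      m$provenance$replicate <- r
      models[[length(models) + 1L]] <- m
    }
  }
  summary <- bind_rows(lapply(models, glance))
  attr(models, "summary") <- summary
  models
}
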