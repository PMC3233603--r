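cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Virtual dihedral angle over four points
#'
#' Signed torsion in degrees, in `(-180, 180]`; the standard IUPAC sign
#' convention (positive = clockwise rotation of the far bond viewed along
#' the central bond).
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @export
virtual_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  atan2(y, x) * 180 / pi
}

#' Handedness score of a candidate structure
#'
#' Helix component: fraction of virtual C-alpha `(i..i+3)` dihedrals inside
#' predicted helix segments that fall in the right-handed window
#' (+30 to +70 degrees around the canonical +50). Strand component:
#' fraction of inter-strand virtual dihedrals with right-handed sign, for
#' residue pairings detected by C-alpha proximity (< 5.5 A) between
#' distinct predicted strands. Combined: mean weighted by the number of
#' residues predicted H and E. With no helix or strand residues the score
#' is undefined and reported neutral (0.5) with a flag.
#'
#' @param model A `fold_model` (or `L x 3` C-alpha matrix).
#' @param ss An [ss_track] of the same length.
#' @param helix_window Right-handed helix dihedral window in degrees.
#' @param pair_cut Inter-strand C-alpha pairing cutoff (A).
#' @return A list (`ranking_score`): `helix_score`, `strand_score`,
#'   `combined`, `n_helix_dihedrals`, `n_strand_dihedrals`, `undefined`.
#' @export
handedness_score <- function(model, ss, helix_window = c(30, 70),
                             pair_cut = 5.5) {
  ca <- if (is.matrix(model)) model else model$ca
  L <- nrow(ca)
  stopifnot(nrow(ss) == L)
  seg <- ss$segment
  state <- ss$state
  helix_dih <- numeric(0)
  for (i in seq_len(max(L - 3L, 0L))) {
    s <- seg[i:(i + 3L)]
    if (all(!is.na(s)) && length(unique(s)) == 1L && state[i] == "H") {
      helix_dih <- c(helix_dih,
                     virtual_dihedral(ca[i, ], ca[i + 1L, ],
                                      ca[i + 2L, ], ca[i + 3L, ]))
    }
  }
  strand_dih <- numeric(0)
  e_res <- which(state == "E")
  if (length(e_res) >= 4L) {
    d <- as.matrix(dist(ca))
    for (i in e_res) {
      if (!(i + 1L) %in% e_res || seg[i] != seg[i + 1L]) next
      partners <- e_res[seg[e_res] != seg[i] & d[i, e_res] < pair_cut]
      for (j in partners) {
        jn <- if ((j + 1L) %in% e_res && seg[j + 1L] == seg[j] &&
                    d[i + 1L, j + 1L] < pair_cut) j + 1L
              else if ((j - 1L) %in% e_res && seg[j - 1L] == seg[j] &&
                         d[i + 1L, j - 1L] < pair_cut) j - 1L
              else NA_integer_
        if (is.na(jn)) next
        strand_dih <- c(strand_dih,
                        virtual_dihedral(ca[i, ], ca[i + 1L, ],
                                         ca[jn, ], ca[j, ]))
      }
    }
  }
  n_h_res <- sum(state == "H"); n_e_res <- sum(state == "E")
  undefined <- (n_h_res + n_e_res) == 0L ||
    (length(helix_dih) + length(strand_dih)) == 0L
  helix_score <- if (length(helix_dih))
    mean(helix_dih >= helix_window[1] & helix_dih <= helix_window[2]) else
      if (n_h_res > 0L) 0.5 else NA_real_
  strand_score <- if (length(strand_dih)) mean(strand_dih < 0) else
    if (n_e_res > 0L) 0.5 else NA_real_
  if (undefined) {
    combined <- 0.5
  } else {
    wgt <- c(n_h_res, n_e_res)
    comp <- c(helix_score %||% NA_real_, strand_score %||% NA_real_)
    use <- !is.na(comp) & wgt > 0
    combined <- sum(comp[use] * wgt[use]) / sum(wgt[use])
  }
  structure(list(helix_score = helix_score, strand_score = strand_score,
                 combined = combined,
                 n_helix_dihedrals = length(helix_dih),
                 n_strand_dihedrals = length(strand_dih),
                 undefined = undefined),
            class = "ranking_score")
}

# --- knot detection: KMT reduction + Alexander determinant at t = -1 ------

# remove vertices of a CLOSED polygon whose elimination triangle is not
# pierced by any other segment (topology-preserving on closed curves only)
kmt_reduce <- function(P, max_pass = 100L) {
  for (pass in seq_len(max_pass)) {
    if (nrow(P) <= 3L) return(P)
    removed <- FALSE
    i <- 1L
    while (i <= nrow(P) && nrow(P) > 3L) {
      if (!triangle_pierced(P, i)) {
        P <- P[-i, , drop = FALSE]
        removed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!removed) break
  }
  P
}

# does any polygon segment intersect triangle (i-1, i, i+1) (circular)?
triangle_pierced <- function(P, i) {
  n <- nrow(P)
  ip <- if (i == 1L) n else i - 1L
  inx <- if (i == n) 1L else i + 1L
  a <- P[ip, ]; b <- P[i, ]; c <- P[inx, ]
  segs <- cbind(seq_len(n), c(2:n, 1L))
  touch <- segs[, 1] %in% c(ip, i, inx) | segs[, 2] %in% c(ip, i, inx)
  segs <- segs[!touch, , drop = FALSE]
  if (!nrow(segs)) return(FALSE)
  e1 <- b - a; e2 <- c - a
  for (k in seq_len(nrow(segs))) {
    p <- P[segs[k, 1], ]; q <- P[segs[k, 2], ]
    dirv <- q - p
    h <- cross3(dirv, e2)
    det <- sum(e1 * h)
    if (abs(det) < 1e-12) next
    s <- p - a
    u <- sum(s * h) / det
    if (u < 0 || u > 1) next
    qv <- cross3(s, e1)
    v <- sum(dirv * qv) / det
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * qv) / det
    if (t > 1e-9 && t < 1 - 1e-9) return(TRUE)
  }
  FALSE
}

# close an open chain through a sphere far outside the structure
close_chain <- function(P) {
  ctr <- colMeans(P)
  R <- 3 * max(sqrt(rowSums(sweep(P, 2L, ctr)^2))) + 10
  ext <- function(p) {
    v <- p - ctr
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) v <- c(1, 0, 0) else v <- v / nv
    ctr + R * v
  }
  a <- ext(P[1L, ]); b <- ext(P[nrow(P), ])
  mid <- ctr + 2 * R * {
    v <- (a - ctr) + (b - ctr)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) c(0, 0, 1) else v / nv
  }
  rbind(mid, a, P, b)   # closed implicitly: last vertex connects to first
}

# crossings of the closed polygon projected on the xy-plane
find_crossings <- function(P) {
  n <- nrow(P)
  nxt <- c(2:n, 1L)
  res <- list()
  for (s1 in seq_len(n)) {
    for (s2 in seq_len(n)) {
      if (s2 <= s1) next
      if (s2 == s1 + 1L || (s1 == 1L && s2 == n)) next  # adjacent
      a <- P[s1, ]; b <- P[nxt[s1], ]; c <- P[s2, ]; d <- P[nxt[s2], ]
      den <- (b[1] - a[1]) * (d[2] - c[2]) - (b[2] - a[2]) * (d[1] - c[1])
      if (abs(den) < 1e-12) next
      t <- ((c[1] - a[1]) * (d[2] - c[2]) - (c[2] - a[2]) * (d[1] - c[1])) / den
      u <- ((c[1] - a[1]) * (b[2] - a[2]) - (c[2] - a[2]) * (b[1] - a[1])) / den
      if (t <= 1e-9 || t >= 1 - 1e-9 || u <= 1e-9 || u >= 1 - 1e-9) next
      z1 <- a[3] + t * (b[3] - a[3])
      z2 <- c[3] + u * (d[3] - c[3])
      if (abs(z1 - z2) < 1e-9) return(NULL)        # degenerate projection
      # crossing sign from 2D orientation of (under dir, over dir)
      sgn <- sign((b[1] - a[1]) * (d[2] - c[2]) - (b[2] - a[2]) * (d[1] - c[1]))
      if (z1 < z2) {
        res[[length(res) + 1L]] <- list(under_pos = s1 + t, over_pos = s2 + u,
                                        sign = sgn)
      } else {
        res[[length(res) + 1L]] <- list(under_pos = s2 + u, over_pos = s1 + t,
                                        sign = -sgn)
      }
    }
  }
  res
}

rotation_matrix <- function(ax, ang) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

#' Alexander determinant |Delta(-1)| of a closed or closable chain
#'
#' KMT chain reduction, radial endpoint closure to a far sphere, generic
#' planar projection, then the Alexander polynomial of the knot diagram
#' evaluated at `t = -1` (the knot determinant). The unknot gives 1, the
#' trefoil 3; any value other than 1 certifies a knot (the converse does
#' not hold, which is the standard limitation of this invariant).
#'
#' @param coords `L x 3` coordinate matrix (open chain) or `fold_model`.
#' @param closed Treat the input as an already-closed curve.
#' @return Integer-valued determinant (>= 1).
#' @export
alexander_determinant <- function(coords, closed = FALSE) {
  P <- if (is.matrix(coords)) coords else coords$ca
  stopifnot(nrow(P) >= 4L)
  if (!closed) P <- close_chain(P)
  P <- kmt_reduce(P)
  if (nrow(P) <= 3L) return(1)
  # deterministic search for a generic projection direction
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  for (k in 0:19) {
    Q <- if (k == 0L) P else
      P %*% rotation_matrix(axes[[k %% 5L + 1L]], 0.37 * k + 0.11)
    cr <- find_crossings(Q)
    if (!is.null(cr)) return(alexander_from_crossings(cr))
  }
  abort("could not find a generic projection for knot analysis")
}

alexander_from_crossings <- function(crossings) {
  n <- length(crossings)
  if (n < 3L) return(1)
  under <- vapply(crossings, `[[`, numeric(1), "under_pos")
  over <- vapply(crossings, `[[`, numeric(1), "over_pos")
  ord <- order(under)
  under_sorted <- under[ord]
  # arc r covers curve positions (under_sorted[r-1], under_sorted[r]];
  # arc index for any position:
  arc_of <- function(pos) {
    idx <- findInterval(pos, under_sorted)
    ifelse(idx == 0L, n, idx)     # wraparound: before first underpass
  }
  M <- matrix(0, n, n)
  for (r in seq_len(n)) {
    k_in <- if (r == 1L) n else r - 1L   # arc ending at this underpass
    k_out <- r                            # arc starting here
    i_over <- arc_of(over[ord[r]])
    # Alexander row at t = -1: x_in + x_out - 2 x_over = 0 (sign-free)
    M[r, k_in] <- M[r, k_in] + 1
    M[r, k_out] <- M[r, k_out] + 1
    M[r, i_over] <- M[r, i_over] - 2
  }
  sub <- M[-n, -n, drop = FALSE]
  round(abs(det(sub)))
}

#' Is the chain knotted?
#'
#' `TRUE` when the Alexander determinant differs from 1. Chirality-blind
#' (a knot and its mirror give the same determinant).
#'
#' @inheritParams alexander_determinant
#' @export
detect_knot <- function(coords, closed = FALSE) {
  alexander_determinant(coords, closed = closed) != 1
}

#' Rank candidate structures by handedness and knot exclusion
#'
#' Knotted models are excluded; the remainder is sorted by combined
#' handedness score (descending), ties broken by lower restraint energy,
#' then provenance (N_C, replicate).
#'
#' @param models List of `fold_model`s (e.g. from [generate_ensemble()]).
#' @param ss An [ss_track].
#' @return Tibble: one row per model with scores, knot flag, energies, in
#'   rank order (knotted models at the bottom, `rank = NA`).
#' @export
rank_candidates <- function(models, ss) {
  stopifnot(length(models) >= 1L)
  rows <- imap(models, function(m, idx) {
    sc <- handedness_score(m, ss)
    tibble(model = idx,
           n_c = m$provenance$n_c %||% NA_integer_,
           replicate = m$provenance$replicate %||% NA_integer_,
           chirality = m$provenance$chirality %||% NA_character_,
           helix_score = sc$helix_score %||% NA_real_,
           strand_score = sc$strand_score %||% NA_real_,
           combined = sc$combined,
           undefined = sc$undefined,
           knotted = detect_knot(m),
           restraint_energy = m$restraint_energy)
  })
  tab <- bind_rows(rows)
  ok <- tab |>
    filter(!.data$knotted) |>
    arrange(desc(.data$combined), .data$restraint_energy, .data$n_c,
            .data$replicate) |>
    mutate(rank = row_number())
  if (nrow(ok) == 0L) warn("all candidate models are knotted")
  bind_rows(ok, mutate(filter(tab, .data$knotted), rank = NA_integer_))
}
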