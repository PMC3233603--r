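#' Ideal alpha-helix C-alpha trace
#'
#' Canonical right-handed helix: radius 2.3 A, rise 1.5 A per residue,
#' 100 degrees per turn, giving a consecutive C-alpha spacing of ~3.8 A.
#'
#' @param n Number of residues.
#' @param radius,rise,twist_deg Helix parameters.
#' @return `n x 3` coordinate matrix.
#' @export
ideal_helix <- function(n, radius = 2.3, rise = 1.5, twist_deg = 100) {
  th <- (seq_len(n) - 1L) * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(n) - 1L))
}

#' Toy helix-hairpin structure with its secondary-structure track
#'
#' Two antiparallel ideal helices packed at a fixed axis separation and
#' joined by a semicircular turn; the standard synthetic target for planted
#' contact topologies. Consecutive C-alpha spacing stays near 3.8 A.
#'
#' @param n_helix Residues per helix (default 26).
#' @param n_turn Residues in the connecting turn (default 8).
#' @param separation Axis-to-axis helix distance in Angstrom (default 10).
#' @return List with `ca` (`L x 3`), `ss` (an [ss_track]), and `L`.
#' @export
helix_hairpin <- function(n_helix = 26L, n_turn = 8L, separation = 10) {
  h1 <- ideal_helix(n_helix)
  h2 <- ideal_helix(n_helix)
  # second helix runs back down, displaced in x
  h2 <- cbind(separation - h2[, 1], h2[, 2],
              max(h1[, 3]) - h2[, 3])
  a <- h1[n_helix, ]; b <- h2[1L, ]
  # half-elliptic arc over the top joining the two helix ends, its height
  # chosen so inter-residue spacing stays near 3.8 A
  mid <- (a + b) / 2
  r <- sqrt(sum((b - a)^2)) / 2
  u <- (b - a) / (2 * r)
  target <- 3.8 * (n_turn + 1L)
  # circular arc (uniform curvature, hence uniform spacing) standing in the
  # plane spanned by the end-to-end direction and the helix axis
  phi <- stats::uniroot(function(f) (target / f) * 2 * sin(f / 2) - 2 * r,
                        c(pi + 1e-6, 2 * pi - 1e-3))$root
  R <- target / phi
  m <- sqrt(max(R^2 - r^2, 0))
  w <- c(0, 0, 1)
  c0 <- mid + m * w
  th_a <- atan2(-m, -r)
  th <- th_a - seq_len(n_turn) * phi / (n_turn + 1L)
  turn <- t(vapply(th, function(t) c0 + R * (cos(t) * u + sin(t) * w),
                   numeric(3)))
  ca <- rbind(h1, turn, h2)
  L <- nrow(ca)
  ss <- ss_track(c(rep("H", n_helix), rep("C", n_turn), rep("H", n_helix)))
  list(ca = ca, ss = ss, L = L)
}

#' Closed polygonal trefoil knot
#'
#' Parametric (2,3) torus knot sampled at `n` vertices; the canonical
#' knotted test curve (Alexander determinant 3).
#'
#' @param n Number of vertices (default 60).
#' @param scale Overall scale in Angstrom.
#' @return `n x 3` coordinate matrix tracing a closed trefoil.
#' @export
trefoil_curve <- function(n = 60L, scale = 5) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  scale * cbind(sin(t) + 2 * sin(2 * t),
                cos(t) - 2 * cos(2 * t),
                -sin(3 * t))
}
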