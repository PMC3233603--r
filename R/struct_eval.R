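#' Contact map from a reference PDB structure
#'
#' A residue pair is a contact when the minimum heavy-atom distance is
#' below `threshold` (5 A by default). Waters and hetero records are
#' excluded; alternate locations are resolved to the highest-occupancy
#' copy. Residues are numbered sequentially along the chain; an explicit
#' `residue_map` (PDB resno -> model index) can override, and unmappable
#' residues are reported via the `unmapped` attribute, never silently
#' dropped.
#'
#' @param pdb Path to a PDB file or a `bio3d` pdb object.
#' @param chain Chain identifier (default: first protein chain).
#' @param threshold Contact cutoff in Angstrom.
#' @param residue_map Optional named vector mapping PDB residue numbers to
#'   model indices.
#' @return A `contact_map` tibble `(i, j, dist, sep)` with attributes
#'   `threshold`, `definition = "min_heavy_atom"`, `source`.
#' @export
contacts_from_reference <- function(pdb, chain = NULL, threshold = 5,
                                    residue_map = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), ]
  if (!is.null(chain)) at <- at[at$chain == chain, ]
  else at <- at[at$chain == at$chain[1L], ]
  at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", ]
  # resolve altLoc by occupancy
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt])) {
      rows <- which(key == k)
      if (length(rows) > 1L) {
        best <- rows[which.max(at$o[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
    at <- at[keep, ]
  }
  resnos <- unique(at$resno)
  if (is.null(residue_map)) {
    map <- setNames(seq_along(resnos), resnos)
    unmapped <- integer(0)
  } else {
    map <- residue_map
    unmapped <- setdiff(resnos, as.integer(names(map)))
    if (length(unmapped)) {
      warn(sprintf("%d reference residues not mappable to model indices: %s",
                   length(unmapped),
                   paste(head(unmapped, 10L), collapse = ", ")))
    }
    at <- at[at$resno %in% as.integer(names(map)), ]
    resnos <- unique(at$resno)
  }
  idx <- map[as.character(at$resno)]
  xyz <- cbind(at$x, at$y, at$z)
  n <- max(idx)
  pairs <- list()
  res_atoms <- split(seq_len(nrow(at)), idx)
  keys <- sort(as.integer(names(res_atoms)))
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (b <= a) next
      ia <- res_atoms[[as.character(keys[a])]]
      ib <- res_atoms[[as.character(keys[b])]]
      dm <- sqrt(outer(rowSums(xyz[ia, , drop = FALSE]^2),
                       rowSums(xyz[ib, , drop = FALSE]^2), "+") -
                   2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE]))
      mn <- min(dm)
      if (mn < threshold) {
        pairs[[length(pairs) + 1L]] <-
          tibble(i = keys[a], j = keys[b], dist = mn)
      }
    }
  }
  out <- if (length(pairs)) bind_rows(pairs) else
    tibble(i = integer(), j = integer(), dist = numeric())
  out <- mutate(out, sep = .data$j - .data$i)
  structure(out, class = c("contact_map", class(tibble())),
            threshold = threshold, definition = "min_heavy_atom",
            source = "reference", unmapped = unmapped)
}

#' Contact map from coarse-grained model coordinates
#'
#' Coarse models carry no side chains, so model-side contacts use a
#' C-beta proxy: pseudo-C-beta pairs closer than `threshold` (8 A).
#'
#' @param model A `fold_model` or coordinate matrix (then treated as the
#'   contact centers directly).
#' @param threshold Cutoff in Angstrom (default 8).
#' @param min_sep Minimum sequence separation recorded (pairs closer in
#'   chain are omitted, default 0 keeps all).
#' @return A `contact_map` tibble with `definition = "cb_proxy"`.
#' @export
contacts_from_model <- function(model, threshold = 8, min_sep = 0L) {
  cb <- if (is.matrix(model)) model else model$cb
  d <- as.matrix(dist(cb))
  idx <- which(upper.tri(d) & d < threshold &
                 (col(d) - row(d)) > min_sep, arr.ind = TRUE)
  out <- tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                dist = d[idx], sep = as.integer(idx[, 2] - idx[, 1]))
  structure(arrange(out, .data$i, .data$j),
            class = c("contact_map", class(tibble())),
            threshold = threshold, definition = "cb_proxy",
            source = "model", unmapped = integer(0))
}

top_predicted <- function(predicted, n_c, min_sep = 5L) {
  pred <- as_tibble(predicted)
  pred <- filter(pred, .data$j - .data$i > min_sep)
  if (n_c > nrow(pred)) {
    warn(sprintf("n_c = %d exceeds the %d available predictions", n_c,
                 nrow(pred)))
    n_c <- nrow(pred)
  }
  slice_head(pred, n = n_c)
}

observed_longrange <- function(observed, min_sep = 5L) {
  filter(as_tibble(observed), .data$j - .data$i > min_sep)
}

#' True positive rate of predicted contacts
#'
#' Fraction of the top `n_c` predicted pairs present in the observed
#' contact map; both sides restricted to `|i - j| > 5`.
#'
#' @param predicted An `eic_set` or ranked tibble with `i`, `j`.
#' @param observed A `contact_map`.
#' @param n_c Number of top predictions to assess.
#' @param min_sep Minimum sequence separation (default 5).
#' @return Fraction in `[0, 1]`.
#' @export
true_positive_rate <- function(predicted, observed, n_c, min_sep = 5L) {
  pred <- top_predicted(predicted, n_c, min_sep)
  obs <- observed_longrange(observed, min_sep)
  if (nrow(pred) == 0L) return(NA_real_)
  hits <- nrow(semi_join(pred, obs, by = c("i", "j")))
  hits / nrow(pred)
}

#' Severity of false-positive predictions
#'
#' Mean, over the top `n_c` predicted pairs, of the Euclidean distance in
#' `(i, j)` index space to the nearest observed contact; true positives
#' contribute zero.
#'
#' @inheritParams true_positive_rate
#' @return Mean index-space distance (>= 0).
#' @export
fp_severity <- function(predicted, observed, n_c, min_sep = 5L) {
  pred <- top_predicted(predicted, n_c, min_sep)
  obs <- observed_longrange(observed, min_sep)
  if (nrow(obs) == 0L) abort("empty observed contact map")
  if (nrow(pred) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(pred)), function(k) {
    min(sqrt((obs$i - pred$i[k])^2 + (obs$j - pred$j[k])^2))
  }, numeric(1)))
}

#' Spread (coverage) of predicted contacts
#'
#' Mean, over all observed long-range contacts, of the index-space
#' distance to the nearest of the top `n_c` predictions — the coverage
#' dual of [fp_severity()].
#'
#' @inheritParams true_positive_rate
#' @return Mean index-space distance (>= 0).
#' @export
contact_spread <- function(predicted, observed, n_c, min_sep = 5L) {
  pred <- top_predicted(predicted, n_c, min_sep)
  obs <- observed_longrange(observed, min_sep)
  if (nrow(pred) == 0L) abort("empty prediction set")
  if (nrow(obs) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(obs)), function(k) {
    min(sqrt((pred$i - obs$i[k])^2 + (pred$j - obs$j[k])^2))
  }, numeric(1)))
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Proper rotation only (no reflection), via SVD with determinant
#' correction.
#'
#' @param p,q `n x 3` coordinate matrices in correspondence.
#' @return `kabsch_superpose()`: list with rotated/translated `p`
#'   (`aligned`), rotation `R`, and `rmsd`. `kabsch_rmsd()`: the scalar
#'   RMSD.
#' @export
kabsch_superpose <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), nrow(p) >= 3L)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  s <- svd(crossprod(pc, qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- sweep(pc %*% t(R), 2L, cq, "+")
  list(aligned = aligned, R = R,
       rmsd = sqrt(mean(rowSums((aligned - q)^2))))
}

#' @rdname kabsch_superpose
#' @export
kabsch_rmsd <- function(p, q) kabsch_superpose(p, q)$rmsd

#' Trimmed C-alpha RMSD
#'
#' Iteratively superposes, drops residue pairs deviating more than
#' `sigma_cut` times the current RMSD, and re-superposes, reporting the
#' final RMSD together with the number of residues it covers (the
#' `"x A (n)"` reporting convention). Trimming never goes below half the
#' residues; hitting that floor sets a flag.
#'
#' @param p,q `n x 3` coordinate matrices in correspondence.
#' @param max_cycles Trimming cycles (default 5).
#' @param sigma_cut Deviation multiplier for rejection (default 2).
#' @param min_fraction Floor on the retained fraction (default 0.5).
#' @return List: `rmsd`, `n_used`, `used` (indices), `flagged`.
#' @export
trimmed_rmsd <- function(p, q, max_cycles = 5L, sigma_cut = 2,
                         min_fraction = 0.5) {
  n <- nrow(p)
  used <- seq_len(n)
  flagged <- FALSE
  fit <- kabsch_superpose(p, q)
  for (cycle in seq_len(max_cycles)) {
    dev <- sqrt(rowSums((fit$aligned - q[used, , drop = FALSE])^2))
    rms <- sqrt(mean(dev^2))
    keep <- dev <= sigma_cut * rms + 1e-8
    if (all(keep)) break
    proposed <- used[keep]
    if (length(proposed) < ceiling(min_fraction * n)) {
      flagged <- TRUE
      break
    }
    used <- proposed
    fit <- kabsch_superpose(p[used, , drop = FALSE], q[used, , drop = FALSE])
  }
  list(rmsd = fit$rmsd, n_used = length(used), used = used,
       flagged = flagged)
}

# fragment-seeded iterative superposition search shared by TM-score and GDT
all_superpositions <- function(p, q, n_iter = 10L, cut = 5) {
  n <- nrow(p)
  starts <- list(seq_len(n))
  widths <- unique(pmax(c(n, n %/% 2L, n %/% 4L, 8L), 4L))
  for (w in widths) {
    if (w >= n) next
    for (s in unique(round(seq(1L, n - w + 1L, length.out = 8L)))) {
      starts[[length(starts) + 1L]] <- s:(s + w - 1L)
    }
  }
  dists <- list()
  for (sub in starts) {
    subset <- sub
    for (it in seq_len(n_iter)) {
      fit <- kabsch_superpose(p[subset, , drop = FALSE],
                              q[subset, , drop = FALSE])
      cp <- colMeans(p[subset, , drop = FALSE])
      cq <- colMeans(q[subset, , drop = FALSE])
      allp <- sweep(sweep(p, 2L, cp) %*% t(fit$R), 2L, cq, "+")
      d <- sqrt(rowSums((allp - q)^2))
      dists[[length(dists) + 1L]] <- d
      cc <- cut
      new_subset <- which(d < cc)
      while (length(new_subset) < 3L) {
        cc <- cc * 1.5
        new_subset <- which(d < cc)
      }
      if (identical(new_subset, subset)) break
      subset <- new_subset
    }
  }
  dists
}

#' TM-score of a model against a reference
#'
#' \deqn{TM = \max \frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' with \eqn{d_0 = 1.24 (L_{ref} - 15)^{1/3} - 1.8} (floored at 0.5 for
#' short chains, flagged), maximized over superpositions found by
#' iterative fragment-seeded refinement.
#'
#' @param model,reference `n x 3` C-alpha matrices (or `fold_model`s) in
#'   correspondence.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score <- function(model, reference) {
  p <- if (is.matrix(model)) model else model$ca
  q <- if (is.matrix(reference)) reference else reference$ca
  lref <- nrow(q)
  d0 <- 1.24 * max(lref - 15, 0)^(1 / 3) - 1.8
  if (lref <= 15 || d0 < 0.5) d0 <- 0.5
  dists <- all_superpositions(p, q, cut = d0)
  max(vapply(dists, function(d) mean(1 / (1 + (d / d0)^2)), numeric(1)))
}

#' GDT-TS of a model against a reference
#'
#' Mean over cutoffs 1, 2, 4, 8 A of the maximal fraction of residues
#' superposable within each cutoff (approximate search by the same
#' fragment-seeded superposition refinement as [tm_score()]), on the
#' 0-100 scale.
#'
#' @inheritParams tm_score
#' @return GDT-TS in `[0, 100]`.
#' @export
gdt_ts <- function(model, reference) {
  p <- if (is.matrix(model)) model else model$ca
  q <- if (is.matrix(reference)) reference else reference$ca
  cuts <- c(1, 2, 4, 8)
  fracs <- vapply(cuts, function(cc) {
    dists <- all_superpositions(p, q, cut = cc)
    max(vapply(dists, function(d) mean(d < cc), numeric(1)))
  }, numeric(1))
  100 * mean(fracs)
}

#' Evaluate predictions against a reference structure
#'
#' Bundles the four contact metrics and three superposition metrics into
#' one tidy report.
#'
#' @param predicted Ranked prediction tibble (`eic_set` or scores).
#' @param observed A `contact_map` of the reference.
#' @param model Best `fold_model` (or NULL to skip 3D metrics).
#' @param reference Reference C-alpha coordinates.
#' @param nc_values N_C values at which to evaluate contact metrics.
#' @return A `eval_report` tibble of metric/value rows; 3D metrics carried
#'   in the `structure_metrics` attribute.
#' @export
evaluate_prediction <- function(predicted, observed, model = NULL,
                                reference = NULL,
                                nc_values = c(10, 20, 30, 50)) {
  contact <- bind_rows(lapply(nc_values, function(nc) {
    tibble(n_c = nc,
           tp_rate = true_positive_rate(predicted, observed, nc),
           fp_severity = fp_severity(predicted, observed, nc),
           spread = contact_spread(predicted, observed, nc))
  }))
  struct <- NULL
  if (!is.null(model) && !is.null(reference)) {
    ca <- if (is.matrix(model)) model else model$ca
    ref <- if (is.matrix(reference)) reference else reference$ca
    tr <- trimmed_rmsd(ca, ref)
    struct <- tibble(ca_rmsd = tr$rmsd, n_used = tr$n_used,
                     flagged = tr$flagged,
                     tm = tm_score(ca, ref), gdt_ts = gdt_ts(ca, ref))
  }
  structure(contact, class = c("eval_report", class(tibble())),
            structure_metrics = struct)
}

#' Structure-level metrics of an evaluation report
#' @param report An `eval_report`.
#' @export
structure_metrics <- function(report) attr(report, "structure_metrics")
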