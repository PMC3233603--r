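#' Secondary-structure track
#'
#' Per-residue 3-state labels (H = helix, E = strand, C = coil) with a
#' confidence in `[0, 1]`.
#'
#' @param states Character vector of labels in `{H, E, C}`.
#' @param confidence Numeric vector in `[0, 1]` (default 1).
#' @return An `ss_track`: a tibble `(pos, state, confidence)` with segment
#'   ids for contiguous H/E runs.
#' @export
ss_track <- function(states, confidence = NULL) {
  states <- toupper(as.character(states))
  stopifnot(all(states %in% c("H", "E", "C")))
  confidence <- confidence %||% rep(1, length(states))
  stopifnot(length(confidence) == length(states),
            all(confidence >= 0 & confidence <= 1))
  run <- cumsum(c(TRUE, states[-1] != states[-length(states)]))
  seg <- ifelse(states == "C", NA_integer_, run)
  out <- tibble(pos = seq_along(states), state = states,
                confidence = confidence, segment = as.integer(seg))
  class(out) <- c("ss_track", class(out))
  out
}

#' Contiguous helix/strand segments of a track
#' @param ss An `ss_track`.
#' @return Tibble `(segment, state, start, end, length)`.
#' @export
ss_segments <- function(ss) {
  ss |>
    filter(!is.na(.data$segment)) |>
    group_by(.data$segment, .data$state) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              length = dplyr::n(), .groups = "drop")
}

#' Read a secondary-structure track
#'
#' Two dialects: a simple three-column text file `position state confidence`
#' (comments with `#`), or PSIPRED-style vertical `.ss2` (`pos aa state
#' p_coil p_helix p_strand`), auto-detected from the column count.
#'
#' @param path File path.
#' @return An [ss_track].
#' @export
read_ss_track <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 6L) {            # PSIPRED vertical format
    states <- toupper(tab[[3L]])
    conf <- apply(tab[, 4:6], 1L, max)
  } else if (ncol(tab) >= 2L) {
    states <- toupper(tab[[2L]])
    conf <- if (ncol(tab) >= 3L) tab[[3L]] else rep(1, nrow(tab))
  } else {
    abort("unrecognized secondary-structure format")
  }
  states[!states %in% c("H", "E", "C")] <- "C"
  ss_track(states, pmin(pmax(conf, 0), 1))
}

#' Write a secondary-structure track (three-column text)
#' @param ss An [ss_track].
#' @param path Output file.
#' @export
write_ss_track <- function(ss, path) {
  write.table(ss[, c("pos", "state", "confidence")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimum-separation filter
#'
#' Retains pairs more than `minsep` apart in the chain (`j - i > minsep`);
#' short-range pairs are trivially in contact and carry no fold information.
#'
#' @param pairs Tibble with columns `i`, `j` (`i < j`).
#' @param minsep Minimum separation (default 5, exclusive).
#' @return The retained rows.
#' @export
filter_min_separation <- function(pairs, minsep = 5L) {
  filter(pairs, .data$j - .data$i > minsep)
}

#' Conservation filter
#'
#' Removes pairs touching a column whose raw modal frequency exceeds
#' `threshold`: near-invariant columns carry too little covariation for the
#' coupling estimate to be meaningful.
#'
#' @param pairs Tibble with columns `i`, `j`.
#' @param conservation Per-column modal frequencies from
#'   [conservation_fraction()] (raw, unweighted).
#' @param threshold Removal threshold (default 0.9, exclusive).
#' @return The retained rows.
#' @export
filter_conservation <- function(pairs, conservation, threshold = 0.9) {
  filter(pairs, conservation[.data$i] <= threshold,
         conservation[.data$j] <= threshold)
}

#' Secondary-structure conflict filter
#'
#' Removes pairs whose two residues fall inside the same predicted helix or
#' the same predicted strand segment: their distance is already dictated by
#' local geometry, and a long-range restraint would conflict with it. Pairs
#' bridging distinct segments always pass.
#'
#' @param pairs Tibble with columns `i`, `j`.
#' @param ss An [ss_track] covering all indices.
#' @return The retained rows.
#' @export
filter_ss_conflict <- function(pairs, ss) {
  seg <- ss$segment
  keep <- is.na(seg[pairs$i]) | is.na(seg[pairs$j]) |
    seg[pairs$i] != seg[pairs$j]
  pairs[keep, , drop = FALSE]
}

#' Cysteine-exclusivity filter
#'
#' Among pairs whose reference residues are both cysteine (candidate
#' disulfide bridges), each cysteine may be used once: walking down the
#' DI-ranked list, a Cys-Cys pair re-using an already-assigned cysteine is
#' removed. Applied last because it is rank-greedy.
#'
#' @param pairs Tibble with columns `i`, `j`, in rank order.
#' @param aln The [alignment] providing reference-sequence residues.
#' @return The retained rows.
#' @export
filter_cysteine_exclusivity <- function(pairs, aln) {
  ref <- reference_codes(aln)
  cys <- encode_residue("C")
  is_cc <- ref[pairs$i] == cys & ref[pairs$j] == cys
  used <- integer(0)
  keep <- rep(TRUE, nrow(pairs))
  for (k in which(is_cc)) {
    if (pairs$i[k] %in% used || pairs$j[k] %in% used) {
      keep[k] <- FALSE
    } else {
      used <- c(used, pairs$i[k], pairs$j[k])
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Default N_C grid
#'
#' From 30 up to the nearest multiple of 10 below or at `L`, in steps of 10;
#' falls back to a single bin at `min(30, largest multiple of 10 <= L)` for
#' short chains.
#'
#' @param L Number of alignment columns.
#' @param from,by Grid start and step.
#' @export
nc_grid <- function(L, from = 30L, by = 10L) {
  top <- by * (L %/% by)
  if (top < from) return(max(by, top))
  seq(from, top, by = by)
}

#' Select evolutionary inferred contacts (EICs)
#'
#' Applies the four filtering rules to the DI-ranked pair list — minimum
#' chain separation, consistency with predicted secondary structure,
#' conservation, and cysteine exclusivity — and returns the first `n_c`
#' survivors.
#'
#' @param scores A `score_table` (or a pre-ranked tibble with `i`, `j`,
#'   `di`).
#' @param n_c Number of contacts to select (>= 1).
#' @param ss Optional [ss_track]; enables the SS-conflict filter.
#' @param aln Optional [alignment]; enables the conservation and cysteine
#'   filters.
#' @param minsep Minimum separation (default 5).
#' @param conservation_threshold Modal-frequency cutoff (default 0.9).
#' @param filters Character subset of
#'   `c("min_separation", "ss_conflict", "conservation", "cys_exclusivity")`.
#' @return An `eic_set` tibble `(rank, i, j, ref_i, ref_j, di)` with an
#'   `audit` attribute recording removed pairs and the rule that removed
#'   them, and a `short` attribute flagging fewer than `n_c` survivors.
#' @export
select_eics <- function(scores, n_c, ss = NULL, aln = NULL, minsep = 5L,
                        conservation_threshold = 0.9,
                        filters = c("min_separation", "ss_conflict",
                                    "conservation", "cys_exclusivity")) {
  if (n_c < 1L) abort("n_c must be at least 1")
  ranked <- if (inherits(scores, "score_table")) tidy(scores) else
    arrange(as_tibble(scores), desc(.data$di), .data$i, .data$j)
  removed <- list()
  note_removed <- function(before, after, rule) {
    gone <- anti_join(before, after, by = c("i", "j"))
    if (nrow(gone)) removed[[rule]] <<- mutate(gone, rule = rule)
    after
  }
  if ("min_separation" %in% filters) {
    ranked <- note_removed(ranked, filter_min_separation(ranked, minsep),
                           "min_separation")
  }
  if ("ss_conflict" %in% filters && !is.null(ss)) {
    ranked <- note_removed(ranked, filter_ss_conflict(ranked, ss),
                           "ss_conflict")
  }
  if ("conservation" %in% filters && !is.null(aln)) {
    cons <- conservation_fraction(aln)
    ranked <- note_removed(ranked,
                           filter_conservation(ranked, cons,
                                               conservation_threshold),
                           "conservation")
  }
  if ("cys_exclusivity" %in% filters && !is.null(aln)) {
    ranked <- note_removed(ranked, filter_cysteine_exclusivity(ranked, aln),
                           "cys_exclusivity")
  }
  short <- nrow(ranked) < n_c
  if (short) {
    warn(sprintf("only %d pairs survive filtering (requested n_c = %d)",
                 nrow(ranked), n_c))
  }
  out <- slice_head(ranked, n = min(n_c, nrow(ranked)))
  out <- mutate(out, rank = row_number(), .before = 1L)
  structure(out, class = c("eic_set", class(tibble())),
            audit = bind_rows(removed), n_c = n_c, short = short)
}

#' Removed-pair audit trail of an EIC selection
#' @param eics An `eic_set`.
#' @return Tibble of removed pairs with the rule that removed each.
#' @export
eic_audit <- function(eics) {
  attr(eics, "audit") %||% tibble()
}

#' Write an EIC set (and its audit trail) as TSV
#' @param eics An `eic_set`.
#' @param path Output file; audit goes to `<path>.audit.tsv`.
#' @export
write_eics <- function(eics, path) {
  write.table(as_tibble(eics), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  audit <- eic_audit(eics)
  if (nrow(audit)) {
    write.table(audit, paste0(path, ".audit.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
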