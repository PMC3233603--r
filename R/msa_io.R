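#' Amino-acid alphabet used throughout
#'
#' Residues are integer-coded 1..21 in the fixed order
#' `A C D E F G H I K L M N P Q R S T V W Y -`, with code 21 the gap state.
#' Ambiguity codes (B, J, O, U, X, Z) and any other character map to the gap
#' code, so the model always works on exactly `q = 21` states.
#'
#' @format Character vector of length 21.
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' Gap code (state q)
#' @export
gap_code <- 21L

#' Encode amino-acid letters as integer states
#'
#' Bijective on the 20 canonical residues, case-insensitive; `-`, `.` and any
#' non-canonical letter encode as the gap state.
#'
#' @param chars Character vector of single characters.
#' @return Integer vector of codes in `1..21`.
#' @export
#' @examples
#' encode_residue(c("A", "a", "-", "X", "Y"))
encode_residue <- function(chars) {
  idx <- match(toupper(chars), aa_alphabet)
  idx[is.na(idx)] <- gap_code
  as.integer(idx)
}

#' Decode integer states back to letters
#' @param codes Integer vector in `1..21`.
#' @return Character vector.
#' @export
decode_residue <- function(codes) {
  stopifnot(all(codes >= 1L & codes <= gap_code))
  aa_alphabet[codes]
}

new_alignment <- function(ids, matrix, column_map, reference_id) {
  structure(
    list(ids = ids, matrix = matrix, column_map = column_map,
         reference_id = reference_id, q = gap_code),
    class = "alignment"
  )
}

#' Construct an alignment object from an integer matrix
#'
#' @param matrix `M x L` integer matrix with codes in `1..q`.
#' @param ids Sequence identifiers (default `seq_1 ..`).
#' @param column_map Optional map from alignment column to reference-sequence
#'   position; computed from the reference row's gaps when `NULL`.
#' @param reference_id Identifier of the protein of interest (default the
#'   first sequence).
#' @param q Alphabet size (21).
#' @return An `alignment` object.
#' @export
alignment <- function(matrix, ids = NULL, column_map = NULL,
                      reference_id = NULL, q = gap_code) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    abort("empty alignment", class = "dcafold_empty_input")
  }
  if (any(matrix < 1L | matrix > q)) {
    abort(sprintf("alignment codes must lie in 1..%d", q),
          class = "dcafold_malformed_alignment")
  }
  ids <- ids %||% paste0("seq_", seq_len(nrow(matrix)))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  reference_id <- reference_id %||% ids[[1L]]
  if (!reference_id %in% ids) abort("reference_id not among sequence ids")
  if (is.null(column_map)) {
    ref <- matrix[match(reference_id, ids), ]
    column_map <- ifelse(ref == q, NA_integer_, cumsum(ref != q))
  }
  new_alignment(ids, matrix, as.integer(column_map), reference_id)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d columns (q = %d), reference: %s\n",
              nrow(x$matrix), ncol(x$matrix), x$q, x$reference_id))
  invisible(x)
}

#' Number of sequences / columns
#' @param x An `alignment` or `weighted_alignment`.
#' @export
n_seq <- function(x) {
  if (inherits(x, "weighted_alignment")) x <- x$alignment
  nrow(x$matrix)
}

#' @rdname n_seq
#' @export
n_col <- function(x) {
  if (inherits(x, "weighted_alignment")) x <- x$alignment
  ncol(x$matrix)
}

#' Reference-sequence residue codes of an alignment
#' @param x An `alignment`.
#' @return Integer vector of length `L`.
#' @export
reference_codes <- function(x) {
  if (inherits(x, "weighted_alignment")) x <- x$alignment
  x$matrix[match(x$reference_id, x$ids), ]
}

parse_fasta_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty file", class = "dcafold_empty_input")
  hdr <- grepl("^>", lines)
  if (!hdr[[1L]]) abort("not FASTA: first line lacks '>'",
                        class = "dcafold_malformed_alignment")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (length(seqs) != length(ids)) {
    abort("FASTA record without sequence", class = "dcafold_malformed_alignment")
  }
  setNames(seqs, ids)
}

parse_stockholm_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty file", class = "dcafold_empty_input")
  body <- lines[!grepl("^#", lines) & !grepl("^//", lines)]
  if (length(body) == 0L) abort("no sequence lines in Stockholm file",
                                class = "dcafold_malformed_alignment")
  parts <- strsplit(trimws(body), "\\s+")
  bad <- lengths(parts) != 2L
  if (any(bad)) abort("malformed Stockholm sequence line",
                      class = "dcafold_malformed_alignment")
  ids <- vapply(parts, `[[`, character(1), 1L)
  seqs <- vapply(parts, `[[`, character(1), 2L)
  # interleaved blocks: concatenate per id, preserving first-seen order
  tapply_order <- unique(ids)
  seqs <- vapply(tapply_order,
                 function(i) paste(seqs[ids == i], collapse = ""), character(1))
  setNames(seqs, tapply_order)
}

#' Read a multiple sequence alignment
#'
#' Parses FASTA or Stockholm alignments in the "focus" dialect: columns
#' containing lowercase letters or `.` are insert states and are dropped;
#' `-` is the gap character; non-canonical letters (X, B, Z, U, O, ...) in
#' match columns encode as the gap state.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`; guessed from the first line when
#'   `NULL`.
#' @param reference_id Protein of interest (default: first sequence).
#' @return An [alignment] object.
#' @export
read_alignment <- function(path, format = NULL, reference_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (is.null(format)) {
    format <- if (any(grepl("^# STOCKHOLM", lines))) "stockholm" else "fasta"
  }
  format <- match.arg(format, c("fasta", "stockholm"))
  seqs <- switch(format,
                 fasta = parse_fasta_lines(lines),
                 stockholm = parse_stockholm_lines(lines))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("ragged alignment: row lengths %s",
                  paste(unique(lens), collapse = ", ")),
          class = "dcafold_malformed_alignment")
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  insert <- apply(chars, 2L, function(col) any(col == "." | grepl("[a-z]", col)))
  chars <- chars[, !insert, drop = FALSE]
  if (ncol(chars) == 0L) abort("no match columns after dropping inserts",
                               class = "dcafold_malformed_alignment")
  mat <- matrix(encode_residue(chars), nrow = nrow(chars))
  alignment(mat, ids = names(seqs), reference_id = reference_id)
}

#' Write an alignment as FASTA
#'
#' @param x An [alignment] (or `weighted_alignment`).
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @export
write_alignment <- function(x, path, width = 60L) {
  if (inherits(x, "weighted_alignment")) x <- x$alignment
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(nrow(x$matrix))) {
    seq <- paste(decode_residue(x$matrix[s, ]), collapse = "")
    writeLines(c(paste0(">", x$ids[[s]]),
                 substring(seq, seq(1L, nchar(seq), width),
                           pmin(seq(1L, nchar(seq), width) + width - 1L,
                                nchar(seq)))),
               con)
  }
  invisible(path)
}

one_hot <- function(mat, q) {
  m <- nrow(mat); l <- ncol(mat)
  Matrix::sparseMatrix(
    i = rep(seq_len(m), l),
    j = as.integer(mat + q * (rep(seq_len(l), each = m) - 1L)),
    x = 1,
    dims = c(m, l * q)
  )
}

#' Down-weight redundant sequences
#'
#' Each sequence receives weight `1 / n_s`, where `n_s` is the number of
#' alignment rows (including itself) with fractional identity at least
#' `theta`. Identity is computed over all alignment columns, with gap-gap
#' positions counting as matches (switchable via `include_gaps`). The sum of
#' weights is the effective sequence number `meff`.
#'
#' @param aln An [alignment].
#' @param theta Identity threshold in (0,1); default 0.7, boundary inclusive.
#' @param include_gaps Count gap-gap coincidences as identities (default TRUE).
#' @return A `weighted_alignment`: list with `alignment`, `weights`, `theta`,
#'   `meff`.
#' @export
compute_weights <- function(aln, theta = 0.7, include_gaps = TRUE) {
  stopifnot(inherits(aln, "alignment"), theta > 0, theta < 1)
  mat <- aln$matrix
  m <- nrow(mat); l <- ncol(mat)
  X <- one_hot(mat, aln$q)
  ident <- as.matrix(Matrix::tcrossprod(X))
  if (!include_gaps) {
    # drop gap-gap coincidences from the identity count
    gap_cols <- seq(aln$q, l * aln$q, by = aln$q)
    ident <- ident - as.matrix(Matrix::tcrossprod(X[, gap_cols, drop = FALSE]))
  }
  frac <- ident / l
  nbh <- rowSums(frac >= theta - 1e-12)
  w <- 1 / nbh
  structure(
    list(alignment = aln, weights = w, theta = theta, meff = sum(w),
         include_gaps = include_gaps),
    class = "weighted_alignment"
  )
}

#' @export
print.weighted_alignment <- function(x, ...) {
  cat(sprintf(
    "<weighted_alignment> M = %d, L = %d, theta = %.2f, Meff = %.2f (%.0f%% effective)\n",
    n_seq(x), n_col(x), x$theta, x$meff, 100 * x$meff / n_seq(x)))
  invisible(x)
}

#' Sequence weights as a tibble
#' @param x A `weighted_alignment`.
#' @param ... Unused.
#' @export
tidy.weighted_alignment <- function(x, ...) {
  tibble(id = x$alignment$ids, weight = x$weights)
}

#' @export
glance.weighted_alignment <- function(x, ...) {
  tibble(n_seq = n_seq(x), n_col = n_col(x), theta = x$theta,
         meff = x$meff, effective_fraction = x$meff / n_seq(x))
}

#' Write sequence weights as two-column TSV
#' @param x A `weighted_alignment`.
#' @param path Output file.
#' @export
write_weights <- function(x, path) {
  write.table(tidy(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subsample an alignment, always retaining the reference sequence
#'
#' @param aln An [alignment].
#' @param n Number of sequences to keep, `1 <= n <= M`.
#' @param seed Integer seed; the draw is deterministic for a fixed seed.
#' @return An [alignment] with `n` rows.
#' @export
subsample <- function(aln, n, seed) {
  stopifnot(inherits(aln, "alignment"))
  m <- n_seq(aln)
  if (n < 1L || n > m) abort(sprintf("n must be in 1..%d, got %s", m, n))
  ref <- match(aln$reference_id, aln$ids)
  keep <- with_seed(seed, {
    pool <- setdiff(seq_len(m), ref)
    sort(c(ref, sample(pool, n - 1L)))
  })
  alignment(aln$matrix[keep, , drop = FALSE], ids = aln$ids[keep],
            reference_id = aln$reference_id)
}
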