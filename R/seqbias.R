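# Sequence-bias analysis: exhaustive enumeration of the constrained central
# sequence space (P3-P8), energy-based top-fraction selection, position
# probability matrices with the 0.02 floor, and per-position
# Kullback-Leibler divergence.  Energies come from an external scorer or
# the packaged surrogate.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

#' Read per-position alphabets from a TSV
#'
#' Two columns: `position` (e.g. `P3`) and `amino_acids` (comma-separated
#' one-letter codes).  The packaged example
#' (`system.file("extdata", "a0201_position_alphabets.tsv",
#' package = "phlatlas")`) restricts P3-P8 to 8-12 residues each (proline
#' always included) and is user-replaceable configuration.
#'
#' @param path TSV path.
#' @return named list of character vectors, ordered by position.
#' @export
read_position_alphabets <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "amino_acids") %in% names(tab)))
  al <- lapply(tab$amino_acids, function(s) strsplit(gsub("\\s", "", s), ",")[[1]])
  names(al) <- tab$position
  al
}

#' Enumerate the constrained sequence space
#'
#' Cartesian product of the per-position alphabets in lexicographic order
#' (last position varies fastest).  The count is always returned; the
#' sequences themselves are materialized only on request, so the full
#' product can be counted without building it.
#'
#' @param alphabets named list of non-empty character vectors (per position).
#' @param materialize logical; build the sequence vector (default TRUE when
#'   the count is at most `limit`).
#' @param limit materialization guard (default 1e6).
#' @return list with `count` and `sequences` (character vector or NULL).
#' @export
enumerate_space <- function(alphabets, materialize = NULL, limit = 1e6) {
  if (length(alphabets) == 0 || any(lengths(alphabets) == 0)) {
    stop("empty alphabet")
  }
  alphabets <- lapply(alphabets, sort)
  count <- prod(lengths(alphabets))
  if (is.null(materialize)) materialize <- count <= limit
  seqs <- NULL
  if (materialize) {
    if (count > limit) stop("refusing to materialize ", count, " sequences")
    grid <- expand.grid(rev(alphabets), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    seqs <- do.call(paste0, rev(grid))
  }
  list(count = count, sequences = seqs)
}

#' Retain the top fraction of scored sequences by energy
#'
#' Keeps the `floor(fraction * N)` entries with the lowest score (lower is
#' better).  Ties break by input order, so the selection is deterministic
#' and equals a stable full sort followed by head().
#'
#' @param scored data.frame with columns `sequence` and `score`.
#' @param fraction fraction to retain (default 0.01).
#' @return the retained rows, in ascending score order.
#' @export
top_fraction <- function(scored, fraction = 0.01) {
  stopifnot(is.data.frame(scored), all(c("sequence", "score") %in% names(scored)))
  if (any(!is.finite(scored$score))) stop("non-finite scores")
  k <- floor(fraction * nrow(scored))
  if (k == 0) return(scored[0, , drop = FALSE])
  ord <- order(scored$score, seq_len(nrow(scored)))
  scored[ord[seq_len(k)], , drop = FALSE]
}

#' Position probability matrix with the 0.02 floor
#'
#' Per-position amino-acid frequencies over the 20 standard residues; cells
#' that are exactly zero are set to 0.02 and the columns are deliberately
#' not renormalized afterwards -- only zeroes are floored, so floored
#' columns sum to slightly more than 1.
#'
#' @param sequences equal-length peptide sequences.
#' @param floor replacement for zero cells (default 0.02).
#' @return matrix of class `ppm`, 20 amino acids (rows) x positions
#'   (columns); attribute `raw` holds the pre-floor frequencies.
#' @export
build_ppm <- function(sequences, floor = 0.02) {
  stopifnot(length(sequences) >= 1)
  L <- nchar(sequences[1])
  if (any(nchar(sequences) != L)) stop("sequences differ in length")
  mat <- matrix(0, nrow = 20, ncol = L,
                dimnames = list(AA20, paste0("P", seq_len(L))))
  chars <- strsplit(sequences, "")
  for (p in seq_len(L)) {
    tab <- table(factor(vapply(chars, `[`, "", p), levels = AA20))
    mat[, p] <- as.numeric(tab) / length(sequences)
  }
  raw <- mat
  mat[mat == 0] <- floor
  structure(mat, raw = raw, class = c("ppm", "matrix"))
}

#' Per-position Kullback-Leibler divergence between two PPMs
#'
#' `sum_a p(a) * ln(p(a) / q(a))` in nats.  Terms with `p(a) = 0` contribute
#' zero; the floor guarantees `q > 0`.
#'
#' @param p,q `ppm` matrices over the same alphabet.
#' @param position column index or name; `NULL` returns all positions.
#' @return named numeric vector (nats).
#' @export
kl_divergence <- function(p, q, position = NULL) {
  stopifnot(identical(rownames(p), rownames(q)))
  cols <- if (is.null(position)) seq_len(ncol(p)) else position
  out <- vapply(cols, function(j) {
    pj <- p[, j]
    qj <- q[, j]
    if (any(!is.finite(pj)) || any(!is.finite(qj)) || any(qj <= 0)) {
      stop("non-finite or non-positive PPM entries")
    }
    nz <- pj > 0
    sum(pj[nz] * log(pj[nz] / qj[nz]))
  }, 0.0)
  names(out) <- colnames(p)[if (is.character(cols)) match(cols, colnames(p)) else cols]
  out
}

#' Score an enumerated sequence space and retain the top fraction
#'
#' Convenience pipeline: enumerate, score every sequence with `scorer`
#' (a function `character -> numeric`, lower is better), keep the top
#' fraction, and build the retained-set PPM.
#'
#' @param alphabets per-position alphabets.
#' @param scorer vectorized scoring function.
#' @param fraction retained fraction (default 0.01).
#' @param floor PPM floor.
#' @return list with `count`, `retained` (data.frame), `ppm`.
#' @export
score_and_select <- function(alphabets, scorer, fraction = 0.01,
                             floor = 0.02) {
  sp <- enumerate_space(alphabets, materialize = TRUE)
  scored <- data.frame(sequence = sp$sequences,
                       score = scorer(sp$sequences),
                       stringsAsFactors = FALSE)
  kept <- top_fraction(scored, fraction)
  list(count = sp$count, retained = kept, ppm = build_ppm(kept$sequence, floor))
}
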