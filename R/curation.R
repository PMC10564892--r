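# Curation: chain classification against reference sequences, retention
# filters, platform trimming/renumbering and HLA typing.  The end product is
# a standardized complex: 180-residue platform (chain A, residues 1-180) plus
# an 8-10-mer peptide (chain C, residues 1-n).

# Mature beta-2 microglobulin, used as the classification reference.
B2M_REFERENCE <- paste0(
  "IQRTPKIQVYSRHPAENGKSNFLNCYVSGFHPSDIEVDLLKNGERIEKVEHSDLSFSKDWSFYLLYYTEF",
  "TPTEKDEYACRVNHVTLSQPKIVKWDRDM")

PLATFORM_LENGTH <- 180L

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Sanitize a sequence for alignment: anything outside the BLOSUM62 alphabet
# becomes X.
.clean_aa <- function(seq) {
  chartr(" ", "X", gsub("[^ARNDCQEGHILKMFPSTWYVBZX*-]", "X", toupper(seq)))
}

#' Global alignment identity against a reference sequence
#'
#' Needleman-Wunsch alignment with BLOSUM62; identity is the number of
#' matched identical positions divided by the reference length.
#'
#' @param seq,ref one-letter amino-acid strings.
#' @return list with `identity` in `[0, 1]` and `n_missing_nterm`, the number
#'   of leading reference positions not covered by `seq`.
#' @export
align_identity <- function(seq, ref) {
  if (!nzchar(seq) || !nzchar(ref)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(.clean_aa(seq)), Biostrings::AAString(.clean_aa(ref)),
    substitutionMatrix = .blosum62, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  lead <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") break
    if (s[k] != "-") lead <- lead + 1L
  }
  list(identity = matches / nchar(ref), n_missing_nterm = lead)
}

# Per-chain one-letter sequences, residues in file order.
chain_sequences <- function(entry) {
  at <- entry$atoms
  chains <- unique(at$chain)
  setNames(lapply(chains, function(ch) {
    sub <- at[at$chain == ch, , drop = FALSE]
    resnos <- unique(sub$resno)
    paste(aa3to1(vapply(resnos, function(r) sub$resid[sub$resno == r][1], "")),
          collapse = "")
  }), chains)
}

# Keep blank or 'A' alternate locations only.
prune_altloc <- function(atoms) {
  keep <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
  atoms[keep, , drop = FALSE]
}

#' Classify the chains of a raw entry
#'
#' A chain with >50% global-alignment identity to the 180-residue reference
#' heavy chain is the HLA heavy chain; >50% identity to beta-2 microglobulin
#' is b2m; an 8-10-residue chain is a peptide; everything else is "other".
#'
#' @param entry a `raw_entry`.
#' @param reference_heavy 180-residue reference heavy-chain sequence.
#' @param reference_b2m beta-2 microglobulin reference sequence.
#' @return data.frame with columns chain, role, identity, length,
#'   n_missing_nterm (heavy chains only), ordered as in the file.
#' @export
classify_chains <- function(entry, reference_heavy,
                            reference_b2m = B2M_REFERENCE) {
  if (!nzchar(reference_heavy) || !nzchar(reference_b2m)) {
    stop("empty reference sequence")
  }
  seqs <- chain_sequences(entry)
  rows <- lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    n <- nchar(s)
    role <- "other"
    ident <- NA_real_
    nmiss <- NA_integer_
    hv <- align_identity(s, reference_heavy)
    if (hv$identity > 0.5) {
      role <- "heavy_chain"
      ident <- hv$identity
      nmiss <- hv$n_missing_nterm
    } else {
      b2 <- align_identity(s, reference_b2m)
      if (b2$identity > 0.5) {
        role <- "b2m"
        ident <- b2$identity
      } else if (n >= 8 && n <= 10) {
        role <- "peptide"
        ident <- 0
      } else {
        ident <- hv$identity
      }
    }
    data.frame(chain = ch, role = role, identity = ident, length = n,
               n_missing_nterm = nmiss, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accept/reject decision for a classified entry
#'
#' Applies the retention filters: resolution at or better than
#' `resolution_max`; no non-pHLA chain with an atom within `contact_cutoff`
#' of the peptide; complete peptide backbone heavy atoms (N, CA, C, O) with
#' positive occupancy; heavy chain long enough to yield the 180-residue
#' platform.  Zero-occupancy heavy-chain atoms are reported as a warning
#' flag, not a rejection; 1-2 missing N-terminal heavy-chain residues set the
#' `rebuilt_nterm_needed` flag (rebuilding is left to external tools).
#'
#' @param entry a `raw_entry`.
#' @param roles output of [classify_chains()].
#' @param resolution_max resolution cutoff in Angstrom (default 3.0).
#' @param contact_cutoff other-chain contact cutoff in Angstrom (default 5).
#' @return list with `accept`, character `reasons`, and logical `flags`
#'   (`rebuilt_nterm_needed`, `heavy_chain_occupancy_warning`).
#' @export
filter_entry <- function(entry, roles, resolution_max = 3.0,
                         contact_cutoff = 5.0) {
  reasons <- character()
  flags <- list(rebuilt_nterm_needed = FALSE,
                heavy_chain_occupancy_warning = FALSE)
  at <- prune_altloc(entry$atoms)
  if (is.na(entry$resolution) || entry$resolution > resolution_max) {
    reasons <- c(reasons, "resolution")
  }
  heavy <- roles$chain[roles$role == "heavy_chain"]
  pep <- roles$chain[roles$role == "peptide"]
  if (length(heavy) == 0) reasons <- c(reasons, "no_heavy_chain")
  if (length(pep) == 0) reasons <- c(reasons, "no_peptide")
  if (length(heavy) > 0 && length(pep) > 0) {
    heavy <- heavy[1]
    pep <- pep[1]
    others <- roles$chain[roles$role == "other"]
    pxyz <- as.matrix(at[at$chain == pep, c("x", "y", "z")])
    for (oc in others) {
      oxyz <- as.matrix(at[at$chain == oc, c("x", "y", "z")])
      if (nrow(oxyz) > 0 && .min_cross_dist(oxyz, pxyz) < contact_cutoff) {
        reasons <- c(reasons, "other_chain_contact")
        break
      }
    }
    ps <- at[at$chain == pep, , drop = FALSE]
    for (r in unique(ps$resno)) {
      res <- ps[ps$resno == r, , drop = FALSE]
      bb <- res[res$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
      if (length(unique(bb$elety)) < 4) {
        reasons <- c(reasons, "peptide_backbone_incomplete")
        break
      }
      if (any(bb$o <= 0)) {
        reasons <- c(reasons, "peptide_zero_occupancy")
        break
      }
    }
    hs <- at[at$chain == heavy, , drop = FALSE]
    if (any(hs$o <= 0)) flags$heavy_chain_occupancy_warning <- TRUE
    nmiss <- roles$n_missing_nterm[roles$chain == heavy]
    nmiss <- if (is.na(nmiss)) 0L else nmiss
    if (nmiss >= 1 && nmiss <= 2) flags$rebuilt_nterm_needed <- TRUE
    if (length(unique(hs$resno)) + min(nmiss, 2L) < PLATFORM_LENGTH) {
      reasons <- c(reasons, "heavy_chain_too_short")
    }
  }
  list(accept = length(reasons) == 0, reasons = reasons, flags = flags)
}

.min_cross_dist <- function(a, b) {
  # Smallest distance between two coordinate sets, chunked to bound memory.
  best <- Inf
  step <- 2000L
  for (i in seq(1, nrow(a), by = step)) {
    ai <- a[i:min(i + step - 1, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), rowSums(b^2), "+") - 2 * ai %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Trim and renumber an accepted entry
#'
#' The heavy chain is truncated to the platform (first 180 residues counted
#' from the reference N-terminus) and renumbered 1-180 as chain A; the
#' peptide is renumbered 1-n as chain C.  Entries flagged for missing
#' N-terminal residues keep reference numbering (their platform starts at
#' residue 2 or 3).
#'
#' @param entry a `raw_entry` that passed [filter_entry()].
#' @param roles output of [classify_chains()].
#' @param flags flags from [filter_entry()].
#' @return a `curated_complex` (allotype unset until [type_hla()]).
#' @export
renumber_and_trim <- function(entry, roles, flags = list()) {
  at <- prune_altloc(entry$atoms)
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]  # heavy atoms only
  heavy <- roles$chain[roles$role == "heavy_chain"][1]
  pep <- roles$chain[roles$role == "peptide"][1]
  nmiss <- roles$n_missing_nterm[roles$chain == heavy]
  nmiss <- if (is.na(nmiss)) 0L else min(nmiss, 2L)
  hs <- at[at$chain == heavy, , drop = FALSE]
  resnos <- unique(hs$resno)
  keep_n <- PLATFORM_LENGTH - nmiss
  if (length(resnos) < keep_n) stop("heavy chain shorter than the platform")
  resnos <- resnos[seq_len(keep_n)]
  hs <- hs[hs$resno %in% resnos, , drop = FALSE]
  hs$resno <- match(hs$resno, resnos) + nmiss
  hs$chain <- "A"
  ps <- at[at$chain == pep, , drop = FALSE]
  presno <- unique(ps$resno)
  ps$resno <- match(ps$resno, presno)
  ps$chain <- "C"
  atoms <- rbind(hs, ps)
  rownames(atoms) <- NULL
  plat_seq <- paste(aa3to1(vapply(sort(unique(hs$resno)),
                                  function(r) hs$resid[hs$resno == r][1], "")),
                    collapse = "")
  pep_seq <- paste(aa3to1(vapply(sort(unique(ps$resno)),
                                 function(r) ps$resid[ps$resno == r][1], "")),
                   collapse = "")
  structure(list(pdb_id = entry$pdb_id, atoms = atoms,
                 platform_sequence = plat_seq, peptide_sequence = pep_seq,
                 allotype = NA_character_, allotype_identity = NA_real_,
                 resolution = entry$resolution,
                 release_date = entry$release_date,
                 flags = modifyList(list(rebuilt_nterm_needed = FALSE,
                                         heavy_chain_occupancy_warning = FALSE),
                                    flags)),
            class = "curated_complex")
}

#' @export
print.curated_complex <- function(x, ...) {
  cat(sprintf("curated_complex %s: %s, peptide %s (%d-mer), %.2f A, %s\n",
              x$pdb_id, ifelse(is.na(x$allotype), "untyped", x$allotype),
              x$peptide_sequence, nchar(x$peptide_sequence),
              x$resolution, x$release_date))
  invisible(x)
}

#' HLA typing by pairwise alignment against a reference allele set
#'
#' @param platform_sequence platform (alpha1/alpha2) sequence.
#' @param reference_fasta path to a FASTA of reference allele sequences
#'   (record names are allele names), or a named character vector.
#' @return list with `allotype`, `identity`, and `ok` (FALSE when the best
#'   identity is <= 0.5).  Ties break to the lexicographically smallest
#'   allele name.
#' @export
type_hla <- function(platform_sequence, reference_fasta) {
  refs <- if (is.character(reference_fasta) && length(reference_fasta) == 1 &&
              file.exists(reference_fasta)) {
    s <- Biostrings::readAAStringSet(reference_fasta)
    setNames(as.character(s), names(s))
  } else if (is.character(reference_fasta) && !is.null(names(reference_fasta))) {
    reference_fasta
  } else {
    stop("reference_fasta must be a FASTA path or a named character vector")
  }
  if (length(refs) == 0) stop("empty allele reference")
  ids <- vapply(refs, function(r) align_identity(platform_sequence, r)$identity,
                0.0)
  best <- max(ids)
  cand <- sort(names(ids)[ids == best])
  list(allotype = cand[1], identity = best, ok = best > 0.5)
}

#' Curate a single entry end to end
#'
#' Classify chains, filter, trim/renumber and type.  Already-curated
#' complexes pass through unchanged (idempotence).
#'
#' @param entry a `raw_entry`.
#' @param reference_heavy reference heavy-chain sequence (180 residues).
#' @param reference_fasta allele reference FASTA (path or named vector) for
#'   typing; `NULL` skips typing.
#' @param reference_b2m b2m reference sequence.
#' @param resolution_max resolution cutoff (default 3.0).
#' @return list with `accepted`; on success `complex`, else `reasons`.
#' @export
curate_entry <- function(entry, reference_heavy, reference_fasta = NULL,
                         reference_b2m = B2M_REFERENCE, resolution_max = 3.0) {
  roles <- classify_chains(entry, reference_heavy, reference_b2m)
  dec <- filter_entry(entry, roles, resolution_max = resolution_max)
  if (!dec$accept) {
    return(list(accepted = FALSE, reasons = dec$reasons, roles = roles))
  }
  cx <- renumber_and_trim(entry, roles, dec$flags)
  if (!is.null(reference_fasta)) {
    ty <- type_hla(cx$platform_sequence, reference_fasta)
    cx$allotype <- ty$allotype
    cx$allotype_identity <- ty$identity
    cx$flags$typing_failed <- !ty$ok
  }
  list(accepted = TRUE, complex = cx, roles = roles)
}

#' Curate a directory of coordinate files
#'
#' Runs [curate_entry()] over every `.pdb`/`.cif` file, writes curated
#' complexes as PDB files (platform chain A, peptide chain C), a dataset
#' summary FASTA and a TSV rejection log.
#'
#' @param in_dir input directory.
#' @param reference_fasta allele reference FASTA; its `A*02:01` record (or
#'   the first record) also serves as the classification reference heavy
#'   chain.
#' @param out_dir output directory (created if needed).
#' @param resolution_max resolution cutoff.
#' @return invisible list of curated complexes.
#' @export
curate_dir <- function(in_dir, reference_fasta, out_dir,
                       resolution_max = 3.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- Biostrings::readAAStringSet(reference_fasta)
  ref_heavy <- as.character(refs[[if (any(grepl("A\\*02:01", names(refs))))
    grep("A\\*02:01", names(refs))[1] else 1]])
  ref_heavy <- substr(ref_heavy, 1, PLATFORM_LENGTH)
  files <- list.files(in_dir, pattern = "\\.(pdb|ent|cif)$", full.names = TRUE)
  complexes <- list()
  log <- data.frame(pdb_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  for (f in files) {
    res <- tryCatch({
      entry <- read_entry(f)
      curate_entry(entry, ref_heavy, reference_fasta,
                   resolution_max = resolution_max)
    }, error = function(e) list(accepted = FALSE, reasons = "parse_error"))
    id <- toupper(sub("\\.[^.]+$", "", basename(f)))
    if (res$accepted) {
      cx <- res$complex
      complexes[[cx$pdb_id]] <- cx
      write_pdb_file(cx$atoms, file.path(out_dir, paste0(cx$pdb_id, ".pdb")),
                     pdb_id = cx$pdb_id, resolution = cx$resolution,
                     release_date = cx$release_date)
    } else {
      log <- rbind(log, data.frame(pdb_id = id,
                                   reason = paste(res$reasons, collapse = ";"),
                                   stringsAsFactors = FALSE))
    }
  }
  if (length(complexes)) {
    write_summary_fasta(complexes, file.path(out_dir, "summary.fasta"))
  }
  write.table(log, file.path(out_dir, "rejected.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(complexes)
}
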