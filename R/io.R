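# Coordinate-file input/output.  PDB reading goes through bio3d; a minimal
# mmCIF atom_site reader covers CIF inputs.  Writing uses a thin ATOM-record
# writer so that resolution and release date survive a curation round trip
# in the header (HEADER / REMARK 2 records).

#' Raw structure entry
#'
#' A lightly parsed coordinate file: an atom table plus the metadata the
#' curation filters need.
#'
#' @param pdb_id 4-character accession (uppercased).
#' @param atoms data.frame with columns chain, resno, resid (3-letter),
#'   elety, alt, x, y, z, o, b.
#' @param resolution resolution in Angstrom (> 0).
#' @param release_date ISO date string.
#' @param experiment_type free text, default "X-RAY DIFFRACTION".
#' @return object of class `raw_entry`.
#' @export
raw_entry <- function(pdb_id, atoms, resolution, release_date = NA_character_,
                      experiment_type = "X-RAY DIFFRACTION") {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety", "x", "y", "z", "o") %in%
                  names(atoms)))
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be > 0")
  if (is.null(atoms$alt)) atoms$alt <- NA_character_
  if (is.null(atoms$b)) atoms$b <- 0
  structure(list(pdb_id = toupper(pdb_id), atoms = atoms,
                 resolution = resolution, release_date = release_date,
                 experiment_type = experiment_type),
            class = "raw_entry")
}

#' @export
print.raw_entry <- function(x, ...) {
  cat(sprintf("raw_entry %s: %d atoms, chains %s, resolution %s A\n",
              x$pdb_id, nrow(x$atoms),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              format(x$resolution)))
  invisible(x)
}

# PDB month abbreviations used in HEADER records.
.pdb_months <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
                 "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")

.parse_header_date <- function(tok) {
  # DD-MMM-YY -> ISO.  Two-digit years: <50 maps to 20xx, else 19xx.
  m <- regmatches(tok, regexec("([0-9]{2})-([A-Z]{3})-([0-9]{2})", tok))[[1]]
  if (length(m) != 4) return(NA_character_)
  yy <- as.integer(m[4])
  year <- if (yy < 50) 2000L + yy else 1900L + yy
  sprintf("%04d-%02d-%02d", year, match(m[3], .pdb_months), as.integer(m[2]))
}

#' Read a coordinate file into a raw entry
#'
#' PDB files are parsed with bio3d; mmCIF files with a minimal atom_site
#' reader.  Resolution and release date are scraped from the header when
#' present and can be overridden.
#'
#' @param path file path (`.pdb`, `.ent`, or `.cif`).
#' @param pdb_id accession; defaults to the file stem.
#' @param resolution,release_date optional metadata overrides.
#' @return a `raw_entry`.
#' @export
read_entry <- function(path, pdb_id = NULL, resolution = NULL,
                       release_date = NULL) {
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  if (is_cif) {
    parsed <- .read_mmcif(path)
  } else {
    parsed <- .read_pdb_file(path)
  }
  if (is.null(pdb_id)) {
    pdb_id <- if (!is.null(parsed$pdb_id) && !is.na(parsed$pdb_id)) {
      parsed$pdb_id
    } else {
      toupper(sub("\\.[^.]+$", "", basename(path)))
    }
  }
  if (!is.null(resolution)) parsed$resolution <- resolution
  if (!is.null(release_date)) parsed$release_date <- release_date
  raw_entry(pdb_id, parsed$atoms, parsed$resolution, parsed$release_date,
            parsed$experiment_type)
}

.read_pdb_file <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unreadable coordinates: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, alt = at$alt,
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  res <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1], regexec("RESOLUTION\\.\\s*([0-9.]+)", rl[1]))[[1]]
    if (length(m) == 2) res <- as.numeric(m[2])
  }
  date <- NA_character_
  id <- NA_character_
  hl <- grep("^HEADER", lines, value = TRUE)
  if (length(hl)) {
    date <- .parse_header_date(substr(hl[1], 51, 59))
    id0 <- trimws(substr(hl[1], 63, 66))
    if (nzchar(id0)) id <- toupper(id0)
  }
  expt <- "X-RAY DIFFRACTION"
  el <- grep("^EXPDTA", lines, value = TRUE)
  if (length(el)) expt <- trimws(substr(el[1], 11, 79))
  list(atoms = atoms, resolution = res, release_date = date,
       experiment_type = expt, pdb_id = id)
}

# Minimal mmCIF reader: the atom_site loop plus resolution / revision date.
# Only whitespace-delimited atom_site loops (the layout written by the PDB)
# are supported.
.read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^_atom_site\\.", lines)
  if (!length(li)) stop("unreadable coordinates: no _atom_site loop")
  fields <- sub("^_atom_site\\.", "", trimws(lines[li]))
  body_start <- max(li) + 1
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "#" || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "data_")) break
    if (nzchar(ln)) body <- c(body, ln)
  }
  tok <- strsplit(body, "[[:space:]]+")
  bad <- vapply(tok, length, 1L) != length(fields)
  tok <- tok[!bad]
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  grab <- function(nm, default = NA_character_) {
    if (nm %in% fields) m[, nm] else rep(default, nrow(m))
  }
  keep <- grab("group_PDB", "ATOM") == "ATOM"
  alt <- grab("label_alt_id")
  alt[alt == "."] <- NA_character_
  atoms <- data.frame(
    chain = grab("auth_asym_id", grab("label_asym_id")),
    resno = as.integer(grab("auth_seq_id", grab("label_seq_id"))),
    resid = grab("auth_comp_id", grab("label_comp_id")),
    elety = grab("label_atom_id"),
    alt = alt,
    x = as.numeric(grab("Cartn_x")), y = as.numeric(grab("Cartn_y")),
    z = as.numeric(grab("Cartn_z")),
    o = as.numeric(grab("occupancy", "1")),
    b = as.numeric(grab("B_iso_or_equiv", "0")),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  res <- NA_real_
  rl <- grep("^_refine\\.ls_d_res_high", lines, value = TRUE)
  if (length(rl)) res <- suppressWarnings(as.numeric(strsplit(trimws(rl[1]),
                                                   "[[:space:]]+")[[1]][2]))
  date <- NA_character_
  dl <- grep("[0-9]{4}-[0-9]{2}-[0-9]{2}",
             grep("revision_date|recvd_initial", lines, value = TRUE),
             value = TRUE)
  if (length(dl)) {
    date <- regmatches(dl[1], regexpr("[0-9]{4}-[0-9]{2}-[0-9]{2}", dl[1]))
  }
  list(atoms = atoms, resolution = res, release_date = date,
       experiment_type = "X-RAY DIFFRACTION")
}

.iso_to_header_date <- function(iso) {
  if (is.na(iso)) return("01-JAN-00")
  p <- as.integer(strsplit(iso, "-")[[1]])
  sprintf("%02d-%s-%02d", p[3], .pdb_months[p[2]], p[1] %% 100)
}

# Three-letter <-> one-letter via bio3d's residue table.
aa3to1 <- function(resid) bio3d::aa321(resid)
aa1to3 <- function(aa) bio3d::aa123(aa)

#' Write an atom table as a PDB file
#'
#' Emits HEADER (release date), REMARK 2 (resolution) and ATOM records so a
#' curated complex round-trips through [read_entry()].
#'
#' @param atoms atom data.frame (see [raw_entry()]).
#' @param path output file.
#' @param pdb_id accession written into the HEADER record.
#' @param resolution,release_date metadata for the header.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(atoms, path, pdb_id = "XXXX", resolution = NA,
                           release_date = NA_character_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("HEADER    PEPTIDE/HLA COMPLEX                     %s   %s",
                     .iso_to_header_date(release_date), toupper(pdb_id)), con)
  if (!is.na(resolution)) {
    writeLines(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution), con)
  }
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno), ,
                 drop = FALSE]
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    name <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    writeLines(sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       i, name,
                       ifelse(is.na(a$alt), " ", a$alt),
                       a$resid, a$chain, a$resno, a$x, a$y, a$z, a$o, a$b), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Dataset summary FASTA
#'
#' One header/sequence record per chain of each curated complex.  Header
#' fields, `|`-delimited and in order: PDB ID, chain name (`HLA` or
#' `peptide`), allele, release date, resolution.
#'
#' @param complexes list of `curated_complex` objects.
#' @param path output file; `NULL` returns the text.
#' @return the FASTA lines, invisibly when written to a file.
#' @export
write_summary_fasta <- function(complexes, path = NULL) {
  lines <- character()
  for (cx in complexes) {
    hdr <- function(chain) sprintf(">%s|%s|%s|%s|%s", cx$pdb_id, chain,
                                   cx$allotype, cx$release_date,
                                   format(cx$resolution))
    lines <- c(lines, hdr("HLA"), cx$platform_sequence,
               hdr("peptide"), cx$peptide_sequence)
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a dataset summary FASTA back into a metadata table
#'
#' @param path file written by [write_summary_fasta()].
#' @return data.frame with pdb_id, chain, allotype, release_date, resolution,
#'   sequence.
#' @export
read_summary_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hi <- grep("^>", lines)
  out <- lapply(hi, function(i) {
    f <- strsplit(sub("^>", "", lines[i]), "|", fixed = TRUE)[[1]]
    data.frame(pdb_id = f[1], chain = f[2], allotype = f[3],
               release_date = f[4], resolution = as.numeric(f[5]),
               sequence = lines[i + 1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
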