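# Synthetic data generation.  Every module is testable offline: toy pHLA
# coordinate files with a dummy platform scaffold, dihedral-sampled backbone
# families, and feature tables with a planted monotone feature -> D-score
# relation.  None of this is physically realistic and none of it pretends
# to be; the geometry is just sufficient for the code paths it exercises.

#' Reference platform sequence shipped with the package
#'
#' The HLA-A*02:01 alpha1/alpha2 (platform) sequence trimmed to 180
#' residues, read from `inst/extdata/reference_alleles.fasta`.
#'
#' @return one-letter string of length 180.
#' @export
reference_platform_sequence <- function() {
  f <- system.file("extdata", "reference_alleles.fasta", package = "phlatlas")
  s <- Biostrings::readAAStringSet(f)
  substr(as.character(s[[grep("A\\*02:01", names(s))[1]]]), 1, PLATFORM_LENGTH)
}

#' Specification for a synthetic toy complex
#'
#' @param peptide_length 8-10 (default 9).
#' @param phi_mean,psi_mean per-position dihedral means in degrees
#'   (recycled; defaults are the ideal PPII angles).
#' @param phi_sd,psi_sd per-position standard deviations (default 0).
#' @param anchors length-2 vector: the peptide positions placed nearest the
#'   B- and F-pocket probes (default P2 and the last position).
#' @param seed RNG seed for dihedral sampling.
#' @param pdb_id,resolution,release_date metadata for the emitted entry.
#' @param peptide_sequence one-letter sequence (default polyglycine).
#' @param extra_chain_dist if set, adds a short "other" chain whose nearest
#'   atom sits at this distance (Angstrom) from the peptide.
#' @param include_b2m add a beta-2 microglobulin chain (default FALSE).
#' @param platform_offset author-numbering offset for the heavy chain.
#' @return list of class `synthetic_complex_spec`.
#' @export
synthetic_complex_spec <- function(peptide_length = 9, phi_mean = -75,
                                   psi_mean = 145, phi_sd = 0, psi_sd = 0,
                                   anchors = c(2, peptide_length), seed = 1L,
                                   pdb_id = "SYN1", resolution = 2.0,
                                   release_date = "2020-01-01",
                                   peptide_sequence = NULL,
                                   extra_chain_dist = NULL,
                                   include_b2m = FALSE,
                                   platform_offset = 0L) {
  stopifnot(peptide_length >= 2, all(c(phi_sd, psi_sd) >= 0),
            length(anchors) == 2, anchors[1] < anchors[2],
            all(anchors >= 1), all(anchors <= peptide_length))
  structure(as.list(environment()), class = "synthetic_complex_spec")
}

# Flatten a peptide_backbone into atom-table rows.
.backbone_atoms <- function(bb, chain, resno_start = 1L, occupancy = 1) {
  seq3 <- aa1to3(strsplit(bb$sequence, "")[[1]])
  rows <- lapply(seq_len(bb$n), function(i) {
    data.frame(chain = chain, resno = resno_start + i - 1L, resid = seq3[i],
               elety = c("N", "CA", "C", "O"), alt = NA_character_,
               x = bb$xyz[i, , 1], y = bb$xyz[i, , 2], z = bb$xyz[i, , 3],
               o = occupancy, b = 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a synthetic toy pHLA complex
#'
#' Emits a raw entry with a 180-residue dummy platform scaffold (reference
#' A*02:01 sequence on an extended ribbon, with the Calpha probes of
#' residues 24 and 123 relocated 3 Angstrom beneath the requested anchor
#' positions) and a peptide built from the sampled dihedrals.  With default
#' settings the file passes the curation filters.
#'
#' @param spec a [synthetic_complex_spec()].
#' @param path optional output PDB path.
#' @return a `raw_entry` (invisibly when `path` is given).
#' @export
make_complex <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  set.seed(spec$seed)
  L <- spec$peptide_length
  phi <- rnorm(L, rep_len(spec$phi_mean, L), rep_len(spec$phi_sd, L))
  psi <- rnorm(L, rep_len(spec$psi_mean, L), rep_len(spec$psi_sd, L))
  pep_seq <- if (is.null(spec$peptide_sequence)) strrep("G", L) else
    spec$peptide_sequence
  pep <- build_backbone(L, phi, psi, sequence = pep_seq)
  plat_seq <- reference_platform_sequence()
  plat <- build_backbone(PLATFORM_LENGTH, -120, 130, sequence = plat_seq)
  plat$xyz[, , 2] <- plat$xyz[, , 2] - 30    # park the ribbon away in -y
  # Relocate the pocket probes just beneath the requested anchor positions
  # (1 Angstrom offset: small against the ~3.8 Angstrom CA-CA spacing, so
  # the requested position is unambiguously the nearest).
  for (k in 1:2) {
    res <- c(24L, 123L)[k]
    target_ca <- pep$xyz[spec$anchors[k], "CA", ] + c(0, 0, -1)
    shift <- target_ca - plat$xyz[res, "CA", ]
    plat$xyz[res, , ] <- sweep(plat$xyz[res, , ], 2, shift, "+")
  }
  atoms <- rbind(
    .backbone_atoms(plat, "A", resno_start = 1L + spec$platform_offset),
    .backbone_atoms(pep, "C"))
  if (spec$include_b2m) {
    b2m <- build_backbone(nchar(B2M_REFERENCE), -120, 130,
                          sequence = B2M_REFERENCE)
    b2m$xyz[, , 2] <- b2m$xyz[, , 2] + 40
    atoms <- rbind(atoms, .backbone_atoms(b2m, "B"))
  }
  if (!is.null(spec$extra_chain_dist)) {
    ex <- build_backbone(5, -120, 130)
    # place its first N atom exactly extra_chain_dist above the peptide's
    # first N; the rest of the strand points away (+x, +z)
    shift <- pep$xyz[1, "N", ] + c(0, 0, spec$extra_chain_dist) - ex$xyz[1, "N", ]
    ex$xyz <- sweep(ex$xyz, 3, shift, "+")
    atoms <- rbind(atoms, .backbone_atoms(ex, "D"))
  }
  entry <- raw_entry(spec$pdb_id, atoms, spec$resolution, spec$release_date)
  if (!is.null(path)) {
    write_pdb_file(atoms, path, pdb_id = spec$pdb_id,
                   resolution = spec$resolution,
                   release_date = spec$release_date)
    return(invisible(entry))
  }
  entry
}

#' Generate a family of perturbed backbones
#'
#' Gaussian perturbations of a center conformation; with small spread the
#' members are mutual D-score neighbors, with large spread they are not.
#'
#' @param n family size.
#' @param center_phi,center_psi center dihedrals (recycled over positions).
#' @param spread standard deviation in degrees.
#' @param length chain length (default 9).
#' @param seed RNG seed.
#' @param prefix id prefix for names.
#' @return named list of `peptide_backbone` objects.
#' @export
make_backbone_family <- function(n, center_phi = -75, center_psi = 145,
                                 spread = 5, length = 9, seed = 1L,
                                 prefix = "fam") {
  stopifnot(n >= 1, spread >= 0)
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    build_backbone(length,
                   rnorm(length, rep_len(center_phi, length), spread),
                   rnorm(length, rep_len(center_psi, length), spread))
  })
  names(out) <- sprintf("%s%03d", prefix, seq_len(n))
  out
}

#' Specification for a synthetic candidate-model feature table
#'
#' @param n_targets,n_templates table dimensions.
#' @param n_features feature count F (>= 3; the published pipeline uses
#'   129).
#' @param coef planted coefficients linking the leading features to the
#'   true D-score.
#' @param noise_sd feature noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return list of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_targets = 20, n_templates = 10,
                                   n_features = 12, coef = c(1, 0.6, 0.3),
                                   noise_sd = 0.1, seed = 1L) {
  stopifnot(n_features >= 3, noise_sd >= 0, length(coef) <= n_features)
  structure(as.list(environment()), class = "synthetic_feature_spec")
}

#' Generate a candidate-model table with planted structure
#'
#' Each target gets one near-native template (true D-score in 0.3-1.2) and
#' otherwise dissimilar templates (1.8-6.5); the leading features carry the
#' planted linear relation to the true D-score plus Gaussian noise, the rest
#' are pure noise.  Target and template peptide sequences are random 9-mers
#' for homolog-filter exercises.
#'
#' @param spec a [synthetic_feature_spec()].
#' @return list with `candidates` (data.frame: target_id, template_id,
#'   true_dscore, f1..fF), `target_peptides`, `template_peptides`.
#' @export
make_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  set.seed(spec$seed)
  tg <- sprintf("T%03d", seq_len(spec$n_targets))
  tm <- sprintf("M%03d", seq_len(spec$n_templates))
  rand_pep <- function(k) {
    vapply(seq_len(k), function(i)
      paste(sample(AA20, 9, replace = TRUE), collapse = ""), "")
  }
  target_peptides <- setNames(rand_pep(spec$n_targets), tg)
  template_peptides <- setNames(rand_pep(spec$n_templates), tm)
  grid <- expand.grid(target_id = tg, template_id = tm,
                      stringsAsFactors = FALSE)
  best <- setNames(sample(tm, spec$n_targets, replace = TRUE), tg)
  n <- nrow(grid)
  truth <- ifelse(best[grid$target_id] == grid$template_id,
                  runif(n, 0.3, 1.2), runif(n, 1.8, 6.5))
  k <- length(spec$coef)
  feat <- matrix(rnorm(n * spec$n_features), n, spec$n_features)
  for (j in seq_len(k)) {
    feat[, j] <- spec$coef[j] * truth + rnorm(n, 0, spec$noise_sd)
  }
  colnames(feat) <- paste0("f", seq_len(spec$n_features))
  candidates <- cbind(grid, true_dscore = as.numeric(truth),
                      as.data.frame(feat))
  list(candidates = candidates, target_peptides = target_peptides,
       template_peptides = template_peptides)
}

# Crude residue volume proxies (arbitrary units) for the surrogate scorer.
.aa_volume <- c(A = 89, C = 109, D = 111, E = 138, F = 190, G = 60, H = 153,
                I = 167, K = 169, L = 167, M = 163, N = 114, P = 113, Q = 144,
                R = 174, S = 89, T = 116, W = 228, Y = 194, V = 140)

#' Surrogate sequence scorer (non-physical, for tests)
#'
#' A deterministic stand-in for an external energy function: the score of a
#' sequence is a weighted sum of per-position penalties measuring departure
#' from a planted motif (identity mismatch plus a side-chain volume clash
#' proxy).  Lower is better; sequences matching the motif score lowest, so
#' top-fraction selection recovers the planted bias.  It is a test
#' heuristic, not an energy model.
#'
#' @param motif one-letter motif string (same length as the scored
#'   sequences).
#' @param weights per-position weights (default 1).
#' @return vectorized function `character -> numeric`.
#' @export
surrogate_scorer <- function(motif, weights = 1) {
  mchars <- strsplit(motif, "")[[1]]
  w <- rep_len(weights, length(mchars))
  function(sequences) {
    vapply(strsplit(sequences, ""), function(ch) {
      stopifnot(length(ch) == length(mchars))
      mism <- as.numeric(ch != mchars)
      clash <- abs(.aa_volume[ch] - .aa_volume[mchars]) / 100
      sum(w * (mism + clash))
    }, 0.0)
  }
}
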