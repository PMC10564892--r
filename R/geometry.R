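# Quantitative backbone geometry: dihedral extraction, internal-coordinate
# (NeRF) chain building, anchor classification, the anchor-distance
# Ramachandran surface, and groove-frame superposition/RMSD.

# Ideal backbone geometry used by the internal-coordinate builder.  Bond
# lengths in Angstrom, angles in degrees; omega fixed at 180 (trans).
IDEAL_GEOMETRY <- list(
  b_n_ca  = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 109.5, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 121.1
)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) a / vnorm(a)

#' Torsion angle defined by four points
#'
#' Returns the dihedral angle of the chain p1-p2-p3-p4 with the IUPAC sign
#' convention, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz vectors of length 3.
#' @return angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  ang <- -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural-extension reference frame placement: position atom d bonded to c,
# given the three preceding atoms a-b-c, the c-d bond length, the b-c-d bond
# angle and the a-b-c-d torsion (degrees).
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle)
  ch <- deg2rad(torsion)
  d_local <- length * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + cbind(bc, m, n) %*% d_local
}

#' Construct a peptide backbone from internal coordinates
#'
#' Sequential NeRF construction of an all-trans backbone (N, CA, C, O per
#' residue) with ideal bond lengths and angles.  `phi[1]` is not a degree of
#' freedom of the chain (there is no preceding carbonyl); `psi[length]` is
#' used only to orient the terminal carbonyl oxygen.
#'
#' @param length number of residues (>= 2).
#' @param phi,psi backbone dihedrals in degrees; scalars are recycled.
#' @param omega peptide-bond torsion, default 180 (trans).
#' @param sequence optional one-letter sequence (defaults to polyglycine).
#' @return a `peptide_backbone` object.
#' @examples
#' bb <- build_backbone(9, phi = -75, psi = 145)   # ideal PPII nonamer
#' anchor_ca_distance(bb, 2, 9)                    # ~21.4 Angstrom
#' @export
build_backbone <- function(length, phi, psi, omega = 180, sequence = NULL) {
  stopifnot(length >= 2)
  phi <- rep_len(phi, length)
  psi <- rep_len(psi, length)
  omega <- rep_len(omega, length)
  g <- IDEAL_GEOMETRY
  xyz <- array(NA_real_, dim = c(length, 4L, 3L),
               dimnames = list(NULL, c("N", "CA", "C", "O"), c("x", "y", "z")))
  # Residue 1 in a canonical frame: N at origin, CA on +x, C in the xy-plane.
  xyz[1, "N", ] <- c(0, 0, 0)
  xyz[1, "CA", ] <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(180 - g$a_n_ca_c)
  xyz[1, "C", ] <- xyz[1, "CA", ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(length - 1)) {
    xyz[i + 1, "N", ] <- place_atom(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                                    g$b_c_n, g$a_ca_c_n, psi[i])
    xyz[i + 1, "CA", ] <- place_atom(xyz[i, "CA", ], xyz[i, "C", ], xyz[i + 1, "N", ],
                                     g$b_n_ca, g$a_c_n_ca, omega[i])
    xyz[i + 1, "C", ] <- place_atom(xyz[i, "C", ], xyz[i + 1, "N", ], xyz[i + 1, "CA", ],
                                    g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    # Carbonyl oxygen anti to the next amide nitrogen.
    xyz[i, "O", ] <- place_atom(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                                g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  xyz[length, "O", ] <- place_atom(xyz[length, "N", ], xyz[length, "CA", ],
                                   xyz[length, "C", ],
                                   g$b_c_o, g$a_ca_c_o, psi[length] + 180)
  if (is.null(sequence)) sequence <- strrep("G", length)
  peptide_backbone(xyz, sequence)
}

#' Peptide backbone container
#'
#' Wraps per-residue backbone heavy-atom coordinates (N, CA, C, O) together
#' with the one-letter sequence and the phi/psi dihedrals measured from the
#' coordinates.  Dihedrals undefined at the termini are `NA`.
#'
#' @param xyz numeric array `[n, 4, 3]` with atom dimension named
#'   N, CA, C, O.
#' @param sequence one-letter amino-acid string of length n.
#' @return an object of class `peptide_backbone`.
#' @export
peptide_backbone <- function(xyz, sequence = NULL) {
  stopifnot(is.array(xyz), length(dim(xyz)) == 3L, dim(xyz)[2] == 4L)
  n <- dim(xyz)[1]
  if (is.null(sequence)) sequence <- strrep("G", n)
  stopifnot(nchar(sequence) == n)
  bb <- structure(list(xyz = xyz, sequence = sequence, n = n),
                  class = "peptide_backbone")
  di <- compute_dihedrals(bb)
  bb$phi <- di$phi
  bb$psi <- di$psi
  bb
}

#' @export
print.peptide_backbone <- function(x, ...) {
  cat(sprintf("peptide_backbone: %d residues, sequence %s\n", x$n, x$sequence))
  invisible(x)
}

#' Backbone dihedral angles from coordinates
#'
#' @param bb a `peptide_backbone`, or a bare `[n, 4, 3]` coordinate array.
#' @return list with numeric vectors `phi` and `psi` in degrees, `NA` where
#'   undefined (phi at residue 1, psi at residue n, and wherever an atom is
#'   missing).
#' @export
compute_dihedrals <- function(bb) {
  xyz <- if (inherits(bb, "peptide_backbone")) bb$xyz else bb
  n <- dim(xyz)[1]
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      pts <- list(xyz[i - 1, "C", ], xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ])
      if (!anyNA(unlist(pts))) phi[i] <- do.call(torsion_angle, pts)
    }
    if (i < n) {
      pts <- list(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ], xyz[i + 1, "N", ])
      if (!anyNA(unlist(pts))) psi[i] <- do.call(torsion_angle, pts)
    }
  }
  list(phi = phi, psi = psi)
}

#' Calpha-Calpha distance between two peptide positions
#'
#' @param bb a `peptide_backbone`.
#' @param i,j residue positions.
#' @return distance in Angstrom.
#' @export
anchor_ca_distance <- function(bb, i, j) {
  vnorm(bb$xyz[j, "CA", ] - bb$xyz[i, "CA", ])
}

# Anchor distance of a uniform-dihedral chain via the per-residue rigid
# transform: for uniform (phi, psi, omega) every residue is carried onto the
# next by the same isometry T, so |CA_j - CA_i| = |T^(j-i)(CA_1) - CA_1|.
# Much faster than a full build; cross-checked against build_backbone in the
# test suite.
uniform_anchor_distance <- function(phi, psi, length = 9, i = 2, j = length,
                                    omega = 180) {
  g <- IDEAL_GEOMETRY
  n1 <- c(0, 0, 0)
  ca1 <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(180 - g$a_n_ca_c)
  c1 <- ca1 + g$b_ca_c * c(cos(th), sin(th), 0)
  n2 <- place_atom(n1, ca1, c1, g$b_c_n, g$a_ca_c_n, psi)
  ca2 <- place_atom(ca1, c1, n2, g$b_n_ca, g$a_c_n_ca, omega)
  c2 <- place_atom(c1, n2, ca2, g$b_ca_c, g$a_n_ca_c, phi)
  frame <- function(nn, ca, cc) {
    u <- unitv(ca - nn)
    w <- unitv(vcross(u, cc - nn))
    cbind(u, vcross(w, u), w)
  }
  R1 <- frame(n1, ca1, c1)
  R2 <- frame(n2, ca2, c2)
  R <- R2 %*% t(R1)
  t0 <- n2 - R %*% n1
  p <- ca1
  for (k in seq_len(j - i)) p <- R %*% p + t0
  vnorm(p - ca1)
}

#' Anchor classification of a curated complex
#'
#' The B- and F-pocket probes are the Calpha atoms of platform residues 24
#' and 123.  The b anchor is the peptide position whose Calpha is nearest the
#' B-pocket probe, the f anchor the position nearest the F-pocket probe; the
#' anchor class is their sequence separation and the anchor distance their
#' Calpha-Calpha distance.  Ties resolve to the lowest index for the b anchor
#' and the highest for the f anchor.
#'
#' @param complex a `curated_complex`.
#' @return list with `b_anchor`, `f_anchor`, `anchor_class`,
#'   `anchor_distance` (Angstrom) and `ok` (FALSE when b_anchor >= f_anchor).
#' @export
assign_anchors <- function(complex) {
  at <- complex$atoms
  probe <- function(resno) {
    row <- at[at$chain == "A" & at$resno == resno & at$elety == "CA", , drop = FALSE]
    if (nrow(row) == 0) stop("platform residue ", resno, " has no CA atom")
    as.numeric(row[1, c("x", "y", "z")])
  }
  p24 <- probe(24)
  p123 <- probe(123)
  pep <- at[at$chain == "C" & at$elety == "CA", , drop = FALSE]
  pep <- pep[order(pep$resno), , drop = FALSE]
  d24 <- sqrt((pep$x - p24[1])^2 + (pep$y - p24[2])^2 + (pep$z - p24[3])^2)
  d123 <- sqrt((pep$x - p123[1])^2 + (pep$y - p123[2])^2 + (pep$z - p123[3])^2)
  b <- pep$resno[which(d24 == min(d24))[1]]
  fcand <- pep$resno[d123 == min(d123)]
  f <- fcand[length(fcand)]
  bi <- which(pep$resno == b)
  fi <- which(pep$resno == f)
  dist <- sqrt(sum((as.numeric(pep[fi, c("x", "y", "z")]) -
                    as.numeric(pep[bi, c("x", "y", "z")]))^2))
  list(b_anchor = b, f_anchor = f, anchor_class = f - b,
       anchor_distance = dist, ok = b < f)
}

#' Anchor-distance Ramachandran surface
#'
#' For every (phi, psi) pair on a regular lattice a uniform-dihedral nonamer
#' is built with ideal geometry and its P2-P9 Calpha distance recorded.  The
#' mask marks dihedral pairs whose anchor distance falls inside
#' `[dist_lo, dist_hi]` -- the band observed for Delta-7 peptides.  Both
#' -180 and +180 grid endpoints are included (they describe the same
#' torsion; the duplication keeps the lattice symmetric for plotting).
#'
#' @param length chain length, default 9.
#' @param dist_lo,dist_hi distance band in Angstrom (defaults 17.5, 20.0).
#' @param step lattice spacing in degrees (default 1).
#' @return object of class `rama_surface`: list with `phi`, `psi` grid
#'   vectors, `distance` matrix (phi x psi) and logical `mask`.
#' @export
rama_anchor_surface <- function(length = 9, dist_lo = 17.5, dist_hi = 20.0,
                                step = 1) {
  stopifnot(dist_lo < dist_hi)
  phis <- seq(-180, 180, by = step)
  psis <- seq(-180, 180, by = step)
  d <- matrix(NA_real_, length(phis), length(psis))
  for (a in seq_along(phis)) {
    for (b in seq_along(psis)) {
      d[a, b] <- uniform_anchor_distance(phis[a], psis[b], length = length)
    }
  }
  structure(list(phi = phis, psi = psis, distance = d,
                 mask = d >= dist_lo & d <= dist_hi,
                 dist_lo = dist_lo, dist_hi = dist_hi),
            class = "rama_surface")
}

#' Groove-frame superposition and peptide RMSD
#'
#' Superposes complex `b` onto complex `a` by least-squares (Kabsch) fit of
#' the shared platform Calpha atoms, then evaluates the RMSD over the
#' requested peptide positions and atom set in that frame, without refitting
#' on the peptide.
#'
#' @param a,b `curated_complex` objects.
#' @param peptide_positions integer vector of peptide residue numbers
#'   (default: all shared positions).
#' @param atom_set `"backbone"` (N, CA, C, O), `"ca"`, or `"all"` heavy atoms.
#' @return RMSD in Angstrom.
#' @export
superpose_and_rmsd <- function(a, b, peptide_positions = NULL,
                               atom_set = c("backbone", "ca", "all")) {
  atom_set <- match.arg(atom_set)
  sel <- switch(atom_set,
                backbone = c("N", "CA", "C", "O"),
                ca = "CA",
                all = NULL)
  plat_ca <- function(cx) {
    at <- cx$atoms
    p <- at[at$chain == "A" & at$elety == "CA", , drop = FALSE]
    p[order(p$resno), , drop = FALSE]
  }
  pa <- plat_ca(a)
  pb <- plat_ca(b)
  shared <- intersect(pa$resno, pb$resno)
  if (length(shared) < 3) stop("fewer than 3 shared platform CA atoms")
  pa <- pa[match(shared, pa$resno), ]
  pb <- pb[match(shared, pb$resno), ]
  pep <- function(cx) {
    at <- cx$atoms
    p <- at[at$chain == "C", , drop = FALSE]
    if (!is.null(sel)) p <- p[p$elety %in% sel, , drop = FALSE]
    if (!is.null(peptide_positions)) p <- p[p$resno %in% peptide_positions, , drop = FALSE]
    p[order(p$resno, match(p$elety, c("N", "CA", "C", "O", sort(unique(p$elety))))), ,
      drop = FALSE]
  }
  qa <- pep(a)
  qb <- pep(b)
  key <- function(p) paste(p$resno, p$elety)
  if (!identical(key(qa), key(qb))) {
    stop("peptide atom sets differ at the requested positions")
  }
  if (nrow(qa) == 0) stop("no peptide atoms selected")
  # Kabsch fit on platform CA (bio3d), applied to b's peptide atoms.
  fixed <- c(t(as.matrix(pa[, c("x", "y", "z")])))
  mobile <- c(t(as.matrix(rbind(pb[, c("x", "y", "z")], qb[, c("x", "y", "z")]))))
  nfit <- 3L * nrow(pa)
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = mobile,
                           fixed.inds = seq_len(nfit),
                           mobile.inds = seq_len(nfit))
  qb_fit <- matrix(fitted[(nfit + 1):length(fitted)], ncol = 3, byrow = TRUE)
  qa_m <- as.matrix(qa[, c("x", "y", "z")])
  sqrt(mean(rowSums((qa_m - qb_fit)^2)))
}

#' Extract the peptide backbone from a curated complex
#'
#' @param complex a `curated_complex`.
#' @return a `peptide_backbone` for the peptide chain.
#' @export
extract_backbone <- function(complex) {
  at <- complex$atoms
  pep <- at[at$chain == "C", , drop = FALSE]
  resnos <- sort(unique(pep$resno))
  n <- length(resnos)
  xyz <- array(NA_real_, dim = c(n, 4L, 3L),
               dimnames = list(NULL, c("N", "CA", "C", "O"), c("x", "y", "z")))
  for (k in seq_len(n)) {
    for (atom in c("N", "CA", "C", "O")) {
      row <- pep[pep$resno == resnos[k] & pep$elety == atom, , drop = FALSE]
      if (nrow(row) > 0) xyz[k, atom, ] <- as.numeric(row[1, c("x", "y", "z")])
    }
  }
  peptide_backbone(xyz, complex$peptide_sequence)
}
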