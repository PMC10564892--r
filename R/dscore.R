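# The D-score: a cyclic dissimilarity between backbone dihedral angles,
# summed over the central peptide positions of an anchor class.  Two
# backbones with D-score at or below the class threshold are neighbors.

# Summation window per anchor class: the central positions whose dihedrals
# define conformational diversity.
.dscore_window <- function(anchor_class) {
  switch(as.character(anchor_class),
         "6" = 4:6, "7" = 4:7, "8" = 4:8,
         stop("unsupported anchor class: ", anchor_class))
}

#' Cyclic difference between two dihedral angles
#'
#' `2 * (1 - cos(theta1 - theta2))`, in `[0, 4]`, periodic in 360 degrees.
#'
#' @param theta1,theta2 angles in degrees (vectorized).
#' @return D values; `NA` inputs propagate.
#' @export
angle_diff <- function(theta1, theta2) {
  2 * (1 - cos(deg2rad(theta1 - theta2)))
}

#' Per-position D-score profile between two backbones
#'
#' `D(phi_p) + D(psi_p)` for each position p of the class window (P4-P6,
#' P4-P7 or P4-P8 for anchor classes 6, 7, 8).  The profile sums to
#' [dscore()].
#'
#' @param a,b `peptide_backbone` objects.
#' @param anchor_class 6, 7 or 8 (default 7).
#' @return named numeric vector over the window positions.
#' @export
per_position_dscore <- function(a, b, anchor_class = 7) {
  win <- .dscore_window(anchor_class)
  if (max(win) > min(a$n, b$n)) stop("backbone shorter than the class window")
  v <- angle_diff(a$phi[win], b$phi[win]) + angle_diff(a$psi[win], b$psi[win])
  if (anyNA(v)) stop("undefined dihedrals inside the summation window")
  setNames(v, paste0("P", win))
}

#' D-score between two peptide backbones
#'
#' @inheritParams per_position_dscore
#' @return total D-score (>= 0; at most 4 times the number of angles).
#' @export
dscore <- function(a, b, anchor_class = 7) {
  sum(per_position_dscore(a, b, anchor_class))
}

#' Neighbor threshold for an anchor class
#'
#' The Delta-7 criterion is 1.5 over 8 angles; other classes scale
#' proportionally with the number of angles in their window (Delta-6: 1.125
#' over 6 angles; Delta-8: 1.875 over 10).  The scaled values are an
#' inference from the stated scaling rule, not printed constants.
#'
#' @param anchor_class 6, 7 or 8.
#' @return scalar threshold.
#' @export
neighbor_threshold <- function(anchor_class) {
  n_angles <- 2 * length(.dscore_window(anchor_class))
  1.5 * n_angles / 8
}

#' Pairwise D-score matrix with neighbor adjacency
#'
#' Computes all pairwise D-scores over the class window and thresholds them
#' into a symmetric boolean adjacency (self excluded).  Backbones with
#' undefined dihedrals inside the window are excluded and reported.
#'
#' @param backbones named list of `peptide_backbone` objects (names are
#'   structure ids).
#' @param anchor_class 6, 7 or 8 (default 7).
#' @param threshold neighbor criterion; defaults to
#'   [neighbor_threshold()] for the class.
#' @return object of class `dscore_matrix`: list with `ids`, `scores`,
#'   `adjacency`, `anchor_class`, `threshold`, `excluded`.
#' @export
build_dscore_matrix <- function(backbones, anchor_class = 7,
                                threshold = neighbor_threshold(anchor_class)) {
  stopifnot(length(backbones) >= 1)
  if (is.null(names(backbones))) {
    names(backbones) <- sprintf("bb%03d", seq_along(backbones))
  }
  win <- .dscore_window(anchor_class)
  ok <- vapply(backbones, function(b) {
    b$n >= max(win) && !anyNA(b$phi[win]) && !anyNA(b$psi[win])
  }, TRUE)
  excluded <- names(backbones)[!ok]
  backbones <- backbones[ok]
  ids <- names(backbones)
  k <- length(ids)
  phim <- t(vapply(backbones, function(b) b$phi[win], numeric(length(win))))
  psim <- t(vapply(backbones, function(b) b$psi[win], numeric(length(win))))
  scores <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) {
        scores[i, j] <- scores[j, i] <-
          sum(angle_diff(phim[i, ], phim[j, ]) + angle_diff(psim[i, ], psim[j, ]))
      }
    }
  }
  adjacency <- scores <= threshold
  diag(adjacency) <- FALSE
  structure(list(ids = ids, scores = scores, adjacency = adjacency,
                 anchor_class = anchor_class, threshold = threshold,
                 excluded = excluded),
            class = "dscore_matrix")
}

#' @export
print.dscore_matrix <- function(x, ...) {
  cat(sprintf("dscore_matrix: %d backbones (Delta-%d, threshold %.3f), %d neighbor pairs\n",
              length(x$ids), x$anchor_class, x$threshold,
              sum(x$adjacency) / 2))
  invisible(x)
}

#' Neighbor counts per structure
#'
#' @param matrix a `dscore_matrix`.
#' @return named integer vector of row sums of the adjacency.
#' @export
neighbor_counts <- function(matrix) {
  setNames(as.integer(rowSums(matrix$adjacency)), matrix$ids)
}
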