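# Shared helpers and independent oracles for the test suite.  The oracles
# deliberately avoid the package's own code paths.

# Rigid-body motion: rotate a backbone's coordinates about an arbitrary axis
# and translate.
rigid_move <- function(bb, angle = 0.7, shift = c(5, -3, 11)) {
  ax <- c(1, 2, 2) / 3
  ct <- cos(angle); st <- sin(angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * K %*% K
  xyz <- bb$xyz
  for (i in seq_len(dim(xyz)[1])) {
    xyz[i, , ] <- t(R %*% t(xyz[i, , ])) + rep(shift, each = 4)
  }
  peptide_backbone(xyz, bb$sequence)
}

# Apply the same rigid motion to a curated complex's atom table.
rigid_move_complex <- function(cx, angle = 0.7, shift = c(5, -3, 11)) {
  ax <- c(1, 2, 2) / 3
  ct <- cos(angle); st <- sin(angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * K %*% K
  m <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(R)
  cx$atoms$x <- m[, 1] + shift[1]
  cx$atoms$y <- m[, 2] + shift[2]
  cx$atoms$z <- m[, 3] + shift[3]
  cx
}

# Brute-force greedy oracle: straightforward re-implementation of the
# iterative max-neighbor extraction on a plain boolean matrix.
greedy_oracle <- function(adj, ids) {
  out <- list()
  left <- ids
  while (length(left)) {
    sub <- adj[left, left, drop = FALSE]
    cnt <- rowSums(sub)
    pick <- sort(left[cnt == max(cnt)])[1]
    nb <- left[sub[pick, ] > 0]
    out[[length(out) + 1L]] <- list(id = pick, neighbors = sort(nb))
    left <- setdiff(left, c(pick, nb))
  }
  out
}

# Full D-score by direct double loop over the window, independent of
# build_dscore_matrix's vectorized path.
dscore_oracle <- function(a, b, win = 4:7) {
  tot <- 0
  for (p in win) {
    tot <- tot + 2 * (1 - cos((a$phi[p] - b$phi[p]) * pi / 180)) +
      2 * (1 - cos((a$psi[p] - b$psi[p]) * pi / 180))
  }
  tot
}

ref_fasta_path <- system.file("extdata", "reference_alleles.fasta",
                              package = "phlatlas")

make_curated <- function(seed = 3, ...) {
  spec <- synthetic_complex_spec(seed = seed, ...)
  res <- curate_entry(make_complex(spec), reference_platform_sequence(),
                      ref_fasta_path)
  stopifnot(res$accepted)
  res$complex
}
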