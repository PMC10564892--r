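# The backbone atlas: greedy reduction of a neighbor graph to discrete
# representative conformations, historical accumulation, PCA featurization
# of the central dihedrals, and supertype composition of neighbor sets.

#' Greedy selection of discrete peptide backbones
#'
#' Iteratively takes the structure with the most neighbors in the current
#' adjacency, records it as a representative together with its neighbor set,
#' and removes all of them; repeats until every structure is accounted for.
#' Zero-neighbor structures become singleton representatives.  Ties on the
#' neighbor count break to the lexicographically smallest structure id, so
#' the atlas is deterministic and independent of input order.
#'
#' @param matrix a `dscore_matrix`.
#' @return object of class `backbone_atlas`: list with `representatives`
#'   (list of `id`, `neighbors`, `rank`, `n_covered`), `covered`,
#'   `anchor_class`, `threshold`.
#' @export
greedy_select <- function(matrix) {
  adj <- matrix$adjacency
  ids <- matrix$ids
  reps <- list()
  rank <- 0L
  remaining <- ids
  while (length(remaining) > 0) {
    sub <- adj[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub)
    top <- max(counts)
    pick <- sort(remaining[counts == top])[1]
    nb <- remaining[sub[pick, ] > 0]
    rank <- rank + 1L
    reps[[rank]] <- list(id = pick, neighbors = nb, rank = rank,
                         n_covered = 1L + length(nb))
    remaining <- setdiff(remaining, c(pick, nb))
  }
  structure(list(representatives = reps, covered = ids,
                 anchor_class = matrix$anchor_class,
                 threshold = matrix$threshold),
            class = "backbone_atlas")
}

#' @export
print.backbone_atlas <- function(x, ...) {
  cat(sprintf("backbone_atlas: %d structures -> %d discrete backbones (Delta-%d)\n",
              length(x$covered), length(x$representatives), x$anchor_class))
  invisible(x)
}

#' Number of representatives in an atlas
#' @param atlas a `backbone_atlas`.
#' @return integer count.
#' @export
n_representatives <- function(atlas) length(atlas$representatives)

#' Atlas membership table
#'
#' @param atlas a `backbone_atlas`.
#' @return data.frame with id, representative, rank (of the representative).
#' @export
atlas_members <- function(atlas) {
  do.call(rbind, lapply(atlas$representatives, function(r) {
    data.frame(id = c(r$id, r$neighbors), representative = r$id,
               rank = r$rank, stringsAsFactors = FALSE)
  }))
}

#' Serialize an atlas to JSON
#'
#' @param atlas a `backbone_atlas`.
#' @param path output file; `NULL` returns the JSON string.
#' @export
write_atlas_json <- function(atlas, path = NULL) {
  payload <- list(
    schema = "phlatlas/backbone_atlas/1",
    anchor_class = atlas$anchor_class,
    threshold = atlas$threshold,
    representatives = lapply(atlas$representatives, function(r) {
      list(id = r$id, rank = r$rank, neighbors = as.list(r$neighbors))
    }))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Historical accumulation of structures and discrete backbones
#'
#' For each release year the greedy selection is rerun on the subset of
#' structures released up to (and including) that year.
#'
#' @param backbones named list of `peptide_backbone` objects.
#' @param release_dates named ISO date (or year) vector aligned with
#'   `backbones`.
#' @param anchor_class anchor class for the D-score matrix.
#' @return data.frame with year, n_structures (cumulative),
#'   n_representatives.
#' @export
historical_analysis <- function(backbones, release_dates, anchor_class = 7) {
  stopifnot(length(backbones) == length(release_dates))
  years <- as.integer(substr(as.character(release_dates), 1, 4))
  out <- lapply(sort(unique(years)), function(y) {
    sub <- backbones[years <= y]
    dm <- build_dscore_matrix(sub, anchor_class)
    data.frame(year = y, n_structures = length(sub),
               n_representatives = n_representatives(greedy_select(dm)))
  })
  do.call(rbind, out)
}

#' PCA embedding of central-window dihedrals
#'
#' Features are `sin(phi_p)` and `sin(psi_p)` for the window positions
#' (P4-P7 for Delta-7), standardized to zero mean and unit variance; the
#' first two principal components are returned.
#'
#' @param backbones named list of `peptide_backbone` objects (>= 3).
#' @param anchor_class anchor class (default 7).
#' @return list with `embedding` (n x 2 matrix), `explained_variance`
#'   (length-2 fractions), and the fitted `prcomp` object.
#' @export
pca_features <- function(backbones, anchor_class = 7) {
  if (length(backbones) < 3) stop("need at least 3 backbones for PCA")
  win <- .dscore_window(anchor_class)
  feat <- t(vapply(backbones, function(b) {
    c(sin(deg2rad(b$phi[win])), sin(deg2rad(b$psi[win])))
  }, numeric(2 * length(win))))
  colnames(feat) <- c(paste0("sin_phi_P", win), paste0("sin_psi_P", win))
  sds <- apply(feat, 2, sd)
  # features with (numerically) no variance are centered but not scaled, so
  # floating-point noise cannot be inflated to unit variance
  feat_std <- scale(feat, center = TRUE, scale = ifelse(sds > 1e-8, sds, 1))
  fit <- prcomp(feat_std, center = FALSE, scale. = FALSE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(embedding = fit$x[, 1:2, drop = FALSE],
       explained_variance = ev[1:2], fit = fit)
}

#' Supertype composition of each discrete backbone's neighbor set
#'
#' @param atlas a `backbone_atlas`.
#' @param allotypes named character vector: structure id -> allotype.
#' @param supertypes named character vector: allotype -> supertype
#'   (configuration data; unmapped allotypes fall into "unassigned").
#' @return data.frame with representative, supertype, proportion, n_members;
#'   proportions sum to 1 within each representative's set (representative
#'   included).
#' @export
supertype_composition <- function(atlas, allotypes, supertypes) {
  rows <- lapply(atlas$representatives, function(r) {
    members <- c(r$id, r$neighbors)
    st <- supertypes[allotypes[members]]
    st[is.na(st)] <- "unassigned"
    tab <- table(st)
    data.frame(representative = r$id, supertype = names(tab),
               proportion = as.numeric(tab) / length(members),
               n_members = length(members), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
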