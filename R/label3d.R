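# 3-D connected-component labelling under 26-connectivity.
#
# EBImage::bwlabel labels 4-connected components per slice; full
# 26-connectivity is recovered by union-find merges over (a) in-slice
# diagonal adjacencies and (b) all 9 voxel offsets between adjacent slices.

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# merge label pairs appearing at corresponding positions of two label images;
# pairs are encoded as one integer for a fast unique()
collect_pairs <- function(la, lb, n_labels) {
  sel <- la > 0L & lb > 0L
  if (!any(sel)) return(NULL)
  code <- unique((la[sel] - 1) * n_labels + lb[sel])
  cbind(as.integer(floor((code - 1) / n_labels) + 1),
        as.integer((code - 1) %% n_labels + 1))
}

shift2 <- function(m, di, dj) {
  n <- matrix(0L, nrow(m), ncol(m))
  src_i <- seq_len(nrow(m)) - di
  src_j <- seq_len(ncol(m)) - dj
  ok_i <- src_i >= 1 & src_i <= nrow(m)
  ok_j <- src_j >= 1 & src_j <= ncol(m)
  n[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  n
}

#' Label 3-D connected components (26-connectivity)
#'
#' @param mask logical 3-D array.
#' @return integer array of component labels (0 = background), labels dense
#'   from 1.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) dim(mask) <- d <- c(d, 1L)
  labs <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    lk <- EBImage::bwlabel(mask[, , k] * 1)
    lk <- matrix(as.integer(lk), d[1], d[2])
    lk[lk > 0] <- lk[lk > 0] + offset
    labs[, , k] <- lk
    offset <- max(offset, if (any(lk > 0)) max(lk) else offset)
  }
  if (offset == 0L) return(labs)

  pairs <- list()
  # in-slice diagonal adjacency (bwlabel already handles 4-neighbours)
  for (k in seq_len(d[3])) {
    lk <- labs[, , k]
    for (off in list(c(1, 1), c(1, -1))) {
      pairs[[length(pairs) + 1L]] <- collect_pairs(lk, shift2(lk, off[1], off[2]), offset)
    }
  }
  # cross-slice adjacency, all 9 in-plane offsets
  if (d[3] > 1L) {
    for (k in seq_len(d[3] - 1L)) {
      la <- labs[, , k]; lb <- labs[, , k + 1L]
      for (di in -1:1) for (dj in -1:1) {
        pairs[[length(pairs) + 1L]] <- collect_pairs(la, shift2(lb, di, dj), offset)
      }
    }
  }
  parent <- seq_len(offset)
  for (p in pairs) {
    if (is.null(p)) next
    for (r in seq_len(nrow(p))) {
      ra <- uf_find(parent, p[r, 1])
      rb <- uf_find(parent, p[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(offset), function(i) uf_find(parent, i), integer(1))
  dense <- match(roots, sort(unique(roots)))
  pos <- labs > 0
  labs[pos] <- dense[labs[pos]]
  labs
}

#' Keep the largest 3-D connected component of a mask
#'
#' @param mask logical 3-D array.
#' @return logical array retaining only the largest 26-connected component.
#' @export
largest_component_3d <- function(mask) {
  labs <- label_components_3d(mask)
  if (all(labs == 0L)) stop("mask is empty: no connected component to keep")
  counts <- tabulate(labs[labs > 0L])
  labs == which.max(counts)
}
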