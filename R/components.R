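# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, diagonally adjacent 4-labels are merged through a graph
# components pass.
label_components <- function(mask, connectivity = 8L) {
  m <- as_logical_matrix(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  if (connectivity != 8L) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(lab); nc <- ncol(lab)
  # label pairs that touch diagonally
  p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L]))
  p2 <- cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, max(lab) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- lab
  out[lab > 0L] <- memb[lab[lab > 0L]]
  out
}

# Areas of labeled components, index = label id
component_areas <- function(lab) {
  tabulate(lab[lab > 0L])
}

# Fill background regions not reachable from the frame border (4-connected
# background flood fill); these are the interior holes of the 8-connected
# foreground.
fill_holes <- function(mask) {
  m <- as_logical_matrix(mask)
  bg <- label_components(!m, connectivity = 4L)
  border_labels <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  m | (bg > 0L & !(bg %in% border_labels))
}
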