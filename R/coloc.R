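#' Merge per-channel objects into multi-connexin plaques
#'
#' Object-based colocalization: per-channel segmented objects become nodes
#' of a graph; an edge joins two objects from different channels when they
#' satisfy the merge rule, and each connected component becomes one plaque
#' whose combination class is the union of its members' channels. The
#' default rule is voxel overlap of at least \code{min_overlap} voxels; a
#' centroid-distance rule is provided as an alternative since the original
#' colocalization criterion is instrument-software internal.
#'
#' @param channel_objects named list of \code{\link{segment_channel}} results,
#'   one per connexin channel; all must share grid geometry.
#' @param rule \code{"voxel_overlap"} or \code{"centroid_distance"}.
#' @param min_overlap minimum shared voxels (voxel_overlap rule), default 1.
#' @param max_distance maximum centroid separation in um (centroid rule).
#' @return data.frame of plaques: \code{plaque_id}, \code{class}, one-hot
#'   connexin membership columns, \code{n_voxels} (union of member voxel
#'   sets), \code{size_um3}, centroid (um), \code{n_objects}; with the union
#'   voxel sets attached as attribute \code{"voxels"} (list column order).
#' @export
merge_channels <- function(channel_objects, rule = c("voxel_overlap",
                                                     "centroid_distance"),
                           min_overlap = 1L, max_distance = 1) {
  rule <- match.arg(rule)
  stopifnot(is.list(channel_objects), length(channel_objects) >= 1,
            !is.null(names(channel_objects)))
  dims <- lapply(channel_objects, `[[`, "dim")
  vs <- lapply(channel_objects, `[[`, "voxel_size")
  if (length(unique(lapply(dims, as.integer))) > 1 ||
      length(unique(lapply(vs, as.numeric))) > 1) {
    stop("channel geometries (dim / voxel size) do not match")
  }
  d <- dims[[1]]
  voxel_size <- vs[[1]]

  nodes <- data.frame(channel = character(0), obj = integer(0))
  voxlist <- list()
  for (ch in names(channel_objects)) {
    x <- channel_objects[[ch]]
    n <- length(x$voxels)
    if (n) {
      nodes <- rbind(nodes, data.frame(channel = ch, obj = seq_len(n)))
      voxlist <- c(voxlist, x$voxels)
    }
  }
  n_nodes <- nrow(nodes)
  if (n_nodes == 0) {
    return(empty_plaque_table())
  }

  edges <- if (rule == "voxel_overlap") {
    overlap_edges(voxlist, min_overlap)
  } else {
    centroid_edges(voxlist, d, voxel_size, max_distance)
  }
  # never merge two objects of the same channel (they are disjoint by
  # construction under the overlap rule; the centroid rule must not either)
  if (nrow(edges)) {
    same <- nodes$channel[edges[, 1]] == nodes$channel[edges[, 2]]
    edges <- edges[!same, , drop = FALSE]
  }

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership

  comp_ids <- sort(unique(memb))
  np <- length(comp_ids)
  voxsets <- vector("list", np)
  out <- data.frame(class = character(np))
  for (cx in CX_CHANNELS) out[[cx]] <- logical(np)
  out$n_voxels <- integer(np)
  out$size_um3 <- numeric(np)
  out$centroid_z <- out$centroid_y <- out$centroid_x <- numeric(np)
  out$n_objects <- integer(np)
  for (i in seq_len(np)) {
    sel <- which(memb == comp_ids[i])
    members <- unique(nodes$channel[sel])
    union_vox <- sort(unique(unlist(voxlist[sel])))
    co <- vox_coords(union_vox, d)
    voxsets[[i]] <- union_vox
    out$class[i] <- class_label(members)
    for (cx in CX_CHANNELS) out[[cx]][i] <- cx %in% members
    out$n_voxels[i] <- length(union_vox)
    out$size_um3[i] <- length(union_vox) * prod(voxel_size)
    out$centroid_z[i] <- mean((co[, "z"] - 0.5) * voxel_size[1])
    out$centroid_y[i] <- mean((co[, "y"] - 0.5) * voxel_size[2])
    out$centroid_x[i] <- mean((co[, "x"] - 0.5) * voxel_size[3])
    out$n_objects[i] <- length(sel)
  }
  # stable order: by minimum voxel of the union set
  ord <- order(vapply(voxsets, min, numeric(1)))
  out <- out[ord, , drop = FALSE]
  voxsets <- voxsets[ord]
  out$plaque_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("plaque_id", setdiff(names(out), "plaque_id"))]
  attr(out, "voxels") <- voxsets
  attr(out, "field_dim") <- d
  attr(out, "voxel_size") <- voxel_size
  out
}

empty_plaque_table <- function() {
  out <- data.frame(plaque_id = integer(0), class = character(0))
  for (cx in CX_CHANNELS) out[[cx]] <- logical(0)
  out$n_voxels <- integer(0)
  out$size_um3 <- numeric(0)
  out$centroid_z <- out$centroid_y <- out$centroid_x <- numeric(0)
  out$n_objects <- integer(0)
  attr(out, "voxels") <- list()
  out
}

# Pairs of nodes sharing >= k voxels: tabulate co-occurrence of node ids on
# shared voxel addresses.
overlap_edges <- function(voxlist, k) {
  node_id <- rep(seq_along(voxlist), lengths(voxlist))
  vox <- unlist(voxlist)
  if (length(vox) == 0) return(matrix(integer(0), 0, 2))
  dup <- vox %in% vox[duplicated(vox)]
  vox <- vox[dup]
  node_id <- node_id[dup]
  if (length(vox) == 0) return(matrix(integer(0), 0, 2))
  by_vox <- split(node_id, vox)
  pairs <- unlist(lapply(by_vox, function(ids) {
    if (length(ids) < 2) return(NULL)
    cm <- combn(sort(ids), 2)
    split(cm, col(cm))
  }), recursive = FALSE)
  if (length(pairs) == 0) return(matrix(integer(0), 0, 2))
  pm <- do.call(rbind, pairs)
  key <- paste(pm[, 1], pm[, 2])
  cnt <- table(key)
  keep <- names(cnt)[cnt >= k]
  if (length(keep) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(keep, " "), as.integer))
}

centroid_edges <- function(voxlist, d, voxel_size, max_distance) {
  n <- length(voxlist)
  cent <- t(vapply(voxlist, function(v) {
    co <- vox_coords(v, d)
    c(mean((co[, "z"] - 0.5) * voxel_size[1]),
      mean((co[, "y"] - 0.5) * voxel_size[2]),
      mean((co[, "x"] - 0.5) * voxel_size[3]))
  }, numeric(3)))
  dd <- as.matrix(dist(cent))
  idx <- which(dd <= max_distance & upper.tri(dd), arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2)
}

#' Assign plaques to the parenchymal or vascular compartment
#'
#' Operationalizes the parenchymal vs vascular-associated astrocyte
#' distinction per plaque by vessel proximity: a plaque is \code{vascular}
#' iff at least \code{fraction} of its voxels lie within \code{max_distance}
#' um of the vessel mask, else \code{parenchymal}.
#'
#' @param plaques a plaque table from \code{\link{merge_channels}} (its
#'   \code{"voxels"} attribute is used).
#' @param vessel_mask logical 3D array (z, y, x).
#' @param max_distance um from the vessel surface (default 2).
#' @param fraction minimum fraction of plaque voxels within range
#'   (default 0.5).
#' @param voxel_size um per voxel; defaults to the table's recorded geometry.
#' @return the plaque table with a \code{compartment} column added.
#' @export
assign_compartment <- function(plaques, vessel_mask, max_distance = 2,
                               fraction = 0.5,
                               voxel_size = attr(plaques, "voxel_size")) {
  voxsets <- attr(plaques, "voxels")
  stopifnot(!is.null(voxsets), length(voxsets) == nrow(plaques))
  if (nrow(plaques) == 0) {
    plaques$compartment <- character(0)
    return(plaques)
  }
  if (!any(vessel_mask)) {
    warning("empty vessel mask: all plaques assigned parenchymal")
    plaques$compartment <- "parenchymal"
    return(plaques)
  }
  stopifnot(all(dim(vessel_mask) == (attr(plaques, "field_dim") %||%
                                       dim(vessel_mask))))
  near <- dilate_mask(vessel_mask, voxel_size, max_distance)
  frac_near <- vapply(voxsets, function(v) mean(near[v]), numeric(1))
  plaques$compartment <- ifelse(frac_near >= fraction, "vascular",
                                "parenchymal")
  plaques
}
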