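# Topology-preserving thinning and skeleton branch/junction analysis.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# neighbor maps in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW);
# shift_mat(m, dr, dc)[i,j] == m[i+dr, j+dc]
zs_neighbors <- function(m) {
  list(p2 = shift_mat(m, -1L, 0L), p3 = shift_mat(m, -1L, 1L),
       p4 = shift_mat(m, 0L, 1L),  p5 = shift_mat(m, 1L, 1L),
       p6 = shift_mat(m, 1L, 0L),  p7 = shift_mat(m, 1L, -1L),
       p8 = shift_mat(m, 0L, -1L), p9 = shift_mat(m, -1L, -1L))
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iterative two-subcycle thinning to a unit-width, 8-connected skeleton.
#' The classic scheme removes isolated 2x2 blocks entirely; to keep the
#' component count of the source mask, any component that loses all its
#' pixels is restored as its single centroid-nearest pixel. 3D masks are
#' thinned slice-wise.
#'
#' @param mask A `binary_mask` or logical matrix/array.
#' @return Same container type as the input, holding the skeleton.
#' @export
skeletonize <- function(mask) {
  if (inherits(mask, "binary_mask")) {
    sk <- mask
    sk$mask <- skeletonize(mask$mask)
    sk$provenance <- c(mask$provenance, list(skeleton = "zhang-suen"))
    return(sk)
  }
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- mask != 0
  }
  if (length(dim(mask)) == 3L) {
    out <- mask
    for (z in seq_len(dim(mask)[3L])) out[, , z] <- skeletonize(mask[, , z])
    return(out)
  }
  m <- mask
  lab0 <- label_components(mask)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(m)
      b <- Reduce(`+`, nb)
      seq9 <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (!seq9[[i]] & seq9[[i + 1L]])
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1L) {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  # restore components annihilated by thinning (e.g. isolated 2x2 blocks)
  if (max(lab0) > 0L) {
    surviving <- unique(lab0[m & lab0 > 0])
    lost <- setdiff(seq_len(max(lab0)), surviving)
    for (id in lost) {
      idx <- which(lab0 == id, arr.ind = TRUE)
      ctr <- colMeans(idx)
      k <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
      m[idx[k, 1], idx[k, 2]] <- TRUE
    }
  }
  m
}

neighbor_offsets8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Branch and junction metrics of a skeletonized mask
#'
#' Classifies skeleton pixels by their 8-neighbor count: endpoints (< 2
#' neighbors), slab pixels (exactly 2) and junction pixels (> 2). Branches
#' are maximal slab paths connecting endpoints and/or junctions; adjacent
#' junction pixels are merged into a single junction node for tracing, while
#' `n_junctions` reports the raw junction-pixel count. Components without any
#' junction pixel are "individuals" (one branch each), components with at
#' least one junction are "networks". Branch length sums the traced steps
#' (1 for straight, sqrt(2) for diagonal) times the calibration. A component
#' that is a pure cycle (all slab pixels) counts as one circular branch.
#'
#' @param skel A `binary_mask` or logical matrix holding a unit-width
#'   skeleton (a warning is recorded if >5% of foreground pixels look
#'   thicker than unit width).
#' @param calibration Pixel size (um/px); taken from a `binary_mask` input.
#' @param footprint_um2 Total area of the pre-skeleton mask, carried through
#'   to the summary (computed automatically by [skeleton_summary()]).
#' @return List of class `skeleton_summary`: counts, mean branch length,
#'   mean network size (branches per network), footprint, and a `branches`
#'   data.frame (component, length_um, kind).
#' @export
analyze_skeleton <- function(skel, calibration = NULL, footprint_um2 = NA_real_) {
  if (inherits(skel, "binary_mask")) {
    m <- skel$mask; cal <- skel$pixel_size_um
  } else {
    m <- skel
    if (is.null(calibration)) stop("`calibration` required for bare matrices")
    cal <- calibration
  }
  if (length(dim(m)) == 3L) stop("analyze_skeleton expects a 2D skeleton")
  nr <- nrow(m); nc <- ncol(m)
  nb_count <- matrix(0L, nr, nc)
  for (i in seq_len(8))
    nb_count <- nb_count + shift_mat(m, neighbor_offsets8[i, 1], neighbor_offsets8[i, 2])
  nb_count[!m] <- 0L
  is_end <- m & nb_count < 2L
  is_slab <- m & nb_count == 2L
  is_junc <- m & nb_count > 2L
  lab <- label_components(m)
  n_comp <- max(lab)
  # unit-width sanity: solid 2x2 blocks indicate an unthinned region
  solid22 <- m & shift_mat(m, 0L, 1L) & shift_mat(m, 1L, 0L) & shift_mat(m, 1L, 1L)
  if (sum(m) > 0 && sum(solid22) / sum(m) > 0.10)
    warning("skeleton does not look unit-width; junction counts may be inflated")

  # junction nodes: 8-connected clusters of junction pixels
  jlab <- label_components(is_junc)
  node_of <- function(r, c) {
    if (is_junc[r, c]) jlab[r, c] + 1e6 else (c - 1L) * nr + r
  }
  neighbors_of <- function(r, c) {
    rr <- r + neighbor_offsets8[, 1]; cc <- c + neighbor_offsets8[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    on <- m[cbind(rr, cc)]
    cbind(rr[on], cc[on])
  }
  step_len <- function(r1, c1, r2, c2) if (r1 != r2 && c1 != c2) sqrt(2) else 1

  visited_slab <- matrix(FALSE, nr, nc)
  traced_pairs <- character(0)   # dedupe anchor-anchor edges without slabs
  branches <- list()
  add_branch <- function(comp, len, kind)
    branches[[length(branches) + 1L]] <<- data.frame(component = comp,
                                                     length_um = len * cal,
                                                     kind = kind)
  anchors <- which(is_end | is_junc, arr.ind = TRUE)
  if (nrow(anchors)) {
    ord <- order(anchors[, 2], anchors[, 1])   # deterministic scan order
    anchors <- anchors[ord, , drop = FALSE]
  }
  for (ai in seq_len(nrow(anchors))) {
    ar <- anchors[ai, 1]; ac <- anchors[ai, 2]
    nbs <- neighbors_of(ar, ac)
    if (nrow(nbs)) {
      ord <- order(nbs[, 2], nbs[, 1])
      nbs <- nbs[ord, , drop = FALSE]
    }
    for (ni in seq_len(nrow(nbs))) {
      r <- nbs[ni, 1]; c <- nbs[ni, 2]
      if (is_junc[r, c] && is_junc[ar, ac] && jlab[r, c] == jlab[ar, ac])
        next                               # internal to one junction node
      if (is_slab[r, c]) {
        if (visited_slab[r, c]) next
        len <- step_len(ar, ac, r, c)
        prev_r <- ar; prev_c <- ac
        repeat {
          visited_slab[r, c] <- TRUE
          nx <- neighbors_of(r, c)
          nx <- nx[!(nx[, 1] == prev_r & nx[, 2] == prev_c), , drop = FALSE]
          if (nrow(nx) == 0L) break        # dangling end (shouldn't happen)
          # a slab pixel has exactly two neighbors; take the other one
          nr2 <- nx[1, 1]; nc2 <- nx[1, 2]
          len <- len + step_len(r, c, nr2, nc2)
          if (!is_slab[nr2, nc2]) break    # reached an anchor
          if (visited_slab[nr2, nc2]) break
          prev_r <- r; prev_c <- c
          r <- nr2; c <- nc2
        }
        add_branch(lab[ar, ac], len, "path")
      } else {
        # direct anchor-anchor adjacency with no slab between
        key <- paste(sort(c(node_of(ar, ac), node_of(r, c))), collapse = "_")
        if (key %in% traced_pairs) next
        traced_pairs <- c(traced_pairs, key)
        add_branch(lab[ar, ac], step_len(ar, ac, r, c), "direct")
      }
    }
  }
  # pure cycles: remaining unvisited slab pixels with no anchors in component
  left <- which(is_slab & !visited_slab, arr.ind = TRUE)
  if (nrow(left)) {
    for (comp in unique(lab[left])) {
      sel <- left[lab[left] == comp, , drop = FALSE]
      # walk the cycle to measure its length
      r0 <- sel[1, 1]; c0 <- sel[1, 2]
      nxt <- neighbors_of(r0, c0)
      prev_r <- r0; prev_c <- c0
      r <- nxt[1, 1]; c <- nxt[1, 2]
      len <- step_len(r0, c0, r, c)
      visited_slab[r0, c0] <- TRUE
      while (!(r == r0 && c == c0)) {
        visited_slab[r, c] <- TRUE
        nx <- neighbors_of(r, c)
        nx <- nx[!(nx[, 1] == prev_r & nx[, 2] == prev_c), , drop = FALSE]
        prev_r <- r; prev_c <- c
        r <- nx[1, 1]; c <- nx[1, 2]
        len <- len + step_len(prev_r, prev_c, r, c)
      }
      add_branch(comp, len, "cycle")
    }
  }
  # isolated single pixels: one zero-length branch each
  iso <- which(m & nb_count == 0L, arr.ind = TRUE)
  # (already covered: isolated pixels are endpoints with no neighbors, no
  # branch was added for them above)
  if (nrow(iso)) for (i in seq_len(nrow(iso))) add_branch(lab[iso[i, 1], iso[i, 2]], 0, "point")

  br <- if (length(branches)) do.call(rbind, branches) else
    data.frame(component = integer(0), length_um = numeric(0), kind = character(0))
  comp_junc <- if (n_comp) tabulate(lab[is_junc & lab > 0], nbins = n_comp) else integer(0)
  n_networks <- sum(comp_junc > 0)
  n_individuals <- n_comp - n_networks
  br_per_comp <- if (n_comp) tabulate(br$component, nbins = n_comp) else integer(0)
  structure(list(
    n_branches = nrow(br),
    n_junctions = sum(is_junc),
    n_junction_nodes = max(jlab),
    n_endpoints = sum(is_end),
    n_individuals = n_individuals,
    n_networks = n_networks,
    mean_branch_length_um = if (nrow(br)) mean(br$length_um) else NA_real_,
    mean_network_size = if (n_networks) mean(br_per_comp[comp_junc > 0]) else NA_real_,
    footprint_um2 = footprint_um2,
    branches = br
  ), class = "skeleton_summary")
}

#' @export
print.skeleton_summary <- function(x, ...) {
  cat(sprintf(paste0("<skeleton_summary> branches %d, junction px %d, ",
                     "individuals %d, networks %d, mean branch %.3g um, ",
                     "footprint %.4g um^2\n"),
              x$n_branches, x$n_junctions, x$n_individuals, x$n_networks,
              x$mean_branch_length_um, x$footprint_um2))
  invisible(x)
}

#' Skeletonize a mask and summarize it in one step
#'
#' Max-projects 3D masks to 2D (the per-sample skeleton metrics are scalars),
#' thins, and analyzes; the footprint is the area of the (projected)
#' pre-skeleton mask.
#'
#' @param mask A `binary_mask`.
#' @return A `skeleton_summary`.
#' @export
skeleton_summary <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$mask
  if (length(dim(m)) == 3L) m <- apply(m, c(1L, 2L), any)
  fp <- sum(m) * mask$pixel_size_um^2
  analyze_skeleton(skeletonize(m), calibration = mask$pixel_size_um,
                   footprint_um2 = fp)
}
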