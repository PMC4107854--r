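#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (id, structure type, x, y, z,
#' radius, parent id; `#` comments; radii in um, diameter = 2 * radius) and
#' validates the tree: exactly one root (parent -1), all parents present, no
#' cycles, positive radii. Violations raise a parse error naming the
#' offending line.
#'
#' @param path Path to an SWC file.
#' @return Object of class `morphology_tree`: list with `points` (data.frame
#'   `id`, `type`, `x`, `y`, `z`, `radius`, `parent`) plus the source path.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop("SWC parse error at line ", lineno[bad[1L]], ": expected 7 columns")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (any(!is.finite(m))) {
    stop("SWC parse error at line ",
         lineno[which(rowSums(!is.finite(m)) > 0)[1L]], ": non-numeric field")
  }
  pts <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                    parent = as.integer(m[, 7]))
  validate_tree(pts, lineno)
  structure(list(points = pts, path = path), class = "morphology_tree")
}

validate_tree <- function(pts, lineno = seq_len(nrow(pts))) {
  if (any(pts$radius <= 0)) {
    stop("SWC parse error at line ", lineno[which(pts$radius <= 0)[1L]],
         ": non-positive radius")
  }
  if (anyDuplicated(pts$id)) {
    stop("SWC parse error at line ", lineno[which(duplicated(pts$id))[1L]],
         ": duplicate point id")
  }
  roots <- which(pts$parent == -1L)
  if (length(roots) != 1L) {
    stop("SWC tree must have exactly one root (parent -1), found ",
         length(roots))
  }
  idx <- match(pts$parent, pts$id)
  orphan <- which(pts$parent != -1L & is.na(idx))
  if (length(orphan)) {
    stop("SWC parse error at line ", lineno[orphan[1L]],
         ": parent id ", pts$parent[orphan[1L]], " not found")
  }
  # cycle check: walking parents from every node must reach the root
  depth <- rep.int(NA_integer_, nrow(pts))
  depth[roots] <- 0L
  for (pass in seq_len(nrow(pts))) {
    newly <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(newly)) break
    depth[newly] <- depth[idx[newly]] + 1L
  }
  if (anyNA(depth)) {
    stop("SWC parse error at line ", lineno[which(is.na(depth))[1L]],
         ": point unreachable from root (cycle or disconnected)")
  }
  invisible(TRUE)
}

#' Write a morphology tree to SWC
#'
#' @param tree A `morphology_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "morphology_tree"))
  p <- tree$points
  txt <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                 p$id, p$type, p$x, p$y, p$z, p$radius, p$parent)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.morphology_tree <- function(x, ...) {
  cat(sprintf("morphology tree: %d points, %d segment(s)\n",
              nrow(x$points), length(unbranched_segments(x))))
  invisible(x)
}

#' Extract unbranched segments
#'
#' An unbranched segment is a maximal path between branch points and/or
#' terminals. The upstream junction point (branch point or root) is included
#' in each child segment's point list, so adjacent segments share their
#' junction point.
#'
#' @param tree A `morphology_tree`.
#' @return List of integer vectors of point ids, ordered root-to-tip.
#' @export
unbranched_segments <- function(tree) {
  stopifnot(inherits(tree, "morphology_tree"))
  p <- tree$points
  kids <- split(p$id, factor(p$parent, levels = p$id))
  n_kids <- lengths(kids)[as.character(p$id)]
  is_junction <- (p$parent == -1L) | (n_kids >= 2L)
  names(is_junction) <- as.character(p$id)
  segs <- list()
  starts <- p$id[is_junction]
  for (s in starts) {
    for (child in kids[[as.character(s)]]) {
      seg <- c(s, child)
      cur <- child
      while (!is_junction[as.character(cur)] &&
             length(kids[[as.character(cur)]]) == 1L) {
        cur <- kids[[as.character(cur)]][1L]
        seg <- c(seg, cur)
      }
      segs[[length(segs) + 1L]] <- seg
    }
  }
  segs
}

#' Per-segment coefficient of variation of diameters
#'
#' For every unbranched segment, the CV (sample standard deviation over mean,
#' n-1 denominator) of the traced point diameters. Soma-typed points
#' (structure type 1) are excluded from the statistics; segments left with
#' fewer than 2 points are flagged `excluded` with `NA` CV.
#'
#' @param tree A `morphology_tree`.
#' @return data.frame with `segment`, `n_points`, `mean_diam`, `cv`,
#'   `excluded`.
#' @export
diameter_cv <- function(tree) {
  segs <- unbranched_segments(tree)
  p <- tree$points
  rows <- lapply(seq_along(segs), function(i) {
    ids <- segs[[i]]
    sel <- p[match(ids, p$id), ]
    sel <- sel[sel$type != 1L, ]
    diams <- 2 * sel$radius
    n <- length(diams)
    data.frame(segment = i, n_points = n,
               mean_diam = if (n) mean(diams) else NA_real_,
               cv = if (n >= 2L) stats::sd(diams) / mean(diams) else NA_real_,
               excluded = n < 2L)
  })
  do.call(rbind, rows)
}

#' Compartmentalize a morphology
#'
#' Converts each unbranched segment into cylindrical compartments. Mode
#' `one_per_segment` collapses the whole segment into a single compartment
#' with the segment's path length and its length-weighted mean diameter; mode
#' `per_traced_point` makes one compartment per inter-point interval with the
#' two endpoint diameters averaged. Zero-length intervals are collapsed
#' (counted in the `dropped_zero_length` attribute). Total path length is
#' preserved exactly under both modes.
#'
#' @param tree A `morphology_tree`.
#' @param mode `"one_per_segment"` or `"per_traced_point"`.
#' @return Object of class `compartmentalization`: list with `compartments`
#'   (data.frame `id`, `segment`, `diam`, `L`) and `adjacency` (data.frame
#'   `a`, `b` of compartment id pairs sharing an end), plus `mode`.
#' @export
compartmentalize <- function(tree, mode = c("one_per_segment", "per_traced_point")) {
  mode <- match.arg(mode)
  segs <- unbranched_segments(tree)
  p <- tree$points
  comp <- list()
  adjacency <- list()
  dropped <- 0L
  # for cross-junction adjacency: which compartment ends at each point id
  end_comp <- integer(0)
  first_comp_of_seg <- integer(length(segs))
  seg_start_point <- integer(length(segs))
  nid <- 0L
  for (si in seq_along(segs)) {
    ids <- segs[[si]]
    sel <- p[match(ids, p$id), ]
    dx <- diff(sel$x); dy <- diff(sel$y); dz <- diff(sel$z)
    len <- sqrt(dx^2 + dy^2 + dz^2)
    dm <- 2 * (sel$radius[-1L] + sel$radius[-nrow(sel)]) / 2
    keep <- len > 0
    dropped <- dropped + sum(!keep)
    len <- len[keep]; dm <- dm[keep]
    if (!length(len)) next
    if (mode == "one_per_segment") {
      nid <- nid + 1L
      comp[[length(comp) + 1L]] <- data.frame(
        id = nid, segment = si,
        diam = sum(dm * len) / sum(len), L = sum(len))
      first_comp_of_seg[si] <- nid
      end_comp[as.character(ids[length(ids)])] <- nid
    } else {
      idx <- nid + seq_along(len)
      comp[[length(comp) + 1L]] <- data.frame(
        id = idx, segment = si, diam = dm, L = len)
      if (length(idx) > 1L) {
        adjacency[[length(adjacency) + 1L]] <-
          data.frame(a = idx[-length(idx)], b = idx[-1L])
      }
      first_comp_of_seg[si] <- idx[1L]
      end_comp[as.character(ids[length(ids)])] <- idx[length(idx)]
      nid <- nid + length(len)
    }
    seg_start_point[si] <- ids[1L]
  }
  # junction adjacency: the segment's first compartment touches the
  # compartment that ends at the segment's start point (if any)
  for (si in seq_along(segs)) {
    up <- end_comp[as.character(seg_start_point[si])]
    if (!is.na(up) && length(up) && first_comp_of_seg[si] > 0L) {
      adjacency[[length(adjacency) + 1L]] <-
        data.frame(a = up, b = first_comp_of_seg[si])
    }
  }
  compartments <- if (length(comp)) do.call(rbind, comp)
                  else data.frame(id = integer(), segment = integer(),
                                  diam = numeric(), L = numeric())
  adj <- if (length(adjacency)) unique(do.call(rbind, adjacency))
         else data.frame(a = integer(), b = integer())
  structure(list(compartments = compartments, adjacency = adj, mode = mode,
                 dropped_zero_length = dropped),
            class = "compartmentalization")
}

#' @export
print.compartmentalization <- function(x, ...) {
  cat(sprintf("compartmentalization (%s): %d compartments, %d adjacencies\n",
              x$mode, nrow(x$compartments), nrow(x$adjacency)))
  invisible(x)
}
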