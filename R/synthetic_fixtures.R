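#' Recipe for a synthetic morphology tree
#'
#' Describes a parametric binary dendritic tree used as a test fixture:
#' `branch_depth` levels of bifurcations, straight segments of
#' `points_per_segment` traced points over `segment_length` um, diameters
#' tapering within segments and stepping down across branch points, and
#' controlled within-segment diameter variability. Diameter noise is
#' multiplicative truncated Gaussian (truncated at +-3 sigma with
#' `sigma = noise_cv`, floored at 0.05 um) so the realized per-segment CV
#' tracks the target and diameters stay positive.
#'
#' @param branch_depth Number of bifurcation levels (0 = a single segment).
#' @param points_per_segment Traced points per segment (>= 2).
#' @param segment_length Segment path length, um.
#' @param base_diam Diameter at the root end, um.
#' @param taper Within-segment end/start diameter ratio (1 = no taper).
#' @param child_ratio Child/parent starting-diameter ratios at bifurcations
#'   (length 2).
#' @param noise_cv Target within-segment diameter CV (0 = clean).
#' @param seed RNG seed (required for reproducibility).
#' @return Object of class `tree_recipe`.
#' @export
tree_recipe <- function(branch_depth = 2, points_per_segment = 12,
                        segment_length = 20, base_diam = 2, taper = 0.8,
                        child_ratio = c(0.8, 0.65), noise_cv = 0,
                        seed = 1L) {
  stopifnot(branch_depth >= 0, points_per_segment >= 2, segment_length > 0,
            base_diam > 0, taper > 0, all(child_ratio > 0),
            noise_cv >= 0, length(seed) == 1L)
  structure(list(branch_depth = branch_depth,
                 points_per_segment = as.integer(points_per_segment),
                 segment_length = segment_length, base_diam = base_diam,
                 taper = taper, child_ratio = rep_len(child_ratio, 2L),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "tree_recipe")
}

# truncated multiplicative Gaussian noise factor
trunc_noise <- function(n, sigma) {
  if (sigma == 0) return(rep(1, n))
  eps <- stats::rnorm(n, 0, sigma)
  eps <- pmin(pmax(eps, -3 * sigma), 3 * sigma)
  1 + eps
}

#' Generate a synthetic morphology tree
#'
#' Deterministic for a fixed recipe seed: the same recipe always yields the
#' same tree (the global RNG state is saved and restored).
#'
#' @param recipe A [tree_recipe()].
#' @return A `morphology_tree` that passes all morphology validators.
#' @export
generate_tree <- function(recipe) {
  stopifnot(inherits(recipe, "tree_recipe"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(recipe$seed)

  pts <- list()
  nid <- 0L
  add_point <- function(type, x, y, z, radius, parent) {
    nid <<- nid + 1L
    pts[[nid]] <<- data.frame(id = nid, type = type, x = x, y = y, z = z,
                              radius = radius, parent = parent)
    nid
  }
  # soma root
  root <- add_point(1L, 0, 0, 0, recipe$base_diam / 2, -1L)

  grow <- function(parent_id, x0, y0, dir_angle, start_diam, level) {
    # the upstream junction point is shared; this segment adds npts points,
    # the first one step away from the junction
    npts <- recipe$points_per_segment
    step <- recipe$segment_length / npts
    base <- start_diam * seq(1, recipe$taper, length.out = npts)
    noise <- trunc_noise(npts, recipe$noise_cv)
    diams <- pmax(base * noise, 0.05)
    prev <- parent_id
    x <- x0; y <- y0
    for (i in seq_len(npts)) {
      x <- x + step * cos(dir_angle)
      y <- y + step * sin(dir_angle)
      prev <- add_point(3L, x, y, 0, diams[i] / 2, prev)
    }
    if (level < recipe$branch_depth) {
      end_diam <- base[npts]
      grow(prev, x, y, dir_angle + 0.5,
           end_diam * recipe$child_ratio[1L], level + 1L)
      grow(prev, x, y, dir_angle - 0.5,
           end_diam * recipe$child_ratio[2L], level + 1L)
    }
    invisible(NULL)
  }
  grow(root, 0, 0, 0, recipe$base_diam, 0L)
  tree <- structure(list(points = do.call(rbind, pts), path = NA_character_),
                    class = "morphology_tree")
  validate_tree(tree$points)
  tree
}
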