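#' Occlusal reference frame
#'
#' The viewing frame for cusp-tip detection: a unit axis pointing from
#' cervical toward occlusal (heights increase toward the cusp tips) and
#' an origin. For the synthetic dentition meshes the default `+z` axis is
#' correct; for real scans the operator supplies the axis.
#'
#' @param axis Length-3 direction vector (normalised internally; must be
#'   non-zero).
#' @param origin Length-3 point in mm.
#' @return An `occlusal_frame` list with unit `axis` and `origin`.
#' @export
occlusal_frame <- function(axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  origin <- as.numeric(origin)
  if (length(axis) != 3 || length(origin) != 3 ||
      any(!is.finite(c(axis, origin)))) {
    ms_validation_error("axis and origin must be finite length-3 vectors")
  }
  len <- sqrt(sum(axis^2))
  if (len == 0) ms_validation_error("axis must be non-zero")
  structure(list(axis = axis / len, origin = origin),
            class = "occlusal_frame")
}

#' Per-vertex occlusal height field
#'
#' Projects each mesh vertex onto the occlusal axis:
#' `height = (vertex - origin) . axis`. This is the numeric analogue of
#' the colour-coded vertex-height rendering used to locate cusp tips on
#' scanned dentitions.
#'
#' @param mesh A [tri_mesh()].
#' @param frame An [occlusal_frame()].
#' @return Numeric vector of heights (mm), one per vertex.
#' @export
height_field <- function(mesh, frame = occlusal_frame()) {
  if (!inherits(mesh, "tri_mesh")) ms_validation_error("mesh must be a tri_mesh")
  if (!inherits(frame, "occlusal_frame")) {
    ms_validation_error("frame must be an occlusal_frame")
  }
  as.numeric(sweep(mesh$vertices, 2, frame$origin) %*% frame$axis)
}

#' Detect cusp-tip candidates on a dentition mesh
#'
#' Reproducible analogue of the colour-guided manual tip picking on
#' scanned dentitions: vertices above the `1 - top_fraction` height
#' quantile (the highest occlusal band) are partitioned into connected
#' components over mesh edges (per-tooth regions of interest); each
#' component's maximum-height vertex is a tip candidate whose prominence
#' is its height above the component's lowest (saddle) vertex. Candidates
#' with prominence below `min_prominence` are dropped, and candidates
#' closer than `min_separation` are suppressed keeping the higher one.
#'
#' Candidate positions are vertices of the input mesh (no interpolation).
#'
#' @param mesh A [tri_mesh()].
#' @param frame An [occlusal_frame()].
#' @param top_fraction Fraction of vertices forming the high band
#'   (0 < top_fraction < 1; default 0.15).
#' @param min_prominence Minimum height of a tip above its region's
#'   saddle, mm (default 0.5).
#' @param min_separation Minimum distance between reported tips, mm
#'   (default 2.0).
#' @return A data frame of candidates sorted by height descending:
#'   columns `x`, `y`, `z`, `height`, `region_id`, `prominence`. Empty
#'   (with a warning) when no vertex clears the threshold.
#' @export
extract_tip_candidates <- function(mesh, frame = occlusal_frame(),
                                   top_fraction = 0.15,
                                   min_prominence = 0.5,
                                   min_separation = 2.0) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    ms_validation_error("top_fraction must be in (0, 1)")
  }
  h <- height_field(mesh, frame)
  thr <- stats::quantile(h, probs = 1 - top_fraction, names = FALSE)
  keep <- which(h > thr)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      height = numeric(), region_id = integer(),
                      prominence = numeric())
  if (!length(keep)) {
    warning("no vertices above the height threshold; no tip candidates")
    return(empty)
  }
  # connected components of the supra-threshold vertex subgraph
  tri <- mesh$triangles
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  inkeep <- matrix(edges %in% keep, ncol = 2)
  edges <- edges[inkeep[, 1] & inkeep[, 2], , drop = FALSE]
  idx <- match(edges, keep)
  g <- igraph::graph_from_edgelist(matrix(idx, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(keep) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  cands <- do.call(rbind, lapply(seq_len(max(comp)), function(cid) {
    vs <- keep[comp == cid]
    top <- vs[which.max(h[vs])]
    data.frame(x = mesh$vertices[top, 1], y = mesh$vertices[top, 2],
               z = mesh$vertices[top, 3], height = h[top],
               region_id = cid, prominence = h[top] - min(h[vs]))
  }))
  cands <- cands[cands$prominence >= min_prominence, , drop = FALSE]
  cands <- cands[order(-cands$height), , drop = FALSE]
  if (!nrow(cands)) { rownames(cands) <- NULL; return(cands) }
  # non-maximum suppression: keep the higher of any close pair
  kept <- integer()
  for (i in seq_len(nrow(cands))) {
    p <- as.numeric(cands[i, c("x", "y", "z")])
    if (!length(kept)) { kept <- i; next }
    d <- sqrt(rowSums(sweep(as.matrix(cands[kept, c("x", "y", "z")]), 2, p)^2))
    if (all(d >= min_separation)) kept <- c(kept, i)
  }
  cands <- cands[kept, , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Assign landmark labels to tip candidates
#'
#' Matches detected tip candidates to the labels of a complete 26-point
#' template (e.g. the noiseless arch layout registered to the mesh frame)
#' by a one-to-one minimum-total-distance assignment (solved exactly via
#' the linear sum assignment problem). With fewer candidates than labels
#' the result is a partial landmark set and the unmatched labels are
#' reported missing.
#'
#' @param candidates Candidate data frame from
#'   [extract_tip_candidates()] (columns `x`, `y`, `z`), or an n x 3
#'   matrix.
#' @param template A complete [landmark_set()] giving the expected
#'   layout.
#' @return A [landmark_set()] of the labelled candidates, with
#'   attributes `missing` (character vector of unmatched labels) and
#'   `total_cost` (sum of matched distances, mm).
#' @export
assign_labels <- function(candidates, template) {
  if (!inherits(template, "landmark_set") || !template$complete) {
    ms_validation_error("template must be a complete landmark_set")
  }
  if (is.data.frame(candidates)) {
    cand <- as.matrix(candidates[, c("x", "y", "z")])
  } else {
    cand <- as_point_matrix(candidates)
  }
  if (!nrow(cand)) ms_validation_error("no candidates to label")
  tmpl <- as_point_matrix(template)
  cost <- outer(seq_len(nrow(cand)), seq_len(nrow(tmpl)),
                Vectorize(function(i, j) sqrt(sum((cand[i, ] - tmpl[j, ])^2))))
  if (nrow(cand) <= nrow(tmpl)) {
    sol <- clue::solve_LSAP(cost)
    ci <- seq_len(nrow(cand)); li <- as.integer(sol)
  } else {
    sol <- clue::solve_LSAP(t(cost))
    li <- seq_len(nrow(tmpl)); ci <- as.integer(sol)
  }
  labels <- rownames(tmpl)[li]
  pts <- cand[ci, , drop = FALSE]
  rownames(pts) <- labels
  out <- landmark_set(pts, subject_id = template$subject_id)
  attr(out, "missing") <- setdiff(rownames(tmpl), labels)
  attr(out, "total_cost") <- sum(cost[cbind(ci, li)])
  out
}

#' Detect and label cusp tips on a mesh
#'
#' Convenience pipeline: [extract_tip_candidates()] followed by
#' [assign_labels()] when a template is given.
#'
#' @inheritParams extract_tip_candidates
#' @param template Optional complete [landmark_set()] for labelling.
#' @return With a template, a labelled [landmark_set()]; without one,
#'   the candidate data frame.
#' @export
detect_landmarks <- function(mesh, frame = occlusal_frame(),
                             template = NULL, top_fraction = 0.15,
                             min_prominence = 0.5, min_separation = 2.0) {
  cands <- extract_tip_candidates(mesh, frame, top_fraction,
                                  min_prominence, min_separation)
  if (is.null(template)) return(cands)
  if (!nrow(cands)) ms_computation_error("no tip candidates detected")
  assign_labels(cands, template)
}
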