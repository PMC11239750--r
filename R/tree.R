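#' Synthetic coronary tree generator
#'
#' Builds a rooted binary tree of vessel segments whose bifurcation radii
#' obey Murray's cube law exactly: at every bifurcation
#' `r_parent^3 = r_left^3 + r_right^3`. Child asymmetry (ratio of the
#' smaller to the larger daughter radius) and segment length-to-radius
#' ratios are drawn from configurable uniform ranges, so trees of the same
#' depth differ in geometry but share the scaling law. Generation 1 is the
#' single inlet segment; each further generation doubles the segment count,
#' so `n_generations = g` yields `2^g - 1` segments and `2^(g-1)` outlets.
#'
#' The default distal pressure measurement point is the distal end of the
#' main (largest-radius) path; [add_stenosis()] moves it 2.5 cm distal to
#' the lesion.
#'
#' @param n_generations tree depth, >= 1.
#' @param root_radius inlet (healthy lumen) radius, cm.
#' @param seed integer seed; identical seeds give identical trees.
#' @param length_ratio_range range of the segment length/radius ratio.
#' @param asymmetry_range range of the daughter radius ratio (small/large).
#' @return An object of class `coronary_tree`.
#' @examples
#' tr <- generate_tree(3, 0.15, seed = 1)
#' tr
#' @export
generate_tree <- function(n_generations, root_radius = 0.15, seed = NULL,
                          length_ratio_range = c(4, 8),
                          asymmetry_range = c(0.5, 0.8)) {
  n_generations <- as.integer(n_generations)
  if (is.na(n_generations) || n_generations < 1L)
    stop("n_generations must be a positive integer")
  if (!is.numeric(root_radius) || root_radius <= 0)
    stop("root_radius must be positive")
  with_seed(seed, {
    id <- 1L
    seg <- data.frame(
      id = 1L, parent = NA_integer_,
      length_cm = stats::runif(1, length_ratio_range[1], length_ratio_range[2]) * root_radius,
      radius_cm = root_radius,
      sten_degree = NA_real_, sten_length_cm = NA_real_, sten_pos = NA_real_,
      wire = FALSE
    )
    current <- 1L
    if (n_generations > 1L) {
      for (g in 2:n_generations) {
        nxt <- integer(0)
        for (p in current) {
          rp <- seg$radius_cm[p]
          gam <- stats::runif(1, asymmetry_range[1], asymmetry_range[2])
          r_big <- rp / (1 + gam^3)^(1 / 3)
          r_small <- gam * r_big
          for (r in c(r_big, r_small)) {
            id <- id + 1L
            seg <- rbind(seg, data.frame(
              id = id, parent = p,
              length_cm = stats::runif(1, length_ratio_range[1], length_ratio_range[2]) * r,
              radius_cm = r,
              sten_degree = NA_real_, sten_length_cm = NA_real_,
              sten_pos = NA_real_, wire = FALSE
            ))
            nxt <- c(nxt, id)
          }
        }
        current <- nxt
      }
    }
    tree <- structure(list(segments = seg, wire_diameter_cm = NA_real_,
                           measurement = NULL),
                      class = "coronary_tree")
    leaf <- main_path_leaf(tree)
    tree$measurement <- list(segment_id = leaf,
                             offset_cm = seg$length_cm[leaf])
    validate_tree(tree)
    tree
  })
}

# ---- topology helpers -------------------------------------------------------

#' Tree topology queries
#'
#' `tree_outlets` returns the ids of terminal segments; `tree_path` the ids
#' on the root-to-segment path (inclusive); `crown_length` the summed
#' length of the subtree rooted at a segment (the "crown" of an outlet).
#'
#' @param tree a `coronary_tree`.
#' @param segment_id a segment id.
#' @return Integer vector of ids, or a numeric length in cm.
#' @export
tree_outlets <- function(tree) {
  s <- tree$segments
  sort(setdiff(s$id, s$parent[!is.na(s$parent)]))
}

#' @rdname tree_outlets
#' @export
tree_path <- function(tree, segment_id) {
  s <- tree$segments
  if (!segment_id %in% s$id) stop("no segment with id ", segment_id)
  path <- integer(0)
  cur <- segment_id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- s$parent[s$id == cur]
  }
  path
}

#' @rdname tree_outlets
#' @export
crown_length <- function(tree, segment_id) {
  s <- tree$segments
  total <- 0
  stack <- segment_id
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    total <- total + s$length_cm[s$id == cur]
    stack <- c(stack, s$id[!is.na(s$parent) & s$parent == cur])
  }
  total
}

children_of <- function(tree, segment_id) {
  s <- tree$segments
  s$id[!is.na(s$parent) & s$parent == segment_id]
}

# Follow the larger-radius child from `from` (default root) to a leaf.
main_path_leaf <- function(tree, from = 1L) {
  s <- tree$segments
  cur <- from
  repeat {
    ch <- children_of(tree, cur)
    if (!length(ch)) return(cur)
    cur <- ch[which.max(s$radius_cm[match(ch, s$id)])]
  }
}

validate_tree <- function(tree) {
  s <- tree$segments
  if (any(s$length_cm <= 0) || any(s$radius_cm <= 0))
    stop("segment lengths and radii must be positive")
  nroot <- sum(is.na(s$parent))
  if (nroot != 1L) stop("tree must have exactly one root segment")
  if (any(!is.na(s$parent) & !(s$parent %in% s$id)))
    stop("dangling parent reference")
  # parents precede children -> no cycles and topological order by row
  if (any(!is.na(s$parent) & s$parent >= s$id))
    stop("segments must be ordered with parents before children")
  sten <- !is.na(s$sten_degree)
  if (any(sten)) {
    if (any(s$sten_degree[sten] < 0 | s$sten_degree[sten] >= 1))
      stop("stenosis degree must lie in [0, 1)")
    if (any(s$sten_length_cm[sten] <= 0 |
            s$sten_length_cm[sten] > s$length_cm[sten]))
      stop("stenosis length must be positive and no longer than its segment")
  }
  if (!is.null(tree$measurement)) {
    m <- tree$measurement
    if (!m$segment_id %in% s$id) stop("measurement segment does not exist")
    len <- s$length_cm[s$id == m$segment_id]
    if (m$offset_cm < 0 || m$offset_cm > len + 1e-12)
      stop("measurement offset outside its segment")
  }
  invisible(tree)
}

# ---- lesions and wires ------------------------------------------------------

#' Attach a stenosis to a segment
#'
#' Marks a fractional area reduction (degree `1 - A_s/A_0`) of given throat
#' length at a fractional position along an existing segment, and moves the
#' distal measurement point `measurement_distance_cm` downstream of the
#' stenosis (following the larger-radius child at bifurcations, clipped to
#' the branch end). The input tree is not modified.
#'
#' @param tree a `coronary_tree`.
#' @param segment_id id of the segment to narrow.
#' @param degree fractional area reduction in `[0, 1)`; full occlusion
#'   (degree 1) is not supported.
#' @param stenosis_length throat length, cm; must not exceed the segment.
#' @param position fractional position of the throat centre along the
#'   segment, in `[0, 1]`.
#' @param measurement_distance_cm distance from the stenosis to the distal
#'   pressure sampling point.
#' @return A new `coronary_tree` with the stenosis recorded.
#' @examples
#' tr <- generate_tree(3, seed = 1)
#' tr2 <- add_stenosis(tr, segment_id = 2, degree = 0.7)
#' @export
add_stenosis <- function(tree, segment_id, degree, stenosis_length = 0.3,
                         position = 0.5, measurement_distance_cm = 2.5) {
  stopifnot(inherits(tree, "coronary_tree"))
  s <- tree$segments
  i <- match(segment_id, s$id)
  if (is.na(i)) stop("no segment with id ", segment_id)
  if (!is.numeric(degree) || degree < 0 || degree >= 1)
    stop("stenosis degree must lie in [0, 1); full occlusion is unsupported")
  if (stenosis_length <= 0 || stenosis_length > s$length_cm[i])
    stop("stenosis length must be positive and no longer than the segment")
  if (position < 0 || position > 1) stop("position must lie in [0, 1]")
  out <- tree
  out$segments$sten_degree[i] <- degree
  out$segments$sten_length_cm[i] <- stenosis_length
  out$segments$sten_pos[i] <- position
  out$measurement <- measurement_distal_to(out, segment_id, position,
                                           measurement_distance_cm)
  validate_tree(out)
  out
}

# Walk `distance` cm downstream from (segment, fractional position),
# descending into the larger-radius child at bifurcations; clip at leaves.
measurement_distal_to <- function(tree, segment_id, position, distance) {
  s <- tree$segments
  cur <- s$id[match(segment_id, s$id)]
  len <- s$length_cm[s$id == cur]
  offset <- position * len
  remaining <- distance
  repeat {
    len <- s$length_cm[s$id == cur]
    avail <- len - offset
    if (remaining <= avail) return(list(segment_id = cur, offset_cm = offset + remaining))
    remaining <- remaining - avail
    ch <- children_of(tree, cur)
    if (!length(ch)) return(list(segment_id = cur, offset_cm = len))
    cur <- ch[which.max(s$radius_cm[match(ch, s$id)])]
    offset <- 0
  }
}

#' Insert a pressure guidewire
#'
#' Marks the guidewire as present along a path of segments; those segments
#' then carry annular (wire-included) viscous resistance and stenosis
#' throats are evaluated with the wire cross-section removed from both
#' reference and throat areas. The default path follows the clinical
#' situation the model represents: the wire runs along the stenotic branch,
#' from the lesion segment to the distal measurement segment. The
#' alternative `"inlet_to_measurement"` threads it from the tree ostium.
#' The wire must fit: its radius has to be smaller than the narrowest lumen
#' (stenotic throat included) it crosses.
#'
#' @param tree a `coronary_tree`.
#' @param diameter_cm wire diameter, cm (clinical pressure wire: 0.036).
#' @param path `"stenotic_branch"`, `"inlet_to_measurement"`, or an integer
#'   vector of segment ids; an empty integer vector leaves the tree
#'   unchanged.
#' @return A new `coronary_tree` with `wire_present` set along the path.
#' @examples
#' tr <- add_stenosis(generate_tree(3, seed = 1), 2, 0.5)
#' trw <- insert_guidewire(tr)
#' @export
insert_guidewire <- function(tree, diameter_cm = 0.036,
                             path = c("stenotic_branch", "inlet_to_measurement")) {
  stopifnot(inherits(tree, "coronary_tree"))
  if (!is.numeric(diameter_cm) || diameter_cm <= 0)
    stop("wire diameter must be positive")
  if (is.numeric(path)) {
    ids <- as.integer(path)
    if (length(ids) == 0L) return(tree)
    if (!all(ids %in% tree$segments$id)) stop("unknown segment id in wire path")
  } else {
    path <- match.arg(path)
    meas <- tree$measurement$segment_id
    full <- tree_path(tree, meas)
    if (path == "inlet_to_measurement") {
      ids <- full
    } else {
      sten <- tree$segments$id[!is.na(tree$segments$sten_degree)]
      first <- if (length(sten) && any(sten %in% full)) min(match(sten, full), na.rm = TRUE)
               else length(full)  # healthy tree: wire only in measurement segment
      ids <- full[first:length(full)]
    }
  }
  rw <- diameter_cm / 2
  s <- tree$segments
  for (i in match(ids, s$id)) {
    rmin <- if (!is.na(s$sten_degree[i]))
      s$radius_cm[i] * sqrt(1 - s$sten_degree[i]) else s$radius_cm[i]
    if (rw >= rmin)
      stop(sprintf("wire does not fit: wire radius %.4f cm >= lumen radius %.4f cm in segment %d",
                   rw, rmin, s$id[i]))
  }
  out <- tree
  out$segments$wire[match(ids, s$id)] <- TRUE
  out$wire_diameter_cm <- diameter_cm
  out
}

#' @export
print.coronary_tree <- function(x, ...) {
  s <- x$segments
  nsten <- sum(!is.na(s$sten_degree))
  cat(sprintf("Coronary tree: %d segments, %d outlets, root radius %.3f cm\n",
              nrow(s), length(tree_outlets(x)), s$radius_cm[1]))
  if (nsten)
    cat(sprintf("  stenoses: %s\n", paste(sprintf(
      "segment %d (%.0f%% area, %.2f cm)",
      s$id[!is.na(s$sten_degree)], 100 * s$sten_degree[!is.na(s$sten_degree)],
      s$sten_length_cm[!is.na(s$sten_degree)]), collapse = "; ")))
  if (any(s$wire))
    cat(sprintf("  guidewire (%.3f cm) in segments %s\n", x$wire_diameter_cm,
                paste(s$id[s$wire], collapse = ", ")))
  cat(sprintf("  measurement: segment %d, %.2f cm from its inlet\n",
              x$measurement$segment_id, x$measurement$offset_cm))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a coronary tree to JSON
#'
#' Field names carry explicit units (`length_cm`, `radius_cm`,
#' `wire_diameter_cm`). `read_tree()` inverts `write_tree()` exactly.
#'
#' @param tree a `coronary_tree`.
#' @param path file path.
#' @return `write_tree` returns `path` invisibly; `read_tree` a
#'   `coronary_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "coronary_tree"))
  obj <- list(segments = tree$segments,
              wire_diameter_cm = tree$wire_diameter_cm,
              measurement = tree$measurement)
  jsonlite::write_json(obj, path, digits = NA, na = "null", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- as.data.frame(obj$segments)
  seg$id <- as.integer(seg$id)
  seg$parent <- as.integer(seg$parent)
  seg$wire <- as.logical(seg$wire)
  for (col in c("sten_degree", "sten_length_cm", "sten_pos"))
    seg[[col]] <- as.numeric(seg[[col]])
  tree <- structure(list(
    segments = seg,
    wire_diameter_cm = if (is.null(obj$wire_diameter_cm)) NA_real_ else as.numeric(obj$wire_diameter_cm),
    measurement = list(segment_id = as.integer(obj$measurement$segment_id),
                       offset_cm = as.numeric(obj$measurement$offset_cm))
  ), class = "coronary_tree")
  validate_tree(tree)
  tree
}
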