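#' Skeleton joint topology
#'
#' A joint topology names the joints of the skeleton and lists its bones as
#' (parent, child) index pairs.  The bones must form a spanning tree over the
#' joints: connected, acyclic, with exactly `n_joints - 1` edges.
#'
#' @param joint_names Character vector of unique joint identifiers.
#' @param bones Integer matrix with two columns (parent index, child index),
#'   1-based, one row per bone.
#' @param root Index of the root joint (the kinematic anchor, conventionally
#'   the pelvis).
#'
#' @return An object of class `joint_topology` with elements `joint_names`,
#'   `bones` and `root`.
#' @seealso [default_topology()]
#' @export
joint_topology <- function(joint_names, bones, root = 1L) {
  if (!is.character(joint_names) || anyDuplicated(joint_names) > 0L)
    stop_validation("`joint_names` must be unique identifiers")
  n <- length(joint_names)
  bones <- as.matrix(bones)
  if (!is.numeric(bones) || ncol(bones) != 2L)
    stop_validation("`bones` must be a two-column (parent, child) matrix")
  storage.mode(bones) <- "integer"
  root <- check_number(root, "root", lower = 1, upper = n, integer = TRUE)
  validate_bone_tree(bones, n)
  structure(
    list(joint_names = joint_names, bones = unname(bones), root = root),
    class = "joint_topology"
  )
}

# Rejects any edge list that is not a spanning tree on n nodes.
validate_bone_tree <- function(bones, n) {
  if (nrow(bones) != n - 1L)
    stop_validation("a tree on %d joints needs %d bones, got %d",
                    n, n - 1L, nrow(bones))
  if (any(bones < 1L) || any(bones > n))
    stop_validation("bone indices must lie in [1, %d]", n)
  if (any(bones[, 1L] == bones[, 2L]))
    stop_validation("bones must not be self-loops")
  key <- paste(pmin(bones[, 1L], bones[, 2L]), pmax(bones[, 1L], bones[, 2L]))
  if (anyDuplicated(key) > 0L)
    stop_validation("duplicate bone between joints %s", key[duplicated(key)][1L])
  # connectivity by breadth-first search over the undirected edges
  adj <- vector("list", n)
  for (b in seq_len(nrow(bones))) {
    i <- bones[b, 1L]; j <- bones[b, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen))
    stop_validation("bones do not connect all joints (joint %d unreachable)",
                    which(!seen)[1L])
  invisible(TRUE)
}

#' Canonical 16-joint skeleton topology
#'
#' The package's native skeleton has 16 joints: a head-neck-spine-pelvis
#' chain, and left/right shoulder-elbow-wrist and hip-knee-ankle limb chains.
#' Its 15 bones form a tree rooted at the pelvis.  Alternative joint sets can
#' be supplied to every function that takes a topology via
#' [joint_topology()].
#'
#' @return A `joint_topology` with 16 joints and 15 bones, pelvis root.
#' @examples
#' topo <- default_topology()
#' length(topo$joint_names) # 16
#' nrow(topo$bones)         # 15
#' @export
default_topology <- function() {
  names <- c("head", "neck", "spine", "pelvis",
             "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
             "l_wrist", "r_wrist", "l_hip", "r_hip",
             "l_knee", "r_knee", "l_ankle", "r_ankle")
  idx <- function(x) match(x, names)
  edge <- function(p, c) c(idx(p), idx(c))
  bones <- rbind(
    edge("pelvis", "spine"),
    edge("spine", "neck"),
    edge("neck", "head"),
    edge("neck", "l_shoulder"),
    edge("neck", "r_shoulder"),
    edge("l_shoulder", "l_elbow"),
    edge("r_shoulder", "r_elbow"),
    edge("l_elbow", "l_wrist"),
    edge("r_elbow", "r_wrist"),
    edge("pelvis", "l_hip"),
    edge("pelvis", "r_hip"),
    edge("l_hip", "l_knee"),
    edge("r_hip", "r_knee"),
    edge("l_knee", "l_ankle"),
    edge("r_knee", "r_ankle")
  )
  joint_topology(names, bones, root = idx("pelvis"))
}

#' @export
print.joint_topology <- function(x, ...) {
  cat(sprintf("<joint_topology> %d joints, %d bones, root '%s'\n",
              length(x$joint_names), nrow(x$bones),
              x$joint_names[x$root]))
  invisible(x)
}
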