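#' Construct an atlas specification
#'
#' An atlas assigns every network node to exactly one subnetwork (module).
#' The default emulates the 160-node functional parcellation commonly used
#' for resting-state connectomes, split into six subnetworks (cerebellum,
#' sensorimotor, occipital, cingulo-opercular, default, fronto-parietal)
#' with sizes proportional to that scheme.
#'
#' @param n_nodes Number of nodes (>= 3). Default 160.
#' @param subnetwork_of Optional integer vector of length `n_nodes` giving
#'   the subnetwork id (contiguous from 1) of each node. When `NULL`, nodes
#'   are allocated to the six canonical subnetworks by largest-remainder
#'   proportional split.
#' @param labels Optional character vector of node names.
#' @return An object of class `atlas_spec` with fields `n_nodes`,
#'   `subnetwork_of`, `subnetwork_names`, `labels`.
#' @examples
#' atl <- atlas_spec(160)
#' table(atl$subnetwork_of)
#' @export
atlas_spec <- function(n_nodes = 160L, subnetwork_of = NULL, labels = NULL) {
  stopifnot_scalar_count(n_nodes, "n_nodes", min = 3L)
  n_nodes <- as.integer(n_nodes)
  subnetwork_names <- c("cerebellum", "sensorimotor", "occipital",
                        "cingulo_opercular", "default", "frontoparietal")
  if (is.null(subnetwork_of)) {
    # canonical 160-node subnetwork sizes; other n allocated proportionally
    base_sizes <- c(18L, 33L, 22L, 32L, 34L, 21L)
    sizes <- largest_remainder(base_sizes / sum(base_sizes), n_nodes)
    subnetwork_of <- rep.int(seq_along(sizes), sizes)
  } else {
    subnetwork_of <- as.integer(subnetwork_of)
    if (length(subnetwork_of) != n_nodes) {
      stop("`subnetwork_of` must have one entry per node", call. = FALSE)
    }
    ids <- sort(unique(subnetwork_of))
    if (!identical(ids, seq_along(ids))) {
      stop("subnetwork ids must be contiguous integers starting at 1", call. = FALSE)
    }
    if (length(ids) > length(subnetwork_names)) {
      subnetwork_names <- paste0("subnetwork", seq_along(ids))
    } else {
      subnetwork_names <- subnetwork_names[seq_along(ids)]
    }
  }
  if (is.null(labels)) {
    labels <- sprintf("node%03d_%s", seq_len(n_nodes),
                      subnetwork_names[subnetwork_of])
  }
  stopifnot(length(labels) == n_nodes, !anyDuplicated(labels))
  structure(list(n_nodes = n_nodes,
                 subnetwork_of = subnetwork_of,
                 subnetwork_names = subnetwork_names,
                 labels = labels),
            class = "atlas_spec")
}

# allocate n items to proportions, exact total, largest remainder
largest_remainder <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[idx] <- k[idx] + 1
  }
  if (any(k == 0)) {
    # every subnetwork keeps at least one node for tiny atlases
    for (i in which(k == 0)) {
      j <- which.max(k)
      k[j] <- k[j] - 1
      k[i] <- k[i] + 1
    }
  }
  as.integer(k)
}

#' Nodes belonging to a named subnetwork
#'
#' @param atlas An [atlas_spec()].
#' @param name Subnetwork name (e.g. `"cerebellum"`).
#' @return Integer vector of node indices.
#' @export
subnetwork_nodes <- function(atlas, name) {
  stopifnot(inherits(atlas, "atlas_spec"))
  id <- match(name, atlas$subnetwork_names)
  if (is.na(id)) stop("unknown subnetwork: ", name, call. = FALSE)
  which(atlas$subnetwork_of == id)
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("atlas_spec: %d nodes in %d subnetworks\n",
              x$n_nodes, length(x$subnetwork_names)))
  print(stats::setNames(tabulate(x$subnetwork_of), x$subnetwork_names))
  invisible(x)
}
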