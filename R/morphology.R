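# Spine-head volume estimation from labelled projection images and
# dendritic path distances on skeleton graphs.

#' Labelled projection image
#'
#' Container for a 2D intensity projection plus an integer label mask and a
#' table mapping labels to ROIs (spines, one dendrite ROI, one background
#' ROI). Masks must be disjoint by construction (a pixel has one label).
#'
#' @param intensity Numeric matrix.
#' @param labels Integer matrix of the same dimension; 0 = unlabelled.
#' @param roles Tibble with columns `label`, `roi_id`, `roi_kind`
#'   (`"spine"`, `"dendrite"` or `"background"`).
#' @param pixel_size Micrometres per pixel.
#' @return A list of class `roi_image`.
#' @export
roi_image <- function(intensity, labels, roles, pixel_size = 0.1) {
  if (!all(dim(intensity) == dim(labels))) {
    abort("`intensity` and `labels` must have the same dimensions.")
  }
  if (!all(c("label", "roi_id", "roi_kind") %in% names(roles))) {
    abort("`roles` needs columns label, roi_id, roi_kind.")
  }
  if (!any(labels %in% roles$label[roles$roi_kind == "background"])) {
    abort("background ROI is empty.")
  }
  structure(list(intensity = intensity, labels = labels, roles = roles,
                 pixel_size = pixel_size),
            class = "roi_image")
}

mask_of <- function(image, kind = NULL, roi_id = NULL) {
  roles <- image$roles
  if (!is.null(roi_id)) roles <- roles[roles$roi_id == roi_id, , drop = FALSE]
  if (!is.null(kind)) roles <- roles[roles$roi_kind == kind, , drop = FALSE]
  image$labels %in% roles$label
}

#' Estimate spine head volume from a labelled projection image
#'
#' All pixels of the spine ROI brighter than the mean background
#' fluorescence are summed; the sum is divided by the mean of the same
#' number of brightest pixels of the dendrite ROI, which serves as a
#' thick-structure fluorescence reference. The result is a unit-free ratio
#' (pixel-equivalents of dendrite brightness) proportional to spine head
#' volume, and invariant to global brightness scaling.
#'
#' @param image A [roi_image()].
#' @param spine_id ROI id of the spine (default: the only spine ROI).
#' @return One-row tibble: `spine_id`, `volume`, `n_suprathreshold_pixels`.
#' @export
estimate_volume <- function(image, spine_id = NULL) {
  stopifnot(inherits(image, "roi_image"))
  spine_ids <- image$roles$roi_id[image$roles$roi_kind == "spine"]
  spine_id <- spine_id %||% {
    if (length(spine_ids) != 1L) abort("specify `spine_id`: image has several spine ROIs")
    spine_ids
  }
  spine_px <- image$intensity[mask_of(image, "spine", spine_id)]
  dend_px <- image$intensity[mask_of(image, "dendrite")]
  bg_px <- image$intensity[mask_of(image, "background")]
  if (length(spine_px) == 0L) abort("spine ROI is empty")
  if (length(dend_px) == 0L) abort("dendrite ROI is empty")
  bright <- spine_px[spine_px > mean(bg_px)]
  n <- length(bright)
  if (n == 0L) {
    warn(sprintf("spine %s: no pixel exceeds the background mean; volume 0", spine_id))
    return(tibble::tibble(spine_id = spine_id, volume = 0,
                          n_suprathreshold_pixels = 0L))
  }
  ref <- mean(sort(dend_px, decreasing = TRUE)[seq_len(min(n, length(dend_px)))])
  tibble::tibble(spine_id = spine_id, volume = sum(bright) / ref,
                 n_suprathreshold_pixels = n)
}

# Gaussian blur by FFT-based circular convolution with a centred,
# normalised Gaussian kernel.
gaussian_blur <- function(img, sigma) {
  conv2_fft(img, gaussian_psf(dim(img), sigma))
}

gaussian_psf <- function(dims, sigma) {
  r <- (seq_len(dims[1]) - 1 + dims[1] / 2) %% dims[1] - dims[1] / 2
  c <- (seq_len(dims[2]) - 1 + dims[2] / 2) %% dims[2] - dims[2] / 2
  k <- exp(-outer(r^2, c^2, "+") / (2 * sigma^2))
  k / sum(k)
}

conv2_fft <- function(img, psf_centred_at_origin) {
  Re(fft(fft(img) * fft(psf_centred_at_origin), inverse = TRUE)) / length(img)
}

#' Richardson-Lucy deconvolution of a projection image
#'
#' Iterative maximum-likelihood deconvolution with a Gaussian PSF. This is
#' an optional, pluggable pre-step before volume estimation:
#' `iterations = 0` returns the image unchanged. Non-positive pixels are
#' floored at a small epsilon; total intensity is conserved by the
#' multiplicative updates.
#'
#' @param image Numeric matrix (or [roi_image()], whose intensity is
#'   deconvolved in place).
#' @param psf_sigma Gaussian PSF sigma in pixels (> 0).
#' @param iterations Number of RL iterations (>= 0).
#' @return Same type as `image`.
#' @export
deconvolve_projection <- function(image, psf_sigma = 1.5, iterations = 10L) {
  check_number(psf_sigma, "psf_sigma", lower = 1e-9)
  check_number(iterations, "iterations", lower = 0, integer = TRUE)
  if (inherits(image, "roi_image")) {
    image$intensity <- deconvolve_projection(image$intensity, psf_sigma, iterations)
    return(image)
  }
  if (iterations == 0L) return(image)
  eps <- 1e-12
  data <- pmax(image, eps)
  psf <- gaussian_psf(dim(image), psf_sigma)
  est <- data
  for (i in seq_len(iterations)) {
    blur <- pmax(conv2_fft(est, psf), eps)
    est <- est * conv2_fft(data / blur, psf) # Gaussian PSF is symmetric
  }
  est
}

#' Dendrite skeleton graph
#'
#' Weighted undirected graph of dendrite geometry: nodes with 2D
#' coordinates in micrometres, edges with positive lengths, and a table
#' attaching spine ids to nodes. Each dendrite's subgraph must be
#' connected.
#'
#' @param nodes Tibble `node`, `x`, `y` (and optionally `dendrite_id`).
#' @param edges Tibble `node_a`, `node_b`, `length_um` (> 0).
#' @param attachments Tibble `spine_id`, `node`.
#' @return A list of class `dendrite_skeleton`.
#' @export
dendrite_skeleton <- function(nodes, edges, attachments = NULL) {
  stopifnot(all(c("node", "x", "y") %in% names(nodes)),
            all(c("node_a", "node_b", "length_um") %in% names(edges)))
  if (any(edges$length_um <= 0)) abort("edge lengths must be positive.")
  if (!all(c(edges$node_a, edges$node_b) %in% nodes$node)) {
    abort("edges refer to unknown nodes.")
  }
  attachments <- attachments %||% tibble::tibble(spine_id = character(), node = integer())
  if (!all(attachments$node %in% nodes$node)) {
    abort("attachment nodes must exist in the skeleton.")
  }
  structure(list(nodes = nodes, edges = edges, attachments = attachments),
            class = "dendrite_skeleton")
}

skeleton_graph <- function(skeleton) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(skeleton$edges$node_a),
                   to = as.character(skeleton$edges$node_b),
                   weight = skeleton$edges$length_um),
    directed = FALSE,
    vertices = data.frame(name = as.character(skeleton$nodes$node)))
}

#' Project a spine mass centre onto the nearest skeleton node
#'
#' Nearest node by Euclidean distance in the projection plane; ties are
#' broken towards the lowest node id.
#'
#' @param centre Numeric `c(x, y)` in micrometres.
#' @param skeleton A [dendrite_skeleton()].
#' @return The node id.
#' @export
project_spine_to_skeleton <- function(centre, skeleton) {
  stopifnot(inherits(skeleton, "dendrite_skeleton"), length(centre) == 2L)
  nd <- skeleton$nodes[order(skeleton$nodes$node), , drop = FALSE]
  d2 <- (nd$x - centre[1])^2 + (nd$y - centre[2])^2
  nd$node[which.min(d2)] # which.min takes the first of tied minima
}

#' Dendritic path distance between two spines
#'
#' Shortest-path length (micrometres) along the weighted skeleton between
#' the attachment nodes of two spines, computed with Dijkstra's algorithm.
#'
#' @param skeleton A [dendrite_skeleton()] with both spines attached.
#' @param spine_a,spine_b Spine ids.
#' @return Distance in micrometres; 0 for a shared attachment node.
#' @export
path_distance <- function(skeleton, spine_a, spine_b) {
  att <- skeleton$attachments
  na <- att$node[match(spine_a, att$spine_id)]
  nb <- att$node[match(spine_b, att$spine_id)]
  if (is.na(na) || is.na(nb)) abort("both spines must be attached to the skeleton.")
  if (na == nb) return(0)
  g <- skeleton_graph(skeleton)
  d <- igraph::distances(g, v = as.character(na), to = as.character(nb),
                         algorithm = "dijkstra")[1, 1]
  if (!is.finite(d)) {
    abort(sprintf("spines %s and %s lie in disconnected skeleton components",
                  spine_a, spine_b))
  }
  unname(d)
}

#' All-to-all dendritic path distances between attached spines
#'
#' @param skeleton A [dendrite_skeleton()].
#' @param spine_ids Optional subset of spine ids.
#' @return A symmetric matrix of distances in micrometres (`Inf` between
#'   disconnected components), with zero diagonal.
#' @export
spine_path_distances <- function(skeleton, spine_ids = NULL) {
  att <- skeleton$attachments
  if (!is.null(spine_ids)) att <- att[att$spine_id %in% spine_ids, , drop = FALSE]
  if (nrow(att) < 2L) abort("need at least two attached spines")
  g <- skeleton_graph(skeleton)
  nodes <- unique(att$node) # several spines may share an attachment node
  dn <- igraph::distances(g, v = as.character(nodes),
                          to = as.character(nodes), algorithm = "dijkstra")
  idx <- match(att$node, nodes)
  d <- dn[idx, idx, drop = FALSE]
  dimnames(d) <- list(att$spine_id, att$spine_id)
  d
}

#' Summarise pairwise spine distances by group
#'
#' Computes, for each group of spines (e.g. responsive vs unresponsive, or
#' the longitudinal categories), the median within-group dendritic path
#' distance, and a two-sided permutation p-value against the null that
#' group labels are interchangeable (labels shuffled wholesale,
#' within-group median recomputed per shuffle).
#'
#' @param distances Symmetric distance matrix from
#'   [spine_path_distances()].
#' @param groups Factor/character vector of group labels aligned with the
#'   matrix rows.
#' @param n_shuffles,seed Permutation parameters.
#' @return Tibble: `group`, `n`, `median_within_um`, `median_overall_um`,
#'   `p_value` (`NA` for singleton groups, which are flagged with a
#'   warning).
#' @export
pairwise_distance_summary <- function(distances, groups, n_shuffles = 1000L,
                                      seed = 1L) {
  stopifnot(nrow(distances) == length(groups))
  finite_pairs <- function(d) d[upper.tri(d) & is.finite(d)]
  med_within <- function(lab, g) {
    idx <- which(g == lab)
    if (length(idx) < 2L) return(NA_real_)
    median(finite_pairs(distances[idx, idx, drop = FALSE]))
  }
  labs <- unique(as.character(groups))
  overall <- median(finite_pairs(distances))
  obs <- vapply(labs, med_within, numeric(1), g = groups)
  if (any(is.na(obs))) warn("singleton group(s): no within-group distance")
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      gs <- sample(groups)
      vapply(labs, med_within, numeric(1), g = gs)
    }, numeric(length(labs)))
  })
  null <- matrix(null, nrow = length(labs))
  p <- vapply(seq_along(labs), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    centred_obs <- abs(obs[i] - overall)
    centred_null <- abs(null[i, ] - overall)
    (1 + sum(centred_null >= centred_obs)) / (1 + n_shuffles)
  }, numeric(1))
  tibble::tibble(group = labs,
                 n = vapply(labs, function(l) sum(groups == l), integer(1)),
                 median_within_um = unname(obs),
                 median_overall_um = overall,
                 p_value = p)
}
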