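# Shared fixtures, all built in code.

# A small, fast experiment configuration for pipeline tests.
small_config <- function(...) {
  defaults <- list(n_spines = 6, n_sessions = 2, n_trials_per_session = 12,
                   generate_images = FALSE, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(experiment_config, args)
}

# Hand-built truth table for the survival-sequence rules over 5 sessions:
# persistent = all present; formed = leading absences then present to the
# end; eliminated = present from the start then absent to the end;
# everything else transient. Written out explicitly, independent of the
# implementation.
survival_truth_table <- function() {
  seqs <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  seqs <- seqs[rowSums(seqs) > 0, ]
  truth <- apply(seqs, 1, function(p) {
    runs <- paste(as.integer(p), collapse = "")
    if (runs == "11111") return("persistent")
    if (runs %in% c("01111", "00111", "00011", "00001")) return("formed")
    if (runs %in% c("10000", "11000", "11100", "11110")) return("eliminated")
    "transient"
  })
  list(sequences = as.matrix(seqs), truth = unname(truth))
}

# Random weighted tree with n nodes (edges parent-child, random weights).
random_tree <- function(n, seed) {
  with_seed_local(seed, {
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    tibble::tibble(node_a = parent[-1L], node_b = 2:n,
                   length_um = round(runif(n - 1L, 0.5, 5), 3))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Brute-force path length between two nodes of a tree by depth-first
# search — the independent oracle for Dijkstra distances.
dfs_tree_distance <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$node_a[i]); b <- as.character(edges$node_b[i])
    adj[[a]] <- rbind(adj[[a]], c(edges$node_b[i], edges$length_um[i]))
    adj[[b]] <- rbind(adj[[b]], c(edges$node_a[i], edges$length_um[i]))
  }
  from <- as.numeric(from); to <- as.numeric(to)
  found <- NULL
  walk <- function(node, prev, acc) {
    if (node == to) { found <<- acc; return() }
    nb <- adj[[as.character(node)]]
    if (is.null(nb)) return()
    for (j in seq_len(nrow(nb))) {
      if (!identical(nb[j, 1], prev)) walk(nb[j, 1], node, acc + nb[j, 2])
    }
  }
  walk(from, NA_real_, 0)
  found
}

# Skeleton with unit geometry from a tree edge table.
tree_skeleton <- function(edges, attachments = NULL, seed = 1) {
  n <- max(edges$node_a, edges$node_b)
  nodes <- with_seed_local(seed, tibble::tibble(node = seq_len(n),
                                                x = runif(n, 0, 50),
                                                y = runif(n, 0, 50)))
  dendrite_skeleton(nodes, edges, attachments)
}

# 10 x 10 labelled image with known pixel values for volume arithmetic.
toy_volume_image <- function(spine_value = 2, background_value = 1,
                             dendrite_value = 2) {
  intensity <- matrix(background_value, 10, 10)
  labels <- matrix(0L, 10, 10)
  labels[1:2, 1:5] <- 1L                      # spine ROI, 10 px
  intensity[1:2, 1:5] <- spine_value
  labels[9:10, 1:5] <- 2L                     # dendrite ROI, 10 px
  intensity[9:10, 1:5] <- dendrite_value
  labels[5:6, 6:10] <- 3L                     # background ROI, 10 px
  intensity[5:6, 6:10] <- background_value
  roi_image(intensity, labels,
            roles = tibble::tibble(label = 1:3,
                                   roi_id = c("spine_001", "dendrite_01", "background"),
                                   roi_kind = c("spine", "dendrite", "background")))
}
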