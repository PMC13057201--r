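test_that("volume arithmetic follows the brightest-dendrite-reference rule", {
  img <- toy_volume_image(spine_value = 2, background_value = 1, dendrite_value = 2)
  v <- estimate_volume(img)
  expect_equal(v$n_suprathreshold_pixels, 10L)
  expect_equal(v$volume, 10)  # sum 20 over mean-of-10-brightest 2

  dim_spine <- toy_volume_image(spine_value = 0.5)
  expect_warning(v0 <- estimate_volume(dim_spine), "volume 0")
  expect_equal(v0$volume, 0)

  scaled <- img
  scaled$intensity <- img$intensity * 11
  expect_equal(estimate_volume(scaled)$volume, v$volume)
})

test_that("deconvolution is optional, flux-conserving and sharpening", {
  img <- matrix(0, 32, 32); img[16, 16] <- 100
  blurred <- spinedyn:::gaussian_blur(img, 2) + 1
  expect_identical(deconvolve_projection(blurred, 2, iterations = 0), blurred)

  peaks <- vapply(c(2, 5, 10, 20), function(it)
    max(deconvolve_projection(blurred, 2, iterations = it)), numeric(1))
  expect_true(all(diff(peaks) > 0))  # point source sharpens with iterations

  dec <- deconvolve_projection(blurred, 2, iterations = 10)
  expect_lt(abs(sum(dec) - sum(blurred)) / sum(blurred), 0.01)
})

test_that("spine projection picks the nearest node with low-id tie-breaks", {
  nodes <- tibble::tibble(node = c(3L, 1L, 2L), x = c(0, 10, 20), y = c(0, 0, 0))
  edges <- tibble::tibble(node_a = c(3L, 1L), node_b = c(1L, 2L), length_um = c(10, 10))
  sk <- dendrite_skeleton(nodes, edges)
  expect_equal(project_spine_to_skeleton(c(10, 0), sk), 1L)
  expect_equal(project_spine_to_skeleton(c(15, 0), sk), 1L)  # tie 1 vs 2 -> lower id

  big <- tree_skeleton(random_tree(10, 3), seed = 4)
  for (i in 1:20) {
    p <- with_seed_local(100 + i, runif(2, 0, 50))
    d2 <- (big$nodes$x - p[1])^2 + (big$nodes$y - p[2])^2
    brute <- min(big$nodes$node[d2 == min(d2)])
    expect_equal(project_spine_to_skeleton(p, big), brute)
  }
})

test_that("path distances are exact on chains and satisfy metric identities", {
  nodes <- tibble::tibble(node = 1:3, x = c(0, 2, 5), y = c(0, 0, 0))
  edges <- tibble::tibble(node_a = c(1L, 2L), node_b = c(2L, 3L), length_um = c(2, 3))
  att <- tibble::tibble(spine_id = c("a", "b", "c"), node = 1:3)
  sk <- dendrite_skeleton(nodes, edges, att)
  expect_equal(path_distance(sk, "a", "c"), 5)
  expect_equal(path_distance(sk, "a", "c"), path_distance(sk, "c", "a"))
  expect_equal(path_distance(sk, "a", "b") + path_distance(sk, "b", "c"),
               path_distance(sk, "a", "c"))
  att_same <- tibble::tibble(spine_id = c("a", "b"), node = c(2L, 2L))
  expect_equal(path_distance(dendrite_skeleton(nodes, edges, att_same), "a", "b"), 0)

  disc_nodes <- tibble::tibble(node = 1:4, x = c(0, 1, 10, 11), y = 0)
  disc_edges <- tibble::tibble(node_a = c(1L, 3L), node_b = c(2L, 4L), length_um = c(1, 1))
  disc <- dendrite_skeleton(disc_nodes, disc_edges,
                            tibble::tibble(spine_id = c("a", "b"), node = c(1L, 3L)))
  expect_error(path_distance(disc, "a", "b"), "disconnected")
})

test_that("grouped distance summaries are symmetric in identical groups", {
  sk <- tree_skeleton(random_tree(9, 5),
                      tibble::tibble(spine_id = sprintf("s%d", 1:6),
                                     node = c(1L, 2L, 3L, 1L, 2L, 3L)), seed = 6)
  d <- spine_path_distances(sk)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  groups <- c("g1", "g1", "g1", "g2", "g2", "g2")  # identical attachment sets
  s <- pairwise_distance_summary(d, groups, n_shuffles = 200, seed = 1)
  expect_equal(s$median_within_um[1], s$median_within_um[2])
  expect_warning(pairwise_distance_summary(d, c("a", rep("b", 5)),
                                           n_shuffles = 50, seed = 1),
                 "singleton")
})
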