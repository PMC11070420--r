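test_that("vessel graph generation is deterministic and respects the disc radius", {
  p <- small_params(seed = 42)
  g1 <- generate_vessel_graph(p)
  g2 <- generate_vessel_graph(p)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)

  d <- as.matrix(dist(g1$nodes))
  diag(d) <- Inf
  expect_gte(min(d), p$mean_capillary_spacing_px)
  expect_true(all(g1$nodes >= 1 & g1$nodes <= p$image_size))
  expect_true(all(g1$edges >= 1 & g1$edges <= nrow(g1$nodes)))
  expect_true(graph_connected(g1))
})

test_that("node count at spacing image_size/4 sits in the packing band", {
  for (s in 1:5) {
    g <- generate_vessel_graph(
      synth_params(image_size = 128, mean_capillary_spacing_px = 32, seed = s))
    expect_gte(nrow(g$nodes), 4)
    expect_lte(nrow(g$nodes), 30)
  }
})

test_that("too-small domains raise the degenerate-geometry error", {
  expect_error(
    generate_vessel_graph(
      synth_params(image_size = 8, mean_capillary_spacing_px = 32, seed = 1)),
    "degenerate geometry")
})

test_that("dropout hits the expected edge fraction and is deterministic", {
  p <- small_params(seed = 5)
  g <- generate_vessel_graph(p)
  expect_true(all(apply_dropout(g, 0, seed = 1)$edge_alive))
  expect_false(any(apply_dropout(g, 1, seed = 1)$edge_alive))
  expect_identical(apply_dropout(g, 0.3, seed = 9)$edge_alive,
                   apply_dropout(g, 0.3, seed = 9)$edge_alive)

  # binomial 99% band for the dead-edge count at p = 0.3 over 1000 edges
  big <- generate_vessel_graph(
    synth_params(image_size = 512, mean_capillary_spacing_px = 12, seed = 3))
  idx <- seq_len(1000)
  sub <- big
  sub$edges <- big$edges[idx, ]
  sub$edge_alive <- big$edge_alive[idx]
  dead <- sum(!apply_dropout(sub, 0.3, seed = 17)$edge_alive)
  expect_gte(dead, qbinom(0.005, 1000, 0.3))
  expect_lte(dead, qbinom(0.995, 1000, 0.3))
})

test_that("rendering an empty graph gives a uniform background and empty mask", {
  p <- small_params(seed = 2, noise_level = 0)
  g <- generate_vessel_graph(p)
  g$edge_alive[] <- FALSE
  r <- render_image(g, p)
  expect_equal(length(unique(as.numeric(r$image))), 1)
  expect_false(any(r$mask))
})

test_that("truth mask is exactly the sigma-tube around alive centrelines", {
  p <- synth_params(image_size = 48, mean_capillary_spacing_px = 14,
                    vessel_sigma_px = 1.5, noise_level = 0, seed = 8)
  g <- generate_vessel_graph(p)
  keep <- head(order(g$nodes[g$edges[, 1], 1]), 5)  # any 5 edges
  g$edges <- g$edges[keep, , drop = FALSE]
  g$edge_alive <- rep(TRUE, 5)
  r <- render_image(g, p)

  seg_dist <- function(pr, pc, a, b) {
    v <- b - a; t <- sum((c(pr, pc) - a) * v) / sum(v^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((c(pr, pc) - (a + t * v))^2))
  }
  for (i in seq_len(48)) for (j in seq_len(48)) {
    dmin <- min(vapply(seq_len(5), function(e) {
      seg_dist(i, j, g$nodes[g$edges[e, 1], ], g$nodes[g$edges[e, 2], ])
    }, numeric(1)))
    expect_identical(r$mask[i, j], dmin <= p$vessel_sigma_px)
  }
})

test_that("truth-mask vessel density falls as dropout rises (in expectation)", {
  mean_vd <- vapply(c(0, 0.2, 0.4), function(dp) {
    mean(vapply(1:10, function(s) {
      p <- small_params(seed = s, noise_level = 0)
      g <- apply_dropout(generate_vessel_graph(p), dp, seed = s + 100)
      mean(render_image(g, p)$mask)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_vd) < 0))
})

test_that("cohort generation writes a deterministic, well-formed manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  pc <- small_params(seed = 0)
  pg <- small_params(seed = 0, dropout_prob = 0.35)
  man <- generate_cohort(10, 10, pc, pg, seed = 3, out_dir = dir1)
  expect_equal(nrow(man), 20)
  expect_equal(sum(man$label == "control"), 10)
  expect_equal(sum(man$label == "glaucoma"), 10)
  expect_false(anyDuplicated(man$image_id) > 0)
  expect_gte(sum(table(man$patient_id) == 2), 2)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))

  generate_cohort(10, 10, pc, pg, seed = 3, out_dir = dir2)
  m1 <- readBin(file.path(dir1, "manifest.csv"), "raw", 1e6)
  m2 <- readBin(file.path(dir2, "manifest.csv"), "raw", 1e6)
  # identical up to the differing directory prefix embedded in paths
  c1 <- gsub(dir1, "DIR", rawToChar(m1), fixed = TRUE)
  c2 <- gsub(dir2, "DIR", rawToChar(m2), fixed = TRUE)
  expect_identical(c1, c2)

  # round-trip through the reader
  rt <- read_manifest(file.path(dir1, "manifest.csv"))
  expect_equal(rt$image_id, man$image_id)

  expect_error(
    generate_cohort(2, 2, pc, pg, seed = 1,
                    out_dir = "/proc/octaperf_unwritable/dir"),
    "cannot create")
})

test_that("perfusion distance on a truth mask is zero exactly on vessels", {
  p <- small_params(seed = 13, noise_level = 0)
  r <- render_image(generate_vessel_graph(p), p)
  pdm <- perfusion_distance_map(r$mask)
  expect_true(all(pdm[r$mask] == 0))
  expect_true(all(pdm[!r$mask] > 0))
})

test_that("mean deficit area grows with dropout severity (in expectation)", {
  mean_pda <- vapply(c(0, 0.3), function(dp) {
    mean(vapply(1:10, function(s) {
      p <- small_params(seed = s, noise_level = 0)
      g <- apply_dropout(generate_vessel_graph(p), dp, seed = s + 50)
      pdm <- perfusion_distance_map(render_image(g, p)$mask)
      rs <- perfusion_deficit_areas(pdm, 30 / 5.7)
      if (n_regions(rs) == 0) 0 else mean(rs$areas)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_pda[2], mean_pda[1])
})
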