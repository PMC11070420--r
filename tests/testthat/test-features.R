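test_that("vessel density matches a naive pixel count", {
  expect_equal(vessel_density(matrix(TRUE, 4, 4)), 1.0)
  m <- matrix(FALSE, 4, 4); m[1, 1:4] <- TRUE
  expect_equal(vessel_density(m), 0.25)
  rnd <- random_mask(3)
  count <- 0
  for (i in seq_len(nrow(rnd))) for (j in seq_len(ncol(rnd)))
    count <- count + as.integer(rnd[i, j])
  expect_equal(vessel_density(rnd), count / length(rnd))
})

test_that("intercapillary areas partition the non-vessel pixels", {
  cross <- fixture_cross()
  for (conn in c(4, 8)) {
    rs <- intercapillary_areas(cross, conn)
    expect_equal(n_regions(rs), 4)
    expect_true(all(rs$areas == 4))
  }
  expect_equal(n_regions(intercapillary_areas(matrix(TRUE, 3, 3))), 0)
  rnd <- random_mask(9)
  rs <- intercapillary_areas(rnd)
  expect_equal(sum(rs$areas) + sum(rnd), length(rnd))
  expect_message(intercapillary_areas(matrix(FALSE, 4, 4)), "no vessel")
})

test_that("perfusion distance map matches closed forms and the brute-force oracle", {
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  pdm <- perfusion_distance_map(m)
  expect_equal(pdm[2, 2], 0)
  expect_equal(pdm[1, 2], 1)
  expect_equal(pdm[1, 1], sqrt(2))

  expect_true(all(perfusion_distance_map(matrix(TRUE, 5, 5)) == 0))
  expect_error(perfusion_distance_map(matrix(FALSE, 5, 5)), "no vessel")

  for (s in 1:5) {
    rnd <- random_mask(s)
    expect_lt(max(abs(perfusion_distance_map(rnd) - bf_edt(rnd))), 1e-9)
  }
})

test_that("adding vessel pixels never increases any distance", {
  for (s in 1:5) {
    m <- random_mask(s + 20, p = 0.1)
    pdm1 <- perfusion_distance_map(m)
    m2 <- m
    set.seed(s)
    add <- sample(which(!m), 10)
    m2[add] <- TRUE
    pdm2 <- perfusion_distance_map(m2)
    expect_true(all(pdm2 <= pdm1 + 1e-12))
  }
})

test_that("distribution features match direct moment computation", {
  f <- distribution_features(c(1, 2, 3, 4))
  expect_equal(f$maximum, 4)
  expect_equal(f$mean, 2.5)
  expect_equal(f$standard_deviation, sqrt(1.25), tolerance = 1e-12)
  expect_equal(f$kurtosis, -1.36)

  o <- bf_moments(c(10, 20, 30, 100))
  g <- distribution_features(c(10, 20, 30, 100))
  expect_equal(as.numeric(g[1, ]), unname(o))

  expect_warning(f1 <- distribution_features(49), "single value")
  expect_equal(as.numeric(f1[1, ]), c(49, 49, 0, 0))
  expect_warning(f0 <- distribution_features(numeric(0)), "no values")
  expect_equal(as.numeric(f0[1, ]), c(0, 0, 0, 0))
  # constant values: zero variance handled by convention
  fc <- distribution_features(c(4, 4, 4, 4))
  expect_equal(as.numeric(fc[1, ]), c(4, 4, 0, 0))
})

test_that("perfusion distance features use non-vessel pixels only", {
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  f <- perfusion_distance_features(perfusion_distance_map(m))
  expect_equal(f$maximum, sqrt(2))
  # oracle over the 8 non-vessel distances
  o <- bf_moments(bf_edt(m)[bf_edt(m) > 0])
  expect_equal(as.numeric(f[1, ]), unname(o), tolerance = 1e-12)
  expect_warning(perfusion_distance_features(perfusion_distance_map(
    matrix(TRUE, 4, 4))), "no non-vessel")
})

test_that("deficit areas use a strict threshold and match the ring closed form", {
  ring <- fixture_ring(11)
  pdm <- perfusion_distance_map(ring)
  rs <- perfusion_deficit_areas(pdm, 2)
  expect_equal(n_regions(rs), 1)
  expect_equal(rs$areas, 49L)
  # brute-force confirmation of the 7x7 interior
  bf <- bf_edt(ring)
  expect_equal(sum(bf > 2), 49)

  expect_equal(n_regions(perfusion_deficit_areas(pdm, max(pdm))), 0)
})

test_that("deficit areas at threshold zero reproduce the intercapillary partition", {
  for (s in 1:5) {
    m <- random_mask(s + 40)
    pdm <- perfusion_distance_map(m)
    for (conn in c(4, 8)) {
      a <- perfusion_deficit_areas(pdm, 0, conn)
      b <- intercapillary_areas(m, conn)
      expect_identical(partition_signature(a$labels),
                       partition_signature(b$labels))
    }
  }
})

test_that("GPDP identities and bounds hold", {
  m <- random_mask(50)
  pdm <- perfusion_distance_map(m)
  expect_equal(gpdp(pdm, 0), 1 - vessel_density(m))
  expect_equal(gpdp(perfusion_distance_map(matrix(TRUE, 6, 6)), 3), 0)
  rs <- perfusion_deficit_areas(pdm, 1.5)
  expect_equal(gpdp(pdm, 1.5), sum(rs$areas) / length(m))
  # restricted reference area
  ref <- matrix(FALSE, nrow(m), ncol(m)); ref[1:16, ] <- TRUE
  expect_equal(gpdp(pdm, 1.5, ref), mean(pdm[ref] > 1.5))
  expect_error(gpdp(pdm, 1, matrix(FALSE, nrow(m), ncol(m))), "empty")
})

test_that("GPDP and total deficit area are non-increasing in the threshold", {
  thresholds <- c(0, 1, 2, 4, 8)
  for (s in 1:5) {
    m <- random_mask(s + 60, p = 0.1)
    pdm <- perfusion_distance_map(m)
    gp <- vapply(thresholds, function(t) gpdp(pdm, t), numeric(1))
    tot <- vapply(thresholds, function(t)
      sum(perfusion_deficit_areas(pdm, t)$areas), numeric(1))
    cnt <- vapply(thresholds, function(t)
      n_regions(perfusion_deficit_areas(pdm, t)), numeric(1))
    expect_true(all(diff(gp) <= 0))
    expect_true(all(diff(tot) <= 0))
    expect_true(all(cnt >= 0))
  }
})

test_that("extract_features emits five records with method-specific lengths", {
  m <- random_mask(70, nr = 64, p = 0.2)
  feats <- extract_features(m, image_id = "img1", patient_id = "P1",
                            label = "control")
  lens <- table(feats$method)
  expect_equal(unname(lens[c("VD", "GPDP", "IA", "PD", "PDA")]),
               as.integer(c(1, 1, 4, 4, 4)), ignore_attr = TRUE)

  # composition identity: records equal the individual operations
  pdm <- perfusion_distance_map(m)
  thr <- 30 / 5.7
  expect_equal(feats$value[feats$method == "VD"], vessel_density(m))
  expect_equal(feats$value[feats$method == "GPDP"], gpdp(pdm, thr))
  expect_equal(feats$value[feats$method == "IA"],
               as.numeric(pda_distribution_features(
                 intercapillary_areas(m, 8))[1, ]))
  expect_equal(feats$value[feats$method == "PD"],
               as.numeric(perfusion_distance_features(pdm)[1, ]))
  expect_equal(feats$value[feats$method == "PDA"],
               as.numeric(pda_distribution_features(
                 perfusion_deficit_areas(pdm, thr, 8))[1, ]))

  expect_warning(all_vessel <- extract_features(matrix(TRUE, 8, 8)),
                 "all-vessel")
  expect_equal(all_vessel$value[all_vessel$method == "VD"], 1)
  expect_equal(all_vessel$value[all_vessel$method == "GPDP"], 0)
  expect_true(all(all_vessel$value[all_vessel$method %in%
                                     c("IA", "PD", "PDA")] == 0))
})

test_that("border-region exclusion drops only border-touching regions", {
  m <- fixture_cross()  # all four corner regions touch the border
  rs <- intercapillary_areas(m, 8, exclude_border = TRUE)
  expect_equal(n_regions(rs), 0)
  ring <- fixture_ring(5)
  expect_equal(n_regions(intercapillary_areas(ring, 8,
                                              exclude_border = TRUE)), 1)
})

test_that("a small segmentation gap merges areas but barely moves distances", {
  intact <- fixture_two_chamber()
  broken <- fixture_two_chamber(gap = TRUE)

  max_ia_intact <- max(intercapillary_areas(intact)$areas)
  max_ia_broken <- max(intercapillary_areas(broken)$areas)
  rel_area_change <- abs(max_ia_broken - max_ia_intact) / max_ia_intact
  expect_gte(rel_area_change, 0.9)

  pd_intact <- mean(perfusion_distance_map(intact))
  pd_broken <- mean(perfusion_distance_map(broken))
  rel_pd_change <- abs(pd_broken - pd_intact) / pd_intact
  expect_lt(rel_pd_change, 0.1)
})

test_that("region sets tidy into per-region area tables", {
  rs <- intercapillary_areas(fixture_cross())
  td <- tidy(rs, pixel_pitch_um = 5.7)
  expect_equal(nrow(td), 4)
  expect_equal(td$area_px, rep(4L, 4))
  expect_equal(td$area_um2, rep(4 * 5.7^2, 4))
})
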