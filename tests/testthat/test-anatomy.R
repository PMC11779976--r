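# Ex vivo morphometry on tube phantoms: thresholding quality, skeleton
# length and branch counting, distance-map radii, densities and the
# pericyte constriction profile.

test_that("thresholding separates a two-level phantom with IoU >= 0.9", {
  g <- tube_phantom(radius = 3, length_um = 120, noise_sd = 5, seed = 2)
  th <- threshold_stack(g$stack)
  truth <- g$true_mask
  iou <- sum(th$mask & truth) / sum(th$mask | truth)
  expect_gte(iou, 0.9)
  expect_true(th$method %in% c("Default", "Huang", "Huang2", "Li"))
  # deterministic for fixed input
  th2 <- threshold_stack(g$stack)
  expect_identical(th$mask, th2$mask)
  expect_identical(th$method, th2$method)
})

test_that("straight tube: length within 5%, radius within one voxel, no branches", {
  g <- tube_phantom(radius = 3, length_um = 150)
  th <- threshold_stack(g$stack)
  sk <- skeleton_3d(th$mask, g$stack$voxel_size)
  expect_equal(sk$total_length_um, 150, tolerance = 0.05)
  expect_equal(sk$n_branch_clusters, 0)
  r <- radii_from_distance_map(th$mask, sk, g$stack$voxel_size)
  expect_true(all(abs(r - 3) <= max(g$stack$voxel_size)))
  # radius halves when the phantom radius halves (up to voxel quantisation)
  g2 <- gen_anatomy_stack(list(list(p0 = c(5, 20, 15), p1 = c(105, 20, 15),
                                    radius = 1.5)),
                          voxel_size = c(0.5, 0.5, 0.5), noise_sd = 5, seed = 2)
  th2 <- threshold_stack(g2$stack)
  sk2 <- skeleton_3d(th2$mask, g2$stack$voxel_size)
  r2 <- radii_from_distance_map(th2$mask, sk2, g2$stack$voxel_size)
  expect_equal(median(r2) / median(r), 0.5, tolerance = 0.2)
})

test_that("a Y junction yields exactly one branch cluster", {
  gy <- gen_anatomy_stack(list(list(p0 = c(5, 30, 15), p1 = c(60, 30, 15), radius = 3),
                               list(p0 = c(60, 30, 15), p1 = c(110, 60, 15), radius = 3),
                               list(p0 = c(60, 30, 15), p1 = c(110, 5, 15), radius = 3)),
                          voxel_size = c(1, 1, 1), noise_sd = 5, seed = 1)
  th <- threshold_stack(gy$stack)
  sk <- skeleton_3d(th$mask, c(1, 1, 1))
  expect_equal(sk$n_branch_clusters, 1)
  expect_equal(sum(sk$degree == 1), 3)       # three free ends
  expect_equal(sk$total_length_um, gy$truth$true_network_length, tolerance = 0.05)
})

test_that("skeleton length is invariant to translation and 45-degree rotation", {
  mk <- function(p0, p1) {
    g <- gen_anatomy_stack(list(list(p0 = p0, p1 = p1, radius = 3)),
                           voxel_size = c(1, 1, 1), noise_sd = 0, seed = 1)
    skeleton_3d(threshold_stack(g$stack)$mask, c(1, 1, 1))$total_length_um
  }
  base <- mk(c(5, 20, 15), c(105, 20, 15))
  shifted <- mk(c(12, 27, 18), c(112, 27, 18))
  diag45 <- mk(c(5, 5, 15), c(5 + 100 / sqrt(2), 5 + 100 / sqrt(2), 15))
  expect_equal(base, shifted, tolerance = 0.02)
  expect_equal(diag45 / base, 1, tolerance = 0.05)
})

test_that("vessel density arithmetic and the <7 um diameter filter", {
  expect_equal(vessel_density(500, volume_mm3 = 0.001), 500)  # 0.5 mm / 0.001 mm^3
  # two tubes: 4 um and 10 um diameter; only the capillary passes the filter
  g <- gen_anatomy_stack(list(list(p0 = c(5, 10, 12), p1 = c(105, 10, 12), radius = 2),
                              list(p0 = c(5, 40, 12), p1 = c(105, 40, 12), radius = 5)),
                         voxel_size = c(0.5, 0.5, 1), noise_sd = 0, seed = 1)
  th <- threshold_stack(g$stack)
  sk <- skeleton_3d(th$mask, g$stack$voxel_size)
  r <- radii_from_distance_map(th$mask, sk, g$stack$voxel_size)
  vol <- g$truth$volume_mm3
  d_all <- vessel_density(sk, vol)
  d_cap <- vessel_density(sk, vol, radii = r, max_diameter_um = 7)
  expect_equal(d_all / 2, d_cap, tolerance = 0.1)   # half the length survives
  expect_gt(d_cap, 0)
  expect_error(vessel_density(sk, 0), "> 0")
})

test_that("pericyte density counts snapped somata; far somata are excluded", {
  g <- gen_anatomy_stack(
    list(list(p0 = c(5, 15, 12), p1 = c(105, 15, 12), radius = 2.5)),
    pericytes = list(list(segment = 1, at = 0.3, constriction = 0.1, extent_um = 8),
                     list(segment = 1, at = 0.7, constriction = 0.1, extent_um = 8)),
    voxel_size = c(1, 1, 1), noise_sd = 0, seed = 1)
  th <- threshold_stack(g$stack)
  sk <- skeleton_3d(th$mask, c(1, 1, 1))
  pd <- pericyte_density(g$pericytes, sk, volume_mm3 = g$truth$volume_mm3)
  expect_equal(pd$n_somata, 2)
  expect_equal(pd$per_mm, 2 / (sk$total_length_um / 1000))
  # a soma 20 um off the vessel is excluded with a warning
  far <- rbind(g$pericytes[, 1:3],
               data.frame(x_um = 50, y_um = 35, z_um = 6))
  expect_warning(pd2 <- pericyte_density(far, sk), "capture")
  expect_equal(pd2$n_somata, 2)
})

test_that("constriction profile dips 20% at the soma and is flat without one", {
  g <- gen_anatomy_stack(
    list(list(p0 = c(5, 15, 12), p1 = c(125, 15, 12), radius = 2.5)),
    pericytes = list(list(segment = 1, at = 0.5, constriction = 0.2, extent_um = 10)),
    voxel_size = c(0.45, 0.45, 1), noise_sd = 0, seed = 1)
  th <- threshold_stack(g$stack)
  sk <- skeleton_3d(th$mask, g$stack$voxel_size)
  r <- radii_from_distance_map(th$mask, sk, g$stack$voxel_size)
  prof <- diameter_vs_soma_distance(sk, r, g$pericytes, bin_width = 2,
                                    max_dist = 40)
  p <- prof$profile[prof$profile$n > 0, ]
  far <- mean(p$mean_diameter_um[abs(p$distance_um) > 25])
  expect_equal(prof$at_soma_um, min(p$mean_diameter_um))  # minimum at bin 0
  expect_equal(prof$at_soma_um / far, 0.8, tolerance = 0.05)

  # without a constriction the profile is flat
  g0 <- gen_anatomy_stack(
    list(list(p0 = c(5, 15, 12), p1 = c(125, 15, 12), radius = 2.5)),
    pericytes = list(list(segment = 1, at = 0.5, constriction = 0, extent_um = 10)),
    voxel_size = c(0.45, 0.45, 1), noise_sd = 0, seed = 1)
  th0 <- threshold_stack(g0$stack)
  sk0 <- skeleton_3d(th0$mask, g0$stack$voxel_size)
  r0 <- radii_from_distance_map(th0$mask, sk0, g0$stack$voxel_size)
  prof0 <- diameter_vs_soma_distance(sk0, r0, g0$pericytes, bin_width = 2,
                                     max_dist = 40)
  p0 <- prof0$profile[prof0$profile$n > 0, ]
  expect_lt(diff(range(p0$mean_diameter_um)), 0.1 * mean(p0$mean_diameter_um))
})

test_that("every reported diameter is twice a distance-map radius; bins non-negative counts", {
  g <- tube_phantom(radius = 3, length_um = 80)
  th <- threshold_stack(g$stack)
  sk <- skeleton_3d(th$mask, g$stack$voxel_size)
  r <- radii_from_distance_map(th$mask, sk, g$stack$voxel_size)
  expect_true(all(r > 0))
  expect_equal(length(r), nrow(sk$points))
})
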