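# shared small reconstruction for the segmentation tests
seg_pair <- small_pair(noise_sd = 0, n_slices = 3L)
seg_vol <- seg_pair$small
seg_phantom <- small_phantom(n_slices = 3L)

test_that("body mask recovers the phantom body and drops detached speckles", {
  vol <- seg_vol
  # add detached above-threshold speckles in the air
  v <- vol$values
  v[5:6, 5:6, 1] <- 500
  v[120:121, 10:11, 2] <- 800
  noisy <- ct_volume(v, vol$geometry, id = "speckled")
  body <- body_mask(noisy)
  truth_body <- ellipse_mask_on(vol$geometry, c(0, 0), c(30, 25))
  expect_gte(dice(body, truth_body), 0.99)
  expect_false(any(body[5:6, 5:6, 1]))
  expect_false(any(body[120:121, 10:11, 2]))
})

test_that("body mask keeps only the largest of two disjoint bodies", {
  v <- array(-1000, c(60, 60, 2))
  v[10:40, 10:40, ] <- 50     # large block
  v[50:55, 50:55, ] <- 50     # small detached block
  vol <- vol_from_array(v)
  body <- body_mask(vol)
  expect_true(all(body[10:40, 10:40, ]))
  expect_false(any(body[50:55, 50:55, ]))
})

test_that("body mask errors on all-air input and is idempotent", {
  expect_error(body_mask(vol_from_array(array(-1000, c(16, 16, 2)))))
  body <- body_mask(seg_vol)
  v <- seg_vol$values
  v[!body] <- -1000
  body2 <- body_mask(ct_volume(v, seg_vol$geometry))
  expect_gte(dice(body, body2), 0.999)
})

test_that("bone mask recovers the phantom bones", {
  body <- body_mask(seg_vol)
  bone <- bone_mask(seg_vol, body)
  truth_bone <- circles_mask_on(seg_vol$geometry, seg_phantom$bones)
  expect_gte(dice(bone, truth_bone), 0.95)
  expect_true(all(bone <= body))  # bone never reaches the air
})

test_that("bone components below min_voxels are dropped", {
  v <- array(-1000, c(60, 60, 1))
  v[10:50, 10:50, 1] <- 40
  v[20:29, 20:29, 1] <- 1200    # 100-voxel bone
  v[40:41, 40:41, 1] <- 1200    # 4-voxel speckle
  vol <- vol_from_array(v)
  body <- body_mask(vol)
  bone <- bone_mask(vol, body, min_voxels = 50L)
  expect_true(all(bone[20:29, 20:29, 1]))
  expect_false(any(bone[40:41, 40:41, 1]))
})

test_that("analysis ROI honours the physical exclusion margin", {
  body <- body_mask(seg_vol)
  bone <- bone_mask(seg_vol, body)
  roi0 <- analysis_roi(body, array(FALSE, dim(body)), seg_vol$geometry, 0)
  expect_identical(roi0, body)

  roi <- analysis_roi(body, bone, seg_vol$geometry, 2)
  expect_true(all(roi <= body))
  # minimum distance from any ROI voxel to any bone voxel >= 2 mm (in-plane)
  dx <- seg_vol$geometry$in_plane_spacing[1]
  for (k in 1:dim(roi)[3]) {
    bidx <- which(bone[, , k], arr.ind = TRUE)
    ridx <- which(roi[, , k], arr.ind = TRUE)
    if (nrow(bidx) == 0 || nrow(ridx) == 0) next
    dmin <- min(sqrt(outer(ridx[, 1], bidx[, 1], `-`)^2 +
                       outer(ridx[, 2], bidx[, 2], `-`)^2)) * dx
    expect_gte(dmin, 2 - 1e-9)
  }

  # monotone: a larger margin never grows the ROI
  roi3 <- analysis_roi(body, bone, seg_vol$geometry, 3)
  expect_true(all(roi3 <= roi))
  expect_error(analysis_roi(body, bone, seg_vol$geometry, -1))
})

test_that("bone-removal quality scores captured high-HU volume fraction", {
  body <- body_mask(seg_vol)
  bone <- bone_mask(seg_vol, body)
  q <- bone_removal_quality(bone, seg_vol, body, vessel_max_voxels = 100L)
  expect_equal(q$score, 1.0, tolerance = 1e-6)
  expect_true(q$eligible)

  # drop the smaller bone circle from the mask: score ~ captured fraction
  xs <- grid_coords(seg_vol$geometry, 1)
  miss <- bone
  sel <- xs > 5   # second bone sits at cx = 12
  miss[sel, , ] <- FALSE
  q2 <- bone_removal_quality(miss, seg_vol, body, vessel_max_voxels = 100L)
  r <- seg_phantom$bones$r
  expect_equal(q2$score, r[1]^2 / sum(r^2), tolerance = 0.05)
  expect_false(q2$eligible)
})
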