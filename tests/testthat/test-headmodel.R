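# MRI import/resampling, fiducial head frame, surface-to-shape, sphere fits.

test_that("anisotropic MRI is resampled isotropic within 256^3", {
  arr <- array(0, c(40, 50, 20))
  arr[15:25, 20:30, 8:12] <- 100
  img <- RNifti::asNifti(arr)
  aff <- rbind(cbind(diag(c(1, 1, 3)), c(0, 0, 0)), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  mri <- import_mri(img)
  expect_equal(mri$spacing, 1)
  expect_true(all(dim(mri$data) <= 256))
  # extents preserved: 3 mm axis now ~57 voxels at 1 mm
  expect_equal(dim(mri$data)[3], 58)

  # already-isotropic input is returned unchanged
  iso <- RNifti::asNifti(array(rnorm(27), c(3, 3, 3)))
  RNifti::sform(iso) <- structure(rbind(cbind(diag(3) * 2, c(0, 0, 0)),
                                        c(0, 0, 0, 1)), code = 2L)
  out <- import_mri(iso)
  expect_equal(out$data, array(as.numeric(iso), c(3, 3, 3)))

  # trilinear interpolation is exact on a constant volume
  const <- RNifti::asNifti(array(7, c(10, 10, 5)))
  RNifti::sform(const) <- structure(rbind(cbind(diag(c(1, 1, 2)), c(0, 0, 0)),
                                          c(0, 0, 0, 1)), code = 2L)
  cm <- import_mri(const)
  expect_equal(max(abs(cm$data - 7)), 0, tolerance = 1e-12)

  expect_error(import_mri(RNifti::asNifti(array(0, c(4, 4, 4, 2)))), "3-D")
})

test_that("fiducial head frame is canonical, rigid, and axis-aligned", {
  # canonical fiducials give the identity frame
  tr <- head_transform_from_fiducials(c(10, 0, 0), c(0, 6, 0), c(0, -6, 0))
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$origin, c(0, 0, 0))

  # a scrambled frame: transform is rigid and lands fiducials on the axes
  set.seed(8)
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  shift <- c(3, -2, 12)
  na <- drop(R %*% c(10, 1, 0)) + shift
  le <- drop(R %*% c(0, 6, 0)) + shift
  re <- drop(R %*% c(0, -6, 0)) + shift
  tr2 <- head_transform_from_fiducials(na, le, re)
  pts <- matrix(rnorm(30), 10, 3)
  out <- apply_transform(tr2, pts)
  expect_equal(as.numeric(dist(out)), as.numeric(dist(pts)), tolerance = 1e-9)
  na_h <- apply_transform(tr2, na)
  le_h <- apply_transform(tr2, le)
  re_h <- apply_transform(tr2, re)
  expect_equal(na_h[2], 0, tolerance = 1e-9)   # nasion on +x axis
  expect_equal(na_h[3], 0, tolerance = 1e-9)
  expect_gt(na_h[1], 0)
  expect_gt(le_h[2], 0)                        # left ear on +y
  expect_equal(le_h[c(3)], 0, tolerance = 1e-9)
  expect_lt(re_h[2], 0)                        # right ear on -y
  expect_equal(le_h[3], 0, tolerance = 1e-9)

  expect_error(head_transform_from_fiducials(c(1, 0, 0), c(2, 0, 0),
                                             c(3, 0, 0)), "collinear")
})

test_that("surface vertices map to head-frame shape points and back", {
  mri <- list(affine = rbind(cbind(diag(2, 3), c(-10, -20, -5)),
                             c(0, 0, 0, 1)),
              spacing = 2)
  tr <- head_transform_from_fiducials(c(100, 0, 0), c(0, 60, 0), c(0, -60, 0))
  mesh <- list(vertices = rbind(c(55, 10, 2.5), c(5, 40, 25)))
  shape <- surface_to_shape(mesh, mri, tr)
  # oracle: voxel -> mm -> head (identity here) -> cm
  mm <- cbind(mesh$vertices, 1) %*% t(mri$affine)
  expect_equal(unclass(shape), apply_transform(tr, mm[, 1:3]) / 10,
               ignore_attr = TRUE, tolerance = 1e-12)

  # round trip through the inverse transform recovers the voxels
  back_mm <- apply_transform(invert_transform(tr), unclass(shape) * 10)
  back_vox <- (cbind(back_mm, 1) %*% t(solve(mri$affine)))[, 1:3]
  expect_equal(back_vox, mesh$vertices, tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(surface_to_shape(list(vertices = NULL), mri, tr), "vertices")
})

test_that("sphere fitting recovers exact and noisy spheres, rejects planes", {
  set.seed(9)
  dirs <- matrix(rnorm(1500), 500, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * 7.5, 2, c(0, 0, 5), `+`)
  fit <- fit_sphere(pts)
  expect_equal(fit$origin, c(0, 0, 5), tolerance = 1e-6)
  expect_equal(fit$radius, 7.5, tolerance = 1e-6)
  expect_lt(fit$rms_error, 1e-9)

  # Monte-Carlo with 0.05 cm isotropic noise
  errs <- replicate(50, {
    noisy <- pts + matrix(rnorm(1500, sd = 0.05), 500, 3)
    f <- fit_sphere(noisy)
    c(sqrt(sum((f$origin - c(0, 0, 5))^2)), abs(f$radius - 7.5))
  })
  expect_lt(max(errs[1, ]), 0.05)
  expect_lt(max(errs[2, ]), 0.05)

  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(1, 1, 0))), "coplanar")
  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 4")
})

test_that("sphere fit is equivariant under rotation and translation", {
  set.seed(10)
  dirs <- matrix(rnorm(900), 300, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * 6.8, 2, c(1, -0.5, 4), `+`) +
    matrix(rnorm(900, sd = 0.02), 300, 3)
  f0 <- fit_sphere(pts)
  ang <- 0.4
  R <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  shift <- c(-2, 3, 1)
  f1 <- fit_sphere(sweep(pts %*% t(R), 2, shift, `+`))
  expect_equal(f1$origin, drop(R %*% f0$origin) + shift, tolerance = 1e-6)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-8)
})

test_that("multi-sphere fits collapse to the global sphere on spherical heads", {
  set.seed(11)
  dirs <- matrix(rnorm(1800), 600, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * 7.5, 2, c(0, 0, 5), `+`)
  ch <- small_layout(12)
  mm <- fit_multisphere(pts, ch)
  expect_equal(nrow(mm$channel_spheres), 12)
  for (i in 1:12) {
    expect_lt(max(abs(c(mm$channel_spheres$ox[i], mm$channel_spheres$oy[i],
                        mm$channel_spheres$oz[i]) - c(0, 0, 5))), 1e-3)
    expect_lt(abs(mm$channel_spheres$r[i] - 7.5), 1e-3)
  }
  expect_error(fit_multisphere(pts, NULL), "geometry")
})

test_that("per-channel spheres vary smoothly on an ellipsoidal head", {
  set.seed(12)
  dirs <- matrix(rnorm(3000), 1000, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ell <- sweep(dirs %*% diag(c(7.5, 6.5, 7.0)), 2, c(0, 0, 5), `+`)
  ch <- small_layout(60)
  mm <- fit_multisphere(ell, ch)
  cs <- mm$channel_spheres
  origins <- cbind(cs$ox, cs$oy, cs$oz)
  sensors <- ch$coil1
  # neighbouring channels (< 3 cm apart) get origins differing < 1 cm
  sd2 <- as.matrix(dist(sensors))
  od2 <- as.matrix(dist(origins))
  near <- sd2 < 3 & upper.tri(sd2)
  expect_gt(sum(near), 0)
  expect_lt(max(od2[near]), 1)
})
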