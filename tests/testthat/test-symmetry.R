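test_that("plane reflection follows the Householder map", {
  p <- Plane(c(1, 0, 0), 0)
  expect_equal(reflectPoints(matrix(c(1, 0, 0), 1), p),
               matrix(c(-1, 0, 0), 1), ignore_attr = TRUE)

  # points on the plane are fixed
  q <- Plane(c(1, 2, 2) / 3, 1.5)
  on_plane <- matrix(c(4.5, 0, 0), 1)   # n . x = 1.5
  expect_equal(reflectPoints(on_plane, q), on_plane, tolerance = 1e-12,
               ignore_attr = TRUE)

  # involution: reflecting twice restores the cloud exactly
  cloud <- make_cloud(200, seed = 3)
  expect_equal(reflectPoints(reflectPoints(cloud, q), q), cloud,
               tolerance = 1e-12)

  # H = I - 2nn' is an involution with det -1 for random unit normals
  set.seed(4)
  for (i in 1:10) {
    n <- rnorm(3)
    n <- n / sqrt(sum(n^2))
    H <- diag(3) - 2 * tcrossprod(n)
    expect_equal(H %*% H, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(det(H), -1, tolerance = 1e-12)
  }
})

test_that("ICP recovers identity, translations and rotations", {
  cloud <- make_cloud(400, seed = 5)

  r0 <- icpRegister(cloud, cloud)
  expect_equal(r0$transform@rotation, diag(3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(r0$transform@translation, c(0, 0, 0), tolerance = 1e-6)
  expect_lt(r0$residualRMS, 1e-6)

  r1 <- icpRegister(cloud, sweep(cloud, 2, c(3, 2, 2), "+"))
  expect_equal(r1$transform@translation, c(3, 2, 2), tolerance = 1e-3)
  expect_lt(rotation_angle_deg(r1$transform@rotation), 0.1)

  R10 <- rotationMatrix(c(0, 0, 10))
  ctr <- colMeans(cloud)
  target <- sweep(sweep(cloud, 2, ctr) %*% t(R10), 2, ctr, "+")
  r2 <- icpRegister(cloud, target)
  expect_lt(rotation_angle_deg(r2$transform@rotation, R10), 0.1)
})

test_that("ICP residual history is non-increasing", {
  cloud <- make_cloud(300, seed = 6)
  R <- rotationMatrix(c(4, -7, 9))
  target <- cloud %*% t(R) + matrix(c(1, -2, 0.5), nrow(cloud), 3,
                                    byrow = TRUE)
  h <- icpRegister(cloud, target)$history
  expect_true(all(diff(h) <= 1e-9 * pmax(h[-length(h)], 1)))
})

test_that("ICP rejects degenerate clouds", {
  same <- matrix(1, 50, 3)
  expect_error(icpRegister(same, make_cloud(50)), "rank|coincident")
  expect_error(icpRegister(matrix(numeric(0), 0, 3), make_cloud(50)),
               "non-empty")
})

test_that("the symmetry plane of a mirrored cloud is recovered", {
  cloud <- make_symmetric_cloud(400, seed = 7)
  s <- bestSymmetryPlane(cloud)
  expect_lt(axis_angle_deg(planeNormal(s), c(1, 0, 0)), 1)
  expect_lt(abs(planeOffset(s)), 0.5)

  # the frame is orthonormal and right-handed
  B <- cbind(planeNormal(s), axisU(s), axisV(s))
  expect_equal(crossprod(B), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("symmetry-plane estimation is equivariant under rigid motion", {
  cloud <- make_symmetric_cloud(400, seed = 8)
  for (ang in list(c(12, -9, 6), c(-15, 15, -15))) {
    R <- rotationMatrix(ang)
    moved <- cloud %*% t(R) + matrix(c(4, -3, 2), nrow(cloud), 3,
                                     byrow = TRUE)
    s <- bestSymmetryPlane(moved)
    expect_lt(axis_angle_deg(planeNormal(s), drop(R %*% c(1, 0, 0))), 2)
  }
})

test_that("asymmetric clouds still yield a best-effort plane with residual", {
  cloud <- make_cloud(300, seed = 9)
  s <- bestSymmetryPlane(cloud)
  expect_s4_class(s, "SymmetryPlane")
  expect_true(is.finite(residualRMS(s)))
  expect_gt(residualRMS(s), 0)
  expect_error(bestSymmetryPlane(cloud[1:3, ]), "at least 4")
})

test_that("a perfect reflection has eigenvalues {-1, 1, 1} and recovers the offset", {
  # composite map assembled the way the estimator does it, on an exactly
  # symmetric cloud placed off-origin
  cloud <- make_symmetric_cloud(300, seed = 10)
  cloud[, 1] <- cloud[, 1] + 12         # symmetric about x = 12
  s <- bestSymmetryPlane(cloud)
  expect_lt(abs(planeOffset(s) - 12), 0.5)

  refl <- reflectPoints(cloud, Plane(planeNormal(s), planeOffset(s)))
  reg <- icpRegister(refl, cloud)
  H <- diag(3) - 2 * tcrossprod(planeNormal(s))
  M <- reg$transform@rotation %*% H
  ev <- sort(Re(eigen(M)$values))
  expect_equal(ev, c(-1, 1, 1), tolerance = 1e-3)
})

test_that("SymmetryPlane JSON serialization round-trips", {
  cloud <- make_symmetric_cloud(200, seed = 12)
  s <- bestSymmetryPlane(cloud)
  f <- tempfile(fileext = ".json")
  writeSymmetryPlane(s, f)
  back <- readSymmetryPlane(f)
  expect_equal(planeNormal(back), planeNormal(s), tolerance = 1e-12)
  expect_equal(planeOffset(back), planeOffset(s), tolerance = 1e-12)
  expect_equal(axisU(back), axisU(s), tolerance = 1e-12)
  expect_equal(residualRMS(back), residualRMS(s), tolerance = 1e-12)
})
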