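test_that("rigid transforms: isometry, identity, inverse, composition", {
  set.seed(21)
  R <- random_rotation(pi / 4)
  tr <- rigid_transform(R, c(0.01, -0.02, 0.03))
  pts <- matrix(rnorm(30, sd = 0.05), ncol = 3)
  moved <- apply_transform(tr, pts)
  d0 <- as.matrix(dist(pts)); d1 <- as.matrix(dist(moved))
  expect_equal(d1, d0, tolerance = 1e-12)

  expect_equal(apply_transform(rigid_transform(), pts), pts)
  back <- apply_transform(invert_transform(tr), moved)
  expect_equal(back, pts, tolerance = 1e-12)

  tr2 <- rigid_transform(random_rotation(pi / 5), c(0, 0.004, -0.001))
  expect_equal(apply_transform(compose_transform(tr2, tr), pts),
               apply_transform(tr2, apply_transform(tr, pts)),
               tolerance = 1e-12)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
})

test_that("intermammary detection recovers the built-in strip", {
  fx <- bilateral_fixture()
  patch <- detect_intermammary(fx$surface, fx$nipples)
  strip <- fx$surface$labels$strip
  # patch covers >= 95% of the strip
  expect_gte(length(intersect(patch, strip)) / length(strip), 0.95)
  # and stays within the strip plus its 1-ring
  nb <- breastdeform:::vertex_neighbors(fx$surface)
  ring1 <- unique(c(strip, unlist(nb[strip])))
  expect_true(all(patch %in% ring1))

  # threshold 0: nothing is perfectly flat on a jittered mesh
  expect_error(detect_intermammary(fx$surface, fx$nipples,
                                   threshold_deg = 0), "threshold")

  # single-breast surface: no inter-breast flat band
  model <- make_breast_phantom(phantom_spec(edge = 13e-3))
  s <- model$outer_surface
  v <- s$vertices
  fake <- landmark_set(list(nipple_left = v[which.min(v[, 1]), ],
                            nipple_right = v[which.max(v[, 1]), ]))
  sv <- sort(unique(as.vector(s$faces)))
  map <- integer(nrow(v)); map[sv] <- seq_along(sv)
  s2 <- tri_surface(v[sv, ], matrix(map[s$faces], ncol = 3))
  expect_error(detect_intermammary(s2, fake), "flat|band|patch")
})

test_that("boundary transfer honours the geodesic radius rule", {
  fx <- bilateral_fixture()
  s <- fx$surface
  v <- s$vertices
  il <- s$labels$nipple_left; ir <- s$labels$nipple_right
  dl <- geodesic_distance(s, il)
  dr <- geodesic_distance(s, ir)

  # radius 0 -> the whole inter-breast band
  p0 <- transfer_boundary(s, fx$nipples, 0, 0)
  band <- which(v[, 1] > v[il, 1] & v[, 1] < v[ir, 1])
  expect_setequal(p0, band)

  # known geometry: nipple-to-strip geodesic ~ quarter arc + gap
  rad_l <- min(dl[s$labels$strip]); rad_r <- min(dr[s$labels$strip])
  patch <- transfer_boundary(s, fx$nipples, rad_l, rad_r)
  expect_gt(length(patch), 0)
  # the patch boundary sits at the prescribed geodesic radius within an
  # edge length
  h <- fx$spec$edge
  expect_gte(min(dl[patch]), rad_l - h)
  expect_gte(min(dr[patch]), rad_r - h)
  # strip vertices (away from breasts) are inside the patch
  expect_gte(length(intersect(patch, s$labels$strip)) /
               length(s$labels$strip), 0.95)

  expect_error(transfer_boundary(s, fx$nipples, 10, 10), "extent")
})

test_that("ICP registration: identity, SE(3) recovery, noise, leveling", {
  fx <- bilateral_fixture()
  patch_ids <- detect_intermammary(fx$surface, fx$nipples)
  src <- fx$surface$vertices[patch_ids, ]

  # identical patches -> identity
  tr0 <- rigid_register(src, src)
  expect_lt(max(abs(tr0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tr0$translation)), 1e-9)

  # known SE(3) motion (<= 30 degrees) recovered to 1e-6 m RMS
  set.seed(33)
  R <- random_rotation(30 * pi / 180)
  tvec <- c(0.02, -0.015, 0.01)
  truth <- rigid_transform(R, tvec)
  tgt <- apply_transform(truth, src)
  tr <- rigid_register(src, tgt)
  moved <- apply_transform(tr, src)
  expect_lt(sqrt(mean(rowSums((moved - tgt)^2))), 1e-6)

  # Gaussian noise sigma = 0.5 mm: least-squares recovery within
  # 3 sigma / sqrt(n) on the translation
  sigma <- 0.5e-3
  tgt_n <- tgt + matrix(rnorm(length(tgt), sd = sigma), ncol = 3)
  tr_n <- rigid_register(src, tgt_n)
  moved_n <- apply_transform(tr_n, src)
  expect_lt(sqrt(mean(rowSums((moved_n - tgt)^2))),
            3 * sigma / sqrt(nrow(src)) + sigma) # residual ~ noise floor
  expect_lt(max(abs(colMeans(moved_n) - colMeans(tgt))),
            3 * sigma / sqrt(nrow(src)))

  # leveling only shifts z
  nip_s <- landmark(fx$nipples, "nipple_left")
  nip_t <- apply_transform(truth, nip_s) + c(0, 0, 0.004)
  tr_l <- rigid_register(src, tgt, level_nipples = TRUE,
                         nipple_source = nip_s, nipple_target = nip_t)
  expect_equal(tr_l$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(tr_l$translation[1:2], tr$translation[1:2],
               tolerance = 1e-9)
  expect_equal(tr_l$translation[3] - tr$translation[3], 0.004,
               tolerance = 1e-9)

  expect_error(rigid_register(src[1:2, ], src[1:2, ]), "3 points")
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(rigid_register(line, line), "degenerate")
})

test_that("full alignment pipeline recovers a known rigid motion", {
  fx <- bilateral_fixture()
  set.seed(44)
  R <- random_rotation(20 * pi / 180)
  truth <- rigid_transform(R, c(0.03, -0.01, 0.02))
  supine <- apply_transform(truth, fx$surface)
  sup_nips <- apply_transform(truth, fx$nipples)
  tr <- align_prone_supine(fx$surface, supine, fx$nipples, sup_nips,
                           level_nipples = FALSE)
  moved <- apply_transform(tr, fx$surface$vertices)
  err <- sqrt(mean(rowSums((moved -
                              apply_transform(truth,
                                              fx$surface$vertices))^2)))
  expect_lt(err, 1e-3) # 1 mm RMS over the whole surface
})
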