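# Digital-plant construction: object filtering, per-cell selection,
# shoot-root merging, morphology, hue profiles and the damage index.

test_that("object filters enforce strict bounds on area, distance and circularity", {
  layout <- grid_layout(1, 1, c(300, 300), "L", pitch = 100)
  # area exactly 39 under min_area 40 (strict >) is rejected, 41 kept
  co39 <- rect_coords(13, 3, 143, 143)          # 39 px near the centre
  co41 <- rect_coords(41, 1, 129, 155)
  lc <- components_from_coords(list(co39, co41), 300, 300)
  spec <- object_filter_spec(min_area = 40, max_dist_to_center = 130)
  kept <- filter_objects(lc, spec, layout)
  expect_equal(kept$summary$label, 2L)

  # centroid at distance just over the bound is rejected
  far <- disk_coords(4, 280, 280)               # far from centre (149.5,149.5)
  lc2 <- components_from_coords(list(far), 300, 300)
  expect_equal(nrow(filter_objects(lc2, spec, layout)$summary), 0L)

  # an elongated 3-px-wide polyline passes the root circularity cut,
  # a disk of the same area does not
  line <- do.call(rbind, lapply(0:2, function(w)
    cbind(x = 100 + w, y = 50:229)))
  colnames(line) <- c("x", "y")
  disk <- disk_coords(13, 150, 150)
  lc3 <- components_from_coords(list(line, disk), 300, 300)
  root_spec <- object_filter_spec(min_area = 109, circ_max = 0.70)
  kept3 <- filter_objects(lc3, root_spec, layout)
  expect_equal(kept3$summary$label, 1L)
  expect_lt(kept3$summary$circularity, 0.2)

  # distance filtering without a layout is a configuration error
  expect_error(filter_objects(lc2, spec, NULL), "layout")
})

test_that("filtering is idempotent and always returns a subset", {
  set.seed(61)
  mask <- matrix(runif(60 * 60) < 0.2, 60, 60)
  lc <- label_components(mask)
  spec <- object_filter_spec(min_area = 3)
  once <- filter_objects(lc, spec)
  twice <- filter_objects(once, spec)
  expect_true(all(once$summary$label %in% lc$summary$label))
  expect_equal(once$summary$label, twice$summary$label)
})

test_that("largest-object-per-cell selection is deterministic", {
  layout <- grid_layout(1, 2, c(200, 400), "L", pitch = 200)
  cells <- c(1L, 1L, 2L)
  big <- disk_coords(6, 99, 99)      # area 113
  small <- disk_coords(4, 120, 99)
  other <- disk_coords(6, 299, 99)
  lc <- components_from_coords(list(big, small, other), 200, 400,
                               cells = cells)
  sel <- select_largest_per_cell(lc, layout, "P")
  expect_equal(sort(names(sel)), c("1", "2"))
  expect_equal(nrow(sel[["1"]]$coords), nrow(big))

  # area tie: the lowest label wins
  tie1 <- disk_coords(5, 80, 80)
  tie2 <- disk_coords(5, 120, 120)
  lct <- components_from_coords(list(tie1, tie2), 200, 400, cells = c(1L, 1L))
  selt <- select_largest_per_cell(lct, layout, "P")
  expect_setequal(paste(selt[["1"]]$coords[, 1], selt[["1"]]$coords[, 2]),
                  paste(tie1[, 1], tie1[, 2]))
})

test_that("shoot-root merging pairs by column and picks the nearest root below", {
  layout <- grid_layout(1, 2, c(600, 600), "L", pitch = 300)
  # columns at x = 150 and 450
  shoot <- disk_coords(8, 150, 100)
  root_same_col <- cbind(x = rep(149:151, each = 120), y = rep(140:259, 3))
  root_other_col <- cbind(x = rep(449:451, each = 100), y = rep(150:249, 3))
  far_root <- cbind(x = rep(149:151, each = 50), y = rep(400:449, 3))
  shoots <- components_from_coords(list(shoot), 600, 600, cells = 1L)
  roots <- components_from_coords(list(root_same_col, far_root,
                                       root_other_col), 600, 600,
                                  cells = c(1L, 1L, 2L))
  plants <- merge_shoot_root(shoots, roots, layout, "P")
  expect_length(plants, 1)
  p <- plants[[1]]
  # nearest root below the shoot centroid was chosen and pixels add up
  expect_equal(nrow(p$coords), nrow(shoot) + nrow(root_same_col))
  expect_equal(nrow(p$parts$root), nrow(root_same_col))

  # a shoot with no root in its column becomes a shoot-only plant
  shoots2 <- components_from_coords(list(disk_coords(8, 450, 100)),
                                    600, 600, cells = 2L)
  roots2 <- components_from_coords(list(cbind(x = rep(149:151, each = 50),
                                              y = rep(200:249, 3))),
                                   600, 600, cells = 1L)
  plants2 <- merge_shoot_root(shoots2, roots2, layout, "P")
  expect_length(plants2, 1)
  expect_null(plants2[[1]]$parts$root)
})

test_that("merging conserves pixels over many random plants", {
  set.seed(71)
  layout <- grid_layout(1, 1, c(500, 300), "L", pitch = 100)
  for (i in 1:50) {
    r0 <- sample(5:9, 1)
    cx <- 150 + sample(-10:10, 1)
    shoot <- disk_coords(r0, cx, 60)
    L <- sample(80:300, 1)
    root <- cbind(x = rep(cx + (-1:1), each = L),
                  y = rep(seq(60 + r0 + 2, length.out = L), 3))
    shoots <- components_from_coords(list(shoot), 500, 300, cells = 1L)
    roots <- components_from_coords(list(root), 500, 300, cells = 1L)
    p <- merge_shoot_root(shoots, roots, layout)[[1]]
    expect_equal(nrow(p$coords), nrow(shoot) + nrow(root))
  }
})

test_that("morphology reproduces the drawn-shape oracles", {
  rect <- compute_morphology(rect_coords(20, 10))
  expect_equal(rect$area, 200)
  expect_equal(rect$perimeter, 2 * ((20 - 1) + (10 - 1)))
  expect_equal(rect$compactness, 200 / 56, tolerance = 1e-12)
  expect_equal(rect$eccentricity, 2, tolerance = 1e-9)

  disk <- compute_morphology(disk_coords(20))
  expect_gte(disk$circularity, 0.9)
  expect_lte(disk$circularity, 1.1)
  expect_lte(disk$eccentricity, 1.05)

  ell <- compute_morphology(ellipse_coords(40, 10))
  expect_equal(ell$eccentricity, 4.0, tolerance = 0.05)

  g <- matrix(100L, 40, 40)
  const <- compute_morphology(disk_coords(5, 20, 20), g)
  expect_equal(const$hisgreypeak, 100L)

  # modal-intensity tie resolves to the lowest value
  g2 <- matrix(0L, 1, 4)
  g2[1, ] <- c(7L, 7L, 3L, 3L)
  two <- compute_morphology(cbind(x = 0:3, y = 0L), g2)
  expect_equal(two$hisgreypeak, 3L)

  expect_true(compute_morphology(cbind(x = 0L, y = 0L))$degenerate)
})

test_that("shape features are invariant to translation and 90-degree rotation", {
  set.seed(81)
  base <- disk_coords(9)
  base <- rbind(base, cbind(x = 9:24, y = 0L))   # asymmetric appendage
  base <- base[!duplicated(paste(base[, 1], base[, 2])), ]
  m0 <- compute_morphology(base)
  shifted <- cbind(x = base[, 1] + 37, y = base[, 2] + 12)
  rotated <- cbind(x = -base[, 2], y = base[, 1])
  rotated <- cbind(x = rotated[, 1] - min(rotated[, 1]),
                   y = rotated[, 2] - min(rotated[, 2]))
  for (other in list(shifted, rotated)) {
    m1 <- compute_morphology(other)
    expect_equal(m1$area, m0$area)
    expect_equal(m1$perimeter, m0$perimeter, tolerance = 1e-9)
    expect_equal(m1$circularity, m0$circularity, tolerance = 1e-9)
    expect_equal(m1$eccentricity, m0$eccentricity, tolerance = 1e-9)
  }
  expect_gte(m0$eccentricity, 1)
})

test_that("hue-class histograms bin by floor(H*K/256) and sum to one", {
  hsb <- list(H = matrix(0L, 10, 10), S = matrix(255L, 10, 10),
              Bri = matrix(255L, 10, 10))
  co <- rect_coords(10, 10)
  h0 <- hue_class_histogram(co, hsb, 16)
  expect_equal(unname(h0[1]), 1)
  expect_equal(sum(h0), 1)

  hsb2 <- list(H = matrix(0:255, 16, 16), S = matrix(255L, 16, 16),
               Bri = matrix(255L, 16, 16))
  hu <- hue_class_histogram(rect_coords(16, 16), hsb2, 16)
  expect_equal(unname(hu), rep(1 / 16, 16))

  Hm <- matrix(c(rep(85L, 50), rep(20L, 50)), 10, 10)
  hsb3 <- list(H = Hm, S = matrix(255L, 10, 10), Bri = matrix(255L, 10, 10))
  hh <- hue_class_histogram(rect_coords(10, 10), hsb3, 16)
  expect_equal(unname(hh[6]), 0.5)   # floor(85*16/256) = 5 (0-based)
  expect_equal(unname(hh[2]), 0.5)   # floor(20*16/256) = 1
})

test_that("yellow damage fraction flags seedlings above the 50% band", {
  mk <- function(hvals) list(H = matrix(hvals, 10, 10),
                             S = matrix(255L, 10, 10),
                             Bri = matrix(200L, 10, 10))
  co <- rect_coords(10, 10)
  all_yellow <- yellow_damage_fraction(co, mk(rep(20L, 100)))
  expect_equal(all_yellow$fraction, 1)
  expect_true(all_yellow$damaged)

  all_green <- yellow_damage_fraction(co, mk(rep(85L, 100)))
  expect_equal(all_green$fraction, 0)
  expect_false(all_green$damaged)

  half <- yellow_damage_fraction(co, mk(c(rep(20L, 50), rep(85L, 50))))
  expect_equal(half$fraction, 0.5)
  expect_false(half$damaged)   # strictly greater than 0.5 required
})
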