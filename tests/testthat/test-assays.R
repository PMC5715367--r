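# End-to-end assay pipelines on synthetic plates with known truth.

test_that("salt pipeline detects every seedling once, in the right cell", {
  layout <- small_grid_layout("Col-0", n = 3)
  pl <- generate_plate("salt", layout, line_effect_spec("Col-0"), seed = 21)
  rec <- run_salt_plate(pl$vis, pl$fluo, layout)
  expect_equal(nrow(rec), 9)
  expect_setequal(rec$cell, pl$truth$cell)
  # joined colour profile: 32 columns, each modality summing to 1 when
  # detected (FLUO zero-filled for dead seedlings)
  vis_cols <- grep("^vis_hue_", names(rec))
  fluo_cols <- grep("^fluo_hue_", names(rec))
  expect_length(c(vis_cols, fluo_cols), 32)
  expect_equal(unname(rowSums(rec[, vis_cols])), rep(1, 9), tolerance = 1e-9)
  fs <- rowSums(rec[, fluo_cols])
  expect_equal(unname(fs[rec$detected_fluo]),
               rep(1, sum(rec$detected_fluo)), tolerance = 1e-9)
  expect_equal(unname(fs[!rec$detected_fluo]),
               rep(0, sum(!rec$detected_fluo)))
  # FLUO detection marks the alive seedlings
  alive_cells <- pl$truth$cell[pl$truth$status == "alive"]
  expect_setequal(rec$cell[rec$detected_fluo], alive_cells)
})

test_that("a blank plate produces no records", {
  layout <- small_grid_layout("Col-0", n = 2, dims = c(500, 500))
  set.seed(31)
  vis <- plate_image(flat_image(500, 500, c(178, 178, 178)), "VIS", "salt")
  fluo <- plate_image(flat_image(500, 500, c(18, 18, 18)), "FLUO", "salt")
  expect_null(run_salt_plate(vis, fluo, layout))
})

test_that("the standard growth condition only raises the salt saturation cut", {
  stress <- assay_config("salt", "stress")
  standard <- assay_config("salt", "standard")
  s_thresh <- function(cfg) cfg$vis_rule$clauses[[1]]$value
  expect_equal(s_thresh(stress), 49)
  expect_equal(s_thresh(standard), 74)
  expect_equal(standard$fluo_rule, stress$fluo_rule)
  expect_equal(standard$vis_filter, stress$vis_filter)
  # a mid-saturation pixel flips between the two conditions
  px <- array(as.integer(hsb_to_rgb(85, 60, 120)), c(1, 1, 3))
  expect_true(apply_pixel_rule(px, stress$vis_rule)[1, 1])
  expect_false(apply_pixel_rule(px, standard$vis_rule)[1, 1])
})

test_that("records are invariant to whole-cell translation of plate and layout", {
  layout <- small_grid_layout("Col-0", n = 2, dims = c(800, 800))
  pl <- generate_plate("salt", layout, line_effect_spec("Col-0"), seed = 41)
  rec <- run_salt_plate(pl$vis, pl$fluo, layout)

  shift <- 200L  # one cell pitch, circular roll keeps the background
  roll <- function(px) {
    out <- px
    out[, c((shift + 1):800, 1:shift), ] <- px
    out
  }
  vis2 <- plate_image(roll(pl$vis$pixels), "VIS", "salt")
  fluo2 <- plate_image(roll(pl$fluo$pixels), "FLUO", "salt")
  centers2 <- layout$cell_centers
  centers2$cx <- centers2$cx + shift
  layout2 <- plate_layout("square_grid", 2, 2, centers2,
                          layout$cell_to_line, c(800, 800))
  rec2 <- run_salt_plate(vis2, fluo2, layout2)
  ord <- order(rec$cell); ord2 <- order(rec2$cell)
  expect_equal(rec2$cell[ord2], rec$cell[ord])
  expect_equal(rec2$area[ord2], rec$area[ord])
  expect_equal(rec2$centroid_x[ord2], rec$centroid_x[ord] + shift)
  vis_cols <- grep("^vis_hue_", names(rec))
  expect_equal(rec2[ord2, vis_cols], rec[ord, vis_cols],
               ignore_attr = TRUE)
})

test_that("arsenic pipeline keeps seeds and seedlings apart in profile space", {
  skip_if_not_installed("cluster")
  layout <- grid_layout(4, 4, c(900, 900), "Col-0", pitch = 210)
  pl <- generate_plate("arsenic", layout,
                       line_effect_spec("Col-0", germination_prob = 0.5),
                       seed = 51)
  rec <- run_arsenic_plate(pl$vis, pl$fluo, layout)
  expect_equal(nrow(rec), 16)
  # seeds concentrate their VIS profile in the low-hue classes
  seeds <- pl$truth$cell[pl$truth$status == "seed"]
  low <- rowSums(rec[, c("vis_hue_00", "vis_hue_01", "vis_hue_02")])
  expect_true(all(low[rec$cell %in% seeds] > 0.9))
  expect_true(all(low[!rec$cell %in% seeds] < 0.1))
  # the two populations are cleanly separated (silhouette > 0.5)
  prof <- as.matrix(rec[, grep("hue_", names(rec))])
  lab <- as.integer(rec$cell %in% seeds) + 1L
  sil <- cluster::silhouette(lab, dist(prof))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("freezing pipeline applies the area band and scores damage", {
  layout <- round_layout(c(1800, 1800), "Col-0", n_positions = 12)
  pl <- generate_plate("freezing", layout,
                       line_effect_spec("Col-0", damage_prob = 0.5),
                       seed = 61)
  rec <- run_freezing_plate(pl$vis, layout)
  expect_equal(nrow(rec), 12)
  expect_true(all(rec$area > 10000 & rec$area < 40000))
  # recovered damage fractions match the truth at the nearest anchor
  idx <- vapply(seq_len(nrow(rec)), function(i)
    which.min((pl$truth$anchor_x - rec$centroid_x[i])^2 +
                (pl$truth$anchor_y - rec$centroid_y[i])^2), integer(1))
  expect_equal(rec$damage_fraction, pl$truth$damage_fraction[idx],
               tolerance = 0.05)
  expect_equal(rec$damaged, pl$truth$status[idx] == "damaged")

  # objects outside the area band are never seedlings
  spec <- object_filter_spec(min_area = 10000, max_area = 40000)
  small <- components_from_coords(list(disk_coords(39, 100, 100)), 300, 300)
  expect_equal(nrow(filter_objects(small, spec)$summary), 0L)  # ~4800 px
  ok <- components_from_coords(list(disk_coords(62, 100, 100)), 300, 300)
  expect_equal(nrow(filter_objects(ok, spec)$summary), 1L)     # ~12000 px
})

test_that("phosphate pipeline recovers plants whose major axis tracks root length", {
  pl <- generate_plate("phosphate", specs = line_effect_spec("Col-0"),
                       seed = 71)
  rec <- run_phosphate_plate(pl$vis, pl$layout)
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$has_root))
  expect_setequal(rec$cell, pl$truth$cell)

  # the reported major axis equals the moment oracle on the detected
  # pixel set by construction; against the *drawn* geometry it scales
  # with the rod formula 4*L/sqrt(12) plus the shoot mass, so recovered
  # values must correlate strongly and monotonically with drawn length
  tr <- pl$truth[match(rec$cell, pl$truth$cell), ]
  expect_gt(cor(rec$major_axis, tr$root_length), 0.8)
  ratio <- rec$major_axis / tr$root_length
  expect_true(all(ratio > 1.1 & ratio < 1.5))

  # a grid-lines-only plate yields nothing after artifact removal
  blank_layout <- pl$layout
  sp <- line_effect_spec("Col-0")
  bg <- generate_plate("phosphate", blank_layout, sp, seed = 91)
  # wipe the seedlings, keep background + embossed grid
  px <- bg$vis$pixels
  for (ch in 1:3) {
    band <- px[1:40, , ch]
    px[261:1697, , ch] <- matrix(sample(band, 1437 * 1800, replace = TRUE),
                                 1437, 1800)
  }
  # redraw the vertical grid lines over the wiped area
  xs_cc <- sort(unique(blank_layout$cell_centers$cx))
  for (x in utils::head(xs_cc, -1) + diff(xs_cc) / 2) {
    cols <- round(x) + (-1:1)
    for (ch in 1:3) px[, cols + 1L, ch] <- 165L
  }
  vis0 <- plate_image(px, "VIS", "phosphate")
  expect_null(run_phosphate_plate(vis0, blank_layout))
})

test_that("a longer-rooted line separates from wild-type at n = 12", {
  specs <- list(
    `Col-0` = line_effect_spec("Col-0"),
    longroot = line_effect_spec("longroot", root_length_mean = 350))
  ex <- generate_experiment("phosphate", specs, replicates = 2, seed = 33)
  cfg <- assay_config("phosphate")
  rec <- segment_plates(ex$plates, cfg)
  tab <- data.frame(line_id = rec$line_id, value = rec$major_axis)
  res <- line_significance(tab, "anova", "Col-0", condition = "phosphate")
  expect_lt(res$p_raw, 0.05)
  expect_gt(mean(tab$value[tab$line_id == "longroot"]),
            mean(tab$value[tab$line_id == "Col-0"]))
})
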