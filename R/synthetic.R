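# Synthetic plate generator: renders the four plate types with known
# per-seedling ground truth so segmentation, feature extraction,
# clustering and the line tests can all be validated without any raw
# screen images.

#' Per-line effect specification for the synthetic generator
#'
#' Encodes the statistical structure the analysis assumes: a binary
#' survival (salt) or germination (arsenic) state per seedling, a binary
#' heavy-damage state with a continuous damage fraction (freezing), and
#' a Gaussian drawn root length (phosphate). Defaults are the wild-type
#' reference levels of the screen (66% salt survival, 64% arsenic
#' germination, 50% freezing damage); the drawn root extent defaults to
#' 250 px, which together with the shoot geometry puts the wild-type
#' root-length proxy (merged-plant major axis) on the reference scale of
#' about 345 px.
#'
#' @param line_id line identifier.
#' @param survival_prob probability a salt seedling is alive.
#' @param germination_prob probability an arsenic seed germinated.
#' @param damage_prob probability a freezing seedling is heavily
#'   damaged (> 50% yellowish).
#' @param root_length_mean,root_length_sd drawn vertical root extent,
#'   px.
#' @param render optional named list overriding rendering parameters
#'   (hue/saturation/brightness means and spreads, blob radii).
#' @return List of class `line_effect_spec`.
#' @export
line_effect_spec <- function(line_id, survival_prob = 0.66,
                             germination_prob = 0.64, damage_prob = 0.50,
                             root_length_mean = 250, root_length_sd = 25,
                             render = list()) {
  stopifnot(survival_prob >= 0, survival_prob <= 1,
            germination_prob >= 0, germination_prob <= 1,
            damage_prob >= 0, damage_prob <= 1,
            root_length_sd >= 0)
  rp <- modifyList(default_render_params(), render)
  structure(list(line_id = line_id, survival_prob = survival_prob,
                 germination_prob = germination_prob,
                 damage_prob = damage_prob,
                 root_length_mean = root_length_mean,
                 root_length_sd = root_length_sd, render = rp),
            class = "line_effect_spec")
}

# Rendering parameters: hue/saturation/brightness distributions per
# tissue state, all on the 8-bit HSB scale, truncated to keep every
# rendered tissue pixel inside its assay's foreground rule. Freezing
# "alive" tissue uses a lower hue band than salt/arsenic because the
# red-blue index rule requires R > B, i.e. hue strictly below 120
# degrees (byte 85): leaves reflect more red than blue light.
default_render_params <- function() {
  list(
    alive_hue = c(85, 8), alive_sat = c(190, 25), alive_bri = c(150, 20),
    dead_hue = c(22, 6), dead_sat = c(170, 25), dead_bri = c(130, 20),
    seed_hue = c(15, 5), seed_sat = c(180, 20), seed_bri = c(120, 15),
    freeze_green_hue = c(68, 5), freeze_sat = c(220, 12),
    freeze_bri = c(140, 18),
    fluo_hue = c(5, 3), fluo_sat = c(220, 15), fluo_bri = c(160, 20),
    rosette_radius = c(14, 20),        # salt/arsenic centre-disk radius
    seed_axes = c(10, 7),              # seed ellipse semi-axes
    freeze_radius = c(62, 96),         # freezing disk radius
    shoot_radius = c(15, 19),          # phosphate shoot radius
    root_width = 5, root_amp = 8, root_period = 110,
    root_gray = c(155, 6))  # translucent root on backlight: darker than
                            # the field but brighter than the shoot-mask
                            # band, as real backlit roots appear
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

disk_offsets <- function(r) {
  s <- -ceiling(r):ceiling(r)
  g <- expand.grid(dx = s, dy = s)
  g[g$dx^2 + g$dy^2 <= r^2, ]
}

# rosette: centre disk plus leaf disks at random angles, deduplicated
rosette_offsets <- function(r0) {
  parts <- list(disk_offsets(r0))
  n_leaves <- sample(4:6, 1)
  for (a in runif(n_leaves, 0, 2 * pi)) {
    d <- disk_offsets(r0 * 0.65)
    d$dx <- d$dx + round(cos(a) * r0 * 0.9)
    d$dy <- d$dy + round(sin(a) * r0 * 0.9)
    parts[[length(parts) + 1]] <- d
  }
  all <- do.call(rbind, parts)
  all[!duplicated(paste(all$dx, all$dy)), ]
}

ellipse_offsets <- function(a, b, theta) {
  s <- -ceiling(a):ceiling(a)
  g <- expand.grid(dx = s, dy = s)
  u <- g$dx * cos(theta) + g$dy * sin(theta)
  v <- -g$dx * sin(theta) + g$dy * cos(theta)
  g[(u / a)^2 + (v / b)^2 <= 1, ]
}

sample_hsb <- function(n, hue, sat, bri, hue_range = c(0, 255)) {
  cbind(h = rtrunc_norm(n, hue[1], hue[2], hue_range[1], hue_range[2]),
        s = rtrunc_norm(n, sat[1], sat[2], max(sat[1] - 3 * sat[2], 100), 255),
        v = rtrunc_norm(n, bri[1], bri[2], max(bri[1] - 3 * bri[2], 60),
                        min(bri[1] + 3 * bri[2], 230)))
}

#' Render one synthetic seedling patch
#'
#' Draws the VIS (and, for salt/arsenic, FLUO) pixels of a single
#' seedling in the given state, as coordinate offsets around an anchor
#' plus per-pixel RGB values, together with its ground-truth row.
#' States: `"alive"` / `"dead"` (salt), `"germinated"` / `"seed"`
#' (arsenic), `"damaged"` / `"undamaged"` (freezing; a contiguous
#' angular sector of the rosette is rendered yellowish, covering > 50%
#' of the pixels iff damaged), `"plant"` (phosphate; shoot blob plus a
#' wavy dark root polyline of sampled length).
#'
#' Uses the current RNG stream.
#'
#' @param assay assay id.
#' @param status seedling state (see Details).
#' @param spec a [line_effect_spec()].
#' @return List with `dx`, `dy` (integer offsets), `vis` (N x 3 RGB
#'   matrix), `fluo` (RGB matrix or `NULL`), and `truth` (list with
#'   `status`, `damage_fraction`, `root_length`).
#' @export
render_seedling <- function(assay, status, spec) {
  rp <- spec$render
  truth <- list(status = status, damage_fraction = NA_real_,
                root_length = NA_real_)
  fluo <- NULL
  if (assay %in% c("salt", "arsenic") && status %in% c("alive", "germinated")) {
    off <- rosette_offsets(runif(1, rp$rosette_radius[1], rp$rosette_radius[2]))
    hsb <- sample_hsb(nrow(off), rp$alive_hue, rp$alive_sat, rp$alive_bri,
                      hue_range = c(60, 110))
    vis <- hsb_to_rgb(hsb[, 1], hsb[, 2], hsb[, 3])
    fh <- sample_hsb(nrow(off), rp$fluo_hue, rp$fluo_sat, rp$fluo_bri,
                     hue_range = c(0, 12))
    fluo <- hsb_to_rgb(fh[, 1], fh[, 2], fh[, 3])
  } else if (assay == "salt" && status == "dead") {
    off <- rosette_offsets(runif(1, rp$rosette_radius[1], rp$rosette_radius[2]))
    hsb <- sample_hsb(nrow(off), rp$dead_hue, rp$dead_sat, rp$dead_bri,
                      hue_range = c(4, 40))
    vis <- hsb_to_rgb(hsb[, 1], hsb[, 2], hsb[, 3])
  } else if (assay == "arsenic" && status == "seed") {
    off <- ellipse_offsets(runif(1, rp$seed_axes[1] - 1, rp$seed_axes[1] + 2),
                           runif(1, rp$seed_axes[2] - 1, rp$seed_axes[2] + 1),
                           runif(1, 0, pi))
    hsb <- sample_hsb(nrow(off), rp$seed_hue, rp$seed_sat, rp$seed_bri,
                      hue_range = c(4, 32))
    vis <- hsb_to_rgb(hsb[, 1], hsb[, 2], hsb[, 3])
  } else if (assay == "freezing") {
    r <- runif(1, rp$freeze_radius[1], rp$freeze_radius[2])
    off <- disk_offsets(r)
    f <- if (status == "damaged") runif(1, 0.55, 0.95) else runif(1, 0.02, 0.35)
    a0 <- runif(1, 0, 2 * pi)
    ang <- (atan2(off$dy, off$dx) - a0) %% (2 * pi)
    yellow <- ang < 2 * pi * f
    hsb <- matrix(0, nrow(off), 3)
    if (any(yellow))
      hsb[yellow, ] <- sample_hsb(sum(yellow), rp$dead_hue,
                                  rp$freeze_sat, rp$freeze_bri,
                                  hue_range = c(4, 39))
    if (any(!yellow))
      hsb[!yellow, ] <- sample_hsb(sum(!yellow), rp$freeze_green_hue,
                                   rp$freeze_sat, rp$freeze_bri,
                                   hue_range = c(56, 76))
    vis <- hsb_to_rgb(hsb[, 1], hsb[, 2], hsb[, 3])
    truth$damage_fraction <- mean(yellow)
    truth$status <- if (mean(yellow) > 0.5) "damaged" else "undamaged"
  } else if (assay == "phosphate") {
    r0 <- runif(1, rp$shoot_radius[1], rp$shoot_radius[2])
    shoot <- disk_offsets(r0)
    sh <- sample_hsb(nrow(shoot), rp$alive_hue, rp$alive_sat,
                     c(100, 12), hue_range = c(60, 110))
    sh[, 3] <- pmin(pmax(sh[, 3], 60), 130)   # Bri inside (23, 138)
    shoot_rgb <- hsb_to_rgb(sh[, 1], sh[, 2], sh[, 3])
    L <- max(40, round(rnorm(1, spec$root_length_mean, spec$root_length_sd)))
    phase <- runif(1, 0, 2 * pi)
    ys <- seq_len(L)
    xs <- round(rp$root_amp * sin(2 * pi * ys / rp$root_period + phase))
    half <- (rp$root_width - 1) / 2
    root <- do.call(rbind, lapply(-half:half, function(w)
      data.frame(dx = xs + w, dy = ys + round(r0) - 2)))
    g <- round(rtrunc_norm(nrow(root), rp$root_gray[1], rp$root_gray[2],
                           142, 168))
    root_rgb <- cbind(g, g, g)
    off <- rbind(shoot, root)
    vis <- rbind(shoot_rgb, root_rgb)
    truth$root_length <- L
  } else stop("unknown status '", status, "' for assay ", assay)
  list(dx = as.integer(off$dx), dy = as.integer(off$dy), vis = vis,
       fluo = fluo, truth = truth)
}

# flat achromatic background (equal channels -> saturation 0)
flat_background <- function(H, W, level, noise_sd, max_dev = 6) {
  g <- round(pmin(pmax(matrix(rnorm(H * W, level, noise_sd), H, W),
                       level - max_dev), level + max_dev))
  array(rep(g, 3L), c(H, W, 3L))
}

arsenic_background <- function(H, W) {
  px <- array(0L, c(H, W, 3L))
  px[, , 1] <- 254L + (runif(H * W) < 0.5)              # R >= 254 always
  px[, , 2] <- round(247 + runif(H * W) * 4)
  px[, , 3] <- round(251 + runif(H * W) * 4)
  px
}

# clip patch coordinates to the image and return (x, y, rgb) for bulk
# assignment; pasting is deferred so the big pixel array is written once
clip_patch <- function(anchor_x, anchor_y, patch, which, H, W) {
  x <- anchor_x + patch$dx
  y <- anchor_y + patch$dy
  ok <- x >= 0 & x < W & y >= 0 & y < H
  list(x = x[ok], y = y[ok], rgb = patch[[which]][ok, , drop = FALSE])
}

blit_patches <- function(px, patches) {
  if (!length(patches)) return(px)
  x <- unlist(lapply(patches, `[[`, "x"))
  y <- unlist(lapply(patches, `[[`, "y"))
  rgb <- do.call(rbind, lapply(patches, `[[`, "rgb"))
  for (ch in 1:3)
    px[cbind(y + 1L, x + 1L, ch)] <- rgb[, ch]
  px
}

# positions for 60 seedlings on a round plate: 8x8 lattice, the 60
# points closest to the plate centre
freezing_positions <- function(H, W, n = 60, pitch = 215) {
  xs <- ((1:8) - 4.5) * pitch + (W - 1) / 2
  ys <- ((1:8) - 4.5) * pitch + (H - 1) / 2
  g <- expand.grid(x = xs, y = ys)
  d <- sqrt((g$x - (W - 1) / 2)^2 + (g$y - (H - 1) / 2)^2)
  g[order(d)[seq_len(n)], ]
}

default_layout <- function(assay, line_id, dims = c(1800, 1800)) {
  switch(assay,
    salt = ,
    arsenic = grid_layout(6, 6, dims, line_id, pitch = 290),
    freezing = round_layout(dims, line_id, n_positions = 60),
    phosphate = {
      dc <- as.matrix(expand.grid(seq(75, dims[2] - 75, by = 150),
                                  seq(75, dims[1] - 75, by = 150)))
      grid_layout(1, 6, dims, line_id, pitch = 295, center_y = 340,
                  dist_centers = dc)
    })
}

plate_seed <- function(seed, plate_index) {
  (as.integer(seed) + 1000003L * as.integer(plate_index)) %% 2147483647L
}

#' Generate one synthetic plate with ground truth
#'
#' Renders the plate background so that it produces zero foreground
#' pixels under the matching assay rules (achromatic agar for salt,
#' near-white backlight for arsenic, pale field for freezing, bright
#' backlit field with embossed grid lines for phosphate), samples a
#' state per sown seedling from the line's effect spec, and pastes
#' rendered seedling patches at the layout positions. Deterministic for
#' a fixed `seed`.
#'
#' @param assay assay id.
#' @param layout a [plate_layout()]; defaults to the assay's standard
#'   layout. Must match the assay shape (round for freezing, single-row
#'   for phosphate).
#' @param specs a [line_effect_spec()], or a named list of them keyed by
#'   line id (layout cells look their line up by id).
#' @param seed integer seed for the plate's RNG stream.
#' @param condition `"stress"` or `"standard"` (metadata only; the
#'   generator renders the stressed phenotype mix given by the specs).
#' @param plate_id plate identifier.
#' @return List with `vis` ([plate_image]), `fluo` (or `NULL`),
#'   `truth` (data frame: plate, cell, line, status, damage fraction,
#'   root length, anchor coordinates) and `layout`.
#' @export
generate_plate <- function(assay, layout = NULL, specs, seed = 1,
                           condition = "stress", plate_id = "P1") {
  if (inherits(specs, "line_effect_spec"))
    specs <- setNames(list(specs), specs$line_id)
  if (is.null(layout)) layout <- default_layout(assay, names(specs)[1])
  if (assay == "freezing" && layout$shape != "round")
    stop("the freezing assay uses round plates")
  if (assay != "freezing" && layout$shape == "round")
    stop("round layouts are only valid for the freezing assay")
  missing_lines <- setdiff(unique(layout$cell_to_line), names(specs))
  if (length(missing_lines))
    stop("no effect spec for line(s): ", paste(missing_lines, collapse = ", "))
  set.seed(seed)
  H <- layout$image_dims[1]; W <- layout$image_dims[2]

  vis_px <- switch(assay,
    salt = flat_background(H, W, 178, 3),
    arsenic = arsenic_background(H, W),
    freezing = flat_background(H, W, 200, 4),
    phosphate = flat_background(H, W, 205, 2, max_dev = 5))
  fluo_px <- if (assay %in% c("salt", "arsenic"))
    flat_background(H, W, 18, 3) else NULL

  if (assay == "phosphate") {
    xs_cc <- sort(unique(layout$cell_centers$cx))
    bounds <- utils::head(xs_cc, -1) + diff(xs_cc) / 2
    for (x in bounds) {                               # vertical grid lines
      cols <- round(x) + (-1:1)
      cols <- cols[cols >= 0 & cols < W]
      for (ch in 1:3) vis_px[, cols + 1L, ch] <- 165L
    }
    for (y in c(150, 1750)) {                         # border grid lines
      if (y < H) for (ch in 1:3) vis_px[y + (0:2) + 1L, , ch] <- 165L
    }
  }

  anchors <- if (assay == "freezing") {
    fp <- freezing_positions(H, W, layout$n_positions %||% 60)
    data.frame(cell = NA_integer_, x = round(fp$x), y = round(fp$y),
               line = layout$cell_to_line[1])
  } else {
    data.frame(cell = layout$cell_centers$cell,
               x = round(layout$cell_centers$cx),
               y = round(layout$cell_centers$cy),
               line = layout$cell_to_line)
  }

  truth <- vector("list", nrow(anchors))
  vis_patches <- list()
  fluo_patches <- list()
  for (i in seq_len(nrow(anchors))) {
    sp <- specs[[anchors$line[i]]]
    status <- switch(assay,
      salt = if (runif(1) < sp$survival_prob) "alive" else "dead",
      arsenic = if (runif(1) < sp$germination_prob) "germinated" else "seed",
      freezing = if (runif(1) < sp$damage_prob) "damaged" else "undamaged",
      phosphate = "plant")
    patch <- render_seedling(assay, status, sp)
    vis_patches[[i]] <- clip_patch(anchors$x[i], anchors$y[i], patch,
                                   "vis", H, W)
    if (!is.null(patch$fluo) && !is.null(fluo_px))
      fluo_patches[[length(fluo_patches) + 1]] <-
        clip_patch(anchors$x[i], anchors$y[i], patch, "fluo", H, W)
    truth[[i]] <- data.frame(
      plate_id = plate_id, cell = anchors$cell[i], line_id = anchors$line[i],
      status = patch$truth$status,
      damage_fraction = patch$truth$damage_fraction,
      root_length = patch$truth$root_length,
      anchor_x = anchors$x[i], anchor_y = anchors$y[i])
  }

  vis_px <- blit_patches(vis_px, vis_patches)
  if (!is.null(fluo_px)) fluo_px <- blit_patches(fluo_px, fluo_patches)
  vis <- plate_image(vis_px, "VIS", assay, condition, plate_id)
  fluo <- if (!is.null(fluo_px))
    plate_image(fluo_px, "FLUO", assay, condition, plate_id) else NULL
  list(vis = vis, fluo = fluo, truth = do.call(rbind, truth),
       layout = layout)
}

#' Generate a multi-line, multi-replicate synthetic experiment
#'
#' One plate per line and replicate (each plate is sown with a single
#' line, as in the screen's design: 36 seeds x 3 replicates for
#' salt/arsenic, 60 x 3 for freezing, 6 x 2 for phosphate). Also
#' computes the per-line *expected* significance calls by running the
#' assay's oracle test (Fisher's exact test on the true states, or
#' ANOVA on the true root lengths) against the wild-type truth, with
#' BH adjustment — the reference an image-free analysis would give.
#'
#' @param assay assay id.
#' @param specs named list of [line_effect_spec()]s including the
#'   wild-type.
#' @param replicates plates per line (default: the assay's design).
#' @param seed experiment seed; each plate derives its own stream from
#'   `(seed, plate index)`.
#' @param wild_type wild-type line id.
#' @param dir optional directory: when given, plate images are written
#'   as PNG plus `layout.yaml` and `truth.csv`.
#' @return List with `plates` (list of [generate_plate()] results),
#'   `truth` (master table) and `expected` (per-line oracle calls).
#' @export
generate_experiment <- function(assay, specs, replicates = NULL, seed = 1,
                                wild_type = "Col-0", dir = NULL) {
  if (!wild_type %in% names(specs))
    stop("specs must include the wild-type line '", wild_type, "'")
  replicates <- replicates %||%
    switch(assay, salt = 3, arsenic = 3, freezing = 3, phosphate = 2)
  plates <- list()
  k <- 0L
  for (line in names(specs)) for (rep in seq_len(replicates)) {
    k <- k + 1L
    pid <- sprintf("%s_%s_r%d", assay, line, rep)
    pl <- generate_plate(assay, default_layout(assay, line),
                         specs[line], seed = plate_seed(seed, k),
                         plate_id = pid)
    pl$replicate <- rep
    pl$truth$replicate <- rep
    plates[[pid]] <- pl
  }
  truth <- do.call(rbind, lapply(plates, `[[`, "truth"))
  rownames(truth) <- NULL
  expected <- expected_calls(assay, truth, wild_type)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(plates)) {
      png::writePNG(plates[[pid]]$vis$pixels / 255,
                    file.path(dir, paste0(pid, "_vis.png")))
      if (!is.null(plates[[pid]]$fluo))
        png::writePNG(plates[[pid]]$fluo$pixels / 255,
                      file.path(dir, paste0(pid, "_fluo.png")))
      write_layout_yaml(plates[[pid]]$layout,
                        file.path(dir, paste0(pid, "_layout.yaml")))
    }
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(plates = plates, truth = truth, expected = expected)
}

# oracle line calls from true states (no images involved)
expected_calls <- function(assay, truth, wild_type) {
  if (assay == "phosphate") {
    tab <- data.frame(line_id = truth$line_id, value = truth$root_length)
    return(line_significance(tab, "anova", wild_type, condition = assay))
  }
  pos <- switch(assay, salt = "alive", arsenic = "germinated",
                freezing = "damaged")
  cnt <- data.frame(
    line_id = names(table(truth$line_id)),
    n_group1 = as.integer(tapply(truth$status == pos, truth$line_id, sum)),
    n_group2 = as.integer(tapply(truth$status != pos, truth$line_id, sum)))
  line_significance(cnt, "fisher", wild_type, condition = assay)
}
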