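# Shared fixtures: drawn shapes, independent oracles and small synthetic
# plates. Everything is generated in code at test time.

# ---- drawn pixel sets (0-based x, y coordinates) ----

rect_coords <- function(w, h, x0 = 0, y0 = 0) {
  as.matrix(expand.grid(x = x0:(x0 + w - 1), y = y0:(y0 + h - 1)))
}

disk_coords <- function(r, cx = 0, cy = 0) {
  g <- as.matrix(expand.grid(x = -ceiling(r):ceiling(r),
                             y = -ceiling(r):ceiling(r)))
  g <- g[g[, 1]^2 + g[, 2]^2 <= r^2, , drop = FALSE]
  cbind(x = g[, 1] + cx, y = g[, 2] + cy)
}

ellipse_coords <- function(a, b, cx = 0, cy = 0) {
  g <- as.matrix(expand.grid(x = -ceiling(a):ceiling(a),
                             y = -ceiling(b):ceiling(b)))
  g <- g[(g[, 1] / a)^2 + (g[, 2] / b)^2 <= 1, , drop = FALSE]
  cbind(x = g[, 1] + cx, y = g[, 2] + cy)
}

coords_to_mask <- function(coords, H, W) {
  m <- matrix(FALSE, H, W)
  m[cbind(coords[, 2] + 1L, coords[, 1] + 1L)] <- TRUE
  m
}

# uniform-colour H x W x 3 image
flat_image <- function(H, W, rgb) {
  px <- array(0L, c(H, W, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  px
}

# ---- independent oracles ----

# flood-fill component labeling in plain R (queue-based), the reference
# for the Rcpp labeler
flood_fill_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    cbind(dx = c(1, -1, 0, 0, 1, 1, -1, -1), dy = c(0, 0, 1, -1, 1, -1, 1, -1))
  else cbind(dx = c(1, -1, 0, 0), dy = c(0, 0, 1, -1))
  nxt <- 0L
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (!mask[y, x] || lab[y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x)); lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ny <- p[1] + nb[k, "dy"]; nx2 <- p[2] + nb[k, "dx"]
        if (ny >= 1 && ny <= H && nx2 >= 1 && nx2 <= W &&
            mask[ny, nx2] && lab[ny, nx2] == 0L) {
          lab[ny, nx2] <- nxt
          queue[[length(queue) + 1]] <- c(ny, nx2)
        }
      }
    }
  }
  lab
}

# exhaustive two-sided Fisher p for a 2x2 table via choose(), no
# distribution functions involved
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# literal step-up BH definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- parametric colour-profile fixture for clustering tests ----
# joined VIS+FLUO profiles mimicking rendered seedlings: `flip` rows are
# rendered with the wrong class (label noise)
make_profile_records <- function(n, p_alive = 0.5, flip_frac = 0,
                                 n_px = 400, K = 16) {
  status <- ifelse(runif(n) < p_alive, "alive", "dead")
  rendered <- status
  if (flip_frac > 0) {
    flip <- sample(n, round(flip_frac * n))
    rendered[flip] <- ifelse(status[flip] == "alive", "dead", "alive")
  }
  prof <- t(vapply(rendered, function(st) {
    hue <- if (st == "alive") rnorm(n_px, 85, 8) else rnorm(n_px, 22, 6)
    hue <- pmin(pmax(round(hue), 0), 255)
    vis <- tabulate(floor(hue * K / 256) + 1L, K) / n_px
    fluo <- if (st == "alive") {
      fh <- pmin(pmax(round(rnorm(n_px, 5, 3)), 0), 255)
      tabulate(floor(fh * K / 256) + 1L, K) / n_px
    } else rep(0, K)
    c(vis, fluo)
  }, numeric(2 * K)))
  colnames(prof) <- c(sprintf("vis_hue_%02d", 0:(K - 1)),
                      sprintf("fluo_hue_%02d", 0:(K - 1)))
  cbind(data.frame(line_id = "L", truth = status, rendered = rendered),
        as.data.frame(prof))
}

# ---- hand-built labeled_components (for merge fixtures) ----
components_from_coords <- function(coord_list, H, W, cells = NULL) {
  lab <- matrix(0L, H, W)
  summ <- lapply(seq_along(coord_list), function(i) {
    co <- coord_list[[i]]
    lab[cbind(co[, 2] + 1L, co[, 1] + 1L)] <<- i
    data.frame(label = i, area = nrow(co),
               xmin = min(co[, 1]), xmax = max(co[, 1]),
               ymin = min(co[, 2]), ymax = max(co[, 2]),
               cx = mean(co[, 1]), cy = mean(co[, 2]))
  })
  summ <- do.call(rbind, summ)
  summ$cell <- if (is.null(cells)) seq_along(coord_list) else cells
  structure(list(labels = lab, summary = summ, connectivity = 8),
            class = "labeled_components")
}

# small salt/arsenic layout for fast plate tests
small_grid_layout <- function(line_id = "Col-0", n = 3, dims = c(700, 700)) {
  grid_layout(n, n, dims, line_id, pitch = 200)
}
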