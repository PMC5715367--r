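#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of the probabilities of all tables
#' with the same margins whose hypergeometric probability does not exceed
#' that of the observed table (with a relative tolerance of 1e-7 for
#' ties). Used to compare each mutant line against wild-type on the
#' clustered group counts (alive/dead, germinated/seed,
#' damaged/undamaged).
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`
#'   (rows = cluster groups, columns = line and wild-type).
#' @return The two-sided p-value. A table with a zero margin is
#'   degenerate and returns `p = 1` with a warning.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (min(a + b, c + d, a + c, b + d) == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  k <- a + c                       # first-column margin
  lo <- max(0L, k - (c + d))
  hi <- min(a + b, k)
  probs <- stats::dhyper(lo:hi, a + b, c + d, k)
  p_obs <- stats::dhyper(a, a + b, c + d, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up adjustment: for sorted raw p-values `p_(i)`,
#' `p_adj_(i) = min_{j >= i} ( p_(j) * m / j )`, clipped at 1 and mapped
#' back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order (empty in, empty out).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)          # largest first
  i <- m:1                                  # their ranks
  adj <- pmin(1, cummin(p[o] * m / i))
  adj[order(o)]
}

#' Classical one-way ANOVA for two groups
#'
#' The two-group F test used to compare each line's root-length proxy
#' (major axis of the merged digital plant) against wild-type in the
#' phosphate assay.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with `F`, `p` and `df = c(1, n - 2)`. Identical constant
#'   groups give `F = 0, p = 1`; zero within-group variance with unequal
#'   means reports `p = 0` with a `degenerate` flag.
#' @export
oneway_anova <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  ma <- mean(group_a); mb <- mean(group_b)
  g <- (sum(group_a) + sum(group_b)) / (na + nb)
  ssb <- na * (ma - g)^2 + nb * (mb - g)^2
  ssw <- sum((group_a - ma)^2) + sum((group_b - mb)^2)
  df2 <- na + nb - 2
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df = c(1, df2)))
    return(list(F = Inf, p = 0, df = c(1, df2), degenerate = TRUE))
  }
  f <- (ssb / 1) / (ssw / df2)
  list(F = f, p = stats::pf(f, 1, df2, lower.tail = FALSE), df = c(1, df2))
}

profile_columns <- function(records) {
  grep("^(vis|fluo)_hue_[0-9]+$", names(records), value = TRUE)
}

#' Two-group clustering of colour profiles
#'
#' Seedling state (alive vs dead in salt, germinated vs still-a-seed in
#' arsenic) is called without manual scoring: the Euclidean distance
#' matrix of the joined VIS + FLUO hue-class profiles feeds an
#' agglomerative hierarchical clustering (average linkage by default),
#' the tree is cut into exactly two groups, and the group with the larger
#' mean mass in the green hue classes of the VIS profile receives the
#' first semantic label (`"alive"` / `"germinated"`).
#'
#' @param records data frame of seedling records (one assay, one
#'   condition) containing the profile columns.
#' @param labels length-2 semantic labels, green group first.
#' @param linkage linkage method for [stats::hclust()].
#' @return `records` with `group` (1 = green group) and `group_label`
#'   columns added. If all profiles are identical the clustering is
#'   degenerate: a single group is returned and the
#'   `"degenerate"` attribute is `TRUE` (no test should be run).
#' @export
two_group_color_clustering <- function(records,
                                       labels = c("alive", "dead"),
                                       linkage = "average") {
  cols <- profile_columns(records)
  if (!length(cols)) stop("records carry no hue-profile columns")
  if (nrow(records) < 2) stop("need at least 2 records to cluster")
  prof <- as.matrix(records[, cols])
  d <- dist(prof)
  if (all(d == 0)) {
    records$group <- 1L
    records$group_label <- labels[1]
    attr(records, "degenerate") <- TRUE
    warning("all colour profiles identical; clustering is degenerate")
    return(records)
  }
  grp <- cutree(hclust(d, method = linkage), k = 2)
  vis_cols <- grep("^vis_hue_", cols, value = TRUE)
  gcols <- if (length(vis_cols)) {
    K <- length(vis_cols)
    vis_cols[green_class_indices(K)]
  } else {
    K <- length(cols)
    cols[green_class_indices(K)]
  }
  green_mass <- rowSums(prof[, gcols, drop = FALSE])
  m1 <- mean(green_mass[grp == 1])
  m2 <- mean(green_mass[grp == 2])
  if (m2 > m1) grp <- 3L - grp            # make group 1 the green group
  records$group <- grp
  records$group_label <- labels[grp]
  attr(records, "degenerate") <- FALSE
  records
}

#' Per-line group counts
#'
#' Tabulates clustered records into the per-line 2-group counts that feed
#' [line_significance()].
#'
#' @param records output of [two_group_color_clustering()], or freezing
#'   records (counted on the `damaged` flag instead of cluster groups).
#' @return Data frame with columns `line_id`, `n_group1`, `n_group2`.
#' @export
count_groups <- function(records) {
  grp <- if ("group" %in% names(records)) records$group
         else if ("damaged" %in% names(records)) records$damaged + 1L
         else stop("records carry neither cluster groups nor damage calls")
  tab <- table(records$line_id, factor(grp, levels = 1:2))
  data.frame(line_id = rownames(tab),
             n_group1 = as.integer(tab[, 1]),
             n_group2 = as.integer(tab[, 2]),
             row.names = NULL)
}

#' Line-versus-wild-type significance with FDR control
#'
#' Tests every line against wild-type and adjusts across all lines of the
#' condition with Benjamini-Hochberg; a line has a stress-related
#' phenotype iff its FDR-adjusted p-value is below 0.05.
#'
#' Two test types:
#' * `"fisher"`: input is a per-line group-count table (see
#'   [count_groups()]); each line forms a 2x2 table against wild-type.
#'   The reported statistic is the sample odds ratio.
#' * `"anova"`: input is a data frame with `line_id` and `value` (the
#'   root-length proxy); each line is compared to wild-type by two-group
#'   one-way ANOVA. The statistic is F.
#'
#' @param table input table (see Details).
#' @param test `"fisher"` or `"anova"`.
#' @param wild_type reserved wild-type line id.
#' @param alpha FDR level (default 0.05).
#' @param condition condition id carried into the results.
#' @return Data frame with columns `line_id`, `condition`, `statistic`,
#'   `p_raw`, `p_adj`, `significant`. Lines with zero observations are
#'   omitted with a warning.
#' @export
line_significance <- function(table, test = c("fisher", "anova"),
                              wild_type = "Col-0", alpha = 0.05,
                              condition = NA_character_) {
  test <- match.arg(test)
  if (test == "fisher") {
    stopifnot(all(c("line_id", "n_group1", "n_group2") %in% names(table)))
    wt <- table[table$line_id == wild_type, ]
    if (nrow(wt) != 1L) stop("wild-type line '", wild_type, "' not found")
    lines <- table[table$line_id != wild_type, ]
    empty <- lines$n_group1 + lines$n_group2 == 0
    if (any(empty)) {
      warning("omitting line(s) with zero detected seedlings: ",
              paste(lines$line_id[empty], collapse = ", "))
      lines <- lines[!empty, ]
    }
    stat <- (lines$n_group1 / pmax(lines$n_group2, 1)) /
      (wt$n_group1 / max(wt$n_group2, 1))
    p <- vapply(seq_len(nrow(lines)), function(i)
      suppressWarnings(fisher_exact_2x2(lines$n_group1[i], wt$n_group1,
                                        lines$n_group2[i], wt$n_group2)),
      numeric(1))
    ids <- lines$line_id
  } else {
    stopifnot(all(c("line_id", "value") %in% names(table)))
    wt_vals <- table$value[table$line_id == wild_type]
    if (length(wt_vals) < 2) stop("wild-type needs >= 2 measurements")
    ids <- setdiff(unique(table$line_id), wild_type)
    keep <- vapply(ids, function(id)
      sum(table$line_id == id) >= 2, logical(1))
    if (any(!keep)) {
      warning("omitting line(s) with fewer than 2 measurements: ",
              paste(ids[!keep], collapse = ", "))
      ids <- ids[keep]
    }
    res <- lapply(ids, function(id)
      oneway_anova(table$value[table$line_id == id], wt_vals))
    stat <- vapply(res, `[[`, numeric(1), "F")
    p <- vapply(res, `[[`, numeric(1), "p")
  }
  if (!length(ids))
    return(data.frame(line_id = character(0), condition = character(0),
                      statistic = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  p_adj <- bh_adjust(p)
  data.frame(line_id = ids, condition = condition, statistic = stat,
             p_raw = p, p_adj = p_adj, significant = p_adj < alpha,
             row.names = NULL)
}

#' Multi-trait profile clustering and line-density heatmap
#'
#' Profiles every plant by the eight morpho-colorimetric features,
#' z-scores them within the condition, clusters the plants hierarchically
#' (Ward linkage on Euclidean distances) and cuts the tree into five
#' groups C1-C5. Each line is then summarised by its density over the
#' five groups (rows sum to 1) and the lines themselves are clustered on
#' those density vectors, yielding the dendrogram + heatmap view in
#' which lines with similar multi-trait phenotypes sit together.
#'
#' @param records seedling records across lines for one condition.
#' @param k_groups number of plant groups (default 5).
#' @param features feature columns to use.
#' @return List of class `multitrait_result`: `plant_groups` (per-record
#'   C1..C5 assignment), `density` (lines x groups matrix), `line_tree`
#'   and `plant_tree` ([stats::hclust] objects), `heatmap` (density
#'   matrix with rows in dendrogram order) and `features_used`.
#' @export
multitrait_profile_heatmap <- function(records, k_groups = 5,
                                       features = c("area", "perimeter",
                                                    "circularity",
                                                    "compactness",
                                                    "major_axis",
                                                    "minor_axis",
                                                    "eccentricity",
                                                    "hisgreypeak")) {
  if (nrow(records) < k_groups)
    stop("need at least ", k_groups, " plants for the multi-trait clustering")
  X <- as.matrix(records[, features])
  if (any(!is.finite(X))) stop("all features must be finite")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  plant_tree <- hclust(dist(Z), method = "ward.D2")
  grp <- cutree(plant_tree, k = k_groups)
  dens <- table(records$line_id, factor(grp, levels = seq_len(k_groups)))
  dens <- sweep(as.matrix(dens), 1, rowSums(dens), "/")
  colnames(dens) <- paste0("C", seq_len(k_groups))
  line_tree <- if (nrow(dens) > 1)
    hclust(dist(dens), method = "average")
  else NULL
  heat <- if (!is.null(line_tree)) dens[line_tree$order, , drop = FALSE]
          else dens
  structure(list(plant_groups = paste0("C", grp), density = dens,
                 line_tree = line_tree, plant_tree = plant_tree,
                 heatmap = heat, features_used = colnames(X)),
            class = "multitrait_result")
}

#' Plot a multi-trait line-density heatmap
#'
#' @param x a [multitrait_profile_heatmap()] result.
#' @param path optional PNG path; when given, the plot is written there.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_multitrait <- function(x, path = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotting needs the 'pheatmap' package")
  args <- list(mat = x$density, cluster_cols = FALSE,
               clustering_method = "average", ...)
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 1200)
    on.exit(grDevices::dev.off())
  }
  p <- do.call(pheatmap::pheatmap, args)
  invisible(p)
}
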