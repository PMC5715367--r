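# Statistical layer: Fisher's exact test, BH adjustment, two-group
# ANOVA, colour clustering, the line screen and the multi-trait view.

test_that("Fisher's exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / 184756, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(2, 8, 7, 3), 12892 / 184756,
               tolerance = 1e-12)

  set.seed(91)
  for (i in 1:40) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (min(rowSums(tab), colSums(tab)) == 0) next
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    expect_equal(fisher_exact_2x2(a, b, c, d),
                 fisher_enum_oracle(a, b, c, d), tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(a, b, c, d),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_warning(p <- fisher_exact_2x2(0, 0, 3, 4), "zero margin")
  expect_equal(p, 1)
})

test_that("BH adjustment equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  set.seed(101)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))                     # adjusted >= raw
    expect_true(all(diff(adj[order(p)]) >= -1e-12))        # order-preserving
  }
})

test_that("two-group one-way ANOVA matches the F distribution and lm", {
  r0 <- oneway_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  r1 <- oneway_anova(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r1$F, 1.5, tolerance = 1e-12)
  expect_equal(r1$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(oneway_anova(1, c(1, 2)), "at least 2")

  set.seed(111)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = 0.5)
    got <- oneway_anova(a, b)
    fit <- anova(lm(y ~ g, data.frame(y = c(a, b),
                                      g = rep(c("a", "b"), c(length(a),
                                                             length(b))))))
    expect_equal(got$F, fit$`F value`[1], tolerance = 1e-9)
    expect_equal(got$p, fit$`Pr(>F)`[1], tolerance = 1e-9)
  }

  const <- oneway_anova(c(2, 2), c(5, 5))
  expect_equal(const$p, 0)
  expect_true(isTRUE(const$degenerate))
})

test_that("two-group colour clustering separates profiles and labels by green mass", {
  set.seed(121)
  rec <- make_profile_records(40, p_alive = 0.5)
  out <- two_group_color_clustering(rec)
  expect_false(attr(out, "degenerate"))
  expect_equal(out$group_label, out$truth)

  # permutation invariance of the grouping
  perm <- sample(nrow(rec))
  out2 <- two_group_color_clustering(rec[perm, ])
  expect_equal(out2$group_label, out$group_label[perm])

  # identical profiles are degenerate
  same <- rec[rep(1, 10), ]
  expect_warning(d <- two_group_color_clustering(same), "degenerate")
  expect_true(attr(d, "degenerate"))
  expect_equal(unique(d$group), 1L)
})

test_that("clustering tolerates label noise at the screen's validation level", {
  set.seed(131)
  rec <- make_profile_records(200, p_alive = 0.5, flip_frac = 0.05)
  out <- two_group_color_clustering(rec)
  # ground truth here is the intended status; the 5% mis-rendered
  # seedlings bound attainable agreement at 95%
  expect_gte(mean(out$group_label == out$truth), 0.90)
})

test_that("line significance screens against wild-type with BH control", {
  # line identical to wild-type: p = 1, not significant
  tab <- data.frame(line_id = c("Col-0", "same"),
                    n_group1 = c(70, 70), n_group2 = c(38, 38))
  r <- line_significance(tab, "fisher", "Col-0")
  expect_equal(r$p_raw, 1)
  expect_false(r$significant)

  # a strong effect stays significant across a 100-line family
  set.seed(141)
  nulls <- data.frame(line_id = sprintf("n%02d", 1:99),
                      n_group1 = rbinom(99, 108, 0.65))
  nulls$n_group2 <- 108 - nulls$n_group1
  fam <- rbind(data.frame(line_id = "Col-0", n_group1 = 71, n_group2 = 37),
               data.frame(line_id = "hit", n_group1 = 14, n_group2 = 94),
               nulls)
  res <- line_significance(fam, "fisher", "Col-0")
  expect_lt(res$p_adj[res$line_id == "hit"], 1e-6)
  expect_true(res$significant[res$line_id == "hit"])

  # zero-seedling lines are omitted with a warning
  tab0 <- rbind(tab, data.frame(line_id = "empty", n_group1 = 0,
                                n_group2 = 0))
  expect_warning(r0 <- line_significance(tab0, "fisher", "Col-0"),
                 "zero detected")
  expect_false("empty" %in% r0$line_id)
})

test_that("the null screen keeps the false-positive proportion under control", {
  set.seed(151)
  flagged <- 0L; total <- 0L
  for (exp_i in 1:5) {
    tab <- data.frame(line_id = c("Col-0", sprintf("n%03d", 1:100)),
                      n_group1 = rbinom(101, 108, 0.65))
    tab$n_group2 <- 108 - tab$n_group1
    res <- line_significance(tab, "fisher", "Col-0")
    flagged <- flagged + sum(res$significant)
    total <- total + nrow(res)
  }
  expect_equal(total, 500L)
  expect_lte(flagged / total, 0.10)
})

test_that("multi-trait clustering yields normalised densities and groups like lines", {
  set.seed(161)
  n <- 60
  pop <- rep(c("big_green", "small_yellow"), each = n / 2)
  recs <- data.frame(
    line_id = rep(sprintf("L%d", 1:6), each = 10),
    area = ifelse(pop == "big_green", rnorm(n, 2000, 100), rnorm(n, 400, 50)),
    perimeter = ifelse(pop == "big_green", rnorm(n, 180, 10), rnorm(n, 80, 8)),
    circularity = runif(n, 0.7, 0.9),
    compactness = ifelse(pop == "big_green", rnorm(n, 11, 1), rnorm(n, 5, 1)),
    major_axis = ifelse(pop == "big_green", rnorm(n, 60, 5), rnorm(n, 25, 3)),
    minor_axis = ifelse(pop == "big_green", rnorm(n, 50, 5), rnorm(n, 20, 3)),
    eccentricity = runif(n, 1, 1.3),
    hisgreypeak = ifelse(pop == "big_green", rnorm(n, 90, 5), rnorm(n, 35, 5)))
  mt <- multitrait_profile_heatmap(recs)
  expect_equal(unname(rowSums(mt$density)), rep(1, 6))
  expect_length(mt$plant_groups, n)
  expect_setequal(unique(mt$plant_groups), paste0("C", 1:5))
  # lines of the same population are adjacent in the dendrogram order
  ord <- rownames(mt$heatmap)
  pop_of <- setNames(rep(c("A", "B"), each = 3), sprintf("L%d", 1:6))
  expect_equal(length(rle(unname(pop_of[ord]))$lengths), 2)

  # a duplicated line has an identical density row
  recs2 <- rbind(recs, transform(recs[recs$line_id == "L1", ],
                                 line_id = "L1copy"))
  mt2 <- multitrait_profile_heatmap(recs2)
  expect_equal(unname(mt2$density["L1", ]), unname(mt2$density["L1copy", ]))

  expect_error(multitrait_profile_heatmap(recs[1:3, ]), "at least 5")
  recs3 <- recs; recs3$circularity <- 0.8
  expect_warning(multitrait_profile_heatmap(recs3), "constant feature")
})
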