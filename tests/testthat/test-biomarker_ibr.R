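test_that("2^-ddCt fold changes follow the analytic form", {
  expect_equal(ddct_fold_change(25, 20, 24, 19), 1.0)   # equal dCt
  expect_equal(ddct_fold_change(26, 20, 24, 19), 0.5)   # ddCt = 1
  expect_equal(ddct_fold_change(22, 20, 23, 19), 4.0)   # ddCt = -2
  expect_error(ddct_fold_change(NA, 20, 24, 19), "finite")
})

test_that("panels collapse replicates to means and validate coverage", {
  tb <- expand.grid(group = c("g1", "g2"), replicate = 1:3,
                    biomarker = c("b1", "b2"), stringsAsFactors = FALSE)
  tb$value <- 2
  dirs <- c(b1 = "up", b2 = "down")
  p <- build_panel(tb, dirs)
  expect_true(all(p$X == 2))

  tb2 <- data.frame(group = rep(c("g1", "g2"), each = 6),
                    replicate = rep(1:3, 4),
                    biomarker = rep(rep(c("b1", "b2"), each = 3), 2),
                    value = c(1, 2, 3, rep(5, 9)))
  expect_equal(build_panel(tb2, dirs)$X["g1", "b1"], 2)

  # missing cell named in the error
  tb3 <- tb2[!(tb2$group == "g2" & tb2$biomarker == "b2"), ]
  expect_error(build_panel(tb3, dirs), "\\(g2, b2\\)")
  # direction validation
  expect_error(build_panel(tb2, c(b1 = "up")), "b2")
  expect_error(build_panel(tb2, c(b1 = "up", b2 = "sideways")), "sideways")
})

test_that("standardization is centered, unit-scaled, with SD modes", {
  X <- matrix(c(0, 1, 2, 5, 5, 5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("b1", "b2")))
  p <- panel_from_means(X, c(b1 = "up", b2 = "up"))
  expect_warning(std <- standardize(p), "constant")
  expect_equal(std$Y[, "b1"], c(g1 = -1, g2 = 0, g3 = 1))  # sample SD = 1
  expect_equal(std$Y[, "b2"], c(g1 = 0, g2 = 0, g3 = 0))
  expect_equal(std$m, c(b1 = 1, b2 = 5))

  # population SD rescales by sqrt((G-1)/G)
  expect_warning(stdp <- standardize(p, "population"))
  expect_equal(stdp$Y[, "b1"], c(g1 = -1, g2 = 0, g3 = 1) / sqrt(2 / 3))

  # two-group degeneracy: |Y| = sqrt(2)/2 whatever the values
  for (seed in 1:10) {
    set.seed(seed)
    X2 <- matrix(stats::runif(4, 1, 9), nrow = 2,
                 dimnames = list(c("a", "b"), c("m1", "m2")))
    std2 <- standardize(panel_from_means(X2, c(m1 = "up", m2 = "down")))
    expect_equal(abs(std2$Y), matrix(sqrt(2) / 2, 2, 2,
                                     dimnames = dimnames(X2)),
                 tolerance = 1e-12)
  }
})

test_that("direction signing flips down-biomarkers only", {
  Y <- matrix(c(-1, 0, 1, -1, 0, 1), nrow = 3,
              dimnames = list(NULL, c("b1", "b2")))
  Z <- apply_direction(Y, c(b1 = "up", b2 = "down"))
  expect_equal(Z[, "b1"], Y[, "b1"])
  expect_equal(Z[, "b2"], -Y[, "b2"])
  expect_equal(apply_direction(Y * 0, c(b1 = "down", b2 = "down")), Y * 0)
  expect_error(apply_direction(Y, c(b1 = "up")), "b2")
})

test_that("min-translation yields zero for the minimizing group", {
  Z <- matrix(c(-1, 0, 1), ncol = 1, dimnames = list(NULL, "b"))
  expect_equal(translate_scores(Z)[, 1], c(0, 1, 2))
  expect_equal(translate_scores(Z * 0), Z * 0)
  # |min| added literally even when min(Z) > 0
  Zpos <- matrix(c(0.5, 1.5), ncol = 1, dimnames = list(NULL, "b"))
  expect_equal(translate_scores(Zpos)[, 1], c(1.0, 2.0))
  # global scope shifts every column by the same amount
  Z2 <- cbind(b1 = c(-2, 1), b2 = c(-1, 3))
  expect_equal(translate_scores(Z2, "global"), Z2 + 2)
})

test_that("star area matches closed forms and the shoelace oracle", {
  expect_equal(star_area(rep(0, 5)), 0)
  expect_equal(star_area(rep(1, 4)), 2)                  # 4 right triangles
  expect_equal(star_area(rep(1, 3)), 3 * sin(2 * pi / 3) / 2)
  expect_error(star_area(1), "at least 2")
  for (k in 2:8) for (seed in 1:5) {
    set.seed(k * 100 + seed)
    S <- stats::runif(k, 0, 3)
    expect_equal(star_area(S), oracle_star_shoelace(S),
                 tolerance = 1e-12)
  }
})

test_that("compute_ibr chains the stages and exposes coordinates", {
  X <- matrix(c(1.0, 2.0, 1.5,
                4.0, 2.0, 3.0,
                0.5, 0.9, 0.7,
                10,  30,  20), nrow = 3,
              dimnames = list(c("ctrl", "tox", "mix"),
                              c("b1", "b2", "b3", "b4")))
  dirs <- c(b1 = "up", b2 = "down", b3 = "up", b4 = "down")
  res <- compute_ibr(panel_from_means(X, dirs))
  orc <- oracle_ibr(X, dirs)
  expect_equal(res$Y, orc$Y, tolerance = 1e-12)
  expect_equal(res$Z, orc$Z, tolerance = 1e-12)
  expect_equal(res$S, orc$S, tolerance = 1e-12)
  expect_equal(res$ibr_index, orc$ibr_index, tolerance = 1e-12)
  # per biomarker, some group sits at radius zero
  expect_true(all(apply(res$S, 2, min) < 1e-12))
  # star coordinates carry S as radii at equally spaced angles
  expect_equal(res$star_coordinates$tox$radius, unname(res$S["tox", ]))
  expect_equal(res$star_coordinates$ctrl$angle,
               2 * pi * (0:3) / 4)

  # identical groups -> zero index everywhere (constant-biomarker warnings)
  flat <- matrix(1, 3, 4, dimnames = dimnames(X))
  res0 <- suppressWarnings(compute_ibr(panel_from_means(flat, dirs)))
  expect_equal(unname(res0$ibr_index), c(0, 0, 0))
})

test_that("IBR is invariant to positive affine rescaling per biomarker", {
  for (seed in 1:10) {
    rp <- random_panel(sample(2:6, 1), sample(2:8, 1), seed)
    res <- compute_ibr(rp$panel)
    a <- stats::runif(ncol(rp$X), 0.1, 10)
    b <- stats::runif(ncol(rp$X), -5, 5)
    X2 <- sweep(sweep(rp$X, 2, a, `*`), 2, b, `+`)
    res2 <- compute_ibr(panel_from_means(X2, rp$directions))
    expect_equal(res2$Y, res$Y, tolerance = 1e-10)
    expect_equal(res2$S, res$S, tolerance = 1e-10)
    expect_equal(res2$ibr_index, res$ibr_index, tolerance = 1e-10)
  }
})

test_that("direction inference uses the designated control group", {
  X <- matrix(c(1, 2, 2, 5, 3, 4), nrow = 3,
              dimnames = list(c("ctrl", "t1", "t2"), c("b1", "b2")))
  p <- panel_from_means(X, c(b1 = "up", b2 = "up"))
  expect_message(d <- infer_directions(p, "ctrl"), "inferred")
  expect_equal(unname(d), c("up", "down"))
  expect_error(suppressMessages(infer_directions(p, "nope")), "unknown control")
})

test_that("axis-order sensitivity: k=3 invariant, k=4 has <= 3 values", {
  rp3 <- random_panel(3, 3, 11)
  sens3 <- order_sensitivity(compute_ibr(rp3$panel))
  expect_true(sens3$exhaustive)
  expect_equal(sens3$summary$min, sens3$summary$max, tolerance = 1e-12)

  rp4 <- random_panel(3, 4, 12)
  res4 <- compute_ibr(rp4$panel)
  sens4 <- order_sensitivity(res4)
  expect_equal(sens4$summary$n_orderings[1], 3L)
  # brute force over all 4! orderings gives the same min/max
  all_perms <- expand.grid(rep(list(1:4), 4))
  all_perms <- all_perms[apply(all_perms, 1, function(r) length(unique(r)) == 4), ]
  vals <- apply(all_perms, 1, function(o) star_area(res4$S[1, as.integer(o)]))
  expect_lte(length(unique(round(vals, 10))), 3L)
  expect_equal(sens4$summary$min[1], min(vals), tolerance = 1e-12)
  expect_equal(sens4$summary$max[1], max(vals), tolerance = 1e-12)

  # sampled mode is deterministic given the seed
  rp8 <- random_panel(2, 8, 13)
  res8 <- compute_ibr(rp8$panel)
  s1 <- order_sensitivity(res8, n_permutations = 50, seed = 7)
  s2 <- order_sensitivity(res8, n_permutations = 50, seed = 7)
  expect_false(s1$exhaustive)
  expect_identical(s1$summary, s2$summary)
})
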