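test_that("panel generation is deterministic and noise-free when asked", {
  sp0 <- panel_spec(noise_sd = 0, seed = 5)
  g1 <- generate_panel(sp0)
  g2 <- generate_panel(sp0)
  expect_identical(g1, g2)

  # delta = 0 and no noise: all groups identical, downstream index 0
  spec_null <- panel_spec(biomarkers = data.frame(
    label = c("b1", "b2"), direction = c("up", "down"),
    baseline = 1, delta = 0, stringsAsFactors = FALSE),
    noise_sd = 0, seed = 1)
  gnull <- generate_panel(spec_null)
  panel <- build_panel(gnull$table, gnull$directions)
  suppressWarnings(res <- compute_ibr(panel))
  expect_equal(unname(res$ibr_index), rep(0, 3))

  # direction down, no noise: treated mean below control mean
  p <- build_panel(g1$table, g1$directions)
  expect_lt(p$X["toxicant", "PINK1"], p$X["control", "PINK1"])
  expect_gt(p$X["toxicant", "CASP3"], p$X["control", "CASP3"])
  # protected arm sits between control and toxicant by construction
  expect_true(p$X["protected", "PINK1"] < p$X["control", "PINK1"] &&
              p$X["protected", "PINK1"] > p$X["toxicant", "PINK1"])
})

test_that("generated marginal means converge to the specified effects", {
  sp <- panel_spec(n_replicates = 10000, noise_sd = 0.1, seed = 42)
  g <- generate_panel(sp)
  p <- build_panel(g$table, g$directions)
  se <- 0.1 / sqrt(10000)
  # down biomarker, full effect: baseline * (1 - 0.4)
  expect_lt(abs(p$X["toxicant", "PINK1"] - 0.6), 3 * se)
  # up biomarker, half effect: baseline * (1 + 0.4 * 0.5)
  expect_lt(abs(p$X["protected", "CASP3"] - 1.2), 3 * se)
  expect_lt(abs(p$X["control", "ATP"] - 1.0), 3 * se)
})

test_that("overlap sets honor exact planted intersection sizes", {
  sp <- overlap_spec(n_universe = 100, n_a = 30, n_b = 40, k_overlap = 7,
                     seed = 3)
  sets <- generate_overlap_sets(sp)
  expect_length(sets$universe$symbols, 100L)
  expect_equal(venn_counts(sets$a, sets$b)$both, 7L)
  expect_true(all(sets$a$symbols %in% sets$universe$symbols))

  # nested and disjoint extremes
  nested <- generate_overlap_sets(overlap_spec(50, 10, 20, 10, seed = 1))
  expect_equal(venn_counts(nested$a, nested$b)$both, 10L)
  disjoint <- generate_overlap_sets(overlap_spec(50, 10, 20, 0, seed = 1))
  expect_length(intersect_sets(disjoint$a, disjoint$b)$symbols, 0L)

  # infeasible specs refused
  expect_error(overlap_spec(10, 8, 8, 2), "cannot overlap")
  expect_error(overlap_spec(100, 5, 10, 6), "exceeds")
})

test_that("the study-shaped fixture reproduces the published set sizes", {
  sets <- generate_overlap_sets(overlap_spec(20000, 164, 865, 21, seed = 9))
  vc <- venn_counts(sets$a, sets$b)
  expect_equal(vc$both, 21L)
  expect_length(sets$a$symbols, 164L)
  expect_length(sets$b$symbols, 865L)
})

test_that("annotation generation plants exact overlaps deterministically", {
  ann1 <- generate_annotation(seed = 4)
  ann2 <- generate_annotation(seed = 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(ann1$annotation, f1)
  write_gmt(ann2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))

  planted <- ann1$annotation$terms$PLANTED_1
  expect_length(planted$genes, 50L)
  expect_length(intersect(planted$genes, ann1$query$symbols), 20L)

  # maximal plant: overlap = term size = query size ranks first
  ext <- generate_annotation(planted_terms = c(TOP = 12), planted_size = 12,
                             query_size = 12, seed = 2)
  res <- run_ora(ext$query, ext$annotation)
  expect_equal(res$term_id[1], "TOP")

  expect_error(generate_annotation(planted_terms = c(T = 60),
                                   planted_size = 50),
               "exceeds")
})

test_that("fixture workspace round-trips through the readers", {
  dir <- withr::local_tempdir()
  files <- write_fixtures(dir, seed = 11)
  expect_true(all(file.exists(files)))
  a <- read_gene_list(files[["targets_a"]])
  b <- read_gene_list(files[["targets_b"]])
  expect_equal(venn_counts(a, b)$both, 21L)
  ann <- load_gmt(files[["annotation"]])
  expect_gt(length(ann$terms), 200L - 1L)
  tb <- utils::read.delim(files[["panel"]])
  expect_setequal(unique(tb$group), c("control", "toxicant", "protected"))

  # identical seed reproduces identical bytes
  dir2 <- withr::local_tempdir()
  files2 <- write_fixtures(dir2, seed = 11)
  for (nm in names(files))
    expect_identical(readLines(files[[nm]]), readLines(files2[[nm]]))
})
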