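# Cohort table arithmetic, Spearman correlation, Cohen's kappa, reports.

paper_counts <- list(
  vessels = c(`1` = 16L, `2` = 31L, `3` = 4L, `4` = 1L),
  origin = c(SCP_only = 20L, DVC_only = 26L, both = 6L),
  layers = c(GCC = 23L, INL = 42L, OPL = 31L, ONL = 4L),
  shape = c(saccular = 31L, fusiform = 8L, focal_bulge = 13L),
  orientation = c(parallel = 17L, oblique = 35L))

test_that("the grading table reproduces published-style count arithmetic", {
  df <- records_from_counts(paper_counts$vessels, paper_counts$origin,
                            paper_counts$layers, paper_counts$shape,
                            paper_counts$orientation)
  tb <- build_table(df)
  expect_equal(tb$n_total, 52)
  expect_equal(tb$mean_vessels, 1.8)
  expect_equal(unname(tb$vessel_pct), c(30.8, 59.6, 7.7, 1.9, 0.0))
  expect_equal(unname(tb$shape_pct), c(59.6, 15.4, 25.0))
  expect_equal(unname(tb$layer_pct), c(44.2, 80.8, 59.6, 7.7))
  expect_equal(unname(tb$orientation_pct), c(32.7, 67.3))
  expect_equal(unname(tb$origin_pct[2]), 50.0)
  # marginals survive the reconstruction
  expect_equal(unname(tb$vessel_counts[1:4]), unname(paper_counts$vessels))
  expect_equal(unname(tb$layer_counts), unname(paper_counts$layers))
})

test_that("table building is permutation-invariant and guards empty input", {
  df <- records_from_counts(paper_counts$vessels, paper_counts$origin,
                            paper_counts$layers, paper_counts$shape,
                            paper_counts$orientation)
  set.seed(1)
  tb1 <- build_table(df)
  tb2 <- build_table(df[sample(nrow(df)), ])
  expect_equal(tb1, tb2)
  expect_error(build_table(df[0, ]), "no graded records")

  single <- df[1, ]
  tbs <- build_table(single)
  expect_equal(unname(tbs$origin_pct[tbs$origin_counts > 0]), 100.0)
})

test_that("spearman matches mid-rank hand computation and the t approximation", {
  expect_equal(spearman_corr(1:5, (1:5) * 3 + 2)$rho, 1)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 2, 1))$rho, -1)

  # tie-broken case, hand oracle: ranks x = 1, 2.5, 2.5, 4; y = 1, 3, 2, 4
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearman_corr(x, y)
  expect_equal(got$rho, rho_hand)
  expect_equal(got$rho,
               suppressWarnings(stats::cor.test(x, y,
                                                method = "spearman"))$estimate,
               ignore_attr = TRUE)

  # t approximation against an untied reference case
  set.seed(4)
  a <- rnorm(20); b <- a + rnorm(20, sd = 2)
  got2 <- spearman_corr(a, b)
  rho <- got2$rho
  tval <- rho * sqrt(18 / (1 - rho^2))
  expect_equal(got2$p_value, 2 * stats::pt(-abs(tval), 18))

  expect_false(spearman_corr(c(1, 1, 1), c(1, 2, 3))$defined)
})

test_that("exact permutation p matches the reference implementation", {
  set.seed(2)
  x <- c(3, 1, 4, 1.5, 5); y <- c(2.7, 1.8, 2.9, 0.5, 3.1)
  got <- spearman_corr(x, y, exact = TRUE)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value)
})

test_that("Cohen's kappa handles perfect, chance and hand-computed agreement", {
  a <- c("sacc", "fusi", "bulge", "sacc")
  expect_identical(cohens_kappa(a, a)$kappa, 1.0)
  expect_equal(cohens_kappa(c("A", "A", "B", "B"),
                            c("A", "B", "A", "B"))$kappa, 0)
  # hand calculation: p_o = 2/3, p_e = 4/9, kappa = 0.4
  got <- cohens_kappa(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(got$kappa, 0.4)
  if (requireNamespace("e1071", quietly = TRUE)) {
    ref <- e1071::classAgreement(table(c("A", "A", "B"), c("A", "B", "B")))
    expect_equal(got$kappa, ref$kappa)
  }
  deg <- cohens_kappa(c("A", "A"), c("A", "A"))
  expect_identical(deg$kappa, 1.0)
  expect_true(deg$degenerate)
})

test_that("reports round trip through JSON and CSV", {
  df <- records_from_counts(paper_counts$vessels, paper_counts$origin,
                            paper_counts$layers, paper_counts$shape,
                            paper_counts$orientation)
  tb <- build_table(df)
  dir <- tempfile()
  write_report(tb, list(size_vs_layers = spearman_corr(1:10, c(2:10, 1))),
               cohens_kappa(c("a", "b"), c("a", "b")), dir)
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$table$n_total, 52)
  expect_equal(back$table$mean_vessels, 1.8)
  expect_equal(unlist(back$table$shape_pct), c(saccular = 59.6,
                                               fusiform = 15.4,
                                               focal_bulge = 25.0))
  csv <- utils::read.csv(file.path(dir, "table.csv"))
  expect_equal(csv$count[csv$axis == "shape" & csv$category == "saccular"],
               31)
  # empty correlations serialize without error
  write_report(tb, list(), NULL, dir)
  back2 <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_length(back2$correlations, 0)
})
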