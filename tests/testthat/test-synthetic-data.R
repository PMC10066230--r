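test_that("generation is a pure function of model and seed", {
  truth <- preset_sem("soil")
  a <- generate_from_sem(truth, 6, seed = 42)
  b <- generate_from_sem(truth, 6, seed = 42)
  expect_identical(a$values, b$values)
  c_ <- generate_from_sem(truth, 6, seed = 43)
  expect_false(identical(a$values, c_$values))
  expect_equal(a$group, rep(0:1, each = 6))
  expect_equal(a$values[, "Cmp"], as.numeric(a$group))
})

test_that("edge-free unit-variance model yields near-identity covariance at scale", {
  truth <- ground_truth_sem(c("Cmp", paste0("v", 1:4)), noise = "gaussian")
  d <- generate_from_sem(truth, 5000, seed = 7)
  emp <- stats::cov(d$values[, paste0("v", 1:4)])
  expect_lt(max(abs(emp - diag(4))), 0.05)
})

test_that("chain correlation matches the implied covariance from the SEM engine", {
  truth <- ground_truth_sem(c("Cmp", "Pnb", "S_A"),
                            data.frame(source = c("Cmp", "Pnb"),
                                       target = c("Pnb", "S_A"),
                                       coefficient = c(0.8, 0.5)),
                            noise = "gaussian")
  sigma <- implied_covariance(truth_to_path_model(truth), truth_theta(truth))
  v <- truth_to_path_model(truth)$variables
  pred_corr <- sigma[v == "Cmp", v == "S_A"] /
    sqrt(sigma[v == "Cmp", v == "Cmp"] * sigma[v == "S_A", v == "S_A"])
  d <- generate_from_sem(truth, 5000, seed = 8)
  emp <- stats::cor(d$values[, "Cmp"], d$values[, "S_A"])
  expect_equal(emp, pred_corr, tolerance = 0.05)
})

test_that("every noise family is unit-variance-calibrated; mixture and uniform are non-Gaussian", {
  kurt <- function(z) mean((z - mean(z))^4) / stats::var(z)^2 - 3
  for (fam in c("gaussian", "uniform", "laplace", "gaussian_mixture")) {
    truth <- ground_truth_sem(c("Cmp", "v1"), noise = fam,
                              variances = c(v1 = 2.5))
    d <- generate_from_sem(truth, 50000, seed = 3)
    z <- d$values[, "v1"]
    expect_equal(stats::var(z), 2.5, tolerance = 0.05 * 2.5)
    if (fam %in% c("uniform", "gaussian_mixture"))
      expect_gt(abs(kurt(z)), 0.2)
  }
  expect_error(ground_truth_sem("Cmp", noise = "cauchy"))
  expect_error(ground_truth_sem(c("Cmp", "a"), variances = c(a = -1)),
               "variances")
  expect_error(ground_truth_sem(c("Cmp", "a"),
                                data.frame(source = "a", target = "Cmp",
                                           coefficient = 1)),
               "no parents")
})

test_that("taxa generator produces closed compositions responding to multipliers", {
  cfg <- list(taxa = paste0("g", 1:8), baseline = rep(3, 8),
              multipliers = c(5, rep(1, 7)), n_control = 6, n_treated = 6)
  tt <- generate_taxa(cfg, seed = 2)
  expect_s3_class(tt, "taxa_table")
  expect_true(all(abs(rowSums(tt) - 1) < 1e-9))
  expect_true(all(tt >= 0))
  grp <- attr(tt, "group")
  hits <- vapply(1:30, function(s) {
    t2 <- generate_taxa(cfg, seed = 100 + s)
    g <- attr(t2, "group")
    mean(t2[g == 1, "g1"]) > mean(t2[g == 0, "g1"])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(generate_taxa(list(taxa = "a", baseline = -1), 1), "positive")
  expect_identical(generate_taxa(cfg, seed = 5), generate_taxa(cfg, seed = 5))
})

test_that("carrot image generator fills the ellipse and round-trips through the mask", {
  img <- generate_carrot_image(c(200, 0, 0), noise_sd = 0, seed = 1)
  fg <- img$mask
  expect_true(all(img$R[fg] == 200) && all(img$G[fg] == 0) && all(img$B[fg] == 0))
  expect_true(all(img$R[!fg] == 255))
  expect_identical(foreground_mask(img), structure(fg, empty = FALSE),
                   ignore_attr = TRUE)
  expect_error(generate_carrot_image(c(0, 0, 300), seed = 1), "\\[0, 255\\]")
  expect_error(generate_carrot_image(c(1, 1, 1),
                                     shape = list(height = 10, width = 10,
                                                  cx = 5, cy = 5, rx = 9, ry = 2),
                                     seed = 1),
               "canvas")
})

test_that("taste-count generator is multinomial with the configured marginals", {
  tab <- generate_taste_counts(c(1, 0, 0, 0), c(1, 0, 0, 0),
                               n_raters = c(4, 8), seed = 1)
  expect_equal(dim(tab), c(2, 4))
  expect_equal(sum(tab[, 1]), 12)
  expect_equal(sum(tab[, -1]), 0)
  expect_equal(rowSums(generate_taste_counts(rep(0.25, 4), rep(0.25, 4),
                                             n_raters = 4, n_attributes = 3,
                                             seed = 2)),
               c(control = 12, compost = 12))
  expect_identical(generate_taste_counts(rep(0.25, 4), rep(0.25, 4), 8, seed = 9),
                   generate_taste_counts(rep(0.25, 4), rep(0.25, 4), 8, seed = 9))
  expect_error(generate_taste_counts(c(0.5, 0.5, 0.5, 0), rep(0.25, 4), 4),
               "sum to 1")
})

test_that("taste chi-square p-values are uniform under the null", {
  p <- rep(0.25, 4)
  pv <- vapply(1:200, function(s) {
    tab <- generate_taste_counts(p, p, n_raters = 40, seed = s)
    suppressWarnings(chisq_independence(tab)$p_value)
  }, 0)
  ks <- max(abs(sort(pv) - (seq_along(pv) - 0.5) / length(pv)))
  expect_lt(ks, 0.1)
})

test_that("omics TSV round-trips with annotations", {
  d <- generate_from_sem(preset_sem("leaf"), 5, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_omics_tsv(d, f)
  d2 <- read_omics_tsv(f)
  expect_equal(d2$values, d$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(d2$group, d$group)
  expect_identical(d2$compartment, d$compartment)
  expect_identical(d2$category, d$category)
})
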