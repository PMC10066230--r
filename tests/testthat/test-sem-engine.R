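test_that("model syntax parses, rejects cycles and duplicates, and round-trips", {
  m <- parse_model("L_DPP ~ L_AA + L_Fav")
  expect_equal(nrow(m$regressions), 2)
  expect_setequal(m$regressions$predictor, c("L_AA", "L_Fav"))
  expect_error(parse_model("a ~ b\nb ~ a"), "cycle")
  expect_error(parse_model("a ~ b\na ~ b"), "duplicate")
  expect_error(parse_model("a ~ b", variables = c("a")), "undeclared|unknown")
  m2 <- parse_model("variables: Cmp x y\nx ~ Cmp\ny ~ x\nx ~~ y")
  expect_identical(serialize_model(parse_model(serialize_model(m2))),
                   serialize_model(m2))
  # over-parameterised models are refused
  expect_error(parse_model("x ~ y\ny ~~ x"), "over-parameterised")
})

test_that("implied covariance reproduces closed forms", {
  m <- parse_model("variables: a b c")
  expect_equal(implied_covariance(m, c(1, 1, 1)), diag(3),
               ignore_attr = TRUE)
  chain <- parse_model("y ~ x")
  sigma <- implied_covariance(chain, c(0.5, 1, 1))  # coef, var(y)=psi, var(x)
  # layout: coefficients, then variances in variable order (y first: it
  # appears first in the declarations)
  v <- chain$variables
  expect_equal(sigma[v == "x", v == "x"], 1)
  expect_equal(sigma[v == "x", v == "y"], 0.5)
  expect_equal(sigma[v == "y", v == "y"], 1.25)
  expect_error(implied_covariance(chain, c(0.5, 1)), "length")
})

test_that("implied covariance agrees with Monte-Carlo simulation of a random DAG", {
  truth <- random_truth(4, seed = 21)
  pm <- truth_to_path_model(truth)
  theta <- truth_theta(truth)
  sigma <- implied_covariance(pm, theta)
  d <- generate_from_sem(truth, 100000, seed = 22)
  emp <- stats::cov(dataset_values(d)[, pm$variables])
  expect_lt(max(abs(emp - sigma[pm$variables, pm$variables])), 0.02)
})

test_that("saturated model fits any PD covariance exactly (F=0, chi^2=0, df=0)", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), 200, dimnames = list(NULL, letters[1:4]))
  X[, 2] <- X[, 1] * 0.5 + X[, 2]
  fit <- sem_fit(saturated_model(letters[1:4]), data = X)
  expect_true(fit$converged)
  expect_equal(fit$df, 0)
  expect_lt(fit$fml, 1e-8)
  expect_lt(max(abs(fit$implied_sigma - fit$S)), 1e-4)
  ix <- fit_indices(fit)
  expect_equal(ix$chisq, (fit$n - 1) * fit$fml)
  expect_true(ix$saturated)
  expect_lt(ix$srmr, 1e-5)
  expect_equal(ix$gfi, 1, tolerance = 1e-6)
  expect_true(is.na(ix$tli) && is.na(ix$rmsea) && is.na(ix$agfi))
})

test_that("chain-model coefficients are recovered from simulated data", {
  truth <- chain_truth(0.8, 0.5)
  d <- generate_from_sem(truth, 5000, seed = 31)
  fit <- sem_fit(truth_to_path_model(truth), data = d)
  expect_true(fit$converged)
  est <- coef(fit)
  expect_equal(unname(est["x~Cmp"]), 0.8, tolerance = 0.08)
  expect_equal(unname(est["y~x"]), 0.5, tolerance = 0.05)
  # standardized coefficient equals raw * sd(x)/sd(y) on the implied scale
  sds <- sqrt(diag(fit$implied_sigma))
  expect_equal(unname(coef(fit, standardized = TRUE)["y~x"]),
               unname(est["y~x"] * sds["x"] / sds["y"]))
})

test_that("numeric ML solution agrees with equation-wise OLS on random models", {
  for (s in 1:5) {
    truth <- random_truth(4, seed = 40 + s)
    pm <- truth_to_path_model(truth)
    d <- generate_from_sem(truth, 150, seed = 140 + s)
    X <- as.data.frame(dataset_values(d)[, pm$variables])
    fit <- sem_fit(pm, data = X, starts = "neutral")
    expect_true(fit$converged)
    for (yv in unique(pm$regressions$outcome)) {
      xs <- pm$regressions$predictor[pm$regressions$outcome == yv]
      ols <- stats::lm(stats::reformulate(xs, yv), data = X)
      for (xv in xs)
        expect_equal(unname(coef(fit)[paste0(yv, "~", xv)]),
                     unname(stats::coef(ols)[xv]), tolerance = 1e-4)
    }
  }
})

test_that("F_ML is invariant to variable reordering and beta to rescaling", {
  truth <- random_truth(4, seed = 61)
  pm <- truth_to_path_model(truth)
  d <- dataset_values(generate_from_sem(truth, 200, seed = 62))[, pm$variables]
  f1 <- sem_fit(pm, data = d)
  perm <- rev(pm$variables)
  pm2 <- path_model(perm, regressions = pm$regressions)
  f2 <- sem_fit(pm2, data = d[, perm])
  expect_equal(f1$fml, f2$fml, tolerance = 1e-6)
  # rescale one variable by a positive constant: standardized beta unchanged
  v <- pm$regressions$outcome[1]
  d3 <- d; d3[, v] <- d3[, v] * 7
  f3 <- sem_fit(pm, data = d3)
  expect_equal(unname(f1$standardized), unname(f3$standardized),
               tolerance = 1e-5)
})

test_that("nested models never fit better than their supersets", {
  truth <- chain_truth(0.7, 0.6)
  d <- generate_from_sem(truth, 100, seed = 77)
  small <- parse_model("variables: Cmp x y\nx ~ Cmp\ny ~ x")
  big <- parse_model("variables: Cmp x y\nx ~ Cmp\ny ~ x + Cmp")
  f_small <- sem_fit(small, data = d)
  f_big <- sem_fit(big, data = d)
  expect_gte((f_small$n - 1) * f_small$fml + 1e-6,
             (f_big$n - 1) * f_big$fml)
})

test_that("fit indices reproduce the hand-derived toy and the RMSEA zero point", {
  # construct a fit with T = 10, df = 5, and a 5x5 equicorrelated S whose
  # independence-baseline discrepancy is exactly 1, so T_b = 100, df_b = 10
  # at n = 101
  p <- 5
  fb <- function(r) -log((1 - r)^(p - 1) * (1 + (p - 1) * r))
  r <- stats::uniroot(function(r) fb(r) - 1, c(0.01, 0.9), tol = 1e-14)$root
  S <- matrix(r, p, p); diag(S) <- 1
  fake <- structure(list(S = S, n = 101, fml = 10 / 100, df = 5,
                         implied_sigma = S, converged = TRUE,
                         model = parse_model(paste("variables:",
                                                   paste(letters[1:5], collapse = " ")))),
                    class = "sem_fit")
  ix <- fit_indices(fake)
  expect_equal(ix$chisq, 10)
  expect_equal(ix$baseline_chisq, 100, tolerance = 1e-9)
  expect_equal(ix$baseline_df, 10)
  expect_equal(round(ix$cfi, 4), 0.9444)
  expect_equal(round(ix$tli, 4), 0.8889)
  expect_equal(ix$rmsea, 0.1)
  # package path: T == df gives RMSEA 0 on a real fit
  truth <- chain_truth()
  d <- generate_from_sem(truth, 400, seed = 9)
  fit <- sem_fit(truth_to_path_model(truth), data = d)
  ix2 <- fit_indices(fit)
  expect_gte(ix2$rmsea, 0)
  expect_lte(ix2$cfi, 1)
  expect_gte(ix2$srmr, 0)
  expect_identical(ix2$p_value, chisq_tail(ix2$chisq, ix2$df))
})

test_that("simulate/residuals/summary methods are coherent", {
  truth <- chain_truth()
  d <- generate_from_sem(truth, 300, seed = 13)
  fit <- sem_fit(truth_to_path_model(truth), data = d)
  sim <- simulate(fit, seed = 1, n = 5000)
  expect_equal(dim(sim), c(5000, 3))
  expect_lt(max(abs(stats::cov(sim) - fit$implied_sigma)), 0.15)
  expect_equal(residuals(fit), fit$S - fit$implied_sigma)
  s <- summary(fit)
  expect_s3_class(s, "summary.sem_fit")
  expect_true(all(is.finite(s$parameters$estimate)))
})
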