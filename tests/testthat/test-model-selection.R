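test_that("candidate enumeration matches brute-force DAG counts", {
  # pool {Cmp, A}: only edge Cmp->A possible -> present/absent
  expect_length(enumerate_candidates(c("Cmp", "A")), 2)
  # pool of 3 with treatment exogenous: subsets of {Cmp->A, Cmp->B, A->B,
  # B->A} without the 2-cycle = 16 - 4 = 12
  cands <- enumerate_candidates(c("Cmp", "A", "B"))
  expect_length(cands, 12)
  # brute force: count acyclic labeled digraphs on {A, B} x {Cmp edges}
  brute <- 0
  for (m in 0:15) {
    e <- c(bitwAnd(m, 1) > 0, bitwAnd(m, 2) > 0,   # Cmp->A, Cmp->B
           bitwAnd(m, 4) > 0, bitwAnd(m, 8) > 0)   # A->B, B->A
    if (!(e[3] && e[4])) brute <- brute + 1
  }
  expect_equal(length(cands), brute)
  # 4-variable pool: 8 treatment-edge subsets x 25 DAGs on 3 nodes
  expect_length(enumerate_candidates(c("Cmp", "a", "b", "c")), 200)
})

test_that("constraints only shrink the candidate set and order restricts to forward edges", {
  full <- enumerate_candidates(c("Cmp", "A", "B"))
  forb <- enumerate_candidates(c("Cmp", "A", "B"),
                               forbidden = data.frame(source = "A", target = "B"))
  expect_lte(length(forb), length(full))
  ordered <- enumerate_candidates(c("Cmp", "A", "B"), order = c("Cmp", "A", "B"))
  expect_length(ordered, 8)   # subsets of 3 forward edges
  capped <- enumerate_candidates(c("Cmp", "A", "B"), max_edges = 1)
  expect_true(all(vapply(capped, function(m) nrow(m$regressions), 0L) <= 1))
  expect_error(enumerate_candidates(c("Cmp", paste0("v", 1:6))), "max_edges")
})

test_that("a single converged candidate wins trivially and duplicates break ties deterministically", {
  truth <- chain_truth()
  d <- generate_from_sem(truth, 100, seed = 3)
  pm <- truth_to_path_model(truth)
  fits <- fit_candidates(list(pm), data = d)
  rk <- rank_models(fits)
  expect_equal(rk$winner, 1)
  fits2 <- fit_candidates(list(pm, pm), data = d)
  rk2 <- rank_models(fits2)
  expect_equal(rk2$winner, 1)   # first of the identical pair, stably
  expect_setequal(rk2$table$rank, 1:2)
})

test_that("composite ranking is invariant to candidate input order", {
  truth <- preset_sem("soil", noise = "gaussian")
  d <- generate_from_sem(truth, 300, seed = 11)
  cands <- enumerate_candidates(c("Cmp", "Pnb", "S_A", "S_N"), max_edges = 2)
  fits <- fit_candidates(cands, data = d)
  rk1 <- rank_models(fits)
  perm <- rev(seq_along(fits))
  rk2 <- rank_models(fits[perm])
  expect_identical(serialize_model(ranking_winner(rk1)$model),
                   serialize_model(ranking_winner(rk2)$model))
  t1 <- rk1$table[order(rk1$table$model), c("model", "rank")]
  t2 <- rk2$table[order(rk2$table$model), c("model", "rank")]
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("a candidate dominating every index ranks first under the pure index vote", {
  mk <- function(cfi, tli, rmsea, srmr, gfi, agfi, p, nedg) {
    vars <- c("Cmp", "a", "b", "c")
    reg <- data.frame(outcome = c("a", "b", "c")[seq_len(nedg)],
                      predictor = rep("Cmp", nedg))
    model <- path_model(vars, regressions = reg)
    fit <- structure(list(model = model, converged = TRUE, df = 2,
                          n = 100), class = "sem_fit")
    ix <- structure(list(chisq = 1, df = 2, p_value = p, cfi = cfi, tli = tli,
                         rmsea = rmsea, srmr = srmr, gfi = gfi, agfi = agfi,
                         baseline_chisq = 50, baseline_df = 6,
                         saturated = FALSE), class = "fit_indices")
    list(model = model, fit = fit, indices = ix)
  }
  dominant <- mk(0.99, 0.99, 0.01, 0.01, 0.99, 0.99, 0.9, 1)
  weaker <- mk(0.90, 0.85, 0.10, 0.06, 0.93, 0.90, 0.3, 2)
  rk <- rank_models(list(weaker, dominant), method = "mean_rank")
  expect_equal(rk$winner, 2)
})

test_that("the generating model is recovered by the default ranking at moderate scale", {
  truth <- preset_sem("soil", noise = "gaussian")
  true_txt <- serialize_model(truth_to_path_model(truth))
  cands <- enumerate_candidates(c("Cmp", "Pnb", "S_A", "S_N"))
  wins <- vapply(1:10, function(s) {
    d <- generate_from_sem(truth, 1000, seed = 500 + s)
    rk <- rank_models(fit_candidates(cands, data = d))
    serialize_model(ranking_winner(rk)$model) == true_txt
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("saturated candidates rank after testable ones and failures error out", {
  truth <- chain_truth()
  d <- generate_from_sem(truth, 150, seed = 19)
  pm <- truth_to_path_model(truth)
  sat <- saturated_model(pm$variables)
  fits <- fit_candidates(list(sat, pm), data = d)
  rk <- rank_models(fits)
  expect_equal(serialize_model(ranking_winner(rk)$model), serialize_model(pm))
  expect_error(rank_models(list(list(model = pm, fit = NULL, indices = NULL))),
               "no candidate converged")
})
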