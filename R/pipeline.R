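#' Default pipeline configuration
#'
#' All thresholds of the multi-stage analysis in one place; every value is
#' recorded verbatim in the run report.
#'
#' @param seed integer master seed.
#' @param out_dir output directory for stage artifacts.
#' @param preset synthetic preset for the simulate stage (`"soil"`,
#'   `"leaf"`, `"root"`; alias `"fig5c"` = `"soil"`) — ignored when
#'   `input_tsv` is given.
#' @param input_tsv optional path to an existing [write_omics_tsv()] table;
#'   replaces the simulate stage.
#' @param n_per_group samples per arm for the simulate stage.
#' @param stages character vector of enabled stages, in pipeline order,
#'   among: simulate, screen, associate, sem, mediate, lingam.
#' @param pinned variables always included in the SEM pool (the analyst's
#'   prior-knowledge picks joined with the association-selected features).
#' @param scheme,min_support,min_confidence,lift_threshold association-rule
#'   stage settings.
#' @param max_pool maximum SEM pool size including the treatment (default 4:
#'   keeps the exhaustive candidate enumeration and the downstream DAG
#'   posterior tractable; raise to at most 6 for larger pools).
#' @param rank_method,rank_digits model-ranking settings (see
#'   [rank_models()]).
#' @param n_sims mediation simulation draws.
#' @param treatment treatment variable name.
#' @return named list (class `run_config`).
#' @export
run_config <- function(seed = 1, out_dir = tempfile("compostsem_run_"),
                       preset = "soil", input_tsv = NULL, n_per_group = 6,
                       stages = c("simulate", "screen", "associate", "sem",
                                  "mediate", "lingam"),
                       pinned = character(0), scheme = "median_split",
                       min_support = 0.2, min_confidence = 0.5,
                       lift_threshold = 1.0, max_pool = 4,
                       rank_method = "parsimonious_fit", rank_digits = 3,
                       n_sims = 1000, treatment = "Cmp") {
  structure(list(seed = as.integer(seed), out_dir = out_dir, preset = preset,
                 input_tsv = input_tsv, n_per_group = n_per_group,
                 stages = stages, pinned = pinned, scheme = scheme,
                 min_support = min_support, min_confidence = min_confidence,
                 lift_threshold = lift_threshold, max_pool = max_pool,
                 rank_method = rank_method, rank_digits = rank_digits,
                 n_sims = n_sims, treatment = treatment),
            class = "run_config")
}

config_fingerprint <- function(config)
  paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")

#' Run the full inference pipeline
#'
#' Executes the enabled stages in order — simulate (or load), univariate
#' screen, association-rule feature selection, SEM candidate
#' enumeration/fitting/ranking, mediation over the winner's 2-paths, and
#' BayesLiNGAM edge ranking over a treatment-anchored sub-pool of the winner
#' — writing every stage's outputs under `config$out_dir` and returning a
#' run report. Identical config + seed reproduces identical outputs. A rerun
#' over an existing output directory with an unchanged config skips stages
#' whose outputs are already on disk; a stage failure marks the stage failed
#' in the report and skips dependent stages.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `config` (thresholds
#'   verbatim), `stages` (per-stage status: done/skipped/cached/failed),
#'   `winner` (model text), `indices`, `mediation` (data.frame), `edges`
#'   (LiNGAM edge ranking), `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp_path <- file.path(config$out_dir, "config.txt")
  fp <- config_fingerprint(config)
  reuse <- file.exists(fp_path) && identical(paste(readLines(fp_path),
                                                   collapse = "\n"), fp)
  writeLines(fp, fp_path)
  status <- list(); files <- list()
  report <- list(config = unclass(config), stages = NULL, winner = NULL,
                 indices = NULL, mediation = NULL, edges = NULL, files = NULL)
  enabled <- function(s) s %in% config$stages
  pth <- function(f) file.path(config$out_dir, f)
  cached <- function(fs) reuse && all(file.exists(vapply(fs, pth, "")))
  run_stage <- function(name, outputs, fun) {
    if (!enabled(name)) { status[[name]] <<- "disabled"; return(NULL) }
    if (cached(outputs)) { status[[name]] <<- "cached" }
    else {
      ok <- tryCatch({ fun(); TRUE },
                     error = function(e) { status[[name]] <<- paste("failed:",
                       conditionMessage(e)); FALSE })
      if (!ok) return(NULL)
      status[[name]] <<- "done"
    }
    files[[name]] <<- vapply(outputs, pth, "")
    TRUE
  }

  dataset <- NULL
  ok <- run_stage("simulate", "dataset.tsv", function() {
    ds <- if (!is.null(config$input_tsv)) read_omics_tsv(config$input_tsv)
    else generate_from_sem(preset_sem(config$preset), config$n_per_group,
                           seed = config$seed)
    write_omics_tsv(ds, pth("dataset.tsv"))
  })
  if (identical(status$simulate, "done") || identical(status$simulate, "cached"))
    dataset <- tryCatch(read_omics_tsv(pth("dataset.tsv")),
                        error = function(e) NULL)

  run_stage("screen", "screen.tsv", function() {
    if (is.null(dataset)) stop("no dataset (simulate stage missing)")
    utils::write.table(screen_dataset(dataset), pth("screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage("associate", c("rules.tsv", "pool.json"), function() {
    if (is.null(dataset)) stop("no dataset (simulate stage missing)")
    tx <- discretize(dataset, scheme = config$scheme)
    rules <- mine_rules(tx, min_support = config$min_support,
                        min_confidence = config$min_confidence)
    utils::write.table(rules, pth("rules.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sel <- if (nrow(rules)) select_high_lift(rules,
                                             lift_threshold = config$lift_threshold)
    else character(0)
    pool <- unique(c(config$treatment, config$pinned, sel))
    pool <- intersect(pool, c(colnames(dataset$values), config$treatment))
    pool <- utils::head(pool, config$max_pool)
    jsonlite::write_json(pool, pth("pool.json"))
  })

  ranking <- NULL
  run_stage("sem", c("ranking.tsv", "winner.txt"), function() {
    pool <- if (file.exists(pth("pool.json")))
      unlist(jsonlite::read_json(pth("pool.json"), simplifyVector = TRUE))
    else unique(c(config$treatment, config$pinned))
    if (length(pool) < 2) stop("SEM pool has fewer than 2 variables")
    cands <- enumerate_candidates(pool, treatment = config$treatment)
    fits <- fit_candidates(cands, data = dataset)
    rk <- rank_models(fits, method = config$rank_method,
                      digits = config$rank_digits)
    ranking <<- rk
    write_ranking_tsv(rk, pth("ranking.tsv"))
    writeLines(serialize_model(ranking_winner(rk)$model), pth("winner.txt"))
  })
  winner_model <- if (!is.null(ranking)) ranking_winner(ranking)$model
  else if (identical(status$sem, "cached") && file.exists(pth("winner.txt")))
    parse_model(paste(readLines(pth("winner.txt")), collapse = "\n"))
  else NULL

  run_stage("mediate", "mediation.tsv", function() {
    if (is.null(winner_model)) stop("no winning model (sem stage missing)")
    med <- mediate_model_paths(winner_model, dataset,
                               treatment = config$treatment,
                               n_sims = config$n_sims, seed = config$seed)
    utils::write.table(med, pth("mediation.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  run_stage("lingam", c("lingam_edges.tsv", "lingam_hypotheses.tsv"),
            function() {
    if (is.null(winner_model)) stop("no winning model (sem stage missing)")
    vars <- winner_model$variables
    if (length(vars) > 4) {       # treatment-anchored sub-pool
      endo <- setdiff(vars, config$treatment)
      vars <- c(config$treatment, utils::head(endo, 3))
    }
    post <- posterior_over_dags(dataset, vars)
    utils::write.table(post$edges, pth("lingam_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(post$hypotheses, pth("lingam_hypotheses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  report$stages <- status
  report$files <- files
  if (!is.null(winner_model)) {
    report$winner <- serialize_model(winner_model)
    if (!is.null(ranking)) {
      w <- ranking_winner(ranking)
      if (!is.null(w$indices)) report$indices <- indices_row(w$indices)
    }
  }
  if (file.exists(pth("mediation.tsv")) && !is.null(files$mediate))
    report$mediation <- utils::read.table(pth("mediation.tsv"), sep = "\t",
                                          header = TRUE)
  if (file.exists(pth("lingam_edges.tsv")) && !is.null(files$lingam))
    report$edges <- utils::read.table(pth("lingam_edges.tsv"), sep = "\t",
                                      header = TRUE)
  class(report) <- "run_report"
  jsonlite::write_json(
    list(config = unclass(config), stages = status,
         winner = report$winner, indices = as.list(report$indices)),
    pth("report.json"), auto_unbox = TRUE, digits = NA, null = "null",
    force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ")\n", sep = "")
  for (s in names(x$stages)) cat(sprintf("  %-10s %s\n", s, x$stages[[s]]))
  if (!is.null(x$winner)) {
    cat("Winning model:\n  ", gsub("\n", "\n  ", x$winner), "\n", sep = "")
    if (!is.null(x$indices))
      cat(sprintf("  chi^2 = %.3f (df %d), CFI %.3f, RMSEA %.3f, SRMR %.3f\n",
                  x$indices["chisq"], x$indices["df"], x$indices["cfi"],
                  x$indices["rmsea"], x$indices["srmr"]))
  }
  if (!is.null(x$edges)) {
    cat("Top LiNGAM edges:\n")
    print(utils::head(x$edges, 6), digits = 3, row.names = FALSE)
  }
  invisible(x)
}
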