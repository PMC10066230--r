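#' Ground-truth structural model for the synthetic generator
#'
#' Describes a recursive linear system with a binary treatment node (the
#' compost arm indicator) and a configurable disturbance family, from which
#' multi-omics-like sample tables are drawn. The treatment node has no
#' parents and is generated as a fixed 0/1 design column, not sampled.
#'
#' @param variables variable names; must include `treatment`.
#' @param edges data.frame with columns `source`, `target`, `coefficient`.
#' @param variances named numeric vector: exogenous variance for source-only
#'   variables, disturbance variance for endogenous ones. Defaults to 1 for
#'   every non-treatment variable. All must be positive.
#' @param noise one of `"gaussian"`, `"uniform"`, `"laplace"`,
#'   `"gaussian_mixture"`. All families are standardized to unit variance and
#'   then scaled by `sqrt(variance)`; the mixture (components at means +-1,
#'   sd 0.5, equal weights, then standardized) and the uniform are
#'   non-Gaussian with nonzero excess kurtosis, which is what makes causal
#'   direction identifiable downstream.
#' @param treatment name of the binary exposure node (default `"Cmp"`).
#' @param compartments,categories optional named character vectors of
#'   per-variable annotations carried into generated datasets.
#' @return object of class `ground_truth_sem`.
#' @export
ground_truth_sem <- function(variables, edges = NULL, variances = NULL,
                             noise = c("gaussian", "uniform", "laplace",
                                       "gaussian_mixture"),
                             treatment = "Cmp",
                             compartments = NULL, categories = NULL) {
  noise <- match.arg(noise)
  variables <- as.character(variables)
  if (!treatment %in% variables) stop("treatment variable not in variables")
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        coefficient = numeric(), stringsAsFactors = FALSE)
  edges <- data.frame(source = as.character(edges[[1]]),
                      target = as.character(edges[[2]]),
                      coefficient = as.numeric(edges[[3]]),
                      stringsAsFactors = FALSE)
  if (any(edges$target == treatment)) stop("treatment variable must have no parents")
  ord <- topological_order(variables,
                           data.frame(outcome = edges$target, predictor = edges$source))
  vr <- setdiff(variables, treatment)
  v <- rep(1, length(vr)); names(v) <- vr
  if (!is.null(variances)) {
    bad <- setdiff(names(variances), variables)
    if (length(bad)) stop("variance for unknown variable: ", paste(bad, collapse = ", "))
    v[intersect(names(variances), vr)] <- variances[intersect(names(variances), vr)]
  }
  if (any(v <= 0)) stop("all variances must be > 0")
  structure(list(variables = variables, edges = edges, variances = v,
                 noise = noise, treatment = treatment, order = ord,
                 compartments = compartments, categories = categories),
            class = "ground_truth_sem")
}

# unit-variance disturbance draws per family
draw_noise <- function(family, n) {
  switch(family,
    gaussian = stats::rnorm(n),
    uniform  = stats::runif(n, -sqrt(3), sqrt(3)),
    laplace  = {                       # inverse CDF; var(Laplace(b)) = 2 b^2
      u <- stats::runif(n) - 0.5
      -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
    },
    gaussian_mixture = {               # means +-1, sd 0.5, equal weights
      comp <- stats::rbinom(n, 1, 0.5)
      x <- stats::rnorm(n, mean = ifelse(comp == 1, 1, -1), sd = 0.5)
      x / sqrt(1.25)
    },
    stop("unknown noise family: ", family))
}

#' Convert a ground-truth model to an equivalent `path_model`
#' @param truth a `ground_truth_sem`.
#' @return the `path_model` with the same directed edges (all variances free).
#' @export
truth_to_path_model <- function(truth) {
  path_model(truth$variables,
             regressions = if (nrow(truth$edges))
               data.frame(outcome = truth$edges$target,
                          predictor = truth$edges$source,
                          stringsAsFactors = FALSE))
}

#' Parameter vector of a ground-truth model in `path_model` layout
#'
#' The treatment column is a balanced 0/1 design, so its population variance
#' is 1/4; that value fills the treatment's variance slot so that
#' [implied_covariance()] of the ground truth predicts the large-sample
#' covariance of generated data.
#' @param truth a `ground_truth_sem`.
#' @return named numeric vector matching `truth_to_path_model(truth)`.
#' @export
truth_theta <- function(truth) {
  pm <- truth_to_path_model(truth)
  v <- truth$variances
  allv <- c(v, stats::setNames(0.25, truth$treatment))[pm$variables]
  c(truth$edges$coefficient, allv)
}

#' Generate a sample-by-feature dataset from a ground-truth model
#'
#' Samples `2 * n_per_group` rows: the first `n_per_group` are controls
#' (treatment = 0), the rest compost-amended (treatment = 1). Every other
#' variable is the coefficient-weighted sum of its parents plus a disturbance
#' drawn from the model's noise family, scaled to the declared variance.
#' Fully deterministic given (`model`, `n_per_group`, `seed`).
#'
#' @param model a `ground_truth_sem`.
#' @param n_per_group samples per arm (>= 2).
#' @param seed integer seed.
#' @return an [omics_dataset()].
#' @export
generate_from_sem <- function(model, n_per_group, seed) {
  stopifnot(inherits(model, "ground_truth_sem"))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  set.seed(as.integer(seed))
  n <- 2L * as.integer(n_per_group)
  group <- rep(c(0L, 1L), each = n_per_group)
  vals <- matrix(0, n, length(model$variables),
                 dimnames = list(NULL, model$variables))
  vals[, model$treatment] <- group
  for (v in model$order) {            # disturbances drawn in topological order
    if (v == model$treatment) next
    e <- model$edges[model$edges$target == v, , drop = FALSE]
    mu <- if (nrow(e)) as.vector(vals[, e$source, drop = FALSE] %*% e$coefficient) else 0
    vals[, v] <- mu + sqrt(model$variances[v]) * draw_noise(model$noise, n)
  }
  comp <- rep("soil", length(model$variables))
  names(comp) <- model$variables
  comp[model$treatment] <- "growth"
  if (!is.null(model$compartments)) comp[names(model$compartments)] <- model$compartments
  catg <- rep("metabolite", length(model$variables))
  names(catg) <- model$variables
  catg[model$treatment] <- "treatment"
  if (!is.null(model$categories)) catg[names(model$categories)] <- model$categories
  omics_dataset(values = vals,
                sample_ids = sprintf("S%02d", seq_len(n)),
                group = group, compartment = comp, category = catg)
}

#' Generate a compositional taxa table with treatment-responsive taxa
#'
#' Per-sample proportions are drawn from a Dirichlet law (normalized gammas).
#' For treated samples the concentration of each taxon is its baseline times
#' its multiplier, so multipliers > 1 emulate compost-responsive genera such
#' as the *Paenibacillus*-like node.
#'
#' @param config list with `taxa` (names), `baseline` (positive concentration
#'   per taxon), `multipliers` (per-taxon treatment multiplier, default 1),
#'   `n_control`, `n_treated` (defaults 6 and 6), `rank` ("genus" or
#'   "phylum").
#' @param seed integer seed.
#' @return a [taxa_table()] with a `group` attribute (0/1 per sample).
#' @export
generate_taxa <- function(config, seed) {
  taxa <- config$taxa
  base <- rep_len(config$baseline, length(taxa))
  mult <- rep_len(if (is.null(config$multipliers)) 1 else config$multipliers,
                  length(taxa))
  if (any(base <= 0) || any(base * mult <= 0))
    stop("concentration parameters must be positive")
  n0 <- if (is.null(config$n_control)) 6L else as.integer(config$n_control)
  n1 <- if (is.null(config$n_treated)) 6L else as.integer(config$n_treated)
  rank <- if (is.null(config$rank)) "genus" else config$rank
  set.seed(as.integer(seed))
  draw <- function(alpha, n) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
    g / rowSums(g)
  }
  ab <- rbind(draw(base, n0), draw(base * mult, n1))
  colnames(ab) <- taxa
  tt <- taxa_table(ab, sample_ids = sprintf("S%02d", seq_len(n0 + n1)), rank = rank)
  attr(tt, "group") <- rep(c(0L, 1L), c(n0, n1))
  tt
}

#' Generate a synthetic root photograph (ellipse on white board)
#'
#' Foreground ellipse filled with clipped Gaussian noise around `mean_rgb`;
#' background pure white (255, 255, 255), emulating the white-board field
#' photos behind the RGB pixel-index analysis.
#'
#' @param mean_rgb length-3 vector of mean intensities in [0, 255].
#' @param noise_sd Gaussian sd of per-pixel intensity noise.
#' @param shape list with `height`, `width`, and ellipse `cx`, `cy`, `rx`,
#'   `ry` (pixel units; defaults to a centered ellipse at 60% of the canvas).
#' @param seed integer seed.
#' @return a `pixel_image`: list of integer matrices `R`, `G`, `B`, a logical
#'   `mask` of the generated foreground, and `background = 255L`.
#' @export
generate_carrot_image <- function(mean_rgb, noise_sd = 0,
                                  shape = list(height = 40, width = 60),
                                  seed = 1) {
  if (any(mean_rgb < 0) || any(mean_rgb > 255)) stop("mean_rgb outside [0, 255]")
  h <- shape$height; w <- shape$width
  cx <- if (is.null(shape$cx)) (w + 1) / 2 else shape$cx
  cy <- if (is.null(shape$cy)) (h + 1) / 2 else shape$cy
  rx <- if (is.null(shape$rx)) 0.3 * w else shape$rx
  ry <- if (is.null(shape$ry)) 0.3 * h else shape$ry
  if (cx - rx < 1 || cx + rx > w || cy - ry < 1 || cy + ry > h)
    stop("ellipse does not fit inside the canvas")
  set.seed(as.integer(seed))
  xs <- matrix(rep(seq_len(w), each = h), h)
  ys <- matrix(rep(seq_len(h), times = w), h)
  mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  chan <- function(mu) {
    m <- matrix(255L, h, w)
    k <- sum(mask)
    v <- if (noise_sd > 0) stats::rnorm(k, mu, noise_sd) else rep(mu, k)
    m[mask] <- as.integer(pmin(pmax(round(v), 0), 255))
    m
  }
  structure(list(R = chan(mean_rgb[1]), G = chan(mean_rgb[2]),
                 B = chan(mean_rgb[3]), mask = mask, background = 255L),
            class = "pixel_image")
}

#' Generate a two-group taste-category contingency table
#'
#' Multinomial rater counts over taste categories per arm (the field survey
#' scored four categories; evaluators may score several attributes each, so
#' the per-arm total is `n_raters * n_attributes`).
#'
#' @param p_control,p_treated probability vectors over categories (sum to 1).
#' @param n_raters raters per group (scalar or length-2 vector
#'   control/treated).
#' @param n_attributes attributes scored per rater (default 1).
#' @param seed integer seed.
#' @param categories optional category names.
#' @return 2 x k integer matrix, rows control/compost.
#' @export
generate_taste_counts <- function(p_control, p_treated, n_raters,
                                  n_attributes = 1, seed = 1,
                                  categories = NULL) {
  if (abs(sum(p_control) - 1) > 1e-8 || abs(sum(p_treated) - 1) > 1e-8)
    stop("probability vectors must sum to 1")
  n_raters <- rep_len(n_raters, 2)
  set.seed(as.integer(seed))
  tot <- n_raters * n_attributes
  tab <- rbind(control = as.vector(stats::rmultinom(1, tot[1], p_control)),
               compost = as.vector(stats::rmultinom(1, tot[2], p_treated)))
  colnames(tab) <- if (is.null(categories))
    paste0("category", seq_along(p_control)) else categories
  tab
}

#' Preset ground-truth models mirroring the field study's compartments
#'
#' Named presets over the study's variable vocabulary (Cmp = compost arm;
#' L_* leaf metabolite panels, R_* root panels, S_* soil metabolites, Pnb a
#' *Paenibacillus*-like genus abundance):
#' \itemize{
#'   \item `"leaf"`: Cmp -> L_AA -> L_Fav -> L_DPP (amino acids feed
#'     flavonoids; leaf radical-scavenging activity responds downstream).
#'   \item `"root"`: Cmp -> R_Phe -> R_Car, Cmp -> R_L2A (phenylalanine as
#'     carotenoid precursor; 2-aminoadipate responding directly).
#'   \item `"soil"` (alias `"fig5c"`): Cmp -> Pnb -> {S_A, S_N} — the
#'     compost-introduced genus mediating soil amino-acid and nitrogen
#'     metabolite shifts.
#' }
#' Path coefficients are 0.5–0.8 on the standardized scale with unit
#' disturbance variances: strong, field-plausible effects that a ~10-sample
#' screen can detect.
#'
#' @param name preset name.
#' @param noise disturbance family (default `"gaussian_mixture"`, so causal
#'   direction is identifiable).
#' @return a `ground_truth_sem`.
#' @export
preset_sem <- function(name = c("soil", "fig5c", "leaf", "root"),
                       noise = "gaussian_mixture") {
  name <- match.arg(name)
  if (name == "fig5c") name <- "soil"
  ed <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2],
               coefficient = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  }
  switch(name,
    leaf = ground_truth_sem(
      c("Cmp", "L_AA", "L_Fav", "L_DPP"),
      ed("Cmp", "L_AA", 0.8, "L_AA", "L_Fav", 0.6, "L_Fav", "L_DPP", -0.6),
      noise = noise,
      compartments = c(L_AA = "leaf", L_Fav = "leaf", L_DPP = "leaf"),
      categories = c(L_AA = "amino_acid", L_Fav = "flavonoid", L_DPP = "activity")),
    root = ground_truth_sem(
      c("Cmp", "R_Phe", "R_Car", "R_L2A"),
      ed("Cmp", "R_Phe", 0.7, "R_Phe", "R_Car", 0.6, "Cmp", "R_L2A", -0.6),
      noise = noise,
      compartments = c(R_Phe = "root", R_Car = "root", R_L2A = "root"),
      categories = c(R_Phe = "amino_acid", R_Car = "carotenoid", R_L2A = "amino_acid")),
    soil = ground_truth_sem(
      c("Cmp", "Pnb", "S_A", "S_N"),
      ed("Cmp", "Pnb", 0.8, "Pnb", "S_A", 0.6, "Pnb", "S_N", 0.5),
      noise = noise,
      compartments = c(Pnb = "taxa", S_A = "soil", S_N = "soil"),
      categories = c(Pnb = "genus_abundance", S_A = "amino_acid", S_N = "nitrogen")))
}

#' Serialize a ground-truth model to JSON (and back)
#'
#' Records variables, edges, variances, noise family and treatment node so a
#' generated dataset can always be traced to its generating structure.
#' @param truth a `ground_truth_sem`.
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(variables = truth$variables, edges = truth$edges,
         variances = as.list(truth$variances), noise = truth$noise,
         treatment = truth$treatment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth_sem(js$variables,
                   edges = if (length(js$edges)) js$edges,
                   variances = unlist(js$variances), noise = js$noise,
                   treatment = js$treatment)
}
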