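#' Model-implied covariance matrix
#'
#' For a recursive path model with coefficient matrix B (B[y, x] = coefficient
#' of x in the equation for y) and disturbance covariance Psi, the implied
#' covariance of the observed variables is
#' \deqn{\Sigma(\theta) = (I - B)^{-1} \Psi (I - B)^{-T}.}
#'
#' @param model a `path_model`.
#' @param theta numeric parameter vector in the model's layout
#'   (coefficients, variances, covariances); see [path_model()].
#' @return p x p implied covariance matrix with dimnames.
#' @export
implied_covariance <- function(model, theta) {
  p <- length(model$variables)
  nb <- nrow(model$regressions); nc <- nrow(model$covariances)
  if (length(theta) != nb + p + nc)
    stop("theta has length ", length(theta), ", expected ", nb + p + nc)
  B <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  if (nb) B[cbind(model$regressions$outcome, model$regressions$predictor)] <- theta[seq_len(nb)]
  Psi <- diag(theta[nb + seq_len(p)], p)
  dimnames(Psi) <- dimnames(B)
  if (nc) {
    idx <- cbind(model$covariances$a, model$covariances$b)
    Psi[idx] <- Psi[idx[, 2:1, drop = FALSE]] <- theta[nb + p + seq_len(nc)]
  }
  IB <- diag(p) - B
  A <- solve(IB)          # exists for any DAG (unit-diagonal triangularizable)
  A %*% Psi %*% t(A)
}

# ML discrepancy F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p.
# Non-PD Sigma is repelled with a smooth-ish barrier so quasi-Newton search
# can recover.
fml_value <- function(model, theta, S, logdetS) {
  Sigma <- implied_covariance(model, theta)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    lam <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    return(1e8 + 1e6 * (1 - min(lam, 0)))
  }
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  logdet + tr - logdetS - nrow(S)
}

# Starting values. "ols": per-equation OLS on the sample moments (the exact
# ML solution when Psi is diagonal), covariance starts at the sample value.
# "neutral": B = 0, variances = diag(S), covariances 0.
sem_start <- function(model, S, kind = c("ols", "neutral"), jitter = 0) {
  kind <- match.arg(kind)
  v <- model$variables
  nb <- nrow(model$regressions); p <- length(v); nc <- nrow(model$covariances)
  beta <- numeric(nb); psi <- diag(S)[v]; cv <- numeric(nc)
  if (kind == "ols") {
    for (y in unique(model$regressions$outcome)) {
      sel <- model$regressions$outcome == y
      xs <- model$regressions$predictor[sel]
      b <- tryCatch(solve(S[xs, xs, drop = FALSE], S[xs, y]),
                    error = function(e) rep(0, length(xs)))
      beta[sel] <- b
      psi[y] <- max(S[y, y] - sum(b * S[xs, y]), 0.05 * S[y, y])
    }
    if (nc) cv <- S[cbind(model$covariances$a, model$covariances$b)]
  }
  th <- c(beta, psi, cv)
  if (jitter != 0) {
    th[seq_len(nb)] <- th[seq_len(nb)] + jitter
    th[nb + seq_len(p)] <- th[nb + seq_len(p)] * (1 + abs(jitter))
  }
  th
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the Wishart ML discrepancy
#' \deqn{F_{ML}(\theta) = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \ln|S| - p}
#' over the free parameters by quasi-Newton (BFGS) search from a ladder of
#' deterministic starts. Returns a classed fit with standardized
#' coefficients, standard errors (inverse Hessian of \eqn{(n-1)/2 \cdot F_{ML}}),
#' and the implied covariance.
#'
#' @param model a `path_model`, or model syntax accepted by [parse_model()].
#' @param data sample-by-variable data: an `omics_dataset`, data.frame or
#'   matrix containing the model's variables as columns. Alternatively pass
#'   `S` and `n` directly.
#' @param S sample covariance matrix (used when `data` is NULL).
#' @param n sample size (required with `S`).
#' @param starts `"auto"` (OLS-seeded start first; further starts only if it
#'   fails to converge), `"neutral"` (zero-coefficient start only), or `"all"`
#'   (run the full 5-start ladder and keep the best).
#' @param se compute standard errors from the numerical Hessian (default TRUE;
#'   skipped automatically when `df == 0` saturation makes them uninteresting
#'   can still be forced).
#' @param reltol convergence tolerance on F_ML passed to the optimizer.
#' @return object of class `sem_fit`: list with elements `model`, `estimates`
#'   (named theta-hat), `standardized` (standardized coefficient per
#'   regression edge), `se`, `n`, `S`, `implied_sigma`, `fml`, `df`,
#'   `converged`, `heywood` (negative variance estimate flag), `n_starts_used`.
#' @export
sem_fit <- function(model, data = NULL, S = NULL, n = NULL,
                    starts = c("auto", "neutral", "all"), se = TRUE,
                    reltol = 1e-12) {
  starts <- match.arg(starts)
  if (is.character(model)) model <- parse_model(model)
  stopifnot(inherits(model, "path_model"))
  v <- model$variables
  if (!is.null(data)) {
    m <- as_variable_matrix(data, v)
    n <- nrow(m)
    S <- stats::cov(m)
  }
  if (is.null(S) || is.null(n)) stop("supply either data or both S and n")
  S <- S[v, v, drop = FALSE]
  p <- length(v)
  if (n <= p) stop("need n > p observed samples (n = ", n, ", p = ", p, ")")
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS))
    stop("sample covariance is not positive definite; consider a ridge (S + eps*I)")
  logdetS <- 2 * sum(log(diag(chS)))
  fn <- function(th) fml_value(model, th, S, logdetS)

  start_list <- switch(starts,
    neutral = list(sem_start(model, S, "neutral")),
    list(sem_start(model, S, "ols"), sem_start(model, S, "neutral"),
         sem_start(model, S, "ols", jitter = 0.25),
         sem_start(model, S, "ols", jitter = -0.25),
         sem_start(model, S, "neutral", jitter = 0.5)))

  best <- NULL; used <- 0L
  for (th0 in start_list) {
    used <- used + 1L
    opt <- tryCatch(
      stats::optim(th0, fn, method = "BFGS",
                   control = list(reltol = reltol, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    converged_now <- !is.null(best) && best$convergence == 0
    if (starts != "all" && converged_now) break
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  nb <- nrow(model$regressions); nc <- nrow(model$covariances)
  names(theta) <- c(
    if (nb) paste0(model$regressions$outcome, "~", model$regressions$predictor),
    paste0("var(", v, ")"),
    if (nc) paste0(model$covariances$a, "~~", model$covariances$b))
  Sigma <- implied_covariance(model, theta)
  dimnames(Sigma) <- list(v, v)
  fml <- max(best$value, 0)

  std <- numeric(nb)
  if (nb) {
    sds <- sqrt(pmax(diag(Sigma), .Machine$double.eps))
    names(sds) <- v
    std <- theta[seq_len(nb)] *
      sds[model$regressions$predictor] / sds[model$regressions$outcome]
    names(std) <- names(theta)[seq_len(nb)]
  }

  ses <- rep(NA_real_, length(theta)); names(ses) <- names(theta)
  if (se) {
    H <- tryCatch(stats::optimHess(best$par, function(th) (n - 1) / 2 * fn(th)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
      if (!is.null(Hi)) {
        d <- diag(Hi)
        ses[d > 0] <- sqrt(d[d > 0])
      }
    }
  }

  structure(list(model = model, estimates = theta, standardized = std,
                 se = ses, n = n, S = S, implied_sigma = Sigma, fml = fml,
                 df = model_df(model), converged = best$convergence == 0,
                 heywood = any(theta[nb + seq_len(p)] < 0),
                 n_starts_used = used),
            class = "sem_fit")
}

# Pull the model's variables out of whatever tabular thing the user passed.
as_variable_matrix <- function(data, variables) {
  if (inherits(data, "omics_dataset")) data <- dataset_values(data)
  m <- as.matrix(as.data.frame(data)[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in model variables")
  m
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("SEM fit:", length(x$model$variables), "variables, n =", x$n,
      ", df =", x$df, "\n")
  cat(sprintf("F_ML = %.6g, chi^2 = %.4f%s%s\n", x$fml, (x$n - 1) * x$fml,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$heywood) " [Heywood: negative variance estimate]" else ""))
  if (length(x$standardized)) {
    cat("Standardized coefficients:\n")
    print(round(x$standardized, 4))
  }
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, ...) {
  nb <- nrow(object$model$regressions)
  est <- object$estimates
  tab <- data.frame(estimate = est, se = object$se,
                    z = est / object$se,
                    standardized = c(object$standardized,
                                     rep(NA_real_, length(est) - nb)))
  out <- list(fit = object, parameters = tab,
              indices = tryCatch(fit_indices(object), error = function(e) NULL))
  class(out) <- "summary.sem_fit"
  out
}

#' @export
print.summary.sem_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameters:\n")
  print(round(x$parameters, 4))
  if (!is.null(x$indices)) { cat("\n"); print(x$indices) }
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, standardized = FALSE, ...) {
  if (standardized) object$standardized else object$estimates
}

#' @export
fitted.sem_fit <- function(object, ...) object$implied_sigma

#' Covariance residuals of a SEM fit
#' @param object a `sem_fit`.
#' @param standardized divide each residual by the product of the sample
#'   standard deviations (the SRMR convention).
#' @param ... unused.
#' @return p x p matrix `S - Sigma(theta-hat)`.
#' @export
residuals.sem_fit <- function(object, standardized = FALSE, ...) {
  R <- object$S - object$implied_sigma
  if (standardized) {
    sd <- sqrt(diag(object$S))
    R <- R / tcrossprod(sd)
  }
  R
}

#' Simulate data from a fitted path model
#'
#' Draws Gaussian samples whose population covariance is the fitted implied
#' covariance (disturbances at the estimated variances, coefficients at the
#' estimates).
#' @param object a `sem_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed (set before drawing when non-NULL).
#' @param n samples per dataset (default: the fitting n).
#' @param ... unused.
#' @return a data.frame (nsim = 1) or list of data.frames.
#' @export
simulate.sem_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- object$implied_sigma
  ch <- chol(nearest_pd(Sigma))
  one <- function() {
    z <- matrix(stats::rnorm(n * ncol(Sigma)), n)
    out <- as.data.frame(z %*% ch)
    names(out) <- object$model$variables
    out
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

nearest_pd <- function(M, eps = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, eps)
  out <- e$vectors %*% (ev * t(e$vectors))
  dimnames(out) <- dimnames(M)
  out
}

#' @export
logLik.sem_fit <- function(object, ...) {
  # Wishart log-likelihood up to the saturated-model constant
  val <- -(object$n - 1) / 2 * object$fml
  attr(val, "df") <- n_free_parameters(object$model)
  class(val) <- "logLik"
  val
}

#' Serialize a SEM fit to JSON
#'
#' Writes estimates, standardized coefficients, standard errors, sample
#' size, convergence flags and the fit-index battery.
#' @param fit a `sem_fit`.
#' @param path JSON file path.
#' @export
write_sem_json <- function(fit, path) {
  ix <- tryCatch(fit_indices(fit), error = function(e) NULL)
  jsonlite::write_json(
    list(model = serialize_model(fit$model),
         estimates = as.list(fit$estimates),
         standardized = as.list(fit$standardized),
         se = as.list(fit$se), n = fit$n, df = fit$df, fml = fit$fml,
         converged = fit$converged, heywood = fit$heywood,
         indices = if (!is.null(ix)) ix[c("chisq", "df", "p_value", "cfi",
                                          "tli", "rmsea", "srmr", "gfi",
                                          "agfi")]),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
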