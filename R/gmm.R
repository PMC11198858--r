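#' Fit a 1-D Gaussian mixture with BIC model selection
#'
#' EM fits with 1..`max_components` unequal-variance components; the
#' component count is chosen by BIC. Degenerate inputs (near-constant
#' values) short-circuit to a single component with a floored variance.
#'
#' @param values numeric vector (>= 10 finite values for a meaningful
#'   fit).
#' @param max_components maximum number of components, default 3.
#' @param seed integer seed (the fit is deterministic, but the seed is
#'   honoured for reproducibility of any stochastic fallback).
#' @return list with `component_means`, `component_variances`,
#'   `component_weights`, `assignment` (component index per value) and
#'   `n_components_selected`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fitGmm1d <- function(values, max_components = 3, seed = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no finite values")
  if (stats::var(values) < 1e-12 || n < 2) {
    return(list(component_means = mean(values),
                component_variances = 1e-12,
                component_weights = 1,
                assignment = rep(1L, n),
                n_components_selected = 1L))
  }
  fit <- withSeed(seed, {
    suppressWarnings(mclust::Mclust(values, G = seq_len(max_components),
                                    modelNames = c("V", "E"),
                                    verbose = FALSE))
  })
  if (is.null(fit)) {
    return(list(component_means = mean(values),
                component_variances = max(stats::var(values), 1e-12),
                component_weights = 1,
                assignment = rep(1L, n),
                n_components_selected = 1L))
  }
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1) vars <- rep(vars, fit$G)
  list(component_means = as.numeric(fit$parameters$mean),
       component_variances = pmax(as.numeric(vars), 1e-12),
       component_weights = as.numeric(fit$parameters$pro),
       assignment = as.integer(fit$classification),
       n_components_selected = as.integer(fit$G))
}

#' Mixture-model feature filtration
#'
#' The two feature-selection stages used at each DivIK node. The
#' amplitude stage fits a Gaussian mixture to the log per-gene means and
#' discards the genes of the lowest-mean component (noise floor); the
#' variance stage fits a mixture to the log per-gene variances and
#' retains only the genes of the highest-mean component (most informative
#' features). When BIC selects a single component the stage keeps all
#' genes, and with fewer than 10 genes the stage is skipped with a
#' warning. The log transform uses offset 1e-6 for zeros; when any
#' per-gene mean is non-positive (signed data, where abundance is
#' undefined) the amplitude stage does not apply and all genes are kept.
#'
#' @param x numeric matrix, genes in rows and cells in columns.
#' @param stage `"amplitude"` or `"variance"`.
#' @param seed integer seed forwarded to [fitGmm1d()].
#' @param max_components see [fitGmm1d()].
#' @return logical mask over genes (`TRUE` = keep).
#' @export
selectFeatures <- function(x, stage = c("amplitude", "variance"), seed = 1,
                           max_components = 3) {
  stage <- match.arg(stage)
  ng <- nrow(x)
  if (ng < 10) {
    warning("fewer than 10 genes; ", stage, " filtration skipped")
    return(rep(TRUE, ng))
  }
  stat <- if (stage == "amplitude") rowMeans(x) else rowVars(x)
  if (stage == "amplitude" && any(stat < 0)) {
    # amplitude filtration discards a low-abundance noise floor; with
    # signed (e.g. centred) data abundance is undefined, so the stage
    # does not apply
    return(rep(TRUE, ng))
  }
  v <- log(stat + 1e-6)
  fit <- fitGmm1d(v, max_components = max_components, seed = seed)
  if (fit$n_components_selected == 1) return(rep(TRUE, ng))
  if (stage == "amplitude") {
    drop_comp <- which.min(fit$component_means)
    fit$assignment != drop_comp
  } else {
    keep_comp <- which.max(fit$component_means)
    fit$assignment == keep_comp
  }
}

rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
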