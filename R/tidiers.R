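#' Tidy a demographic fit
#'
#' @param x a `demographic_fit`.
#' @param ... unused.
#' @return one row per parameter: `term`, `estimate`.
#' @export
tidy.demographic_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.demographic_fit
#' @return for `glance()`: a one-row model summary.
#' @export
glance.demographic_fit <- function(x, ...) {
  tibble(
    model = x$model, loglik = x$loglik, theta_hat = x$theta_hat,
    n_restarts = nrow(x$restarts),
    n_local_optima = sum(x$restarts$local_optimum, na.rm = TRUE),
    convergence = x$convergence
  )
}

#' Tidy an FST result
#'
#' @param x an `fst_result`.
#' @param ... unused.
#' @return a one-row tibble with the estimate, CI and locus count.
#' @export
tidy.fst_result <- function(x, ...) {
  tibble(
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    n_loci = x$n_loci, significant_nonzero = x$significant_nonzero
  )
}

#' Tidy a DAPC result (per-locus loadings)
#'
#' @param x a `dapc_result`.
#' @param ... unused.
#' @return the loadings tibble (`locus`, `chrom`, `pos`, `loading`).
#' @export
tidy.dapc_result <- function(x, ...) x$loadings

#' @rdname tidy.dapc_result
#' @export
glance.dapc_result <- function(x, ...) {
  tibble(
    n_individuals = nrow(x$scores), n_loci = nrow(x$loadings),
    n_pcs = x$n_pcs, groups = paste(x$groups, collapse = "/"),
    max_loading = max(x$loadings$loading)
  )
}

#' Tidy a genotype PCA
#'
#' @param x a `pca_geno`.
#' @param ... unused.
#' @return one row per component: `component`, `eigenvalue`,
#'   `var_explained`.
#' @export
tidy.pca_geno <- function(x, ...) {
  tibble(
    component = seq_along(x$values), eigenvalue = x$values,
    var_explained = x$var_explained
  )
}

#' Tidy an isolation-by-distance test
#'
#' @param x an `ibd_result`.
#' @param ... unused.
#' @return a one-row tibble with slope, Mantel r and p-value.
#' @export
tidy.ibd_result <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, mantel_r = x$mantel_r,
    p_value = x$p_value, n_perm = x$n_perm, n_excluded = x$n_excluded
  )
}
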