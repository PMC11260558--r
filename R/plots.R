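#' Plot an ancestry estimate table in q-Q space
#'
#' The classic hybrid-zone triangle: admixture proportion `q` against
#' interspecific ancestry `Q`, coloured by hybrid class. Pure parentals sit
#' at the bottom corners, F1 at the apex (0.5, 1), F2 at (0.5, 0.5), and
#' backcrosses along the triangle's sides.
#'
#' @param object an `ancestry_est` tibble (classified on the fly if it has
#'   no `class` column).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ancestry_est <- function(object, ...) {
  if (!"class" %in% names(object)) object <- classify_ancestry(object)
  tri <- tibble(q = c(0, 0.5, 1), Q = c(0, 1, 0))
  ggplot(object, aes(x = .data$q, y = .data$Q, colour = .data$class)) +
    geom_path(data = tri, aes(x = .data$q, y = .data$Q),
              inherit.aes = FALSE, linetype = "dashed", colour = "grey60") +
    geom_point(size = 2, alpha = 0.8) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "q (walleye ancestry proportion)",
         y = "Q (interspecific ancestry)", colour = "class") +
    theme_minimal()
}

#' Heatmap of a joint SFS
#'
#' @param object a `joint_sfs`.
#' @param log10_scale show `log10(count + 1)`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.joint_sfs <- function(object, log10_scale = TRUE, ...) {
  df <- tibble(
    i = rep(0:object$n1, times = object$n2 + 1),
    j = rep(0:object$n2, each = object$n1 + 1),
    count = as.vector(object$counts),
    masked = as.vector(object$mask)
  )
  df <- df[!df$masked, ]
  if (log10_scale) df$count <- log10(df$count + 1)
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$count)) +
    geom_tile() +
    labs(x = "allele count, population 1", y = "allele count, population 2",
         fill = if (log10_scale) "log10(n+1)" else "n") +
    theme_minimal()
}

#' Scatter of genotype-PCA scores
#'
#' @param object a `pca_geno`.
#' @param colour optional vector (e.g. population or sex) recycled over
#'   individuals.
#' @param ... unused.
#' @return a ggplot of PC1 vs PC2 with variance percentages on the axes.
#' @export
autoplot.pca_geno <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2)) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    theme_minimal()
  if (is.null(colour)) p + geom_point() else
    p + geom_point(aes(colour = .data$colour)) + labs(colour = "group")
}

#' Genome-wide DAPC loading plot
#'
#' Loadings by genome position, with optional horizontal threshold line
#' (e.g. from [randomization_threshold()]).
#'
#' @param object a `dapc_result`.
#' @param threshold optional loading threshold drawn as a dashed line.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dapc_result <- function(object, threshold = NULL, ...) {
  df <- object$loadings
  df$index <- seq_len(nrow(df))
  p <- ggplot(df, aes(x = .data$index, y = .data$loading,
                      colour = .data$chrom)) +
    geom_point(size = 0.8, show.legend = FALSE) +
    labs(x = "locus index (genome order)", y = "DAPC loading") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = as.numeric(threshold),
                        linetype = "dashed")
  }
  p
}

#' Isolation-by-distance scatter plot
#'
#' Linearised divergence against river distance with the least-squares
#' line.
#'
#' @param x an `ibd_result`.
#' @return a ggplot.
#' @export
plot_ibd <- function(x) {
  ggplot(x$pairs, aes(x = .data$dist, y = .data$linearised)) +
    geom_point() +
    geom_abline(slope = x$slope, intercept = x$intercept,
                colour = "steelblue") +
    labs(
      x = "river distance (km)", y = expression(F[ST] / (1 - F[ST])),
      subtitle = sprintf("Mantel r = %.3f, p = %.4g", x$mantel_r, x$p_value)
    ) +
    theme_minimal()
}
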