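# Ordination of per-species receptor count profiles and quasi-Poisson
# trait-association models.

#' Principal component analysis of a species x count matrix
#'
#' Covariance PCA of the per-species receptor counts (the default input is
#' the four type totals; the nine subcategories are equally valid). Columns
#' are centred; set `scale = TRUE` for correlation PCA. The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param counts numeric matrix or data frame, species in rows (unique row
#'   names), count variables in columns; at least 2 x 2, no missing cells.
#' @param scale standardize columns to unit variance?
#' @return object of class `prr_pca`: list with `scores` (species x
#'   component), `loadings` (variable x component, orthonormal columns),
#'   `explained_variance` (non-increasing eigenvalues) and
#'   `prop_variance`.
#' @export
prr_pca <- function(counts, scale = FALSE) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L) stopf("need at least a 2 x 2 matrix")
  if (anyNA(m)) stopf("count matrix has missing cells")
  if (anyDuplicated(rownames(m))) stopf("duplicate row labels")
  v <- apply(m, 2, stats::var)
  if (all(v == 0)) stopf("constant matrix: no variance to decompose")
  if (scale && any(v == 0))
    stopf("cannot scale a zero-variance column: %s",
          paste(colnames(m)[v == 0], collapse = ", "))
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = p$sdev^2,
                 prop_variance = p$sdev^2 / sum(p$sdev^2)),
            class = "prr_pca")
}

#' @export
print.prr_pca <- function(x, ...) {
  cat(sprintf("<prr_pca> %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$explained_variance), 100 * x$prop_variance[1],
              100 * x$prop_variance[2]))
  invisible(x)
}

#' Quasi-Poisson regression of total receptor count on one binary trait
#'
#' Fits `total ~ trait` with a log link and quasi-Poisson variance
#' (`variance = dispersion * mean`) via [stats::glm()]. Point estimates
#' coincide with the ordinary Poisson fit; the Pearson dispersion estimate
#' (`Pearson chi-square / df_residual`) inflates the standard errors by its
#' square root, and two-sided p-values use the t distribution with the
#' residual degrees of freedom.
#'
#' @param totals numeric vector of counts (one per species).
#' @param trait logical/0-1 vector (or two-level factor) aligned with
#'   `totals`; both levels must be present.
#' @param trait_name label carried into the result.
#' @return object of class `prr_glm`: list with `trait_name`,
#'   `coefficients` (log scale: intercept, trait effect), `standard_errors`,
#'   `dispersion_hat`, `t_statistics`, `p_values`, `df_residual`,
#'   `separation` (TRUE when one group has all-zero counts) and `fit` (the
#'   underlying `glm` object).
#' @export
quasipoisson_glm <- function(totals, trait, trait_name = "trait") {
  if (length(totals) != length(trait)) stopf("length mismatch")
  if (length(totals) < 3L) stopf("need at least 3 observations")
  if (anyNA(totals) || anyNA(trait)) stopf("missing values in model input")
  x <- if (is.factor(trait)) trait else factor(as.logical(trait),
                                               levels = c(FALSE, TRUE))
  if (nlevels(droplevels(x)) < 2L)
    stopf("trait '%s' has a single level", trait_name)
  separation <- any(tapply(totals, x, function(y) all(y == 0)))
  if (separation)
    warnf("trait '%s': one group has all-zero counts; %s", trait_name,
          "its log-scale coefficient diverges")
  fit <- stats::glm(totals ~ x, family = stats::quasipoisson(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  s <- summary(fit)
  co <- s$coefficients
  structure(list(trait_name = trait_name,
                 coefficients = stats::setNames(co[, 1],
                                                c("intercept", "trait")),
                 standard_errors = stats::setNames(co[, 2],
                                                   c("intercept", "trait")),
                 dispersion_hat = s$dispersion,
                 t_statistics = stats::setNames(co[, 3],
                                                c("intercept", "trait")),
                 p_values = stats::setNames(co[, 4],
                                            c("intercept", "trait")),
                 df_residual = fit$df.residual,
                 separation = separation, fit = fit),
            class = "prr_glm")
}

#' @export
print.prr_glm <- function(x, ...) {
  cat(sprintf("<prr_glm> total ~ %s: effect %.3f (SE %.3f, p = %.4g, phi = %.2f)\n",
              x$trait_name, x$coefficients[["trait"]],
              x$standard_errors[["trait"]], x$p_values[["trait"]],
              x$dispersion_hat))
  invisible(x)
}

#' Run the battery of single-trait quasi-Poisson models
#'
#' One model per listed trait, each univariable (`total ~ trait`), with no
#' multiplicity correction. The traits overlap strongly in this system
#' (anthozoans are largely the symbiotic, colonial, sessile species), which
#' is exactly why they are fitted separately. For `"clade"` the contrast is
#' anthozoa vs medusozoa and outgroup species are dropped.
#'
#' @param totals named numeric vector of per-species totals.
#' @param traits trait table ([read_trait_table()]); must cover every
#'   species in `totals`.
#' @param model_list traits to fit (default: clade, symbiotic, colonial,
#'   sessile, i.e. the named study traits).
#' @return `data.frame`, one row per model: `trait`, `estimate`, `se`, `t`,
#'   `p`, `dispersion`, `df_residual`; full fits attached as attribute
#'   `"fits"`.
#' @export
run_trait_models <- function(totals, traits,
                             model_list = c("clade", "symbiotic", "colonial",
                                            "sessile")) {
  miss <- setdiff(names(totals), traits$species_id)
  if (length(miss) > 0L)
    stopf("species missing from trait table: %s", paste(miss, collapse = ", "))
  if (length(model_list) == 0L) {
    return(data.frame(trait = character(), estimate = numeric(),
                      se = numeric(), t = numeric(), p = numeric(),
                      dispersion = numeric(), df_residual = integer(),
                      stringsAsFactors = FALSE))
  }
  fits <- lapply(model_list, function(tn) {
    if (tn == "clade") {
      keep <- traits$species_id[traits$clade %in% c("anthozoa", "medusozoa")]
      keep <- intersect(names(totals), keep)
      y <- totals[keep]
      x <- factor(traits$clade[match(keep, traits$species_id)],
                  levels = c("medusozoa", "anthozoa"))
    } else {
      if (!tn %in% names(traits)) stopf("unknown trait '%s'", tn)
      y <- totals
      x <- traits[[tn]][match(names(totals), traits$species_id)]
    }
    quasipoisson_glm(y, x, trait_name = tn)
  })
  out <- data.frame(
    trait = model_list,
    estimate = vapply(fits, function(f) f$coefficients[["trait"]], 1),
    se = vapply(fits, function(f) f$standard_errors[["trait"]], 1),
    t = vapply(fits, function(f) f$t_statistics[["trait"]], 1),
    p = vapply(fits, function(f) f$p_values[["trait"]], 1),
    dispersion = vapply(fits, function(f) f$dispersion_hat, 1),
    df_residual = vapply(fits, function(f) f$df_residual, 1L),
    stringsAsFactors = FALSE)
  attr(out, "fits") <- stats::setNames(fits, model_list)
  out
}
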