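#' Marker matrix for genomic prediction
#'
#' Codes individuals at the map's marker loci as -1/0/+1 (allele-1 dosage
#' minus 1). QTL loci are excluded by default so markers must tag QTLs
#' through linkage disequilibrium, as in a real genotyping panel; set
#' `include_qtl = TRUE` for an oracle panel with markers on the QTLs
#' themselves.
#'
#' @param pop A [bean_pop()].
#' @param include_qtl Include `kind == "qtl"` loci in the panel.
#' @return Numeric matrix, individuals by markers, with locus_id colnames.
#' @export
marker_matrix <- function(pop, include_qtl = FALSE) {
  keep <- if (include_qtl) rep(TRUE, nrow(pop$map)) else pop$map$kind == "marker"
  m <- geno_dosage(pop)[, keep, drop = FALSE] - 1
  storage.mode(m) <- "double"
  m
}

#' Estimate additive marker effects (ridge-regression BLUP)
#'
#' Fits the genomic-selection mixed model `y = 1*mu + M u + e` with
#' `u ~ N(0, I sigma_u^2)`, i.e. ridge regression of phenotypes on centered
#' marker covariates. The variance ratio `lambda = sigma_e^2 / sigma_u^2` is
#' chosen by restricted-likelihood maximization using the spectral
#' decomposition of the marker kernel `M M'`; the resulting effect estimates
#' equal `M'(MM' + lambda I)^{-1} (y - mu)`, the ridge solution
#' `(M'M + lambda I)^{-1} M'(y - mu)`. If the REML search fails (degenerate
#' toy inputs), a fixed `lambda` equal to the marker count is used and
#' reported.
#'
#' Marker covariates are centered on their training means, so monomorphic
#' markers receive effect 0 and the intercept absorbs their contribution.
#'
#' @param geno Training marker matrix (-1/0/+1), individuals by markers, as
#'   from [marker_matrix()].
#' @param pheno Numeric training phenotypes, one per row of `geno`.
#' @return An object of class `marker_effects`: intercept, per-marker effect
#'   tibble, `lambda`, variance components and training diagnostics.
#' @export
train_marker_effects <- function(geno, pheno) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (n < 2) abort("need at least 2 training individuals")
  if (length(pheno) != n) abort("phenotype length must match genotype rows")
  if (sd(pheno) == 0) abort("constant training phenotype: cannot estimate effects")
  centers <- colMeans(geno)
  M <- sweep(geno, 2, centers)
  poly <- apply(M, 2, function(x) any(x != 0))
  if (sum(poly) < 2) abort("fewer than 2 polymorphic markers in training set")
  Mp <- M[, poly, drop = FALSE]
  K <- tcrossprod(Mp)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, pheno))
  xt <- drop(crossprod(U, rep(1, n)))
  reml_neg2 <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (d + lam)
    xwx <- sum(xt^2 * w)
    beta <- sum(xt * yt * w) / xwx
    r <- yt - xt * beta
    S <- sum(r^2 * w)
    (n - 1) * log(S) + sum(log(d + lam)) + log(xwx)
  }
  lambda <- tryCatch(
    {
      opt <- optimize(reml_neg2, c(-18, 18))
      exp(opt$minimum)
    },
    error = function(e) NA_real_
  )
  reml_ok <- is.finite(lambda)
  if (!reml_ok) lambda <- ncol(Mp)
  w <- 1 / (d + lambda)
  xwx <- sum(xt^2 * w)
  mu <- sum(xt * yt * w) / xwx
  r <- yt - xt * mu
  sigma2_u <- sum(r^2 * w) / (n - 1)
  # effects on the kept (polymorphic) markers; zeros elsewhere
  beta_poly <- drop(crossprod(Mp, U %*% (w * r)))
  beta <- numeric(ncol(geno))
  beta[poly] <- beta_poly
  fitted <- mu + drop(M %*% beta)
  structure(
    list(
      intercept = mu,
      effects = tibble::tibble(
        locus_id = colnames(geno) %||% paste0("m", seq_along(beta)),
        effect = beta
      ),
      centers = centers,
      lambda = lambda,
      sigma2_u = sigma2_u,
      sigma2_e = sigma2_u * lambda,
      reml_converged = reml_ok,
      training_accuracy = suppressWarnings(stats::cor(fitted, pheno)),
      include_qtl = NA
    ),
    class = "marker_effects"
  )
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(
    "<marker_effects> ", nrow(x$effects), " markers | lambda = ",
    signif(x$lambda, 4), " | training r = ",
    signif(x$training_accuracy, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' GEBV = intercept + sum of estimated marker effects over an individual's
#' (training-centered) marker genotype.
#'
#' @param pop A [bean_pop()] on the same map the effects were trained on, or
#'   a marker matrix with matching columns.
#' @param effects A [train_marker_effects()] fit.
#' @param include_qtl Panel definition used at training time (must match).
#' @return Numeric predicted value per individual.
#' @export
predict_gebv <- function(pop, effects, include_qtl = FALSE) {
  m <- if (inherits(pop, "bean_pop")) {
    marker_matrix(pop, include_qtl = isTRUE(effects$include_qtl) ||
      include_qtl)
  } else {
    as.matrix(pop)
  }
  if (ncol(m) != nrow(effects$effects)) {
    abort("marker set does not match the trained effects")
  }
  if (!is.null(colnames(m)) &&
    !identical(colnames(m), effects$effects$locus_id)) {
    abort("marker ids do not match the trained effects")
  }
  effects$intercept + drop(sweep(m, 2, effects$centers) %*%
    effects$effects$effect)
}

#' Train marker effects on a population
#'
#' Convenience wrapper: simulates training phenotypes for `pop` in the given
#' environment and fits [train_marker_effects()] on its marker panel. The
#' training population is typically the cycle's parent set, mirroring a
#' breeding program that genotypes and phenotypes its crossing block.
#'
#' @param pop Training [bean_pop()].
#' @param arch A [trait_architecture()].
#' @param Ve Error variance of the training environment.
#' @param include_qtl Use the oracle panel with markers on QTLs.
#' @return A `marker_effects` object (records the panel definition).
#' @export
train_gs_model <- function(pop, arch, Ve, include_qtl = FALSE) {
  geno <- marker_matrix(pop, include_qtl = include_qtl)
  pheno <- simulate_phenotype(pop, arch, Ve)
  fx <- train_marker_effects(geno, pheno)
  fx$include_qtl <- include_qtl
  fx
}

#' Export marker effects as TSV
#'
#' @param effects A `marker_effects` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_effects <- function(effects, path) {
  readr::write_tsv(effects$effects, path)
  invisible(path)
}
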