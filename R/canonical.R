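#' Canonical transformation of correlated traits
#'
#' Builds the linear transform Q that maps the T correlated traits onto T
#' canonical traits that are genetically and environmentally independent:
#' `Q R Q' = I` (unit, uncorrelated residual variances) and `Q G Q' = diag(lambda)`
#' (diagonal genetic covariance). The canonical genetic variances `lambda` are
#' the generalized eigenvalues of (G, R), sorted ascending; each row of Q has
#' its largest-magnitude element positive, fixing the sign convention.
#'
#' @param traits A [trait_model()] with positive definite G and R.
#' @return Object of class `canonical_transform`: list with `Q`, `Q_inv`,
#'   `lambda` (ascending canonical genetic variances), `trait_names`,
#'   `canonical_names`.
#' @export
canonical_transform <- function(traits) {
  stopifnot(inherits(traits, "trait_model"))
  G <- traits$G; R <- traits$R
  L <- t(chol(R))                          # R = L L'
  C <- forwardsolve(L, t(forwardsolve(L, G)))  # L^-1 G L^-T
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  ord <- order(e$values)                   # ascending
  lambda <- e$values[ord]
  if (any(lambda <= 0)) {
    stop_gwablup("canonical genetic variances must be positive; eigenvalues: %s",
                 paste(signif(lambda, 4), collapse = ", "))
  }
  E <- e$vectors[, ord, drop = FALSE]
  Q <- t(E) %*% forwardsolve(L, diag(nrow(L)))   # t(E) L^-1
  # sign convention: largest-|.| element of each row positive
  for (t in seq_len(nrow(Q))) {
    if (Q[t, which.max(abs(Q[t, ]))] < 0) Q[t, ] <- -Q[t, ]
  }
  canonical_names <- paste0("can", seq_along(lambda))
  dimnames(Q) <- list(canonical_names, traits$trait_names)
  Q_inv <- solve(Q)
  dimnames(Q_inv) <- list(traits$trait_names, canonical_names)
  out <- structure(
    list(Q = Q, Q_inv = Q_inv, lambda = lambda,
         trait_names = traits$trait_names, canonical_names = canonical_names),
    class = "canonical_transform"
  )
  check_canonical(out, traits)
  out
}

check_canonical <- function(transform, traits, tol = 1e-8) {
  Q <- transform$Q
  scale <- max(1, max(abs(traits$R)), max(abs(traits$G)))
  QRQ <- Q %*% traits$R %*% t(Q)
  QGQ <- Q %*% traits$G %*% t(Q)
  if (max(abs(QRQ - diag(nrow(Q)))) > tol * scale) {
    stop_gwablup("canonical transform failed: Q R Q' is not the identity")
  }
  if (max(abs(QGQ - diag(transform$lambda, nrow = nrow(Q)))) > tol * scale) {
    stop_gwablup("canonical transform failed: Q G Q' is not diagonal")
  }
  invisible(transform)
}

#' @export
print.canonical_transform <- function(x, ...) {
  cat(sprintf("<canonical_transform> %d traits; canonical genetic variances: %s\n",
              length(x$lambda), paste(signif(x$lambda, 3), collapse = ", ")))
  invisible(x)
}

#' Transform phenotypes to the canonical trait scale
#'
#' Applies the canonical transform row-wise: animal i's canonical record is
#' `Q %*% yd_i`. Columns of `yd` must be in the trait order of the transform.
#'
#' @param yd Numeric matrix (animals x T) of yield deviations, or a data frame
#'   containing the trait columns.
#' @param transform A [canonical_transform()].
#' @return Numeric matrix (animals x T) on the canonical scale, columns named
#'   after the canonical traits.
#' @export
transform_phenotypes <- function(yd, transform) {
  stopifnot(inherits(transform, "canonical_transform"))
  Y <- as_trait_matrix(yd, transform$trait_names)
  if (ncol(Y) != length(transform$trait_names)) {
    stop_gwablup("yd has %d columns but the transform expects %d traits",
                 ncol(Y), length(transform$trait_names))
  }
  out <- Y %*% t(transform$Q)
  colnames(out) <- transform$canonical_names
  rownames(out) <- rownames(Y)
  out
}

#' Back-transform canonical SNP effects to the original trait scale
#'
#' GWAS on the canonical traits yields, per SNP j, effect estimates and
#' standard errors on the canonical scale. Original-scale effects are
#' `Q^-1 %*% b_j(canonical)`; the per-SNP sampling covariance is
#' `Q^-1 diag(se^2) Q^-T` (canonical estimates are independent across
#' canonical traits by construction), and the reported standard error of trait
#' t is the square root of its diagonal element.
#'
#' @param gwas A [gwas_result][single_snp_scan()] on the canonical scale.
#' @param transform A [canonical_transform()].
#' @return A `gwas_result` on the original trait scale. SNPs excluded from the
#'   canonical scan stay excluded.
#' @export
back_transform_effects <- function(gwas, transform) {
  stopifnot(inherits(gwas, "gwas_result"), inherits(transform, "canonical_transform"))
  if (gwas$trait_scale != "canonical") {
    stop_gwablup("gwas result is already on the original trait scale")
  }
  se <- gwas$se
  if (any(se[!is.na(se)] <= 0)) stop_gwablup("standard errors must be positive")
  Qi <- transform$Q_inv
  effects <- gwas$effects %*% t(Qi)
  se2 <- gwas$se^2 %*% t(Qi^2)
  excluded <- apply(is.na(gwas$se), 1, any)
  effects[excluded, ] <- NA_real_
  se2[excluded, ] <- NA_real_
  colnames(effects) <- colnames(se2) <- transform$trait_names
  new_gwas_result(map = gwas$map, effects = effects, se = sqrt(se2),
                  trait_scale = "original", n_animals = gwas$n_animals)
}

#' Persist and restore a canonical transform
#'
#' Writes Q and the canonical genetic variances to a small TSV so a run can be
#' reproduced, and reads them back.
#'
#' @param transform A [canonical_transform()].
#' @param path File path.
#' @return `read_canonical_transform()` returns a `canonical_transform`.
#' @export
write_canonical_transform <- function(transform, path) {
  tab <- as_tibble(transform$Q)
  tab <- dplyr::bind_cols(
    tibble(canonical = transform$canonical_names, lambda = transform$lambda), tab)
  readr::write_tsv(tab, path)
  invisible(transform)
}

#' @rdname write_canonical_transform
#' @export
read_canonical_transform <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  trait_names <- setdiff(names(tab), c("canonical", "lambda"))
  Q <- as.matrix(tab[, trait_names, drop = FALSE])
  dimnames(Q) <- list(tab$canonical, trait_names)
  Q_inv <- solve(Q)
  structure(list(Q = Q, Q_inv = Q_inv, lambda = tab$lambda,
                 trait_names = trait_names, canonical_names = tab$canonical),
            class = "canonical_transform")
}
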