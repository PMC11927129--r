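#' Bend a symmetric matrix to positive definiteness
#'
#' Published trait correlation tables are rounded and frequently fail to be
#' jointly positive definite. `bend_to_positive_definite()` repairs such a
#' matrix minimally: eigenvalues below the floor are clipped up to it, the
#' matrix is reconstructed from the clipped spectrum, and the result is
#' symmetrized. A matrix already satisfying the floor is returned unchanged.
#'
#' @param S Symmetric matrix.
#' @param min_eigenvalue Eigenvalue floor. The default, `NULL`, uses
#'   `1e-6 * mean(eigenvalues)` (i.e. `1e-6 * trace / T`).
#' @return A symmetric positive definite matrix of the same dimension.
#' @export
bend_to_positive_definite <- function(S, min_eigenvalue = NULL) {
  assert_symmetric(S)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floor_ev <- min_eigenvalue %||% (1e-6 * mean(e$values))
  if (floor_ev <= 0) floor_ev <- 1e-8 * max(abs(e$values), 1)
  if (all(e$values >= floor_ev)) return(S)
  vals <- pmax(e$values, floor_ev)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  out
}

#' Trait model: genetic and residual covariances of the traits
#'
#' Holds the T x T genetic covariance `G` and residual covariance `R` of the
#' analysed traits. Both are bent to positive definiteness at load time (see
#' [bend_to_positive_definite()]); whether bending changed each matrix is
#' recorded.
#'
#' @param trait_names Character vector of trait names (length T).
#' @param G,R Symmetric T x T covariance matrices.
#' @param bend Bend `G` and `R` to positive definiteness (default `TRUE`).
#' @return Object of class `trait_model` with elements `trait_names`, `G`,
#'   `R`, `bent` (named logical: was either matrix modified).
#' @export
trait_model <- function(trait_names, G, R, bend = TRUE) {
  G <- as.matrix(G); R <- as.matrix(R)
  T <- length(trait_names)
  if (!all(dim(G) == T) || !all(dim(R) == T)) {
    stop_gwablup("G and R must be %d x %d to match the trait names", T, T)
  }
  assert_symmetric(G, "G", tol = 1e-6)
  assert_symmetric(R, "R", tol = 1e-6)
  bent <- c(G = FALSE, R = FALSE)
  if (bend) {
    G2 <- bend_to_positive_definite(G)
    R2 <- bend_to_positive_definite(R)
    bent <- c(G = !identical(G2, G), R = !identical(R2, R))
    G <- G2; R <- R2
  }
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop_gwablup("G and R must be positive definite (enable bending?)")
  }
  dimnames(G) <- dimnames(R) <- list(trait_names, trait_names)
  structure(list(trait_names = trait_names, G = G, R = R, bent = bent),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %d traits: %s\n", length(x$trait_names),
              paste(x$trait_names, collapse = ", ")))
  if (any(x$bent)) {
    cat("  bent to positive definiteness:",
        paste(names(x$bent)[x$bent], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a trait model from heritabilities and correlations
#'
#' Convenience constructor under unit phenotypic variance per trait: the
#' genetic variance of trait t is its heritability `h2[t]` and the residual
#' variance is `1 - h2[t]`; covariances follow from the given genetic and
#' residual correlations. The canonical decomposition is invariant to this
#' per-trait scaling, so unit phenotypic variances lose no generality.
#'
#' @param h2 Heritabilities (length T, in (0, 1)).
#' @param genetic_cor,residual_cor Correlations for the trait pairs in
#'   column-major lower-triangle order (length T (T - 1) / 2), e.g. for three
#'   traits: (1,2), (1,3), (2,3).
#' @param trait_names Trait names; default `trait1 ... traitT`.
#' @param bend Passed to [trait_model()].
#' @return A [trait_model()].
#' @export
heritability_trait_model <- function(h2, genetic_cor, residual_cor,
                                     trait_names = paste0("trait", seq_along(h2)),
                                     bend = TRUE) {
  T <- length(h2)
  if (any(h2 <= 0) || any(h2 >= 1)) stop_gwablup("heritabilities must lie in (0, 1)")
  cor_mat <- function(r) {
    C <- diag(T)
    C[lower.tri(C)] <- r
    C[upper.tri(C)] <- t(C)[upper.tri(C)]
    C
  }
  sg <- sqrt(h2); se <- sqrt(1 - h2)
  G <- outer(sg, sg) * cor_mat(genetic_cor)
  R <- outer(se, se) * cor_mat(residual_cor)
  trait_model(trait_names, G, R, bend = bend)
}
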