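new_gwas_result <- function(map, effects, se, trait_scale, n_animals) {
  structure(
    list(map = map, effects = effects, se = se,
         trait_scale = trait_scale, n_animals = n_animals),
    class = "gwas_result"
  )
}

#' Single-SNP association scan of the canonical traits
#'
#' For each trait and SNP, fits a weighted least-squares regression of the
#' phenotype on (intercept, centered genotype) with the record weights as
#' regression weights. The canonical traits are environmentally independent
#' with unit residual variance, so each trait is scanned separately. Residual
#' variance is estimated per SNP with an n - 2 denominator. SNPs whose fit is
#' degenerate (no genotype variance after weighting, or an exact fit leaving
#' zero residual variance) get `NA` effect and standard error and are excluded
#' downstream; the weighting step assigns them the prior probability.
#'
#' @param centered A [center_genotypes()] result.
#' @param yd Numeric matrix (animals x T) of phenotypes on the scanned scale,
#'   rownames = animal ids present in `centered`. Typically the canonical
#'   yield deviations of the training animals.
#' @param record_weight Positive weights, one per row of `yd`; default all 1.
#' @param trait_scale Scale of `yd`: `"canonical"` (default) or `"original"`.
#' @return Object of class `gwas_result`: list with `map`, `effects`
#'   (N_snps x T), `se` (N_snps x T, `NA` where degenerate), `trait_scale`,
#'   `n_animals`.
#' @export
single_snp_scan <- function(centered, yd, record_weight = NULL,
                            trait_scale = c("canonical", "original")) {
  stopifnot(inherits(centered, "centered_genotypes"))
  trait_scale <- match.arg(trait_scale)
  Y <- as_trait_matrix(yd)
  if (is.null(rownames(Y))) stop_gwablup("yd must have animal ids as rownames")
  X <- centered_rows(centered, rownames(Y))
  n <- nrow(Y)
  if (n < 3) stop_gwablup("at least 3 animals are required for the scan")
  w <- record_weight %||% rep(1, n)
  if (length(w) != n || any(w <= 0)) stop_gwablup("record weights must be positive, one per animal")

  sw <- sum(w)
  wX <- w * X
  xbar <- colSums(wX) / sw
  Sxx <- colSums(wX * X) - sw * xbar^2
  N <- ncol(X); T <- ncol(Y)
  effects <- se <- matrix(NA_real_, N, T)
  for (t in seq_len(T)) {
    y <- Y[, t]
    ybar <- sum(w * y) / sw
    Sxy <- as.vector(crossprod(X, w * y)) - sw * xbar * ybar
    Syy <- sum(w * y^2) - sw * ybar^2
    ok <- Sxx > 1e-12 * max(Sxx, 1)
    b <- ifelse(ok, Sxy / Sxx, NA_real_)
    rss <- Syy - b * Sxy
    sigma2 <- rss / (n - 2)
    degenerate <- !ok | !is.finite(sigma2) | sigma2 <= 1e-12 * max(Syy, 1) / (n - 2)
    if (any(degenerate & ok)) {
      warning(sprintf("single_snp_scan: %d SNP(s) with an exact fit excluded for trait %d",
                      sum(degenerate & ok), t))
    }
    effects[, t] <- ifelse(degenerate, NA_real_, b)
    se[, t] <- ifelse(degenerate, NA_real_, sqrt(sigma2 / Sxx))
  }
  trait_names <- colnames(Y) %||% paste0("trait", seq_len(T))
  dimnames(effects) <- dimnames(se) <- list(centered$map$snp_id, trait_names)
  new_gwas_result(map = centered$map, effects = effects, se = se,
                  trait_scale = trait_scale, n_animals = n)
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("<gwas_result> %d SNPs x %d trait(s), %s scale, n = %d animals\n",
              nrow(x$effects), ncol(x$effects), x$trait_scale, x$n_animals))
  n_exc <- sum(apply(is.na(x$se), 1, any))
  if (n_exc > 0) cat(sprintf("  degenerate (excluded) SNPs: %d\n", n_exc))
  invisible(x)
}

#' Tidy a GWAS result into a long tibble
#'
#' @param x A `gwas_result`.
#' @param ... Unused.
#' @return Tibble with columns `chromosome`, `snp_id`, `position`, `trait`,
#'   `effect`, `se`.
#' @export
tidy.gwas_result <- function(x, ...) {
  traits <- colnames(x$effects)
  purrr::map_dfr(seq_along(traits), function(t) {
    tibble(chromosome = x$map$chromosome,
           snp_id = x$map$snp_id,
           position = x$map$position,
           trait = traits[t],
           effect = x$effects[, t],
           se = x$se[, t])
  })
}
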