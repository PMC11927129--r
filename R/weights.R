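#' Log-likelihood ratio of a SNP effect
#'
#' `LR = 0.5 * (effect / se)^2`: the log-likelihood ratio for the SNP having a
#' non-zero effect, computed from a GWAS effect estimate and its standard
#' error. Vectorized.
#'
#' @param effect Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Non-negative numeric of the common length.
#' @export
loglik_ratio <- function(effect, se) {
  if (any(!is.na(se) & se <= 0)) stop_gwablup("standard errors must be positive")
  0.5 * (effect / se)^2
}

#' Moving average along the genome, per chromosome
#'
#' Smooths per-SNP values with a symmetric moving average over the
#' `half_window` SNPs on each side (default 2, i.e. a 5-SNP window). Windows
#' never cross a chromosome boundary — adjacent-SNP smoothing is a linkage
#' proxy and linkage does not cross chromosomes — and are truncated at
#' chromosome ends, dividing by the number of SNPs actually in the window.
#'
#' @param values Numeric vector, one value per SNP in map order.
#' @param map SNP map (tibble with `chromosome`, sorted).
#' @param half_window Non-negative integer; 0 returns the input unchanged.
#' @return Numeric vector of smoothed values.
#' @export
moving_average_by_chromosome <- function(values, map, half_window = 2) {
  if (length(values) != nrow(map)) {
    stop_gwablup("values (%d) and map (%d SNPs) lengths differ", length(values), nrow(map))
  }
  if (half_window < 0) stop_gwablup("half_window must be >= 0")
  if (half_window == 0) return(values)
  out <- numeric(length(values))
  chrom <- as.character(map$chromosome)
  for (idx in split(seq_along(values), factor(chrom, levels = unique(chrom)))) {
    x <- values[idx]
    m <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(m) - half_window, 1L)
    hi <- pmin(seq_len(m) + half_window, m)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Posterior probability of a non-zero SNP effect
#'
#' Under a point-mass mixture prior in which a SNP has a non-zero effect with
#' prior probability `pi`, the posterior probability given a (smoothed)
#' log-likelihood ratio is `PP = pi e^LR / (pi e^LR + 1 - pi)`. Evaluated in
#' log space as the logistic of `LR + log(pi / (1 - pi))`, so very large LR
#' (thousands, on strong QTL) never overflows; the result is clamped to stay
#' strictly inside (0, 1). At `LR = 0` the posterior equals the prior.
#'
#' @param lr_smoothed Non-negative (smoothed) log-likelihood ratio(s).
#' @param pi Prior probability of a non-zero effect, in (0, 1); default 0.001.
#' @return Posterior probabilities in (0, 1), vectorized.
#' @export
posterior_probability <- function(lr_smoothed, pi = 0.001) {
  if (length(pi) != 1 || !is.finite(pi) || pi <= 0 || pi >= 1) {
    stop_gwablup("pi must be a single value in (0, 1)")
  }
  pp <- plogis(lr_smoothed + log(pi) - log1p(-pi))
  pmin(pp, 1 - .Machine$double.eps / 2)
}

#' Per-SNP base prior covariance
#'
#' The unweighted per-SNP prior covariance of the multitrait SNP effects:
#' `V_SNP = G / sum_j 2 p_j (1 - p_j)`, so that summing the implied genetic
#' variance over SNPs recovers G.
#'
#' @param traits A [trait_model()].
#' @param scale_sum `sum(2 p_j (1 - p_j))` over retained SNPs (see
#'   [center_genotypes()]).
#' @return T x T matrix.
#' @export
base_vsnp <- function(traits, scale_sum) {
  stopifnot(inherits(traits, "trait_model"))
  if (!is.finite(scale_sum) || scale_sum <= 0) stop_gwablup("scale_sum must be positive")
  traits$G / scale_sum
}

#' GWAS-derived SNP weights
#'
#' Turns a canonical-scale GWAS into the two weight tracks used by the
#' weighted SNP-BLUP schemes:
#' * trait-specific: canonical effects and standard errors are back-transformed
#'   to the original trait scale, converted to log-likelihood ratios,
#'   smoothed along the genome, and mapped to posterior probabilities
#'   `PP[j, t]`;
#' * uniform across traits: the smoothed canonical-trait log-likelihood
#'   ratios are summed across traits and mapped to a single combined
#'   posterior probability `PP_combined[j]` with the same prior `pi`.
#'
#' SNPs excluded by the GWAS degeneracy rule contribute a zero log-likelihood
#' ratio to the smoothing and receive the prior probability `pi` as their own
#' posterior, rather than being dropped from the prediction model.
#'
#' @param gwas A canonical-scale [gwas_result][single_snp_scan()].
#' @param transform The [canonical_transform()] used to build the canonical
#'   traits.
#' @param pi Prior probability of a non-zero SNP effect (default 0.001).
#' @param half_window Moving-average half window in SNPs (default 2).
#' @return Object of class `snp_weights`: list with `map`, matrices `lr`,
#'   `lr_smoothed`, `pp` (N_snps x T, original-trait columns), vectors
#'   `lr_combined`, `pp_combined`, `excluded` (logical N x T), and the
#'   settings `pi`, `half_window`, `trait_names`.
#' @export
snp_weights <- function(gwas, transform, pi = 0.001, half_window = 2) {
  stopifnot(inherits(gwas, "gwas_result"))
  if (gwas$trait_scale != "canonical") {
    stop_gwablup("snp_weights expects a canonical-scale GWAS result")
  }
  original <- back_transform_effects(gwas, transform)
  excluded <- is.na(original$se)

  lr <- loglik_ratio(original$effects, original$se)
  lr[excluded] <- 0
  lr_smoothed <- apply_smoothing(lr, gwas$map, half_window)
  pp <- posterior_probability(lr_smoothed, pi = pi)  # elementwise, keeps dim
  pp[excluded] <- pi
  dimnames(pp) <- dimnames(lr)

  lr_can <- loglik_ratio(gwas$effects, gwas$se)
  lr_can[is.na(lr_can)] <- 0
  lr_can_smoothed <- apply_smoothing(lr_can, gwas$map, half_window)
  lr_combined <- rowSums(lr_can_smoothed)
  pp_combined <- posterior_probability(lr_combined, pi = pi)
  pp_combined[apply(excluded, 1, all)] <- pi

  structure(
    list(map = gwas$map, lr = lr, lr_smoothed = lr_smoothed, pp = pp,
         lr_combined = lr_combined, pp_combined = pp_combined,
         excluded = excluded, pi = pi, half_window = half_window,
         trait_names = colnames(original$effects)),
    class = "snp_weights"
  )
}

apply_smoothing <- function(mat, map, half_window) {
  out <- mat
  for (t in seq_len(ncol(mat))) {
    out[, t] <- moving_average_by_chromosome(mat[, t], map, half_window)
  }
  out
}

#' @export
print.snp_weights <- function(x, ...) {
  cat(sprintf("<snp_weights> %d SNPs x %d traits (pi = %g, half_window = %d)\n",
              nrow(x$pp), ncol(x$pp), x$pi, x$half_window))
  cat(sprintf("  SNPs with PP > 0.9 for any trait: %d\n", sum(apply(x$pp > 0.9, 1, any))))
  invisible(x)
}

#' Tidy SNP weights into a long tibble
#'
#' @param x An `snp_weights` object.
#' @param ... Unused.
#' @return Tibble with `chromosome`, `snp_id`, `position`, `trait`
#'   (trait names plus `"combined"`), `lr`, `lr_smoothed`, `pp`.
#' @export
tidy.snp_weights <- function(x, ...) {
  per_trait <- purrr::map_dfr(seq_along(x$trait_names), function(t) {
    tibble(chromosome = x$map$chromosome, snp_id = x$map$snp_id,
           position = x$map$position, trait = x$trait_names[t],
           lr = x$lr[, t], lr_smoothed = x$lr_smoothed[, t], pp = x$pp[, t])
  })
  combined <- tibble(chromosome = x$map$chromosome, snp_id = x$map$snp_id,
                     position = x$map$position, trait = "combined",
                     lr = NA_real_, lr_smoothed = x$lr_combined,
                     pp = x$pp_combined)
  dplyr::bind_rows(per_trait, combined)
}

#' Write SNP weights to a TSV
#'
#' One row per SNP: map columns, then per trait `lr_*`, `lr_smoothed_*`,
#' `pp_*`, plus `lr_combined` and `pp_combined`.
#'
#' @param weights An `snp_weights` object.
#' @param path File path.
#' @export
write_snp_weights <- function(weights, path) {
  tab <- weights$map
  for (t in seq_along(weights$trait_names)) {
    nm <- weights$trait_names[t]
    tab[[paste0("lr_", nm)]] <- weights$lr[, t]
    tab[[paste0("lr_smoothed_", nm)]] <- weights$lr_smoothed[, t]
    tab[[paste0("pp_", nm)]] <- weights$pp[, t]
  }
  tab$lr_combined <- weights$lr_combined
  tab$pp_combined <- weights$pp_combined
  readr::write_tsv(tab, path)
  invisible(weights)
}

#' Manhattan plot of posterior probabilities
#'
#' Plots the per-trait posterior probability of a non-zero SNP effect against
#' genome position, one panel per trait, chromosomes alternating in shade.
#'
#' @param object An `snp_weights` object.
#' @param include_combined Also show the across-trait combined track
#'   (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snp_weights <- function(object, include_combined = FALSE, ...) {
  tab <- tidy(object)
  if (!include_combined) tab <- dplyr::filter(tab, .data$trait != "combined")
  tab <- tab %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::mutate(chr_index = dplyr::cur_group_id()) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$chr_index, .data$position) %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::mutate(x = dplyr::row_number()) %>%
    dplyr::ungroup()
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$pp,
                                    colour = factor(.data$chr_index %% 2))) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~trait, ncol = 1) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "SNP index (genome order)",
                  y = "posterior probability of non-zero effect") +
    ggplot2::theme_minimal()
}

#' Per-SNP prior covariance blocks for a weighting scheme
#'
#' Builds the per-SNP T x T prior covariance matrices `V_SNP_j` used in the
#' block-diagonal prior of the multitrait SNP-BLUP:
#' * `unweighted`: every block equals `V_SNP = G / scale_sum`;
#' * `equal_weights`: `V_SNP * PP_combined_j / mean(PP_combined)` — one weight
#'   per SNP, shared by all traits;
#' * `trait_specific`: `S_j V_SNP S_j` with
#'   `S_j = diag(sqrt(PP[j, t] / mean_j(PP[, t])))` — variances re-weighted per
#'   trait, correlations untouched.
#'
#' Normalizing by the mean posterior probability keeps the total prior genetic
#' variance per trait equal to G's diagonal under every scheme. Blocks are
#' represented compactly by `base_V` plus the N x T matrix of diagonal scale
#' factors; use [vsnp_blocks()] to materialize them.
#'
#' @param scheme `"unweighted"`, `"equal_weights"` or `"trait_specific"`.
#' @param traits A [trait_model()].
#' @param scale_sum `sum(2 p_j (1 - p_j))` from [center_genotypes()].
#' @param weights An [snp_weights()] table; required for the two weighted
#'   schemes.
#' @param n_snps Number of SNPs; required for `unweighted` when `weights` is
#'   absent.
#' @return Object of class `snp_prior`: list with `scheme`, `base_V`,
#'   `base_V_inv`, `smat` (N x T diagonal scale factors of `S_j`), `n_snps`,
#'   `trait_names`.
#' @export
build_prior <- function(scheme = c("unweighted", "equal_weights", "trait_specific"),
                        traits, scale_sum, weights = NULL, n_snps = NULL) {
  scheme <- match.arg(scheme)
  base_V <- base_vsnp(traits, scale_sum)
  T <- nrow(base_V)
  if (scheme == "unweighted") {
    n_snps <- n_snps %||% (if (!is.null(weights)) nrow(weights$pp) else NULL)
    if (is.null(n_snps)) stop_gwablup("unweighted scheme needs n_snps (or weights)")
    smat <- matrix(1, n_snps, T)
  } else {
    if (is.null(weights)) stop_gwablup("scheme '%s' requires snp_weights", scheme)
    stopifnot(inherits(weights, "snp_weights"))
    n_snps <- nrow(weights$pp)
    if (scheme == "equal_weights") {
      s <- sqrt(weights$pp_combined / mean(weights$pp_combined))
      smat <- matrix(s, n_snps, T)
    } else {
      if (!identical(weights$trait_names, traits$trait_names)) {
        stop_gwablup("trait-specific weights must be on the original trait scale, in trait-model order")
      }
      smat <- sqrt(sweep(weights$pp, 2, colMeans(weights$pp), "/"))
    }
  }
  structure(
    list(scheme = scheme, base_V = base_V, base_V_inv = solve(base_V),
         smat = smat, n_snps = n_snps, trait_names = traits$trait_names),
    class = "snp_prior"
  )
}

#' Materialize per-SNP prior covariance blocks
#'
#' @param prior An [snp_prior][build_prior()].
#' @param j SNP index (or vector of indices); default all SNPs.
#' @return A T x T matrix for a single index, else a T x T x length(j) array.
#' @export
vsnp_blocks <- function(prior, j = NULL) {
  stopifnot(inherits(prior, "snp_prior"))
  j <- j %||% seq_len(prior$n_snps)
  one <- function(jj) {
    s <- prior$smat[jj, ]
    prior$base_V * outer(s, s)
  }
  if (length(j) == 1) one(j) else {
    out <- vapply(j, one, prior$base_V)
    out
  }
}

#' @export
print.snp_prior <- function(x, ...) {
  cat(sprintf("<snp_prior> scheme = %s, %d SNPs x %d traits\n",
              x$scheme, x$n_snps, length(x$trait_names)))
  invisible(x)
}
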