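#' Configuration for the synthetic multitrait data generator
#'
#' Defines the study conditions for a simulated data set: genotypes with
#' tunable linkage between adjacent SNPs, sparse trait-specific QTL
#' architectures that partially overlap across traits, and multitrait
#' phenotypes `y = mu + M b + e` whose residuals are drawn per animal from
#' `R / w_i`.
#'
#' @param traits A [trait_model()] giving the target genetic covariance G and
#'   residual covariance R (unit phenotypic variances are convenient but not
#'   required).
#' @param n_animals Total number of animals (training + validation).
#' @param n_validation Number of animals (the last ones) set aside for
#'   validation.
#' @param n_snps,n_chromosomes SNP panel size and its split into chromosomes.
#' @param allele_freq_range Range the per-locus allele frequencies are drawn
#'   from.
#' @param ld_decay Adjacent-locus linkage parameter in \[0, 1): the
#'   autocorrelation of the latent haplotype process; 0 gives independent
#'   loci.
#' @param n_qtl_per_trait Number of QTL per trait (0 for a pure-noise null).
#' @param qtl_overlap Fraction of QTL shared between trait pairs: a scalar or
#'   a symmetric T x T matrix. The target genetic correlation of a pair
#'   cannot exceed its overlap in magnitude (shared QTL are the only source
#'   of genetic correlation), except that an overlap of 1 for all pairs makes
#'   every correlation attainable.
#' @param record_weight_range Range of the per-animal record weights
#'   (default `c(1, 1)`, i.e. complete records).
#' @param mu Trait means (default 0).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(traits, n_animals = 1000, n_validation = 0,
                              n_snps = 1000, n_chromosomes = 10,
                              allele_freq_range = c(0.05, 0.95),
                              ld_decay = 0.9, n_qtl_per_trait = 50,
                              qtl_overlap = 0, record_weight_range = c(1, 1),
                              mu = NULL, seed = 1L) {
  stopifnot(inherits(traits, "trait_model"))
  T <- length(traits$trait_names)
  if (is.matrix(qtl_overlap)) {
    assert_symmetric(qtl_overlap, "qtl_overlap")
  } else {
    qtl_overlap <- matrix(qtl_overlap, T, T)
  }
  diag(qtl_overlap) <- 1
  if (any(qtl_overlap < 0) || any(qtl_overlap > 1)) {
    stop_gwablup("qtl_overlap fractions must lie in [0, 1]")
  }
  if (n_qtl_per_trait > n_snps) stop_gwablup("n_qtl_per_trait cannot exceed n_snps")
  if (n_validation >= n_animals) stop_gwablup("n_validation must be below n_animals")
  if (ld_decay < 0 || ld_decay >= 1) stop_gwablup("ld_decay must lie in [0, 1)")
  structure(
    list(traits = traits, n_animals = n_animals, n_validation = n_validation,
         n_snps = n_snps, n_chromosomes = n_chromosomes,
         allele_freq_range = allele_freq_range, ld_decay = ld_decay,
         n_qtl_per_trait = n_qtl_per_trait, qtl_overlap = qtl_overlap,
         record_weight_range = record_weight_range,
         mu = mu %||% rep(0, T), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Ready-made simulation scenarios
#'
#' * `"table1"` emulates a three-trait dairy setting: two strongly correlated
#'   yield-like traits (milk, protein) sharing 80% of their QTL, and a third
#'   near-independent trait (somatic cell count, SCC) sharing 10%;
#'   heritabilities 0.26 / 0.20 / 0.16 and residual correlations
#'   0.96 / -0.17 / 0.16 under unit phenotypic variances. The milk-protein
#'   genetic correlation is set to 0.80, the maximum attainable with 80% QTL
#'   sharing.
#' * `"null"` has no QTL: phenotypes are pure multitrait noise.
#' * `"dense"` makes every SNP causal (every trait, fully shared), the regime
#'   in which GWAS-derived weights are expected to be neutral.
#'
#' @param preset One of `"table1"`, `"null"`, `"dense"`.
#' @param ... Overrides passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
preset_config <- function(preset = c("table1", "null", "dense"), ...) {
  preset <- match.arg(preset)
  dairy <- function(r_g12) heritability_trait_model(
    h2 = c(0.26, 0.20, 0.16),
    genetic_cor = c(r_g12, 0.10, 0.10),
    residual_cor = c(0.96, -0.17, 0.16),
    trait_names = c("milk", "protein", "scc"))
  args <- switch(preset,
    table1 = list(traits = dairy(0.80), n_animals = 3500, n_validation = 500,
                  n_snps = 2000, n_chromosomes = 10, ld_decay = 0.9,
                  n_qtl_per_trait = 50,
                  qtl_overlap = matrix(c(1, 0.8, 0.1,
                                         0.8, 1, 0.1,
                                         0.1, 0.1, 1), 3, 3)),
    null = list(traits = dairy(0.80), n_animals = 1000, n_validation = 200,
                n_snps = 1000, n_chromosomes = 10, ld_decay = 0.9,
                n_qtl_per_trait = 0),
    dense = list(traits = dairy(0.85), n_animals = 3500, n_validation = 500,
                 n_snps = 2000, n_chromosomes = 10, ld_decay = 0.9,
                 n_qtl_per_trait = 2000, qtl_overlap = 1))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' Simulate a genotype panel
#'
#' Draws per-locus allele frequencies uniformly in `allele_freq_range` and
#' generates two haplotypes per animal from a latent first-order Gaussian
#' autoregressive process: the latent value at locus j is
#' `ld_decay * z[j-1] + sqrt(1 - ld_decay^2) * noise`, thresholded at the
#' locus's frequency quantile. This preserves the marginal allele frequencies
#' exactly while inducing linkage between nearby SNPs; the process restarts on
#' every chromosome, so linkage never crosses a chromosome boundary.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default from the config).
#' @return A [genotype_panel()] with animals `a0001 ...` and SNPs
#'   `snp00001 ...`.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_animals; N <- config$n_snps
  n_hap <- 2L * n
  per_chr <- diff(round(seq(0, N, length.out = config$n_chromosomes + 1)))
  a <- config$ld_decay
  counts <- matrix(0L, n, N)
  p_all <- numeric(N)
  pos_all <- integer(N)
  chr_all <- character(N)
  col <- 0L
  for (chr in seq_len(config$n_chromosomes)) {
    m <- per_chr[chr]
    if (m == 0) next
    p <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
    pos <- cumsum(sample(1000:50000, m, replace = TRUE))
    z <- rnorm(n_hap)
    for (j in seq_len(m)) {
      if (j > 1) z <- a * z + sqrt(1 - a^2) * rnorm(n_hap)
      allele <- z < qnorm(p[j])
      col <- col + 1L
      counts[, col] <- as.integer(allele[seq_len(n)]) +
        as.integer(allele[n + seq_len(n)])
      p_all[col] <- p[j]; pos_all[col] <- pos[j]
      chr_all[col] <- sprintf("chr%02d", chr)
    }
  }
  map <- tibble(chromosome = chr_all, snp_id = sprintf("snp%05d", seq_len(N)),
                position = pos_all)
  genotype_panel(counts, map,
                 animal_ids = sprintf("a%05d", seq_len(n)))
}

#' Simulate QTL effects and multitrait phenotypes
#'
#' Assigns each trait `n_qtl_per_trait` QTL with the configured pairwise
#' sharing, draws their effects jointly so that shared QTL induce the target
#' genetic correlations, scales each trait's effects so the realized genetic
#' variance matches the diagonal of G exactly, and adds per-animal residuals
#' drawn from `R / w_i`. At a QTL shared by traits t and s the effect
#' correlation is `r_g(t, s) / overlap(t, s)`; a target correlation exceeding
#' the overlap in magnitude is therefore unreachable and raises an error
#' (unless every pair fully overlaps, in which case effects are drawn jointly
#' for all traits at fully shared QTL).
#'
#' @param panel A [genotype_panel()], typically from [simulate_genotypes()].
#' @param config A [simulation_config()].
#' @param seed Seed (default derived from the config seed).
#' @return List with `phenotypes` (tibble: `animal_id`, trait columns,
#'   `weight`, `cohort`) and `truth` (list: `qtl` tibble of per-trait QTL,
#'   `true_effects` N x T matrix, `true_breeding_values` n x T matrix).
#' @export
simulate_effects_and_phenotypes <- function(panel, config,
                                            seed = config$seed + 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  traits <- config$traits
  G <- traits$G; R <- traits$R
  T <- length(traits$trait_names)
  n <- nrow(panel$counts); N <- ncol(panel$counts)
  q <- config$n_qtl_per_trait

  # genotypes centered on their own frequencies define the true genetic values
  X <- panel$counts
  storage.mode(X) <- "double"
  X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  X[is.na(X)] <- 0

  B <- matrix(0, N, T)
  qtl_idx <- rep(list(integer(0)), T)
  if (q > 0) {
    r_g <- stats::cov2cor(G)
    O <- config$qtl_overlap
    off <- upper.tri(O)
    if (all(abs(O[off] - 1) < 1e-12)) {
      # fully shared architecture: one QTL set, jointly drawn effects
      idx <- sort(sample.int(N, q))
      B[idx, ] <- matrix(rnorm(q * T), q, T) %*% chol(r_g)
      qtl_idx <- rep(list(idx), T)
    } else {
      bad <- off & abs(r_g) > O + 1e-9
      if (any(bad)) {
        pr <- which(bad, arr.ind = TRUE)[1, ]
        stop_gwablup(paste0(
          "target genetic correlation %.2f between %s and %s exceeds their QTL overlap %.2f; ",
          "shared QTL are the only source of genetic correlation, so this architecture ",
          "cannot reach the target"),
          r_g[pr[1], pr[2]], traits$trait_names[pr[1]], traits$trait_names[pr[2]],
          O[pr[1], pr[2]])
      }
      pairs <- utils::combn(T, 2, simplify = FALSE)
      n_shared <- vapply(pairs, function(pr) as.integer(round(O[pr[1], pr[2]] * q)), 1L)
      shared_per_trait <- numeric(T)
      for (k in seq_along(pairs)) {
        shared_per_trait[pairs[[k]]] <- shared_per_trait[pairs[[k]]] + n_shared[k]
      }
      if (any(shared_per_trait > q)) {
        stop_gwablup("pairwise QTL sharing exceeds n_qtl_per_trait; reduce the overlaps")
      }
      n_private <- q - shared_per_trait
      total <- sum(n_shared) + sum(n_private)
      if (total > N) stop_gwablup("QTL architecture needs %d SNPs but only %d exist", total, N)
      pool <- sample.int(N, total)   # disjoint QTL sets
      take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
      for (k in seq_along(pairs)) {
        if (n_shared[k] == 0) next
        pr <- pairs[[k]]
        idx <- take(n_shared[k])
        rho <- max(-1, min(1, r_g[pr[1], pr[2]] / O[pr[1], pr[2]]))
        z1 <- rnorm(n_shared[k]); z2 <- rnorm(n_shared[k])
        B[idx, pr[1]] <- z1
        B[idx, pr[2]] <- rho * z1 + sqrt(1 - rho^2) * z2
        qtl_idx[[pr[1]]] <- c(qtl_idx[[pr[1]]], idx)
        qtl_idx[[pr[2]]] <- c(qtl_idx[[pr[2]]], idx)
      }
      for (t in seq_len(T)) {
        if (n_private[t] == 0) next
        idx <- take(n_private[t])
        B[idx, t] <- rnorm(n_private[t])
        qtl_idx[[t]] <- sort(c(qtl_idx[[t]], idx))
      }
    }
    # scale so the realized genetic variance hits the G diagonal exactly
    g <- X %*% B
    for (t in seq_len(T)) {
      v <- var(g[, t])
      if (v > 0) B[, t] <- B[, t] * sqrt(G[t, t] / v)
    }
  }
  g <- X %*% B

  w <- runif(n, config$record_weight_range[1], config$record_weight_range[2])
  E <- (matrix(rnorm(n * T), n, T) %*% chol(R)) / sqrt(w)
  Y <- sweep(g + E, 2, config$mu, "+")
  colnames(Y) <- traits$trait_names
  colnames(g) <- colnames(B) <- traits$trait_names
  rownames(g) <- panel$animal_ids
  rownames(B) <- panel$map$snp_id

  cohort <- rep("training", n)
  if (config$n_validation > 0) {
    cohort[seq(n - config$n_validation + 1, n)] <- "validation"
  }
  phenotypes <- dplyr::bind_cols(
    tibble(animal_id = panel$animal_ids), as_tibble(Y),
    tibble(weight = w, cohort = cohort))
  qtl <- purrr::map_dfr(seq_len(T), function(t) {
    idx <- sort(qtl_idx[[t]])
    tibble(trait = traits$trait_names[t], snp_id = panel$map$snp_id[idx],
           snp_index = idx)
  })
  list(phenotypes = phenotypes,
       truth = list(qtl = qtl, true_effects = B, true_breeding_values = g))
}

#' Simulate a complete data set
#'
#' Runs [simulate_genotypes()] and [simulate_effects_and_phenotypes()] and
#' bundles the results with the trait model and config.
#'
#' @param config A [simulation_config()].
#' @return Object of class `gwablup_sim`: list with `panel`, `phenotypes`,
#'   `truth`, `traits`, `config`.
#' @export
simulate_dataset <- function(config) {
  panel <- simulate_genotypes(config)
  sim <- simulate_effects_and_phenotypes(panel, config)
  structure(list(panel = panel, phenotypes = sim$phenotypes, truth = sim$truth,
                 traits = config$traits, config = config),
            class = "gwablup_sim")
}

#' @export
print.gwablup_sim <- function(x, ...) {
  cat(sprintf("<gwablup_sim> %d animals (%d validation) x %d SNPs, %d traits, %d QTL/trait\n",
              x$config$n_animals, x$config$n_validation, x$config$n_snps,
              length(x$traits$trait_names), x$config$n_qtl_per_trait))
  invisible(x)
}
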