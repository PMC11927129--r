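# Shared fixtures and independent oracles used across the suite.

tiny_map <- function(n_snps = 4, chromosome = "chr1") {
  tibble::tibble(chromosome = chromosome,
                 snp_id = sprintf("s%02d", seq_len(n_snps)),
                 position = seq_len(n_snps) * 1000L)
}

tiny_panel <- function() {
  counts <- rbind(c(0L, 2L, 1L, 0L),
                  c(1L, 2L, 0L, 1L),
                  c(2L, 2L, 1L, 2L))
  genotype_panel(counts, tiny_map(4), animal_ids = c("a1", "a2", "a3"))
}

random_panel <- function(n = 50, N = 40, seed = 1, ld_decay = 0.5,
                         n_chromosomes = 2) {
  tm <- heritability_trait_model(c(0.3, 0.2, 0.2), c(0.5, 0.1, 0.1),
                                 c(0.3, 0.1, 0.1))
  cfg <- simulation_config(tm, n_animals = n, n_snps = N,
                           n_chromosomes = n_chromosomes, ld_decay = ld_decay,
                           n_qtl_per_trait = 0, seed = seed)
  simulate_genotypes(cfg)
}

random_pd <- function(T, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(T * T), T, T)
  crossprod(A) + diag(0.1, T) * scale
}

# dense assembly of the three-block mixed-model equations; independent of the
# package's matrix-free operator
dense_mme <- function(M, R, w, eps, blocks) {
  n <- nrow(M); N <- ncol(M); T <- nrow(R)
  Rw <- kronecker(diag(w, n), solve(R))
  X <- kronecker(matrix(1, n, 1), diag(T))
  Z <- kronecker(M, diag(T))
  Theta_inv <- matrix(0, N * T, N * T)
  for (j in seq_len(N)) {
    idx <- (j - 1L) * T + seq_len(T)
    Theta_inv[idx, idx] <- solve(blocks[, , j])
  }
  A <- rbind(
    cbind(t(X) %*% Rw %*% X, t(X) %*% Rw, matrix(0, T, N * T)),
    cbind(Rw %*% X, Rw + diag(n * T) / eps, -Z / eps),
    cbind(matrix(0, N * T, T), -t(Z) / eps, crossprod(Z) / eps + Theta_inv))
  rhs_of <- function(Y) {
    y <- as.vector(t(Y))
    c(t(X) %*% Rw %*% y, Rw %*% y, rep(0, N * T))
  }
  list(A = A, rhs_of = rhs_of, X = X, Z = Z, Rw = Rw)
}

# a small fitted scenario shared by solver tests
tiny_mme_case <- function(n = 6, N = 8, T = 3, seed = 42,
                          scheme = "trait_specific", eps = 0.01) {
  set.seed(seed)
  panel <- random_panel(n = n, N = N, seed = seed)
  centered <- suppressMessages(center_genotypes(panel))
  tm <- trait_model(paste0("t", 1:T), random_pd(T, seed + 1),
                    random_pd(T, seed + 2) / 2)
  weights <- fake_weights(centered$map, T, seed = seed + 3,
                          trait_names = tm$trait_names)
  prior <- build_prior(scheme, tm, centered$scale_sum, weights = weights,
                       n_snps = ncol(centered$matrix))
  w <- runif(n, 0.5, 1.5)
  Y <- matrix(rnorm(n * T), n, T, dimnames = list(rownames(centered$matrix),
                                                  tm$trait_names))
  list(panel = panel, centered = centered, traits = tm, weights = weights,
       prior = prior, w = w, Y = Y, eps = eps)
}

# snp_weights object with prescribed posterior probabilities
fake_weights <- function(map, T, pp = NULL, seed = 1,
                         trait_names = paste0("t", seq_len(T))) {
  N <- nrow(map)
  if (is.null(pp)) {
    set.seed(seed)
    pp <- matrix(runif(N * T, 0.001, 0.999), N, T)
  }
  structure(
    list(map = map, lr = matrix(0, N, T), lr_smoothed = matrix(0, N, T),
         pp = pp, lr_combined = rep(0, N),
         pp_combined = rowMeans(pp), excluded = matrix(FALSE, N, T),
         pi = 0.001, half_window = 2, trait_names = trait_names),
    class = "snp_weights"
  )
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(sqrt(sum((x - y)^2)) / max(sqrt(sum(y^2)), 1e-300), tol)
}
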