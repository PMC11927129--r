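test_that("log-likelihood ratios follow 0.5 (effect/se)^2", {
  expect_equal(loglik_ratio(0.1, 0.05), 2.0)
  expect_equal(loglik_ratio(0, 1), 0)
  expect_error(loglik_ratio(1, 0), "positive")
  set.seed(5)
  eff <- rnorm(100); se <- runif(100, 0.01, 1)
  expect_equal(loglik_ratio(eff, se), 0.5 * eff^2 / se^2, tolerance = 1e-14)
})

test_that("moving average respects windows, ends and chromosome boundaries", {
  map1 <- tiny_map(5)
  expect_equal(moving_average_by_chromosome(c(0, 0, 10, 0, 0), map1)[3], 2.0)
  v <- rnorm(5)
  expect_equal(moving_average_by_chromosome(v, map1, half_window = 0), v)

  map2 <- tibble::tibble(chromosome = rep(c("chr1", "chr2"), each = 3),
                         snp_id = sprintf("s%d", 1:6),
                         position = rep(c(100L, 200L, 300L), 2))
  set.seed(6)
  v2 <- rnorm(6)
  out <- moving_average_by_chromosome(v2, map2, half_window = 2)
  # brute-force oracle: average over same-chromosome SNPs within the window
  brute <- vapply(1:6, function(j) {
    idx <- which(map2$chromosome == map2$chromosome[j] &
                   abs(seq_len(6) - j) <= 2)
    mean(v2[idx])
  }, numeric(1))
  expect_equal(out, brute, tolerance = 1e-12)
  # first SNP of chromosome 2 must not see chromosome 1
  expect_equal(out[4], mean(v2[4:6]), tolerance = 1e-12)
})

test_that("posterior probability equals the prior at zero evidence and saturates safely", {
  expect_equal(posterior_probability(0, 0.001), 0.001, tolerance = 1e-12)
  # high-precision value of 0.001 e^20 / (0.001 e^20 + 0.999)
  expect_equal(posterior_probability(20, 0.001), 0.9999979408443908,
               tolerance = 1e-9)
  big <- posterior_probability(800, 0.001)
  expect_true(is.finite(big) && big < 1)
  lr <- seq(0, 30, by = 0.5)
  pp <- posterior_probability(lr, 0.001)
  expect_true(all(diff(pp) > 0))          # monotone in the evidence
  expect_true(all(pp > 0 & pp < 1))
  expect_error(posterior_probability(1, 1.5), "pi")
})

test_that("the base per-SNP prior is G over the heterozygosity sum", {
  tm <- trait_model(paste0("t", 1:3), diag(3), diag(3))
  expect_equal(base_vsnp(tm, 2), diag(3) / 2, ignore_attr = TRUE)
  G <- random_pd(3, 11)
  tm2 <- trait_model(paste0("t", 1:3), G, diag(3), bend = FALSE)
  p <- runif(20, 0.05, 0.95)
  ss <- sum(2 * p * (1 - p))
  V <- base_vsnp(tm2, ss)
  # summing the implied genetic variance over SNPs recovers G exactly
  expect_equal(Reduce(`+`, lapply(p, function(pj) 2 * pj * (1 - pj) * V)),
               G, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("snp_weights smooths back-transformed likelihood ratios into posteriors", {
  set.seed(40)
  panel <- random_panel(n = 60, N = 20, seed = 40)
  centered <- suppressMessages(center_genotypes(panel))
  tm <- trait_model(paste0("t", 1:2), random_pd(2, 41), random_pd(2, 42),
                    bend = FALSE)
  tr <- canonical_transform(tm)
  Y <- matrix(rnorm(120), 60, 2,
              dimnames = list(rownames(centered$matrix), tr$canonical_names))
  gwas <- single_snp_scan(centered, Y)
  w <- snp_weights(gwas, tr, pi = 0.001, half_window = 2)
  N <- nrow(w$pp)
  expect_true(all(w$pp > 0 & w$pp < 1))
  expect_true(all(w$lr >= 0))
  # smoothed LR columns reproduce moving_average_by_chromosome on the raw LR
  back <- back_transform_effects(gwas, tr)
  lr1 <- loglik_ratio(back$effects[, 1], back$se[, 1])
  expect_equal(w$lr_smoothed[, 1],
               moving_average_by_chromosome(lr1, w$map, 2),
               ignore_attr = TRUE)
  # combined track: smoothed canonical LRs summed, then the posterior map
  lr_can <- loglik_ratio(gwas$effects, gwas$se)
  manual <- rowSums(apply(lr_can, 2, moving_average_by_chromosome,
                          map = w$map, half_window = 2))
  expect_equal(w$lr_combined, manual, ignore_attr = TRUE)
  expect_equal(w$pp_combined, posterior_probability(manual, 0.001),
               ignore_attr = TRUE)
})

test_that("degenerate SNPs keep the prior probability instead of being dropped", {
  set.seed(45)
  X <- cbind(c(-1, 0, 1, 0, 1, -1), rnorm(6), c(1, -1, 0, 0, 1, -1))
  dimnames(X) <- list(paste0("a", 1:6), sprintf("s%02d", 1:3))
  centered <- structure(
    list(matrix = X, allele_freq = rep(0.5, 3), scale_sum = 1.5,
         map = tiny_map(3), reference_ids = rownames(X),
         n_dropped_monomorphic = 0L, n_imputed = 0L),
    class = "centered_genotypes")
  Y <- matrix(3 * X[, 1], 6, 1, dimnames = list(rownames(X), "t1"))
  expect_warning(gwas <- single_snp_scan(centered, Y), "exact fit")
  tm <- trait_model("t1", matrix(0.3), matrix(1))
  tr <- canonical_transform(tm)
  w <- snp_weights(gwas, tr, pi = 0.001)
  expect_true(w$excluded[1, 1])
  expect_equal(unname(w$pp[1, 1]), 0.001)
  expect_equal(nrow(w$pp), 3L)     # nothing dropped
})

test_that("trait-specific prior blocks scale variances but preserve correlations", {
  # forced arithmetic: base_V = [[4, 2], [2, 4]], S_j = diag(2, 1)
  prior <- structure(
    list(scheme = "trait_specific", base_V = rbind(c(4, 2), c(2, 4)),
         base_V_inv = solve(rbind(c(4, 2), c(2, 4))),
         smat = rbind(c(2, 1)), n_snps = 1L, trait_names = c("a", "b")),
    class = "snp_prior")
  expect_equal(vsnp_blocks(prior, 1), rbind(c(16, 4), c(4, 4)))
  expect_equal(stats::cov2cor(vsnp_blocks(prior, 1))[1, 2], 0.5)
})

test_that("prior construction normalizes and degenerates correctly across schemes", {
  map <- tiny_map(30)
  tm <- trait_model(paste0("t", 1:3), random_pd(3, 50), random_pd(3, 51),
                    bend = FALSE)
  ss <- 12.3
  base_V <- base_vsnp(tm, ss)

  # equal posterior probabilities: both weighted schemes collapse to unweighted
  wts_flat <- fake_weights(map, 3, pp = matrix(0.4, 30, 3),
                           trait_names = tm$trait_names)
  for (scheme in c("equal_weights", "trait_specific")) {
    pr <- build_prior(scheme, tm, ss, weights = wts_flat)
    expect_equal(vsnp_blocks(pr, 7), base_V, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  # random posteriors: per-trait variances average to base_V's diagonal and
  # correlations are preserved in every block
  wts <- fake_weights(map, 3, seed = 52, trait_names = tm$trait_names)
  pr <- build_prior("trait_specific", tm, ss, weights = wts)
  blocks <- vsnp_blocks(pr)
  vars <- t(apply(blocks, 3, diag))
  expect_equal(colMeans(vars), unname(diag(base_V)), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in c(1, 15, 30)) {
    expect_equal(stats::cov2cor(blocks[, , j]), stats::cov2cor(base_V),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # scale factors average to one per trait
  expect_equal(colMeans(pr$smat^2), c(1, 1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  pr_eq <- build_prior("equal_weights", tm, ss, weights = wts)
  vars_eq <- t(apply(vsnp_blocks(pr_eq), 3, diag))
  expect_equal(colMeans(vars_eq), unname(diag(base_V)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # unweighted needs only the SNP count
  pr_unw <- build_prior("unweighted", tm, ss, n_snps = 30)
  expect_equal(vsnp_blocks(pr_unw, 3), base_V, ignore_attr = TRUE)
  expect_error(build_prior("equal_weights", tm, ss), "requires")
})

test_that("weight tables round-trip to TSV and tidy to long format", {
  set.seed(60)
  panel <- random_panel(n = 40, N = 10, seed = 60)
  centered <- suppressMessages(center_genotypes(panel))
  tm <- trait_model(paste0("t", 1:2), random_pd(2, 61), random_pd(2, 62),
                    bend = FALSE)
  tr <- canonical_transform(tm)
  Y <- matrix(rnorm(80), 40, 2,
              dimnames = list(rownames(centered$matrix), tr$canonical_names))
  w <- snp_weights(single_snp_scan(centered, Y), tr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_weights(w, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(tab$pp_combined, unname(w$pp_combined), tolerance = 1e-9)
  long <- tidy(w)
  expect_setequal(unique(long$trait), c(tm$trait_names, "combined"))
  p <- autoplot(w)
  expect_s3_class(p, "ggplot")
})
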