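#' Matrix-free operator for the augmented multitrait mixed-model equations
#'
#' Represents the coefficient matrix of the three-block mixed-model equations
#' for (mu, u, b) — trait means, multitrait breeding values, multitrait SNP
#' effects — without ever materializing `Z = M (x) I_T` or `Z'Z`. The blocks
#' are, with `Rw = W^-1 (x) R^-1` (record-weighted residual precision):
#'
#' \preformatted{
#'   [ X' Rw X   X' Rw            0                  ]
#'   [ Rw X      Rw + I/epsilon   -Z/epsilon         ]
#'   [ 0         -Z'/epsilon      Z'Z/epsilon + Theta^-1 ]
#' }
#'
#' where `Theta` is the block-diagonal prior with per-SNP blocks `V_SNP_j`
#' and `epsilon` is the small constant regularizing Var(\[u; b\]) (u = Zb in
#' the epsilon -> 0 limit). `Theta^-1` is applied blockwise through the
#' per-SNP diagonal scale factors and the single inverse of the base prior
#' covariance. Vectors are stacked traits-within-level: (mu, u, b).
#'
#' @param centered A [center_genotypes()] result.
#' @param traits A [trait_model()] supplying R.
#' @param prior An [snp_prior][build_prior()].
#' @param record_weight Positive record weights, one per training animal.
#' @param animal_ids Training animal ids (rows of the centered matrix to use);
#'   default all.
#' @param epsilon Regularization constant coupling u to Zb (default 0.01).
#' @return Object of class `mme_operator`.
#' @export
mme_operator <- function(centered, traits, prior, record_weight = NULL,
                         animal_ids = NULL, epsilon = 0.01) {
  stopifnot(inherits(centered, "centered_genotypes"),
            inherits(traits, "trait_model"),
            inherits(prior, "snp_prior"))
  if (epsilon <= 0) stop_gwablup("epsilon must be positive")
  animal_ids <- animal_ids %||% rownames(centered$matrix)
  M <- centered_rows(centered, animal_ids)
  n <- nrow(M); N <- ncol(M); T <- length(traits$trait_names)
  if (prior$n_snps != N) {
    stop_gwablup("prior has %d SNP blocks but the panel has %d SNPs", prior$n_snps, N)
  }
  w <- record_weight %||% rep(1, n)
  if (length(w) != n || any(w <= 0)) stop_gwablup("record weights must be positive, one per training animal")
  structure(
    list(M = M, Rinv = solve(traits$R), w = w, sum_w = sum(w),
         eps = epsilon, smat = prior$smat, base_V_inv = prior$base_V_inv,
         n = n, N = N, T = T, animal_ids = animal_ids,
         snp_ids = centered$map$snp_id, trait_names = traits$trait_names),
    class = "mme_operator"
  )
}

mme_dim <- function(op) op$T + op$n * op$T + op$N * op$T

unstack_mme <- function(op, v) {
  T <- op$T
  list(mu = v[seq_len(T)],
       U = matrix(v[T + seq_len(op$n * T)], op$n, T, byrow = TRUE),
       B = matrix(v[T + op$n * T + seq_len(op$N * T)], op$N, T, byrow = TRUE))
}

stack_mme <- function(mu, U, B) c(mu, as.vector(t(U)), as.vector(t(B)))

theta_inv_apply <- function(op, B) {
  ((B / op$smat) %*% op$base_V_inv) / op$smat
}

#' Apply the mixed-model-equations operator to a stacked vector
#'
#' @param op An [mme_operator()].
#' @param v Numeric vector of length `T + n_a T + N_snps T`, stacked
#'   (mu, u, b) with traits within level.
#' @return The matrix-vector product, same length.
#' @export
apply_mme <- function(op, v) {
  stopifnot(inherits(op, "mme_operator"))
  if (length(v) != mme_dim(op)) {
    stop_gwablup("vector length %d does not match the system dimension %d",
                 length(v), mme_dim(op))
  }
  parts <- unstack_mme(op, v)
  Rinv_mu <- as.vector(op$Rinv %*% parts$mu)
  wU <- op$w * parts$U
  MB <- op$M %*% parts$B
  r1 <- op$sum_w * Rinv_mu + as.vector(op$Rinv %*% colSums(wU))
  r2 <- outer(op$w, Rinv_mu) + wU %*% op$Rinv +
    (parts$U - MB) / op$eps
  r3 <- crossprod(op$M, MB - parts$U) / op$eps + theta_inv_apply(op, parts$B)
  stack_mme(r1, r2, r3)
}

#' Block-diagonal preconditioner for the mixed-model equations
#'
#' Extracts the T x T diagonal block of the coefficient matrix at every level
#' of every effect — one block for the trait means, one per animal
#' (`w_i R^-1 + I/epsilon`), one per SNP (`(m_j' m_j / epsilon) I + V_SNP_j^-1`)
#' — inverts each, and applies them blockwise. A numerically singular block is
#' regularized by adding `1e-8 * trace / T` to its diagonal (logged).
#'
#' @param op An [mme_operator()].
#' @return Object of class `mme_preconditioner` holding the inverted blocks.
#' @export
block_preconditioner <- function(op) {
  stopifnot(inherits(op, "mme_operator"))
  T <- op$T
  n_regularized <- 0L
  inv_block <- function(A) {
    tryCatch(solve(A), error = function(e) {
      n_regularized <<- n_regularized + 1L
      solve(A + diag(1e-8 * sum(diag(A)) / T, T))
    })
  }
  P_mu <- inv_block(op$sum_w * op$Rinv)
  I_eps <- diag(T) / op$eps
  Pa <- matrix(0, op$n, T * T)
  for (i in seq_len(op$n)) {
    Pa[i, ] <- as.vector(inv_block(op$w[i] * op$Rinv + I_eps))
  }
  c2 <- colSums(op$M^2)
  Ps <- matrix(0, op$N, T * T)
  for (j in seq_len(op$N)) {
    dinv <- 1 / op$smat[j, ]
    Vinv_j <- op$base_V_inv * outer(dinv, dinv)
    Ps[j, ] <- as.vector(inv_block(diag(c2[j] / op$eps, T) + Vinv_j))
  }
  if (n_regularized > 0) {
    message(sprintf("block_preconditioner: regularized %d singular diagonal block(s)",
                    n_regularized))
  }
  structure(list(P_mu = P_mu, Pa = Pa, Ps = Ps, T = T, n = op$n, N = op$N),
            class = "mme_preconditioner")
}

#' Apply the block-diagonal preconditioner
#'
#' @param prec An [block_preconditioner()] result.
#' @param v Stacked vector.
#' @return `M^-1 v`, same length.
#' @export
apply_preconditioner <- function(prec, v) {
  stopifnot(inherits(prec, "mme_preconditioner"))
  T <- prec$T
  mu <- as.vector(prec$P_mu %*% v[seq_len(T)])
  U <- matrix(v[T + seq_len(prec$n * T)], prec$n, T, byrow = TRUE)
  B <- matrix(v[T + prec$n * T + seq_len(prec$N * T)], prec$N, T, byrow = TRUE)
  stack_mme(mu, apply_block_rows(prec$Pa, U), apply_block_rows(prec$Ps, B))
}

#' Preconditioned conjugate gradient on the mixed-model equations
#'
#' Solves `A x = rhs` for the stacked (mu, u, b) vector with conjugate
#' gradients preconditioned by the block-diagonal preconditioner. Convergence
#' is the Euclidean norm of the residual relative to that of the right-hand
#' side falling below `tolerance`; the true residual (not the recursive PCG
#' residual) is recomputed every `check_every` iterations, and again to
#' confirm convergence, guarding against drift. The start vector is zero, so
#' repeated runs are bit-identical.
#'
#' @param op An [mme_operator()].
#' @param rhs Right-hand side, stacked like the solution.
#' @param tolerance Relative-residual tolerance (default 1e-9).
#' @param max_iter Iteration cap; reaching it returns `converged = FALSE`
#'   rather than an error.
#' @param check_every True-residual recomputation interval (default 50).
#' @param preconditioner Optional precomputed [block_preconditioner()].
#' @return List: `x`, `iterations`, `rel_residual`, `converged`, `history`
#'   (tibble of checkpoint iteration / relative residual), `tolerance`.
#' @export
solve_mme <- function(op, rhs, tolerance = 1e-9, max_iter = 10000L,
                      check_every = 50L, preconditioner = NULL) {
  stopifnot(inherits(op, "mme_operator"))
  if (length(rhs) != mme_dim(op)) stop_gwablup("rhs length mismatch")
  prec <- preconditioner %||% block_preconditioner(op)
  rhs_norm <- sqrt(sum(rhs^2))
  hist_iter <- integer(0); hist_rel <- numeric(0)
  if (rhs_norm == 0) {
    return(list(x = numeric(length(rhs)), iterations = 0L, rel_residual = 0,
                converged = TRUE,
                history = tibble(iteration = 0L, rel_residual = 0),
                tolerance = tolerance))
  }
  x <- numeric(length(rhs))
  r <- rhs
  z <- apply_preconditioner(prec, r)
  p <- z
  rz <- sum(r * z)
  converged <- FALSE
  rel <- 1
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Ap <- apply_mme(op, p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel_rec <- sqrt(sum(r^2)) / rhs_norm
    if (it %% check_every == 0L || rel_rec < tolerance) {
      r <- rhs - apply_mme(op, x)     # true residual
      rel <- sqrt(sum(r^2)) / rhs_norm
      hist_iter <- c(hist_iter, it); hist_rel <- c(hist_rel, rel)
      if (rel < tolerance) { converged <- TRUE; break }
    } else {
      rel <- rel_rec
    }
    z <- apply_preconditioner(prec, r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (!converged) {
    r <- rhs - apply_mme(op, x)
    rel <- sqrt(sum(r^2)) / rhs_norm
    hist_iter <- c(hist_iter, it); hist_rel <- c(hist_rel, rel)
    converged <- rel < tolerance
  }
  list(x = x, iterations = it, rel_residual = rel, converged = converged,
       history = tibble(iteration = hist_iter, rel_residual = hist_rel),
       tolerance = tolerance)
}

#' Fit a multitrait (GWAS-weighted) SNP-BLUP
#'
#' Assembles the right-hand side of the augmented mixed-model equations from
#' the training phenotypes and solves for the trait means, multitrait breeding
#' values and multitrait SNP effects with [solve_mme()].
#'
#' @param centered A [center_genotypes()] result (centered on the training
#'   animals).
#' @param yd Numeric matrix (training animals x T) of yield deviations on the
#'   original trait scale, rownames = animal ids.
#' @param traits A [trait_model()].
#' @param prior An [snp_prior][build_prior()] for the chosen weighting scheme.
#' @param record_weight Positive record weights, one per row of `yd`.
#' @param epsilon,tolerance,max_iter,check_every Passed to the operator and
#'   solver.
#' @return Object of class `gwablup_fit`: `mu_hat` (named length-T vector),
#'   `u_hat` (n x T), `b_hat` (N_snps x T), `iterations`, `rel_residual`,
#'   `converged`, `history`, `scheme`, `epsilon`, `map`.
#' @export
fit_snpblup <- function(centered, yd, traits, prior, record_weight = NULL,
                        epsilon = 0.01, tolerance = 1e-9, max_iter = 10000L,
                        check_every = 50L) {
  Y <- as_trait_matrix(yd, traits$trait_names)
  if (is.null(rownames(Y))) stop_gwablup("yd must have animal ids as rownames")
  n <- nrow(Y)
  w <- record_weight %||% rep(1, n)
  op <- mme_operator(centered, traits, prior, record_weight = w,
                     animal_ids = rownames(Y), epsilon = epsilon)
  wY <- w * Y
  rhs <- stack_mme(as.vector(op$Rinv %*% colSums(wY)),
                   wY %*% op$Rinv,
                   matrix(0, op$N, op$T))
  sol <- solve_mme(op, rhs, tolerance = tolerance, max_iter = max_iter,
                   check_every = check_every)
  parts <- unstack_mme(op, sol$x)
  trait_names <- traits$trait_names
  mu_hat <- stats::setNames(parts$mu, trait_names)
  u_hat <- parts$U; dimnames(u_hat) <- list(rownames(Y), trait_names)
  b_hat <- parts$B; dimnames(b_hat) <- list(op$snp_ids, trait_names)
  structure(
    list(mu_hat = mu_hat, u_hat = u_hat, b_hat = b_hat,
         iterations = sol$iterations, rel_residual = sol$rel_residual,
         converged = sol$converged, history = sol$history,
         scheme = prior$scheme, epsilon = epsilon, tolerance = tolerance,
         map = centered$map),
    class = "gwablup_fit"
  )
}

#' @export
print.gwablup_fit <- function(x, ...) {
  cat(sprintf("<gwablup_fit> scheme = %s, %d animals x %d SNPs x %d traits\n",
              x$scheme, nrow(x$u_hat), nrow(x$b_hat), ncol(x$b_hat)))
  cat(sprintf("  PCG: %d iterations, relative residual %.2e (%s)\n",
              x$iterations, x$rel_residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy SNP effects of a fitted SNP-BLUP
#'
#' @param x A `gwablup_fit`.
#' @param ... Unused.
#' @return Long tibble: `chromosome`, `snp_id`, `position`, `trait`, `effect`.
#' @export
tidy.gwablup_fit <- function(x, ...) {
  traits <- colnames(x$b_hat)
  purrr::map_dfr(seq_along(traits), function(t) {
    tibble(chromosome = x$map$chromosome, snp_id = x$map$snp_id,
           position = x$map$position, trait = traits[t],
           effect = x$b_hat[, t])
  })
}

#' One-row summary of a fitted SNP-BLUP
#'
#' @param x A `gwablup_fit`.
#' @param ... Unused.
#' @return Tibble with scheme, dimensions and solver diagnostics.
#' @export
glance.gwablup_fit <- function(x, ...) {
  tibble(scheme = x$scheme, n_animals = nrow(x$u_hat), n_snps = nrow(x$b_hat),
         n_traits = ncol(x$b_hat), epsilon = x$epsilon,
         iterations = x$iterations, rel_residual = x$rel_residual,
         converged = x$converged)
}

#' Genomic predictions from estimated SNP effects
#'
#' `g_hat = Z_v b_hat`: multiplies the centered genotypes of the target
#' animals (centered with training allele frequencies) by the estimated SNP
#' effects.
#'
#' @param object A `gwablup_fit`.
#' @param centered A [center_genotypes()] result containing the target
#'   animals; its SNP set must match the fit.
#' @param animal_ids Animals to predict; default all animals in `centered`.
#' @param ... Unused.
#' @return Numeric matrix (animals x T) of predicted genetic values.
#' @export
predict.gwablup_fit <- function(object, centered, animal_ids = NULL, ...) {
  predict_gebv(object$b_hat, centered, animal_ids = animal_ids)
}

#' @param b_hat N_snps x T matrix of SNP effects with SNP ids as rownames.
#' @rdname predict.gwablup_fit
#' @export
predict_gebv <- function(b_hat, centered, animal_ids = NULL) {
  stopifnot(inherits(centered, "centered_genotypes"))
  if (!identical(rownames(b_hat), centered$map$snp_id)) {
    stop_gwablup("SNP set of b_hat does not match the centered genotype panel")
  }
  Z <- if (is.null(animal_ids)) centered$matrix else centered_rows(centered, animal_ids)
  Z %*% b_hat
}
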