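#' Reliability of genomic predictions
#'
#' The squared Pearson correlation between the (masked) validation phenotypes
#' and the predicted genetic values — the standard indicator of prediction
#' reliability in a validation cohort.
#'
#' @param y_v Validation phenotypes (yield deviations).
#' @param g_hat Predicted genetic values, same length.
#' @return A number in \[0, 1\].
#' @export
reliability <- function(y_v, g_hat) {
  check_validation_pair(y_v, g_hat)
  cor(y_v, g_hat)^2
}

#' Inflation slope of genomic predictions
#'
#' The ordinary least-squares regression coefficient of the validation
#' phenotypes on the predictions. A slope of 1 indicates unbiased dispersion;
#' a slope below 1 indicates inflated (over-dispersed) predictions.
#'
#' @inheritParams reliability
#' @return The regression slope.
#' @export
inflation_slope <- function(y_v, g_hat) {
  check_validation_pair(y_v, g_hat)
  cov(y_v, g_hat) / var(g_hat)
}

check_validation_pair <- function(y_v, g_hat) {
  if (length(y_v) != length(g_hat)) stop_gwablup("y_v and g_hat lengths differ")
  if (length(y_v) < 3) stop_gwablup("at least 3 validation animals are required")
  if (sd(y_v) == 0 || sd(g_hat) == 0) {
    stop_gwablup("zero variance in phenotypes or predictions: undefined result")
  }
  invisible(TRUE)
}

#' Reliability relative to the phenotype's own reliability
#'
#' Expresses a genomic-prediction reliability as a fraction of the reliability
#' of the validation phenotypes themselves (e.g. of the yield deviations),
#' rounded to two decimals for reporting.
#'
#' @param reliability Genomic-prediction reliability.
#' @param yd_reliability Reliability of the validation phenotypes (> 0).
#' @return The ratio, rounded to 2 decimals.
#' @export
relative_reliability <- function(reliability, yd_reliability) {
  if (any(yd_reliability <= 0)) stop_gwablup("yd_reliability must be positive")
  round(reliability / yd_reliability, 2)
}

#' Bootstrap comparison of two prediction methods
#'
#' Resamples validation animals with replacement — keeping each animal's
#' phenotype and both methods' predictions together — and scores in what
#' fraction of resamples method k's correlation with the phenotypes exceeds
#' method l's. The comparison is declared significant (two-sided, P < 0.05)
#' when the win fraction exceeds 0.975 (k better) or the loss fraction —
#' resamples in which k's correlation is strictly smaller — exceeds 0.975
#' (l better). Ties count towards neither side (conservative), so a method
#' compared against itself is never significant. A degenerate resample (zero
#' variance in any vector) is redrawn and logged.
#'
#' @param y_v Validation phenotypes.
#' @param g_hat_k,g_hat_l Predictions of methods k and l, aligned with `y_v`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed for reproducible resampling.
#' @param indices Optional precomputed resampling index matrix
#'   (`n_v x n_boot`), e.g. to share resamples across several comparisons as
#'   in a paired design; overrides `seed`.
#' @return List: `win_fraction`, `loss_fraction`, `significant`, `better`
#'   (`"k"`, `"l"` or `NA`), `n_boot`, `n_redrawn`.
#' @export
bootstrap_compare <- function(y_v, g_hat_k, g_hat_l, n_boot = 10000L,
                              seed = NULL, indices = NULL) {
  check_validation_pair(y_v, g_hat_k)
  check_validation_pair(y_v, g_hat_l)
  if (n_boot < 1) stop_gwablup("n_boot must be >= 1")
  n_v <- length(y_v)
  if (is.null(indices)) {
    if (!is.null(seed)) set.seed(seed)
    indices <- matrix(sample.int(n_v, n_v * n_boot, replace = TRUE), n_v, n_boot)
  }
  if (nrow(indices) != n_v) stop_gwablup("index matrix rows must equal length(y_v)")
  n_boot <- ncol(indices)
  wins <- losses <- logical(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    idx <- indices[, b]
    repeat {
      yb <- y_v[idx]; kb <- g_hat_k[idx]; lb <- g_hat_l[idx]
      if (sd(yb) > 0 && sd(kb) > 0 && sd(lb) > 0) break
      n_redrawn <- n_redrawn + 1L
      idx <- sample.int(n_v, n_v, replace = TRUE)
    }
    ck <- cor(yb, kb); cl <- cor(yb, lb)
    wins[b] <- ck > cl
    losses[b] <- ck < cl
  }
  if (n_redrawn > 0) {
    message(sprintf("bootstrap_compare: redrew %d degenerate resample(s)", n_redrawn))
  }
  f <- mean(wins); fl <- mean(losses)
  significant <- f > 0.975 || fl > 0.975
  list(win_fraction = f, loss_fraction = fl, significant = significant,
       better = if (f > 0.975) "k" else if (fl > 0.975) "l" else NA_character_,
       n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Validate several prediction methods on a masked cohort
#'
#' Computes per-trait reliability and inflation slope for each method, and —
#' when two or more methods are supplied — bootstrap significance of every
#' pairwise reliability difference. All comparisons within a run share one
#' set of resampled indices, coupling them positively as in a paired design.
#'
#' @param y_v Validation phenotypes: animals x T matrix (or data frame of the
#'   trait columns).
#' @param predictions Named list of prediction matrices (animals x T), one per
#'   method, aligned with `y_v`.
#' @param n_boot Bootstrap resamples for the pairwise comparisons.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `validation_report`: list with `metrics` (tibble:
#'   `method`, `trait`, `reliability`, `slope`, `n_v`) and `comparisons`
#'   (tibble: `trait`, `method_k`, `method_l`, `win_fraction`, `significant`,
#'   `better`).
#' @export
validate_predictions <- function(y_v, predictions, n_boot = 10000L, seed = NULL) {
  Y <- as_trait_matrix(y_v)
  if (!is.list(predictions) || is.null(names(predictions))) {
    stop_gwablup("predictions must be a named list of matrices")
  }
  traits <- colnames(Y) %||% paste0("trait", seq_len(ncol(Y)))
  n_v <- nrow(Y)
  metrics <- purrr::map_dfr(names(predictions), function(m) {
    P <- as_trait_matrix(predictions[[m]])
    if (!all(dim(P) == dim(Y))) stop_gwablup("predictions '%s' do not match y_v", m)
    purrr::map_dfr(seq_along(traits), function(t) {
      tibble(method = m, trait = traits[t],
             reliability = reliability(Y[, t], P[, t]),
             slope = inflation_slope(Y[, t], P[, t]),
             n_v = n_v)
    })
  })
  comparisons <- NULL
  if (length(predictions) >= 2) {
    if (!is.null(seed)) set.seed(seed)
    indices <- matrix(sample.int(n_v, n_v * n_boot, replace = TRUE), n_v, n_boot)
    pairs <- utils::combn(names(predictions), 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      purrr::map_dfr(seq_along(traits), function(t) {
        res <- bootstrap_compare(Y[, t],
                                 as_trait_matrix(predictions[[pr[1]]])[, t],
                                 as_trait_matrix(predictions[[pr[2]]])[, t],
                                 indices = indices)
        tibble(trait = traits[t], method_k = pr[1], method_l = pr[2],
               win_fraction = res$win_fraction,
               significant = res$significant, better = res$better)
      })
    })
  }
  structure(list(metrics = metrics, comparisons = comparisons),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(tidyr::pivot_wider(x$metrics, id_cols = "method",
                           names_from = "trait", values_from = "reliability"))
  if (!is.null(x$comparisons) && any(x$comparisons$significant)) {
    sig <- dplyr::filter(x$comparisons, .data$significant)
    cat(sprintf("  %d significant pairwise difference(s)\n", nrow(sig)))
  }
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The per-method, per-trait metrics tibble.
#' @export
tidy.validation_report <- function(x, ...) x$metrics

#' Plot validation reliabilities by method and trait
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$trait, y = .data$reliability,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(cor(y[v], hat(g)[v])^2)) +
    ggplot2::theme_minimal()
}
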