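#' Permutation surrogate test of classification performance
#'
#' Chance-level benchmark for the TP/FP classifier: the training labels are
#' randomly permuted (class sizes preserved), a forest with the same
#' hyper-parameters is retrained on each permutation with a fresh seed, and
#' its balanced accuracy on the untouched evaluation events forms the null
#' distribution. Performance is significant when the observed balanced
#' accuracy (unpermuted training) exceeds the 95th quantile of the null
#' (linear-interpolation empirical quantile). The p value uses the add-one
#' permutation convention `(1 + #(null >= observed)) / (1 + n)`, so it is
#' never zero.
#'
#' @param train_table a [feature_table()] with both classes.
#' @param eval_events labeled evaluation events.
#' @param n_randomizations number of label permutations (default 1000; a
#'   warning is given below 20, where the quantile is unstable).
#' @param rng_seed master seed.
#' @param n_trees trees per forest.
#' @return list of class `SurrogateResult` with
#'   `observed_balanced_accuracy_pct`, `null_values`, `q95`, `p_value`,
#'   `significant`.
#' @export
permutation_null_test <- function(train_table, eval_events,
                                  n_randomizations = 1000, rng_seed = 1,
                                  n_trees = 1000) {
  stopifnot(inherits(train_table, "FeatureTable"))
  if (nlevels(droplevels(train_table$y)) < 2L)
    stop("both classes must be present")
  if (n_randomizations < 20)
    warning("fewer than 20 randomizations: the 95th quantile is unstable")
  obs_model <- train_random_forest(train_table, n_trees = n_trees,
                                   rng_seed = derive_seed(rng_seed, 0L))
  observed <- evaluate_balanced_accuracy(obs_model, eval_events)
  null_values <- numeric(n_randomizations)
  for (r in seq_len(n_randomizations)) {
    perm_table <- train_table
    set.seed(derive_seed(rng_seed, r))
    perm_table$y <- sample(train_table$y)
    m <- train_random_forest(perm_table, n_trees = n_trees,
                             rng_seed = derive_seed(rng_seed, 50000L + r))
    null_values[r] <- evaluate_balanced_accuracy(m, eval_events)
  }
  q95 <- stats::quantile(null_values, 0.95, names = FALSE)
  structure(list(observed_balanced_accuracy_pct = observed,
                 null_values = null_values,
                 q95 = q95,
                 p_value = (1 + sum(null_values >= observed)) /
                   (1 + n_randomizations),
                 significant = observed > q95),
            class = "SurrogateResult")
}

#' @export
print.SurrogateResult <- function(x, ...) {
  cat(sprintf(
    "SurrogateResult: observed balanced accuracy %.1f%%, null 95th quantile %.1f%% (n = %d), p = %.4g -> %s\n",
    x$observed_balanced_accuracy_pct, x$q95, length(x$null_values),
    x$p_value, if (x$significant) "significant" else "not significant"))
  invisible(x)
}
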