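#' Split off a fixed validation set by input order
#'
#' Takes the FIRST `n_pos_val` positives and FIRST `n_neg_val` negatives
#' (in input row order) as the validation set; everything else is the
#' remainder.  Input order is therefore part of the protocol: the same
#' dataset in the same order always yields the same split.
#'
#' @param x Feature matrix.
#' @param y Labels in `{-1, +1}` aligned with the rows of `x`.
#' @param n_pos_val,n_neg_val Validation counts per class (may be 0).
#' @return A list with `validation` and `remainder`, each a list with
#'   elements `x` and `y` preserving input row order.
#' @export
split_validation <- function(x, y, n_pos_val, n_neg_val) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  pos <- which(y > 0)
  neg <- which(y < 0)
  if (n_pos_val > length(pos))
    stop("requested ", n_pos_val, " validation positives but only ",
         length(pos), " available")
  if (n_neg_val > length(neg))
    stop("requested ", n_neg_val, " validation negatives but only ",
         length(neg), " available")
  val_idx <- sort(c(utils::head(pos, n_pos_val),
                    utils::head(neg, n_neg_val)))
  take <- function(idx) list(x = x[idx, , drop = FALSE], y = y[idx])
  list(validation = take(val_idx),
       remainder = take(setdiff(seq_along(y), val_idx)))
}

#' Sweep the number of training negatives
#'
#' For each requested count `n`, trains an ensemble on all of the
#' remainder's positives plus the FIRST `n` of its negatives (prefixes,
#' so smaller training sets are nested in larger ones), evaluates it on
#' the fixed validation set, and records the metrics.  This measures how
#' predictive performance responds to the number of negative training
#' samples available to the booster.
#'
#' @param remainder,validation Lists with `x` and `y` as produced by
#'   [split_validation()].
#' @param n_values Ordered vector of negative-set sizes to try.
#' @param registry Base-learner roster (default [default_registry()]).
#' @param T Boosting rounds per training run.
#' @param seed Integer seed (shared across the sweep for comparability).
#' @return A `data.frame` with one row per requested `n`, in request
#'   order: `n`, `ACC`, `MCC`, `SE`, `SP`, `F1` (ACC/SE/SP in percent,
#'   F1/MCC as fractions).
#' @export
sweep_negatives <- function(remainder, validation, n_values,
                            registry = default_registry(),
                            T = length(registry), seed = 1L) {
  pos <- which(remainder$y > 0)
  neg <- which(remainder$y < 0)
  bad <- n_values[n_values > length(neg)]
  if (length(bad))
    stop("requested n = ", bad[1], " negatives but only ",
         length(neg), " available in the remainder")
  if (any(n_values < 1)) stop("'n_values' must be positive")
  rows <- lapply(n_values, function(n) {
    idx <- sort(c(pos, utils::head(neg, n)))
    model <- unbalanced_adaboost(remainder$x[idx, , drop = FALSE],
                                 remainder$y[idx], registry = registry,
                                 T = T, seed = seed)
    m <- evaluate_model(model, validation$x, validation$y)$metrics
    data.frame(n = n, ACC = m$ACC, MCC = m$MCC, SE = m$SE, SP = m$SP,
               F1 = m$F1)
  })
  do.call(rbind, rows)
}
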