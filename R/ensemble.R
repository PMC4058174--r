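#' Uniform initial weight distribution over the negative set
#'
#' @param l Number of negative training samples (>= 1).
#' @return Numeric vector of `l` weights, each `1/l`.
#' @export
initial_weights <- function(l) {
  l <- as.integer(l)
  if (is.na(l) || l < 1L) stop("need at least one negative sample")
  rep(1 / l, l)
}

#' Weighted sampling of negative training rows
#'
#' Draws `k` indices with replacement from `1..length(w)`, each draw
#' taking index i with probability `w[i]`.  Reproducible given `seed`.
#'
#' @param w Weight distribution over the negatives (non-negative, sums
#'   to 1).
#' @param k Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of `k` sampled indices (a multiset).
#' @export
sample_negatives <- function(w, k, seed = 1L) {
  if (k < 1L) stop("'k' must be at least 1")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
    stop("'w' must be a probability distribution")
  set.seed(seed)
  sample.int(length(w), size = k, replace = TRUE, prob = w)
}

#' Weight-increase factor for misclassified negatives
#'
#' After each boosting round, the weights of negatives the round's
#' learner got wrong are multiplied by
#' `f = log_size(size * (1 - eps) / eps)`, where `eps` is the learner's
#' error rate on the full negative training set and `size` is the number
#' of negatives.  The base-`size` logarithm damps the growth so that the
#' many negatives are cycled through gradually rather than a few hard
#' ones taking over: `f = 1` exactly at `eps = 0.5` (a chance-level
#' learner changes nothing), `f > 1` when the learner beats chance on
#' the negatives, and `f < 1` otherwise.  `eps` is clamped into
#' `[1/(2*size), 1 - 1/(2*size)]` so the factor stays finite at
#' `eps` of 0 or 1.
#'
#' @param eps Error rate of the round's learner on the negative set.
#' @param size Number of negative training samples (>= 2).
#' @return The positive scalar factor `f`.
#' @examples
#' weight_factor(0.5, 100)   # exactly 1
#' weight_factor(0.25, 100)  # log_100(300) ~ 1.2386
#' @export
weight_factor <- function(eps, size) {
  if (size < 2) stop("'size' must be at least 2")
  eps_min <- 1 / (2 * size)
  eps <- min(max(eps, eps_min), 1 - eps_min)
  log(size * (1 - eps) / eps, base = size)
}

#' Multiplicative weight update for misclassified negatives
#'
#' Multiplies the weights at `misclassified` indices by `f`, then
#' renormalizes the whole distribution to sum 1.
#'
#' @param w Current weight distribution (sums to 1).
#' @param misclassified Integer indices of negatives the round's learner
#'   misclassified (may be empty).
#' @param f Positive factor from [weight_factor()].
#' @return The updated distribution (sums to 1).
#' @export
update_weights <- function(w, misclassified, f) {
  if (f <= 0) stop("'f' must be positive")
  if (length(misclassified)) {
    if (any(misclassified < 1L | misclassified > length(w)))
      stop("misclassified indices out of range")
    w[misclassified] <- w[misclassified] * f
  }
  w / sum(w)
}

clamp <- function(x, lo, hi) min(max(x, lo), hi)

#' Train an imbalance-aware boosting ensemble
#'
#' Boosting for heavily imbalanced two-class problems (few positives,
#' many negatives).  Every round `t = 1..T` trains on a balanced set:
#' all `n` positives plus `n` negatives drawn with replacement from the
#' negative pool under the current weight distribution `W_t`.  The round
#' learner (taken from `registry`, cycling in order) is then scored on
#' the full negative pool; weights of the negatives it misclassified are
#' inflated by [weight_factor()] and renormalized, so later rounds
#' concentrate on negatives the ensemble still confuses.  Prediction
#' combines the rounds by weighted vote with the standard boosting vote
#' weight `alpha_t = log((1 - e_t)/e_t)` (clamped to `[0, 10]`), where
#' `e_t` is the round learner's unweighted error on the full training
#' set.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels in `{-1, +1}` (+1 = positive / DNA-binding); both
#'   classes must be present.
#' @param registry Ordered list of [base_learner_spec()]s; round `t`
#'   uses entry `((t - 1) mod length(registry)) + 1`.
#' @param T Number of boosting rounds (default: one pass over the
#'   registry).
#' @param seed Integer seed; the run is fully reproducible given
#'   identical data, registry, `T` and `seed`.
#' @param vote `"weighted"` (default) or `"uniform"` vote weights.
#' @return An object of class `"unbalanced_adaboost"`: fitted rounds
#'   with their vote weights `alpha`, negative-set error `eps` and
#'   weight factor `f` per round, plus the full negative-weight history
#'   `W` (a `(T_effective + 1) x l` matrix) for audit.
#' @seealso [predict.unbalanced_adaboost()], [evaluate_model()]
#' @export
unbalanced_adaboost <- function(x, y, registry = default_registry(),
                                T = length(registry), seed = 1L,
                                vote = c("weighted", "uniform")) {
  vote <- match.arg(vote)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (!length(registry)) stop("'registry' must be non-empty")
  if (T < 1L) stop("'T' must be at least 1")
  pos <- which(y > 0)
  neg <- which(y < 0)
  n <- length(pos)
  l <- length(neg)
  if (n == 0L) stop("no positive samples in training data")
  if (l == 0L) stop("no negative samples in training data")
  xpos <- x[pos, , drop = FALSE]
  xneg <- x[neg, , drop = FALSE]
  eps_min <- 1 / (2 * l)

  w <- initial_weights(l)
  W_hist <- matrix(NA_real_, nrow = T + 1L, ncol = l)
  W_hist[1L, ] <- w
  rounds <- vector("list", T)
  kept <- logical(T)
  for (t in seq_len(T)) {
    spec <- registry[[(t - 1L) %% length(registry) + 1L]]
    rs <- (seed + 7919L * t) %% 2147483647L
    idx <- sample_negatives(w, n, seed = rs)
    xt <- rbind(xpos, xneg[idx, , drop = FALSE])
    yt <- c(rep(1, n), rep(-1, n))
    h <- tryCatch(fit_base_learner(spec, xt, yt, seed = rs + 1L),
                  error = function(e) {
                    warning("round ", t, " (", spec$kind,
                            ") failed to fit and was skipped: ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(h)) {
      W_hist[t + 1L, ] <- w          # weights carry over unchanged
      next
    }
    pred_neg <- predict_base_learner(h, xneg)
    eps_raw <- mean(pred_neg != -1)
    eps <- clamp(eps_raw, eps_min, 1 - eps_min)
    f <- weight_factor(eps, l)
    w <- update_weights(w, which(pred_neg == 1), f)
    W_hist[t + 1L, ] <- w

    pred_pos <- predict_base_learner(h, xpos)
    e_full <- mean(c(pred_pos, pred_neg) != c(rep(1, n), rep(-1, l)))
    e_full <- clamp(e_full, eps_min, 1 - eps_min)
    alpha <- if (vote == "uniform") 1
             else clamp(log((1 - e_full) / e_full), 0, 10)
    rounds[[t]] <- list(t = t, kind = spec$kind, fit = h,
                        alpha = alpha, eps = eps_raw, f = f,
                        train_error = e_full)
    kept[t] <- TRUE
  }
  if (!any(kept)) stop("all ", T, " boosting rounds failed to fit")
  structure(list(rounds = rounds[kept], T = sum(kept),
                 T_requested = T, W = W_hist,
                 n_pos = n, n_neg = l, d = ncol(x),
                 feature_names = colnames(x), vote = vote,
                 seed = seed, format_version = "1"),
            class = "unbalanced_adaboost")
}

#' Predict with a trained boosting ensemble
#'
#' The ensemble score of a row is the vote-weight-normalized sum
#' `sum(alpha_t * h_t(x)) / sum(alpha_t)`, in `[-1, 1]`.  The label is
#' +1 for positive score and -1 otherwise; an exact tie goes to the
#' negative class, the majority class of the intended application.
#'
#' @param object A fitted [unbalanced_adaboost()] model.
#' @param x Feature matrix with the training-time layout.
#' @param ... Unused.
#' @return A `data.frame` with columns `label` (in `{-1, 1}`) and
#'   `score`.
#' @export
predict.unbalanced_adaboost <- function(object, x, ...) {
  stopifnot(is.matrix(x))
  if (ncol(x) != object$d)
    stop("feature dimension mismatch: model expects ", object$d,
         " features, got ", ncol(x))
  alphas <- vapply(object$rounds, `[[`, 0, "alpha")
  total <- sum(alphas)
  if (total <= 0) {  # every round at or below chance: fall back to
    alphas <- rep(1, length(alphas))                  # uniform vote
    total <- length(alphas)
  }
  votes <- vapply(object$rounds,
                  function(r) predict_base_learner(r$fit, x),
                  numeric(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  score <- as.vector(votes %*% alphas) / total
  data.frame(label = ifelse(score > 0, 1, -1), score = score)
}

#' @export
print.unbalanced_adaboost <- function(x, ...) {
  cat("Imbalance-aware boosting ensemble\n")
  cat(sprintf("  rounds: %d (%d requested), features: %d\n",
              x$T, x$T_requested, x$d))
  cat(sprintf("  training set: %d positives, %d negatives\n",
              x$n_pos, x$n_neg))
  info <- data.frame(
    round = vapply(x$rounds, `[[`, 0L, "t"),
    learner = vapply(x$rounds, `[[`, "", "kind"),
    alpha = round(vapply(x$rounds, `[[`, 0, "alpha"), 3),
    eps_neg = round(vapply(x$rounds, `[[`, 0, "eps"), 3),
    f = round(vapply(x$rounds, `[[`, 0, "f"), 3))
  print(info, row.names = FALSE)
  invisible(x)
}

#' Save / load a trained ensemble
#'
#' The archive is a single RDS file holding the fitted rounds, vote
#' weights, weight history, feature layout, seeds and a format-version
#' string.
#'
#' @param model A fitted [unbalanced_adaboost()] model.
#' @param path File path for the model archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unbalanced_adaboost"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("model archive '", path, "' does not exist")
  model <- readRDS(path)
  if (!inherits(model, "unbalanced_adaboost"))
    stop("'", path, "' does not contain a dbpboost model archive")
  if (!identical(model$format_version, "1"))
    stop("unsupported model archive version: ", model$format_version)
  model
}
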