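#' Specify a base classifier
#'
#' @param kind Registered algorithm kind; see [default_registry()] for
#'   the roster.
#' @param params Named list of hyperparameter overrides passed to the
#'   underlying fitting function.
#' @return An object of class `"base_learner_spec"`.
#' @export
base_learner_spec <- function(kind, params = list()) {
  kind <- match.arg(kind, learner_kinds())
  structure(list(kind = kind, params = params),
            class = "base_learner_spec")
}

learner_kinds <- function() {
  c("ib1", "ib5", "ib15", "cart", "logistic", "tree", "naive_bayes",
    "cart_deep", "random_forest", "random_tree", "bagged_cart",
    "glmnet_logistic", "lda", "svm_linear", "nnet", "stump",
    "xgboost", "svm_sigmoid", "zero_r", "svm_radial", "ranger_rf")
}

#' Default roster of 20 heterogeneous base classifiers
#'
#' The ensemble draws strength from base-learner diversity, so the
#' default registry spans four families: nearest-neighbour classifiers
#' (k = 1, 5, 15), decision trees of several flavours (pruned and deep
#' CART, a binary tree, a single random tree, bagged trees, a random
#' forest, gradient-boosted trees, a one-split stump), simple
#' probabilistic / linear models standing in for rule learners (naive
#' Bayes, logistic regression, penalized logistic regression, linear
#' discriminant, a majority-class baseline), and margin / function
#' classifiers (linear, sigmoid and radial-kernel SVMs, a small neural
#' network).  No attempt is made to reproduce the internals of any
#' particular machine-learning toolkit's implementations.
#'
#' @return Ordered list of 20 [base_learner_spec()] objects.
#' @export
default_registry <- function() {
  specs <- list(
    base_learner_spec("ib1"),
    base_learner_spec("ib5"),
    base_learner_spec("ib15"),
    base_learner_spec("cart"),
    base_learner_spec("logistic"),
    base_learner_spec("tree"),
    base_learner_spec("naive_bayes"),
    base_learner_spec("cart_deep"),
    base_learner_spec("random_forest"),
    base_learner_spec("random_tree"),
    base_learner_spec("bagged_cart"),
    base_learner_spec("glmnet_logistic"),
    base_learner_spec("lda"),
    base_learner_spec("svm_linear"),
    base_learner_spec("nnet"),
    base_learner_spec("stump"),
    base_learner_spec("xgboost"),
    base_learner_spec("svm_sigmoid"),
    base_learner_spec("zero_r"),
    base_learner_spec("svm_radial")
  )
  names(specs) <- vapply(specs, `[[`, "", "kind")
  specs
}

# merge user params over defaults
merge_params <- function(defaults, override) {
  defaults[names(override)] <- override
  defaults
}

y_factor <- function(y) factor(y, levels = c(-1, 1))

#' Fit a single base classifier
#'
#' Trains one classifier from the roster directly (outside any boosting
#' loop), e.g. to compare a lone learner on the full imbalanced data
#' against the ensemble.
#'
#' @param spec A [base_learner_spec()].
#' @param x Numeric feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param seed Integer seed controlling any internal randomness.
#' @return An object of class `"dbp_base_fit"` for
#'   [predict_base_learner()].
#' @export
fit_base_learner <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "base_learner_spec"))
  yf <- y_factor(y)
  if (nlevels(droplevels(yf)) < 2L && spec$kind != "zero_r")
    stop("base learner '", spec$kind, "' needs both classes present")
  p <- spec$params
  set.seed(seed)
  df <- data.frame(.y = yf, x, check.names = TRUE)
  fit <- switch(spec$kind,
    ib1  = ,
    ib5  = ,
    ib15 = list(train = x, cl = yf,
                k = c(ib1 = 1L, ib5 = 5L, ib15 = 15L)[[spec$kind]]),
    cart = rpart::rpart(.y ~ ., data = df, method = "class",
             control = do.call(rpart::rpart.control,
                               merge_params(list(cp = 0.01), p))),
    cart_deep = rpart::rpart(.y ~ ., data = df, method = "class",
             control = do.call(rpart::rpart.control,
                               merge_params(list(cp = 0.001, minsplit = 5),
                                            p))),
    stump = rpart::rpart(.y ~ ., data = df, method = "class",
             control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                            minsplit = 2)),
    tree = tree::tree(.y ~ ., data = df),
    random_forest = do.call(randomForest::randomForest,
             c(list(x = x, y = yf), merge_params(list(ntree = 100), p))),
    random_tree = randomForest::randomForest(x = x, y = yf, ntree = 1,
             replace = FALSE, sampsize = nrow(x)),
    bagged_cart = do.call(randomForest::randomForest,
             c(list(x = x, y = yf, mtry = ncol(x)),
               merge_params(list(ntree = 50), p))),
    logistic = suppressWarnings(stats::glm(.y ~ ., data = df,
             family = stats::binomial())),
    glmnet_logistic = glmnet::glmnet(x, yf, family = "binomial",
             lambda = if (is.null(p$lambda)) 0.02 else p$lambda),
    # correlated feature blocks routinely trip the collinearity warning
    lda = suppressWarnings(MASS::lda(x, grouping = yf)),
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = yf),
    svm_linear = e1071::svm(x, yf, kernel = "linear", scale = FALSE,
             cost = if (is.null(p$cost)) 1 else p$cost),
    svm_radial = e1071::svm(x, yf, kernel = "radial", scale = FALSE,
             cost = if (is.null(p$cost)) 1 else p$cost),
    svm_sigmoid = e1071::svm(x, yf, kernel = "sigmoid", scale = FALSE),
    nnet = nnet::nnet(.y ~ ., data = df,
             size = if (is.null(p$size)) 4 else p$size,
             decay = if (is.null(p$decay)) 0.1 else p$decay,
             maxit = if (is.null(p$maxit)) 150 else p$maxit,
             trace = FALSE, MaxNWts = 5000),
    xgboost = fit_xgb(x, y, p, seed),
    zero_r = {
      npos <- sum(y > 0)
      # tie -> negative class (the application's majority prior)
      list(label = if (npos > sum(y < 0)) 1 else -1)
    },
    ranger_rf = do.call(ranger::ranger,
             c(list(x = x, y = yf, seed = seed, num.threads = 1L),
               merge_params(list(num.trees = 200), p))),
    stop("unknown learner kind: ", spec$kind)
  )
  structure(list(kind = spec$kind, fit = fit, seed = seed,
                 colnames = colnames(x)),
            class = "dbp_base_fit")
}

fit_xgb <- function(x, y, p, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = (y + 1) / 2)
  params <- merge_params(
    list(objective = "binary:logistic", max_depth = 4, eta = 0.3,
         nthread = 1L, seed = seed), p)
  nrounds <- if (is.null(p$nrounds)) 30 else p$nrounds
  params$nrounds <- NULL
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' Predict labels with a fitted base classifier
#'
#' @param object A `"dbp_base_fit"` from [fit_base_learner()].
#' @param x Feature matrix with the training-time columns.
#' @return Numeric vector of labels in `{-1, +1}`.
#' @export
predict_base_learner <- function(object, x) {
  stopifnot(inherits(object, "dbp_base_fit"))
  if (!is.null(object$colnames) && ncol(x) != length(object$colnames))
    stop("feature dimension mismatch: model expects ",
         length(object$colnames), " columns, got ", ncol(x))
  fit <- object$fit
  df <- data.frame(x, check.names = TRUE)
  out <- switch(object$kind,
    ib1  = ,
    ib5  = ,
    ib15 = {
      set.seed(object$seed)  # tie-breaking in nearest-neighbour voting
      class::knn(fit$train, x, fit$cl, k = fit$k)
    },
    cart = , cart_deep = , stump =
      stats::predict(fit, newdata = df, type = "class"),
    tree = stats::predict(fit, newdata = df, type = "class"),
    random_forest = , random_tree = , bagged_cart =
      stats::predict(fit, newdata = x),
    logistic = ifelse(suppressWarnings(
      stats::predict(fit, newdata = df, type = "response")) > 0.5, 1, -1),
    glmnet_logistic = as.vector(
      stats::predict(fit, newx = x, type = "class")),
    lda = stats::predict(fit, newdata = x)$class,
    naive_bayes = stats::predict(fit, newdata = as.data.frame(x)),
    svm_linear = , svm_radial = , svm_sigmoid =
      stats::predict(fit, newdata = x),
    nnet = stats::predict(fit, newdata = df, type = "class"),
    xgboost = ifelse(
      stats::predict(fit, newdata = xgboost::xgb.DMatrix(x)) > 0.5,
      1, -1),
    zero_r = rep(fit$label, nrow(x)),
    ranger_rf = stats::predict(fit, data = x,
                               num.threads = 1L)$predictions,
    stop("unknown learner kind: ", object$kind)
  )
  lab <- if (is.factor(out)) as.numeric(as.character(out))
         else as.numeric(out)
  if (is.character(out)) lab <- as.numeric(out)
  if (!all(lab %in% c(-1, 1)))
    stop("base learner '", object$kind,
         "' produced labels outside {-1, +1}")
  lab
}
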