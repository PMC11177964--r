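# Regression from topological feature vectors to ddG, with pooled
# cross-validated Pearson correlation and RMSE.

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return Centered product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  as.numeric(stats::cor(x, y))
}

#' Root mean squared error
#'
#' @param pred,obs Numeric vectors (kcal/mol) of equal length.
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) == 0) stop("empty input")
  sqrt(mean((pred - obs)^2))
}

#' Model configuration for ddG regression
#'
#' @param learner `"gbt"` (gradient-boosted trees, the default) or
#'   `"linear"` (ordinary least squares; useful as a reference).
#' @param nrounds,eta,max_depth,subsample,colsample_bytree GBT
#'   hyperparameters.
#' @param seed Integer seed controlling any learner randomness.
#' @return List of class `ddg_model_config`.
#' @export
model_config <- function(learner = c("gbt", "linear"), nrounds = 2000,
                         eta = 0.03, max_depth = 4, subsample = 0.9,
                         colsample_bytree = 0.9, seed = 42) {
  learner <- match.arg(learner)
  structure(list(learner = learner, nrounds = nrounds, eta = eta,
                 max_depth = max_depth, subsample = subsample,
                 colsample_bytree = colsample_bytree, seed = seed),
            class = "ddg_model_config")
}

check_feature_matrix <- function(features) {
  features <- as.matrix(features)
  bad <- which(!is.finite(features), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cn <- colnames(features)
    col <- if (is.null(cn)) bad[1, 2] else cn[bad[1, 2]]
    stop("non-finite feature value in column '", col, "'")
  }
  features
}

#' Train a ddG regressor
#'
#' Deterministic given data, configuration and seed.
#'
#' @param features Numeric matrix (rows = mutations, columns = features).
#' @param targets ddG values, kcal/mol.
#' @param config A [model_config()].
#' @return Object of class `ddg_model` with a `predict` method.
#' @export
train_model <- function(features, targets, config = model_config()) {
  features <- check_feature_matrix(features)
  if (nrow(features) < 10) stop("need at least 10 training rows")
  if (length(targets) != nrow(features)) stop("targets/features mismatch")
  if (any(!is.finite(targets))) stop("non-finite target")

  fit <- if (config$learner == "gbt") {
    set.seed(config$seed)
    dtrain <- xgboost::xgb.DMatrix(features, label = targets)
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = config$eta,
                    max_depth = config$max_depth,
                    subsample = config$subsample,
                    colsample_bytree = config$colsample_bytree,
                    nthread = 1, seed = config$seed),
      data = dtrain, nrounds = config$nrounds, verbose = 0)
  } else {
    df <- as.data.frame(features)
    names(df) <- paste0("f", seq_len(ncol(features)))
    stats::lm(y ~ ., data = cbind(df, y = targets))
  }
  structure(list(fit = fit, config = config,
                 feature_names = colnames(features)),
            class = "ddg_model")
}

#' @export
predict.ddg_model <- function(object, newdata, ...) {
  newdata <- check_feature_matrix(newdata)
  if (object$config$learner == "gbt") {
    as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(newdata)))
  } else {
    df <- as.data.frame(newdata)
    names(df) <- paste0("f", seq_len(ncol(newdata)))
    as.numeric(stats::predict(object$fit, df))
  }
}

fold_groups <- function(records, n, grouping) {
  if (grouping == "record" || is.null(records)) {
    as.character(seq_len(n))
  } else if (grouping == "complex") {
    as.character(records$complex_id)
  } else {
    # a mutation and its reverse share a group
    spec <- lapply(as.character(records$mutation), parse_mutation_code)
    key <- vapply(spec, function(m) {
      aa <- sort(c(m$wt_aa, m$mut_aa))
      paste(m$chain, m$res_seq, aa[1], aa[2])
    }, "")
    paste(records$complex_id, key)
  }
}

#' k-fold cross-validated ddG prediction
#'
#' Random fold assignment with a fixed seed, optionally grouped so that all
#' records of a complex (`grouping = "complex"`) or a mutation and its
#' reverse (`grouping = "mutation-pair"`) stay in one fold. Pearson
#' correlation and RMSE are computed over the pooled out-of-fold
#' predictions.
#'
#' @param features Numeric feature matrix.
#' @param targets ddG values, kcal/mol.
#' @param records Optional `ddg_records` data.frame (needed for grouped
#'   fold assignment; must have `complex_id` and `mutation` columns).
#' @param k_folds Number of folds, default 10.
#' @param seed Fold-assignment seed.
#' @param grouping `"record"` (default), `"complex"` or `"mutation-pair"`.
#' @param config A [model_config()].
#' @return A `CVResult` list: `rp`, `rmse` (kcal/mol), `fold_assignments`,
#'   `predictions`, `seed`.
#' @export
cross_validate <- function(features, targets, records = NULL, k_folds = 10,
                           seed = 42, grouping = c("record", "complex",
                                                   "mutation-pair"),
                           config = model_config()) {
  grouping <- match.arg(grouping)
  features <- check_feature_matrix(features)
  n <- nrow(features)
  if (k_folds < 2) stop("k_folds must be at least 2")
  if (n < k_folds) stop("fewer records than folds")
  if (grouping != "record" && is.null(records)) {
    stop("grouped fold assignment needs the records table")
  }
  groups <- fold_groups(records, n, grouping)
  ug <- unique(groups)
  if (length(ug) < k_folds) {
    stop("only ", length(ug), " groups for ", k_folds, " folds")
  }
  set.seed(seed)
  fold_of_group <- sample(rep_len(seq_len(k_folds), length(ug)))
  names(fold_of_group) <- ug
  folds <- fold_of_group[groups]

  predictions <- rep(NA_real_, n)
  for (f in seq_len(k_folds)) {
    test <- which(folds == f)
    if (length(test) == 0) next
    model <- train_model(features[-test, , drop = FALSE], targets[-test],
                         config)
    predictions[test] <- predict(model, features[test, , drop = FALSE])
  }
  structure(list(rp = pearson_r(predictions, targets),
                 rmse = rmse(predictions, targets),
                 fold_assignments = unname(folds),
                 predictions = predictions, seed = seed,
                 grouping = grouping),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s grouping): Rp = %.3f, RMSE = %.3f kcal/mol\n",
              length(unique(x$fold_assignments)), x$grouping, x$rp, x$rmse))
  invisible(x)
}
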