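#' Configuration for the classification protocol
#'
#' Bundles the experiment-design knobs: stratified 85/15 train/test split,
#' 5-fold cross-validation for the lasso penalty on the training data alone,
#' undersampling-bagging for class imbalance, and 20 repeats of the whole
#' procedure.
#'
#' @param comparison Character pair of labels, positive class first (the
#'   clinically worse diagnosis, e.g. `c("AD", "NC")`).
#' @param train_fraction Fraction of subjects in the training split
#'   (default 0.85).
#' @param n_repeats Number of split/fit/test repeats (default 20).
#' @param cv_folds Cross-validation folds for penalty selection (default 5).
#' @param n_bags Undersampled models averaged in the final ensemble
#'   (default 21, odd so majority vote is defined).
#' @param lambda_grid_size Penalties on the log-spaced path (default 20).
#' @param master_seed Integer seed from which every split, fold, undersample
#'   and bag seed is derived.
#' @param solver Named list of [splr()] settings used for the many interior
#'   fits (`tol`, `max_iter`, `kkt_tol`). The defaults trade a little solver
#'   precision for speed; penalty selection and ensemble averaging are
#'   insensitive at this level.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(comparison, train_fraction = 0.85,
                              n_repeats = 20L, cv_folds = 5L, n_bags = 21L,
                              lambda_grid_size = 20L, master_seed = 1L,
                              solver = list(tol = 1e-6, max_iter = 2000L,
                                            kkt_tol = 1e-4)) {
  if (length(comparison) != 2L || comparison[1] == comparison[2]) {
    stop("comparison must be two distinct labels, positive class first")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (n_bags %% 2L == 0L) stop("n_bags must be odd")
  structure(list(comparison = comparison, train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 cv_folds = as.integer(cv_folds),
                 n_bags = as.integer(n_bags),
                 lambda_grid_size = as.integer(lambda_grid_size),
                 master_seed = as.integer(master_seed),
                 solver = solver),
            class = "experiment_config")
}

#' Standardize feature columns by training statistics
#'
#' Subtracts training means and divides by training standard deviations,
#' applying the same transform to the test block. Constant training columns
#' (sd = 0) become all-zero in both.
#'
#' @param train Training feature matrix.
#' @param test Optional test feature matrix with the same columns.
#' @return List with `train`, `test` (or `NULL`), `means`, `sds`.
#' @export
standardize_columns <- function(train, test = NULL) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sds <- apply(train, 2, stats::sd)
  scale_safe <- ifelse(sds > 0, sds, 1)
  tr <- sweep(sweep(train, 2, mu), 2, scale_safe, "/")
  tr[, sds == 0] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(as.matrix(test), 2, mu), 2, scale_safe, "/")
    te[, sds == 0] <- 0
  }
  list(train = tr, test = te, means = mu, sds = sds)
}

#' Balance a two-class sample by undersampling the majority class
#'
#' Keeps every minority-class index and draws, uniformly without replacement,
#' an equal number of majority-class indices. A balanced input returns all
#' indices unchanged.
#'
#' @param labels Two-class label vector.
#' @param seed Integer seed.
#' @return Integer index vector (sorted).
#' @export
undersample <- function(labels, seed = 1L) {
  classes <- unique(labels)
  if (length(classes) != 2L) stop("undersampling needs exactly two classes")
  counts <- table(factor(labels, levels = classes))
  if (counts[1] == counts[2]) return(seq_along(labels))
  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  keep_major <- sample(which(labels == majority), min(counts))
  sort(c(which(labels == minority), keep_major))
}

#' Ensemble of sparse logistic models on undersampled draws
#'
#' Fits `n_bags` models, each on an independent undersample of the training
#' data, and averages their predicted probabilities. With balanced classes
#' every undersample is the full data, so a single fit represents the whole
#' ensemble.
#'
#' @param x Standardized training feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param lambda Lasso penalty.
#' @param n_bags Ensemble size.
#' @param seed Integer seed; bag b uses `seed + b`.
#' @param ... Passed to [splr()].
#' @return Object of class `splr_bag` (list of `splr` fits).
#' @export
bagged_fit <- function(x, y, lambda, n_bags = 21L, seed = 1L, ...) {
  x <- as.matrix(x)
  check_labels(y)
  balanced <- sum(y == 1) == sum(y == -1)
  n_fit <- if (balanced) 1L else as.integer(n_bags)
  fits <- vector("list", n_fit)
  for (b in seq_len(n_fit)) {
    idx <- undersample(y, seed = seed + b)
    fits[[b]] <- splr(x[idx, , drop = FALSE], y[idx], lambda, ...)
  }
  structure(list(fits = fits, n_bags = as.integer(n_bags),
                 balanced = balanced, lambda = lambda),
            class = "splr_bag")
}

#' @export
predict.splr_bag <- function(object, newdata,
                             type = c("response", "class"), ...) {
  type <- match.arg(type)
  probs <- rowMeans(vapply(object$fits,
                           function(f) predict(f, newdata, type = "response"),
                           numeric(nrow(as.matrix(newdata)))))
  if (type == "response") probs else ifelse(probs >= 0.5, 1, -1)
}

#' @export
print.splr_bag <- function(x, ...) {
  cat(sprintf("Undersampling-bagging ensemble: %d bag(s)%s, lambda = %.4g\n",
              length(x$fits),
              if (x$balanced) " (balanced data, single fit)" else "",
              x$lambda))
  invisible(x)
}

#' Classification performance measures
#'
#' Accuracy, sensitivity (recall on the +1 class), specificity, and AUC
#' computed as the Mann-Whitney rank statistic on the predicted probabilities
#' with midranks for ties. With a one-class truth vector only accuracy is
#' defined; the rest are `NA`.
#'
#' @param probs Predicted probabilities of the +1 class.
#' @param preds Predicted labels in `{-1, +1}`.
#' @param truth True labels in `{-1, +1}`.
#' @return Named numeric vector
#'   `c(accuracy, sensitivity, specificity, auc)`.
#' @export
performance_metrics <- function(probs, preds, truth) {
  if (length(truth) == 0) stop("empty evaluation set")
  acc <- mean(preds == truth)
  pos <- truth == 1
  if (!any(pos) || all(pos)) {
    return(c(accuracy = acc, sensitivity = NA_real_,
             specificity = NA_real_, auc = NA_real_))
  }
  sens <- mean(preds[pos] == 1)
  spec <- mean(preds[!pos] == -1)
  r <- rank(probs)  # midranks
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

stratified_split <- function(labels, train_fraction, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

stratified_folds <- function(labels, k, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_select_lambda <- function(x, y, grid, cv_folds, seed,
                             solver = list()) {
  for (try in 1:10) {
    fold <- stratified_folds(y, cv_folds, seed + try - 1L)
    ok <- all(vapply(seq_len(cv_folds), function(f) {
      length(unique(y[fold != f])) == 2L && sum(fold == f) > 0
    }, logical(1)))
    if (ok) break
    if (try == 10) stop("could not build folds with both classes present")
  }
  acc <- matrix(NA_real_, cv_folds, length(grid))
  for (f in seq_len(cv_folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    us <- undersample(y[tr], seed = seed + 100L + f)
    tr_us <- tr[us]
    std <- standardize_columns(x[tr_us, , drop = FALSE], x[va, , drop = FALSE])
    w0 <- NULL; c0 <- NULL
    for (j in seq_along(grid)) {
      # interior fits routinely stop at the iteration cap; that is fine here
      fit <- withCallingHandlers(
        do.call(splr, c(list(std$train, y[tr_us], grid[j], w0 = w0, c0 = c0),
                        solver)),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      w0 <- fit$w; c0 <- fit$c  # warm start down the path
      pred <- predict(fit, std$test, type = "class")
      acc[f, j] <- mean(pred == y[va])
    }
  }
  mean_acc <- colMeans(acc)
  # grid is descending; ties resolve to the largest (sparsest) penalty
  grid[which.max(mean_acc)]
}

#' Run the full classification protocol on a feature matrix
#'
#' For each repeat: stratified train/test split, penalty selection by
#' cross-validated accuracy on the training data alone (ties toward the larger
#' penalty), an undersampling-bagging ensemble refit on the whole training
#' set, and evaluation on the held-out test set. Fully deterministic given
#' `config$master_seed`.
#'
#' @param features n x m feature matrix (rows aligned with `labels`).
#' @param labels Character label per subject; subjects outside
#'   `config$comparison` are dropped.
#' @param config An [experiment_config()].
#' @return Object of class `connectome_eval`: `per_repeat` (data frame of
#'   accuracy/sensitivity/specificity/auc per repeat), `summary` (mean and sd
#'   per measure), `predictions` (per-repeat test-set probabilities, predicted
#'   and true labels), `lambdas` (penalty chosen per repeat) and `config`.
#' @export
run_experiment <- function(features, labels, config) {
  stopifnot(inherits(config, "experiment_config"))
  features <- as.matrix(features)
  labels <- as.character(labels)
  keep <- labels %in% config$comparison
  x <- features[keep, , drop = FALSE]
  lab <- labels[keep]
  if (length(unique(lab)) != 2L) stop("both comparison classes must be present")
  y <- ifelse(lab == config$comparison[1], 1, -1)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(which(keep))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$master_seed)
  repeat_seeds <- sample.int(.Machine$integer.max %/% 2, config$n_repeats)

  per_repeat <- matrix(NA_real_, config$n_repeats, 4,
                       dimnames = list(NULL, c("accuracy", "sensitivity",
                                               "specificity", "auc")))
  lambdas <- numeric(config$n_repeats)
  preds <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    sr <- repeat_seeds[r]
    tr <- stratified_split(y, config$train_fraction, sr)
    te <- setdiff(seq_along(y), tr)
    grid <- lambda_path(x[tr, , drop = FALSE], y[tr],
                        n_values = config$lambda_grid_size)
    lam <- cv_select_lambda(x[tr, , drop = FALSE], y[tr], grid,
                            config$cv_folds, sr + 1L, config$solver)
    std <- standardize_columns(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    ens <- do.call(bagged_fit,
                   c(list(std$train, y[tr], lam, n_bags = config$n_bags,
                          seed = sr + 1000L), config$solver))
    probs <- predict(ens, std$test, type = "response")
    pred <- ifelse(probs >= 0.5, 1, -1)
    per_repeat[r, ] <- performance_metrics(probs, pred, y[te])
    lambdas[r] <- lam
    preds[[r]] <- data.frame(repeat_id = r, subject_id = ids[te],
                             probability = probs,
                             predicted = ifelse(pred == 1, config$comparison[1],
                                                config$comparison[2]),
                             truth = lab[te], stringsAsFactors = FALSE)
  }
  per_repeat <- as.data.frame(per_repeat)
  per_repeat <- cbind(repeat_id = seq_len(config$n_repeats), per_repeat)
  structure(list(
    per_repeat = per_repeat,
    summary = rbind(mean = colMeans(per_repeat[, -1]),
                    sd = apply(per_repeat[, -1], 2, stats::sd)),
    predictions = do.call(rbind, preds),
    lambdas = lambdas,
    config = config), class = "connectome_eval")
}

#' @export
print.connectome_eval <- function(x, ...) {
  cat(sprintf("Classification: %s vs %s (%d repeats)\n",
              x$config$comparison[1], x$config$comparison[2],
              x$config$n_repeats))
  s <- x$summary
  for (m in colnames(s)) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, s["mean", m], s["sd", m]))
  }
  invisible(x)
}

#' @export
summary.connectome_eval <- function(object, ...) {
  print(object)
  cat(sprintf("  lambda chosen: median %.4g (range %.4g - %.4g)\n",
              stats::median(object$lambdas), min(object$lambdas),
              max(object$lambdas)))
  invisible(object$summary)
}
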