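#' Classifier specifications
#'
#' The nine benchmark classifiers with their fixed parameterizations:
#' 1-nearest neighbor (`KNN`), linear and quadratic discriminant analysis
#' (`LDA`, `QDA`), Gaussian naive Bayes (`NB`), a single-hidden-layer
#' perceptron with 30 units (`MLP`), a random forest with 30 trees
#' (`RF`), an extreme learning machine with 1000 random tanh units and a
#' ridge-regularized linear readout (`ELM`), and support vector machines
#' with linear (`C = 100`, `SVMLin`) and radial-basis (`C = 10`, kernel
#' scale 1, i.e. `gamma = 0.5`, `SVMRBF`) kernels.
#'
#' @param name one of the nine classifier names.
#' @param seed integer seed controlling the stochastic learners
#'   (RF, MLP, ELM).
#' @param ... overrides of the default hyperparameters.
#' @return A list of class `semg_classifier_spec`.
#' @export
classifier_spec <- function(name, seed = 1L, ...) {
  defaults <- list(
    KNN = list(k = 1L),
    LDA = list(),
    NB = list(),
    MLP = list(hidden = 30L, maxit = 500L),
    QDA = list(),
    RF = list(trees = 30L),
    ELM = list(hidden = 1000L, ridge = 1e-6),
    SVMLin = list(C = 100),
    SVMRBF = list(C = 10, kernel_scale = 1))
  if (!name %in% names(defaults)) stop("unknown classifier: ", name)
  hp <- defaults[[name]]
  dots <- list(...)
  unknown <- setdiff(names(dots), names(hp))
  if (length(unknown)) stop(name, ": unknown hyperparameter(s): ",
                            paste(unknown, collapse = ", "))
  hp[names(dots)] <- dots
  structure(list(name = name, hyperparams = hp, seed = as.integer(seed)),
            class = "semg_classifier_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()] (or a name, which is promoted with
#'   defaults).
#' @param X numeric feature matrix (rows = instances).
#' @param y labels (coerced to factor).
#' @return A fitted model of class `semg_model`, usable with [predict()].
#' @export
fit_classifier <- function(spec, X, y) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  X <- as.matrix(X)
  y <- factor(y)
  hp <- spec$hyperparams
  fit <- switch(
    spec$name,
    KNN = list(X = X, y = y),
    LDA = MASS::lda(X, grouping = y),
    QDA = MASS::qda(X, grouping = y),
    NB = e1071::naiveBayes(X, y),
    MLP = with_seed(spec$seed,
      nnet::nnet(X, nnet::class.ind(y), size = hp$hidden, softmax = TRUE,
                 maxit = hp$maxit, MaxNWts = 1e6, trace = FALSE)),
    RF = with_seed(spec$seed,
      randomForest::randomForest(X, y, ntree = hp$trees)),
    ELM = with_seed(spec$seed, {
      W <- matrix(runif(ncol(X) * hp$hidden, -1, 1), ncol(X))
      b <- runif(hp$hidden, -1, 1)
      H <- tanh(sweep(X %*% W, 2, b, "+"))
      Y <- nnet::class.ind(y)
      beta <- solve(crossprod(H) + hp$ridge * diag(hp$hidden), crossprod(H, Y))
      list(W = W, b = b, beta = beta)
    }),
    SVMLin = e1071::svm(X, y, kernel = "linear", cost = hp$C, scale = FALSE),
    SVMRBF = e1071::svm(X, y, kernel = "radial", cost = hp$C,
                        gamma = 1 / (2 * hp$kernel_scale^2), scale = FALSE))
  structure(list(spec = spec, fit = fit, levels = levels(y)),
            class = "semg_model")
}

#' @export
predict.semg_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  hp <- object$spec$hyperparams
  lv <- object$levels
  out <- switch(
    object$spec$name,
    KNN = as.character(class::knn(object$fit$X, X, object$fit$y, k = hp$k)),
    LDA = as.character(predict(object$fit, X)$class),
    QDA = as.character(predict(object$fit, X)$class),
    NB = as.character(predict(object$fit, X, threshold = 1e-3)),
    MLP = lv[max.col(predict(object$fit, X))],
    RF = as.character(predict(object$fit, X)),
    ELM = {
      H <- tanh(sweep(X %*% object$fit$W, 2, object$fit$b, "+"))
      lv[max.col(H %*% object$fit$beta)]
    },
    SVMLin = as.character(predict(object$fit, X)),
    SVMRBF = as.character(predict(object$fit, X)))
  factor(out, levels = lv)
}

# z-scoring fitted on the training rows only; zero-sd columns pass through
scale_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sg, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sg, "/"))
}

stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated evaluation of one classifier on one feature table
#'
#' Three validation schemes are supported. `pooled`: stratified k-fold
#' over all rows (overlapping windows from one activation may land in
#' different folds -- the optimistic setting). `per_subject`: an
#' independent stratified k-fold within each subject, accuracies reported
#' per subject and fold. `trial_grouped`: folds are unions of whole
#' acquisition trials (trial `j` goes to fold `(j - 1) mod folds + 1`),
#' so no trial is split across train and test; accuracies are reported
#' per subject and fold. Feature columns are z-scored with statistics
#' fitted on the training rows of each fold only.
#'
#' @param table a feature table from [extract_table()].
#' @param spec a [classifier_spec()] or classifier name.
#' @param folds number of folds (default 10).
#' @param scheme validation scheme.
#' @param seed seed for the fold assignment.
#' @param feature_subset optional character vector restricting the
#'   feature columns used.
#' @param fold_assign optional externally fixed fold assignment (pooled
#'   scheme only), for paired comparisons across classifiers.
#' @return An object of class `semg_eval` with fields `spec`, `scheme`,
#'   `fold_acc` (data.frame `fold`, `subject`, `accuracy`, `n`),
#'   `accuracy` (overall), and `confusion` (true class in rows).
#' @export
evaluate_cv <- function(table, spec, folds = 10,
                        scheme = c("pooled", "per_subject", "trial_grouped"),
                        seed = 1L, feature_subset = NULL, fold_assign = NULL) {
  scheme <- match.arg(scheme)
  if (is.character(spec)) spec <- classifier_spec(spec, seed = seed)
  cols <- if (is.null(feature_subset)) feature_cols(table) else feature_subset
  X <- as.matrix(table[, cols, drop = FALSE])
  y <- factor(table$label)
  lv <- levels(y)
  conf <- matrix(0L, length(lv), length(lv), dimnames = list(true = lv, pred = lv))
  rows <- list()

  run_fold <- function(tr, te, fold, subj_split = TRUE) {
    if (!length(te)) return()
    missing_cl <- setdiff(unique(as.character(y[te])), unique(as.character(y[tr])))
    if (length(missing_cl))
      warning("fold ", fold, ": class(es) absent from training data: ",
              paste(missing_cl, collapse = ", "), call. = FALSE)
    sc <- scale_train_test(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    if (length(unique(as.character(y[tr]))) < 2) {
      # degenerate training fold: the only fittable model is constant
      warning("fold ", fold, ": single-class training data; constant prediction",
              call. = FALSE)
      pred <- factor(rep(as.character(y[tr][1]), length(te)), levels = lv)
    } else {
      model <- fit_classifier(spec, sc$train, y[tr])
      pred <- factor(as.character(predict(model, sc$test)), levels = lv)
    }
    for (i in seq_along(te))
      conf[as.character(y[te[i]]), as.character(pred[i])] <<-
        conf[as.character(y[te[i]]), as.character(pred[i])] + 1L
    if (subj_split) {
      for (s in unique(table$subject[te])) {
        sel <- table$subject[te] == s
        rows[[length(rows) + 1L]] <<- data.frame(
          fold = fold, subject = s,
          accuracy = mean(pred[sel] == y[te][sel]), n = sum(sel))
      }
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        fold = fold, subject = NA_character_,
        accuracy = mean(pred == y[te]), n = length(te))
    }
  }

  if (scheme == "pooled") {
    if (is.null(fold_assign)) fold_assign <- with_seed(seed, stratified_folds(y, folds))
    for (f in seq_len(folds))
      run_fold(which(fold_assign != f), which(fold_assign == f), f,
               subj_split = FALSE)
  } else if (scheme == "per_subject") {
    for (s in unique(table$subject)) {
      si <- which(table$subject == s)
      fa <- with_seed(seed, stratified_folds(droplevels(y[si]), folds))
      for (f in seq_len(folds))
        run_fold(si[fa != f], si[fa == f], f)
    }
  } else {  # trial_grouped
    trials <- sort(unique(table$trial))
    if (length(trials) < folds)
      stop("trial_grouped needs at least as many trials (", length(trials),
           ") as folds (", folds, ")")
    tf <- ((seq_along(trials) - 1L) %% folds) + 1L
    names(tf) <- trials
    fa <- tf[table$trial]
    for (f in seq_len(folds))
      run_fold(which(fa != f), which(fa == f), f)
  }

  fold_acc <- do.call(rbind, rows)
  structure(list(spec = spec, scheme = scheme, folds = folds,
                 fold_acc = fold_acc,
                 accuracy = sum(diag(conf)) / sum(conf),
                 confusion = conf),
            class = "semg_eval")
}

#' @export
print.semg_eval <- function(x, ...) {
  cat(sprintf("<semg_eval> %s, %s %d-fold: overall accuracy %.4f (%d classes, %d predictions)\n",
              x$spec$name, x$scheme, x$folds, x$accuracy,
              nrow(x$confusion), sum(x$confusion)))
  invisible(x)
}

#' Factorial sweep over segmentation, feature sets, and classifiers
#'
#' For every (window length, overlap fraction) cell the recordings are
#' segmented and the union of the requested feature sets extracted once;
#' every (feature set, classifier) pair is then evaluated with
#' [evaluate_cv()]. Results come back as a tidy table with one row per
#' fold (and subject, where the scheme reports per subject).
#'
#' @param recordings list of [recording()]s.
#' @param cfg a [run_config()] (supplies onset parameters, folds, seed).
#' @param windows,overlaps grid axes (default: from `cfg`).
#' @param feature_sets character vector of set names for [resolve_set()].
#' @param classifiers character vector of classifier names.
#' @param scheme validation scheme.
#' @param derived optional named list of data-derived feature sets.
#' @return A `data.frame` with columns `W`, `phi`, `set`, `classifier`,
#'   `fold`, `subject`, `accuracy`, `n`, with the list of `semg_eval`
#'   objects in attribute `results` (keys `W<W>_phi<phi>_<set>_<clf>`).
#' @export
sweep_grid <- function(recordings, cfg = run_config(),
                       windows = cfg$window_lengths,
                       overlaps = cfg$overlap_fractions,
                       feature_sets = cfg$feature_sets,
                       classifiers = cfg$classifiers,
                       scheme = cfg$scheme, derived = NULL) {
  sets <- lapply(feature_sets, resolve_set, derived = derived)
  names(sets) <- feature_sets
  union_feats <- unique(unlist(lapply(sets, `[[`, "members")))
  out <- list(); results <- list()
  for (W in windows) for (phi in overlaps) {
    segs <- combine_segments(lapply(recordings, segment_recording,
                                    W = W, phi = phi, cfg = cfg))
    tab <- extract_table(segs, union_feats,
                         params = feature_params(n_fft = cfg$n_fft))
    for (sname in feature_sets) for (clf in classifiers) {
      ev <- evaluate_cv(tab, classifier_spec(clf, seed = cfg$seed),
                        folds = cfg$cv_folds, scheme = scheme, seed = cfg$seed,
                        feature_subset = set_columns(sets[[sname]], tab))
      key <- sprintf("W%g_phi%g_%s_%s", W, phi, sname, clf)
      results[[key]] <- ev
      fa <- ev$fold_acc
      out[[key]] <- data.frame(W = W, phi = phi, set = sname,
                               classifier = clf, fold = fa$fold,
                               subject = fa$subject, accuracy = fa$accuracy,
                               n = fa$n, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  attr(grid, "results") <- results
  grid
}
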