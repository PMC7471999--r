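#' Feature-set registry
#'
#' The named feature sets evaluated by the pipeline. G1-G5 are
#' literature sets: G1 the classic Hudgins time-domain quartet, G2
#' autoregressive + histogram, G3 the two features most repeated in
#' related gesture-recognition work, G4 the TD4 set, and G5 the TD9 set
#' (whose "MSF" and "IAV" members are read as MSR and IEMG). G6-G9 are
#' data-derived (best individual features, their time-domain and
#' frequency-domain subsets, and a statistically reduced set); the
#' registry stores reference defaults for them, and
#' [rank_individual_features()] / [greedy_reduction()] rebuild them from
#' data.
#'
#' @return Named list of character vectors.
#' @export
featureset_registry <- function() {
  list(
    G1 = c("MAV", "WL", "ZC", "SSC"),
    G2 = c("AR4", "HIST"),
    G3 = c("MAV", "AR4"),
    G4 = c("MFL", "MSR", "WAMP", "LS"),
    G5 = c("LS", "MFL", "MSR", "WAMP", "ZC", "RMS", "IEMG", "DASDV", "VAREMG"),
    G6 = c("MFL", "MNP", "TTP", "RMS", "SM1", "LS", "DASDV", "SM2", "SM3",
           "IEMG", "MAV", "WL", "MSR", "MAV1", "HIST", "VAREMG", "MAV2"),
    G7 = c("MFL", "RMS", "LS", "DASDV", "IEMG", "MAV", "WL", "MSR", "MAV1",
           "HIST", "VAREMG", "MAV2"),
    G8 = c("MNP", "SM1", "SM2", "SM3", "TTP"),
    G9 = c("MFL", "MNP", "TTP", "RMS"))
}

#' Resolve a feature set
#'
#' @param x a registry name (`"G1"`..`"G9"`) or an explicit character
#'   vector of feature names.
#' @param derived optional named list of data-derived sets overriding the
#'   registry defaults (typically `G6`-`G9` from a pipeline run).
#' @return A list of class `semg_featureset` with fields `name`,
#'   `members`.
#' @export
resolve_set <- function(x, derived = NULL) {
  reg <- featureset_registry()
  if (!is.null(derived)) reg[names(derived)] <- derived
  if (length(x) == 1 && x %in% names(reg)) {
    members <- reg[[x]]
    name <- x
  } else if (length(x) == 1 && grepl("^G[0-9]+$", x)) {
    stop("unknown feature set: ", x)
  } else {
    members <- x
    name <- "custom"
  }
  bad <- setdiff(members, feature_registry()$name)
  if (length(bad))
    stop("feature set '", name, "' contains unknown feature(s): ",
         paste(bad, collapse = ", "))
  if (!length(members)) stop("feature set '", name, "' is empty")
  structure(list(name = name, members = members), class = "semg_featureset")
}

# feature-table columns belonging to a set
set_columns <- function(set, table) {
  comp <- component_names(set$members)
  cols <- feature_cols(table)
  cols[sub("_ch[0-9]+$", "", cols) %in% comp]
}

#' Rank the individual features
#'
#' Evaluates every registry feature alone (all channels of all its
#' components) with cross-validated classification for each classifier,
#' on a fixed fold assignment so that accuracies are paired across
#' features and classifiers. Features are ordered by decreasing mean
#' accuracy over classifiers (ties broken lexicographically); the
#' classifiers whose mean accuracy exceeds the grand mean are marked as
#' selected.
#'
#' @param table feature table from [extract_table()] containing all
#'   features to rank.
#' @param classifiers character vector of classifier names.
#' @param folds number of CV folds.
#' @param seed seed for the shared fold assignment.
#' @param features features to rank (default: all present in `table`).
#' @return A list of class `semg_ranking`: `accuracy` (features x
#'   classifiers matrix of overall CV accuracies), `feature_mean`,
#'   `classifier_mean`, `grand_mean`, `ordered_features`,
#'   `selected_classifiers`.
#' @export
rank_individual_features <- function(table, classifiers, folds = 10,
                                     seed = 1L, features = NULL) {
  y <- factor(table$label)
  if (nlevels(y) < 2) stop("feature ranking needs at least 2 classes")
  present <- unique(sub("_[0-9]+$", "", sub("_ch[0-9]+$", "", feature_cols(table))))
  if (is.null(features)) features <- present
  reg <- feature_registry()
  features <- reg$name[reg$name %in% features]
  fa <- with_seed(seed, stratified_folds(y, folds))
  acc <- matrix(NA_real_, length(features), length(classifiers),
                dimnames = list(features, classifiers))
  for (f in features) {
    cols <- set_columns(list(members = f), table)
    for (clf in classifiers) {
      ev <- evaluate_cv(table, classifier_spec(clf, seed = seed),
                        folds = folds, scheme = "pooled", seed = seed,
                        feature_subset = cols, fold_assign = fa)
      acc[f, clf] <- ev$accuracy
    }
  }
  feature_mean <- rowMeans(acc)
  classifier_mean <- colMeans(acc)
  grand_mean <- mean(acc)
  ord <- order(-feature_mean, names(feature_mean))
  structure(list(accuracy = acc, feature_mean = feature_mean,
                 classifier_mean = classifier_mean, grand_mean = grand_mean,
                 ordered_features = names(feature_mean)[ord],
                 selected_classifiers =
                   colnames(acc)[classifier_mean > grand_mean],
                 folds = folds, seed = seed),
            class = "semg_ranking")
}

#' Derive the data-driven feature sets from a ranking
#'
#' `G6` collects the features whose mean accuracy exceeds the grand mean
#' (in rank order), `G7`/`G8` its time- and frequency-domain subsets.
#'
#' @param ranking a `semg_ranking`.
#' @return Named list with `G6`, `G7`, `G8`.
#' @export
derive_sets <- function(ranking) {
  reg <- feature_registry()
  g6 <- ranking$ordered_features[
    ranking$feature_mean[ranking$ordered_features] > ranking$grand_mean]
  if (!length(g6)) g6 <- ranking$ordered_features[1]
  dom <- reg$domain[match(g6, reg$name)]
  out <- list(G6 = g6, G7 = g6[dom == "time"], G8 = g6[dom == "frequency"])
  out[vapply(out, length, 1L) > 0]
}

#' Greedy rank-order feature reduction
#'
#' Adds features in ranking order, collecting the per-fold accuracies of
#' each prefix for the selected classifiers, and stops at the smallest
#' prefix whose accuracy distribution is statistically indistinguishable
#' (Friedman omnibus with Tukey-style post-hoc on ranks, level `alpha`)
#' from every larger prefix. The returned set is always a non-empty
#' prefix of the ranking order.
#'
#' @param ranking a `semg_ranking`.
#' @param table the feature table the ranking was computed on.
#' @param classifiers classifiers supplying the accuracy blocks (default:
#'   the ranking's selected classifiers).
#' @param alpha significance level of the stop rule.
#' @param max_features cap on the number of prefixes examined.
#' @param folds,seed CV controls (default: those of the ranking).
#' @return A `semg_featureset` named `"reduced"`.
#' @export
greedy_reduction <- function(ranking, table,
                             classifiers = ranking$selected_classifiers,
                             alpha = 0.05, max_features = NULL,
                             folds = ranking$folds, seed = ranking$seed) {
  ord <- ranking$ordered_features
  if (!is.null(max_features)) ord <- head(ord, max_features)
  if (length(ord) < 2) stop("reduction needs at least 2 ranked features")
  if (!length(classifiers)) classifiers <- colnames(ranking$accuracy)
  y <- factor(table$label)
  fa <- with_seed(seed, stratified_folds(y, folds))
  blocks <- matrix(NA_real_, length(ord), folds * length(classifiers),
                   dimnames = list(paste0("p", seq_along(ord)), NULL))
  for (p in seq_along(ord)) {
    cols <- set_columns(list(members = ord[seq_len(p)]), table)
    accs <- c()
    for (clf in classifiers) {
      ev <- evaluate_cv(table, classifier_spec(clf, seed = seed),
                        folds = folds, scheme = "pooled", seed = seed,
                        feature_subset = cols, fold_assign = fa)
      accs <- c(accs, ev$fold_acc$accuracy)
    }
    blocks[p, ] <- accs
  }
  rep <- friedman_posthoc(blocks, method = "tukey", alpha = alpha)
  stop_at <- length(ord)
  for (p in seq_len(length(ord) - 1)) {
    if (!any(rep$signif[p, (p + 1):length(ord)])) { stop_at <- p; break }
  }
  structure(list(name = "reduced", members = ord[seq_len(stop_at)]),
            class = "semg_featureset")
}
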