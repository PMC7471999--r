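stage_result <- function(stage, artifacts, summary, ...) {
  structure(c(list(stage = stage, artifacts = artifacts, summary = summary),
              list(...)),
            class = "semg_stage_result")
}

#' @export
print.semg_stage_result <- function(x, ...) {
  cat("<semg_stage_result> stage:", x$stage, "\n")
  str(x$summary, give.attr = FALSE)
  invisible(x)
}

write_artifact <- function(obj, out_dir, file) {
  if (is.null(out_dir)) return(character(0))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, file)
  if (is.data.frame(obj) || is.matrix(obj)) {
    write.csv(as.data.frame(obj), path, row.names = is.matrix(obj))
  } else {
    yaml::write_yaml(obj, path)
  }
  path
}

#' Stage 1: rank the individual features
#'
#' Segments the dataset with the fixed stage-1 parameters (window 1 s,
#' overlap fraction 1), extracts all 33 features, ranks each feature
#' alone across the configured classifiers, marks the classifiers above
#' the grand mean as selected, and derives the data-driven sets: G6
#' (above-mean features), G7/G8 (their time/frequency subsets), and G9
#' (greedy statistical reduction of G6).
#'
#' @param recordings list of [recording()]s.
#' @param cfg a [run_config()].
#' @param out_dir optional artifact directory.
#' @return A `semg_stage_result` carrying `ranking`, `derived` (named
#'   list of sets), and `table` (the stage-1 feature table, reused by
#'   stage 2).
#' @export
run_stage1 <- function(recordings, cfg = run_config(), out_dir = NULL) {
  segs <- combine_segments(lapply(recordings, segment_recording,
                                  W = 1, phi = 1, cfg = cfg))
  tab <- extract_table(segs, "all", params = feature_params(n_fft = cfg$n_fft))
  ranking <- rank_individual_features(tab, cfg$classifiers,
                                      folds = cfg$cv_folds, seed = cfg$seed)
  derived <- derive_sets(ranking)
  g9 <- greedy_reduction(ranking, tab, alpha = 0.05,
                         max_features = length(derived$G6))
  derived$G9 <- g9$members
  artifacts <- c(
    write_artifact(as.data.frame(ranking$accuracy), out_dir, "ranking.csv"),
    write_artifact(list(ordered_features = ranking$ordered_features,
                        selected_classifiers = ranking$selected_classifiers,
                        grand_mean = ranking$grand_mean,
                        derived_sets = derived),
                   out_dir, "selection.yaml"))
  stage_result("rank_features", artifacts,
               summary = list(selected_classifiers = ranking$selected_classifiers,
                              derived_sets = derived,
                              grand_mean = ranking$grand_mean),
               ranking = ranking, derived = derived, table = tab)
}

#' Stage 2: compare the feature sets
#'
#' Evaluates the configured feature sets on the stage-1 feature table
#' with the selected classifiers, compares their per-fold accuracy
#' distributions with a Friedman test and Tukey-style post-hoc on ranks,
#' and keeps as candidates the sets in the top statistical clique,
#' pruning any set that is a strict superset of another candidate
#' (smaller sets win within a clique).
#'
#' @param stage1 the result of [run_stage1()] (or a list with elements
#'   `table` and `summary$selected_classifiers` / `summary$derived_sets`).
#' @param cfg a [run_config()].
#' @param out_dir optional artifact directory.
#' @return A `semg_stage_result` with `summary$candidate_sets`, the
#'   accuracy blocks, and the stat report.
#' @export
run_stage2 <- function(stage1, cfg = run_config(), out_dir = NULL) {
  tab <- stage1$table
  classifiers <- stage1$summary$selected_classifiers
  if (!length(classifiers)) classifiers <- cfg$classifiers
  derived <- stage1$summary$derived_sets
  sets <- lapply(cfg$feature_sets, resolve_set, derived = derived)
  names(sets) <- cfg$feature_sets
  y <- factor(tab$label)
  fa <- with_seed(cfg$seed, stratified_folds(y, cfg$cv_folds))
  blocks <- matrix(NA_real_, length(sets), cfg$cv_folds * length(classifiers),
                   dimnames = list(names(sets), NULL))
  for (s in names(sets)) {
    accs <- c()
    for (clf in classifiers) {
      ev <- evaluate_cv(tab, classifier_spec(clf, seed = cfg$seed),
                        folds = cfg$cv_folds, scheme = "pooled",
                        seed = cfg$seed,
                        feature_subset = set_columns(sets[[s]], tab),
                        fold_assign = fa)
      accs <- c(accs, ev$fold_acc$accuracy)
    }
    blocks[s, ] <- accs
  }
  report <- friedman_posthoc(blocks, method = "tukey", alpha = 0.05)
  cdd <- cd_diagram_data(report)
  top <- cdd$cliques[[which(vapply(cdd$cliques, function(cl)
    cdd$order[1] %in% cl, TRUE))[1]]]
  keep <- top[vapply(top, function(a) {
    !any(vapply(top, function(b)
      a != b && all(sets[[b]]$members %in% sets[[a]]$members) &&
        length(sets[[b]]$members) < length(sets[[a]]$members), TRUE))
  }, TRUE)]
  artifacts <- c(write_artifact(blocks, out_dir, "set_accuracies.csv"),
                 write_artifact(list(candidate_sets = keep,
                                     mean_ranks = as.list(report$mean_ranks),
                                     p_value = report$p_value),
                                out_dir, "set_selection.yaml"))
  stage_result("compare_sets", artifacts,
               summary = list(candidate_sets = keep,
                              top_clique = top,
                              classifiers = classifiers),
               blocks = blocks, report = report)
}

axis_report <- function(grid, axis) {
  other <- setdiff(c("W", "phi"), axis)
  subj <- ifelse(is.na(grid$subject), "all", grid$subject)
  block <- interaction(grid[[other]], grid$set, grid$classifier, grid$fold,
                       subj, drop = TRUE)
  m <- tapply(grid$accuracy, list(factor(grid[[axis]]), block), mean)
  friedman_posthoc(m, method = "nemenyi", alpha = 0.05)
}

pick_from_clique <- function(report) {
  cdd <- cd_diagram_data(report)
  best <- cdd$order[1]
  top <- cdd$cliques[[which(vapply(cdd$cliques, function(cl) best %in% cl,
                                   TRUE))[1]]]
  min(as.numeric(top))
}

#' Stage 3: sweep the segmentation parameters
#'
#' Runs the full factorial (window length x overlap fraction x candidate
#' feature set x classifier) sweep, then compares window lengths and
#' overlap fractions with Friedman/Nemenyi critical-distance analyses.
#' The chosen window is the smallest one statistically tied with the
#' best-ranked window; the chosen overlap fraction is the smallest one
#' tied with the best-ranked fraction (denser overlap is preferred when
#' distributions tie, mirroring the accuracy-versus-latency reasoning of
#' armband applications).
#'
#' @param recordings list of [recording()]s.
#' @param cfg a [run_config()].
#' @param candidate_sets character vector of set names (from stage 2).
#' @param classifiers classifier names (from stage 1).
#' @param derived named list of data-derived sets.
#' @param out_dir optional artifact directory.
#' @return A `semg_stage_result` with `summary$chosen_W`,
#'   `summary$chosen_phi`, the tidy `grid`, and both axis reports.
#' @export
run_stage3 <- function(recordings, cfg = run_config(),
                       candidate_sets = c("G4", "G8", "G9"),
                       classifiers = c("KNN", "ELM", "RF", "SVMRBF"),
                       derived = NULL, out_dir = NULL) {
  grid <- sweep_grid(recordings, cfg, feature_sets = candidate_sets,
                     classifiers = classifiers, scheme = "pooled",
                     derived = derived)
  if (length(unique(grid$W)) >= 3) {
    rep_W <- axis_report(grid, "W")
    chosen_W <- pick_from_clique(rep_W)
  } else {
    rep_W <- NULL
    agg <- tapply(grid$accuracy, grid$W, mean)
    chosen_W <- as.numeric(names(agg)[which.max(agg)])
  }
  if (length(unique(grid$phi)) >= 3) {
    rep_phi <- axis_report(grid, "phi")
    chosen_phi <- pick_from_clique(rep_phi)
  } else {
    rep_phi <- NULL
    agg <- tapply(grid$accuracy, grid$phi, mean)
    chosen_phi <- as.numeric(names(agg)[which.max(agg)])
  }
  artifacts <- c(write_artifact(grid, out_dir, "grid.csv"),
                 write_artifact(list(chosen_W = chosen_W,
                                     chosen_phi = chosen_phi),
                                out_dir, "segmentation_choice.yaml"))
  stage_result("segmentation_sweep", artifacts,
               summary = list(chosen_W = chosen_W, chosen_phi = chosen_phi),
               grid = grid, report_W = rep_W, report_phi = rep_phi)
}

#' Stage 4: per-subject and trial-grouped validation
#'
#' Evaluates the chosen feature set at the chosen segmentation
#' parameters under the two subject-aware schemes: an independent k-fold
#' within each subject, and trial-grouped folds (whole acquisition trials
#' held out). Reports per-subject accuracy distributions, picks the best
#' classifier by trial-grouped overall accuracy, and aggregates its
#' confusion matrix.
#'
#' @param recordings list of [recording()]s.
#' @param cfg a [run_config()].
#' @param set feature-set name or member vector.
#' @param W,phi chosen segmentation parameters.
#' @param classifiers classifier names.
#' @param derived named list of data-derived sets.
#' @param out_dir optional artifact directory.
#' @return A `semg_stage_result` with per-scheme accuracy tables, the
#'   confusion report of the best classifier, and a summary.
#' @export
run_stage4 <- function(recordings, cfg = run_config(), set = "G9",
                       W = 1.75, phi = 0.125,
                       classifiers = c("KNN", "ELM", "RF", "SVMRBF"),
                       derived = NULL, out_dir = NULL) {
  fset <- resolve_set(set, derived = derived)
  segs <- combine_segments(lapply(recordings, segment_recording,
                                  W = W, phi = phi, cfg = cfg))
  tab <- extract_table(segs, fset$members,
                       params = feature_params(n_fft = cfg$n_fft))
  evals <- list(); acc_rows <- list()
  for (scheme in c("per_subject", "trial_grouped")) {
    for (clf in classifiers) {
      ev <- evaluate_cv(tab, classifier_spec(clf, seed = cfg$seed),
                        folds = cfg$cv_folds, scheme = scheme, seed = cfg$seed)
      evals[[paste(scheme, clf, sep = "_")]] <- ev
      fa <- ev$fold_acc
      acc_rows[[paste(scheme, clf)]] <-
        data.frame(scheme = scheme, classifier = clf, fold = fa$fold,
                   subject = fa$subject, accuracy = fa$accuracy, n = fa$n,
                   stringsAsFactors = FALSE)
    }
  }
  acc <- do.call(rbind, acc_rows)
  rownames(acc) <- NULL
  tg <- vapply(classifiers, function(clf)
    evals[[paste("trial_grouped", clf, sep = "_")]]$accuracy, 1)
  best <- classifiers[which.max(tg)]
  conf <- confusion_report(evals[[paste("trial_grouped", best, sep = "_")]])
  med <- aggregate(accuracy ~ subject,
                   data = acc[acc$scheme == "trial_grouped" &
                                acc$classifier == best, ], FUN = median)
  artifacts <- c(write_artifact(acc, out_dir, "subject_accuracy.csv"),
                 write_artifact(conf$percent, out_dir, "confusion_percent.csv"),
                 write_artifact(list(best_classifier = best,
                                     trial_grouped_accuracy = as.list(tg)),
                                out_dir, "validation_summary.yaml"))
  stage_result("subject_validation", artifacts,
               summary = list(best_classifier = best,
                              trial_grouped_accuracy = tg,
                              per_subject_median = med),
               accuracy = acc, confusion = conf, evals = evals)
}

#' Run the full four-stage pipeline
#'
#' Chains [run_stage1()] to [run_stage4()]: individual-feature ranking
#' and classifier selection, feature-set comparison, segmentation-sweep
#' selection of (W, phi), and subject-aware validation. Each stage draws
#' its randomness from an offset of the root seed and persists its
#' artifacts when `out_dir` is given.
#'
#' @param recordings list of [recording()]s.
#' @param cfg a [run_config()].
#' @param out_dir optional artifact directory (subdirectories `stage1` to
#'   `stage4`).
#' @return Named list of the four `semg_stage_result`s plus a `summary`.
#' @export
run_pipeline <- function(recordings, cfg = run_config(), out_dir = NULL) {
  sub <- function(d) if (is.null(out_dir)) NULL else file.path(out_dir, d)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 101L
  s1 <- run_stage1(recordings, cfg1, sub("stage1"))
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 202L
  s2 <- run_stage2(s1, cfg2, sub("stage2"))
  cfg3 <- cfg; cfg3$seed <- cfg$seed + 303L
  s3 <- run_stage3(recordings, cfg3, candidate_sets = s2$summary$candidate_sets,
                   classifiers = s1$summary$selected_classifiers,
                   derived = s1$derived, out_dir = sub("stage3"))
  cfg4 <- cfg; cfg4$seed <- cfg$seed + 404L
  s4 <- run_stage4(recordings, cfg4,
                   set = s2$summary$candidate_sets[
                     which.min(vapply(s2$summary$candidate_sets, function(s)
                       length(resolve_set(s, derived = s1$derived)$members), 1L))],
                   W = s3$summary$chosen_W, phi = s3$summary$chosen_phi,
                   classifiers = s1$summary$selected_classifiers,
                   derived = s1$derived, out_dir = sub("stage4"))
  list(stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4,
       summary = list(selected_classifiers = s1$summary$selected_classifiers,
                      candidate_sets = s2$summary$candidate_sets,
                      chosen_W = s3$summary$chosen_W,
                      chosen_phi = s3$summary$chosen_phi,
                      best_classifier = s4$summary$best_classifier))
}
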