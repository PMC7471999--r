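#' Friedman omnibus test with post-hoc pairwise comparisons
#'
#' Ranks the groups within every block (mid-ranks for ties; rank 1 =
#' highest accuracy), computes the tie-corrected Friedman chi-square, and
#' compares all group pairs either by the Nemenyi critical distance
#' `CD = q_alpha * sqrt(g (g + 1) / (6 b))` or by Tukey HSD applied to
#' the within-block ranks (via a two-way rank ANOVA on group + block).
#'
#' @param acc numeric matrix, groups in rows, blocks in columns; no
#'   missing cells.
#' @param method `"tukey"` or `"nemenyi"`.
#' @param alpha significance level.
#' @return An object of class `semg_statreport`: `test`, `statistic`,
#'   `p_value`, `mean_ranks` (1 = best), `signif` (symmetric boolean
#'   matrix, `FALSE` diagonal), `cd` (Nemenyi critical distance),
#'   `method`, `alpha`, `n_blocks`.
#' @export
friedman_posthoc <- function(acc, method = c("tukey", "nemenyi"),
                             alpha = 0.05) {
  method <- match.arg(method)
  acc <- as.matrix(acc)
  g <- nrow(acc); b <- ncol(acc)
  if (g < 3)
    stop("need at least 3 groups; for 2 groups use wilcoxon_pair()")
  if (b < 2) stop("need at least 2 blocks")
  if (anyNA(acc)) stop("missing cells are not supported")
  if (is.null(rownames(acc))) rownames(acc) <- paste0("g", seq_len(g))
  r <- apply(-acc, 2, rank)              # g x b, 1 = best within block
  Rsum <- rowSums(r)
  ties <- apply(r, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  denom <- b * g * (g + 1) - sum(ties) / (g - 1)
  # every block fully tied: no evidence against the null by convention
  stat <- if (denom == 0) 0 else 12 * sum((Rsum - b * (g + 1) / 2)^2) / denom
  p <- pchisq(stat, df = g - 1, lower.tail = FALSE)
  mean_ranks <- Rsum / b
  cd <- qtukey(1 - alpha, g, Inf) / sqrt(2) * sqrt(g * (g + 1) / (6 * b))
  sig <- matrix(FALSE, g, g, dimnames = list(rownames(acc), rownames(acc)))
  if (method == "nemenyi") {
    d <- abs(outer(mean_ranks, mean_ranks, "-"))
    sig <- d > cd
  } else {
    df <- data.frame(rank = as.vector(r),
                     group = factor(rep(rownames(acc), b)),
                     block = factor(rep(seq_len(b), each = g)))
    tk <- TukeyHSD(aov(rank ~ group + block, data = df), "group")$group
    pr <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pr)) {
      a1 <- pr[[i]][1]; a2 <- pr[[i]][2]
      sig[a1, a2] <- sig[a2, a1] <- tk[i, "p adj"] < alpha
    }
  }
  diag(sig) <- FALSE
  structure(list(test = "friedman", statistic = stat, p_value = p,
                 mean_ranks = mean_ranks, signif = sig, cd = cd,
                 method = method, alpha = alpha, n_blocks = b),
            class = "semg_statreport")
}

#' @export
print.semg_statreport <- function(x, ...) {
  cat(sprintf("<semg_statreport> %s: statistic %.4g, p = %.4g (%s post-hoc, alpha = %g)\n",
              x$test, x$statistic, x$p_value,
              if (is.null(x$method)) "no" else x$method, x$alpha))
  invisible(x)
}

#' Pairwise Wilcoxon comparison
#'
#' Signed-rank (paired) or rank-sum (unpaired) Wilcoxon test with
#' mid-ranks for ties and the exact distribution where available. The
#' degenerate paired case with all differences zero returns `p = 1` with
#' the `degenerate` flag set.
#'
#' @param a,b accuracy vectors (equal length required for signed-rank).
#' @param mode `"signed_rank"` or `"rank_sum"`.
#' @param alpha significance level recorded in the report.
#' @return A `semg_statreport` with fields `test`, `statistic`,
#'   `p_value`, `alpha`, `degenerate`.
#' @export
wilcoxon_pair <- function(a, b, mode = c("signed_rank", "rank_sum"),
                          alpha = 0.05) {
  mode <- match.arg(mode)
  paired <- mode == "signed_rank"
  if (paired && length(a) != length(b))
    stop("signed_rank requires paired vectors of equal length")
  degenerate <- paired && all(a == b)
  if (degenerate) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    res <- suppressWarnings(wilcox.test(a, b, paired = paired))
  }
  structure(list(test = if (paired) "wilcoxon_signed_rank" else
                   "wilcoxon_rank_sum",
                 statistic = unname(res$statistic), p_value = res$p.value,
                 alpha = alpha, degenerate = degenerate),
            class = "semg_statreport")
}

#' Critical-distance diagram data
#'
#' Orders the groups of a [friedman_posthoc()] report by mean rank (best
#' first) and extracts the maximal cliques of mutually non-significant
#' groups -- the connector lines of a critical-distance diagram.
#'
#' @param report a `semg_statreport` from [friedman_posthoc()].
#' @return A list: `order` (group names, best rank first), `mean_ranks`
#'   (in that order), `cliques` (list of character vectors, each a
#'   maximal clique, ordered by their best member), `cd`.
#' @export
cd_diagram_data <- function(report) {
  stopifnot(inherits(report, "semg_statreport"), !is.null(report$signif))
  mr <- sort(report$mean_ranks)
  adj <- !report$signif
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(gr)
  cliques <- lapply(cl, function(v) {
    nm <- names(report$mean_ranks)[as.integer(v)]
    nm[order(report$mean_ranks[nm])]
  })
  cliques <- cliques[order(vapply(cliques, function(x) min(report$mean_ranks[x]),
                                  1))]
  list(order = names(mr), mean_ranks = mr, cliques = cliques, cd = report$cd)
}

#' Aggregated confusion report
#'
#' Sums the confusion matrices of several [evaluate_cv()] results (which
#' must share a class set), normalizes each true-class row to
#' percentages, and flags cells below a display floor (0.3% by default)
#' as negligible.
#'
#' @param results a `semg_eval` or list of them.
#' @param floor_pct display floor in percent.
#' @return A list: `percent` (row-normalized class x class matrix, rows
#'   sum to 100), `counts`, `precision` (per predicted class),
#'   `negligible` (logical matrix).
#' @export
confusion_report <- function(results, floor_pct = 0.3) {
  if (inherits(results, "semg_eval")) results <- list(results)
  cls <- rownames(results[[1]]$confusion)
  counts <- matrix(0, length(cls), length(cls),
                   dimnames = dimnames(results[[1]]$confusion))
  for (r in results) {
    if (!identical(rownames(r$confusion), cls))
      stop("confusion matrices have mismatching class sets")
    counts <- counts + r$confusion
  }
  rs <- rowSums(counts)
  percent <- sweep(counts, 1, ifelse(rs == 0, 1, rs), "/") * 100
  colsum <- colSums(counts)
  precision <- ifelse(colsum == 0, NA_real_, diag(counts) / colsum)
  list(percent = percent, counts = counts, precision = precision,
       negligible = percent < floor_pct)
}
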