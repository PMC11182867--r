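#' Pool garden-level descriptive statistics into area statistics
#'
#' Combines per-garden summaries (n, mean, min, max) into per-area
#' statistics: the area n is the sum of garden n, the area mean the
#' sample-size-weighted mean of garden means, and the area min/max the
#' extrema of the garden extrema. When raw per-sample values are supplied
#' the same statistics (plus the median) are computed directly from them,
#' and the weighted mean equals the mean of the concatenated raw values.
#'
#' @param garden_summaries data.frame with columns `garden_code`, `area`,
#'   `n`, `mean`, and optionally `min`, `max` (min/max may be `NA`, e.g.
#'   below-detection minima).
#' @param raw optional data.frame of raw samples with columns `area`,
#'   `value`; when given, statistics are computed from it instead.
#' @return data.frame, one row per area: `area`, `n`, `mean`, `min`,
#'   `max` (and `median` when raw values were supplied).
#' @export
pooled_descriptives <- function(garden_summaries = NULL, raw = NULL) {
  if (!is.null(raw)) {
    stopifnot(all(c("area", "value") %in% names(raw)))
    if (nrow(raw) == 0) stop("empty raw table", call. = FALSE)
    agg <- function(f) tapply(raw$value, raw$area, f, na.rm = TRUE)
    areas <- sort(unique(raw$area))
    return(data.frame(area = areas,
                      n = as.integer(table(raw$area)[areas]),
                      mean = as.numeric(agg(mean)[areas]),
                      min = as.numeric(agg(min)[areas]),
                      max = as.numeric(agg(max)[areas]),
                      median = as.numeric(agg(stats::median)[areas])))
  }
  gs <- garden_summaries
  stopifnot(all(c("area", "n", "mean") %in% names(gs)))
  if (nrow(gs) == 0) stop("empty area: no garden summaries", call. = FALSE)
  if (any(gs$n < 1)) stop("garden n must be >= 1", call. = FALSE)
  areas <- sort(unique(gs$area))
  out <- data.frame(area = areas)
  out$n <- as.integer(tapply(gs$n, gs$area, sum)[areas])
  out$mean <- as.numeric(
    tapply(gs$n * gs$mean, gs$area, sum)[areas]) / out$n
  out$min <- if ("min" %in% names(gs))
    suppressWarnings(as.numeric(tapply(gs$min, gs$area, min,
                                       na.rm = TRUE)[areas])) else NA_real_
  out$max <- if ("max" %in% names(gs))
    suppressWarnings(as.numeric(tapply(gs$max, gs$area, max,
                                       na.rm = TRUE)[areas])) else NA_real_
  out$min[is.infinite(out$min)] <- NA_real_
  out$max[is.infinite(out$max)] <- NA_real_
  out
}

# Compact letter display by insert-and-absorb (Piepho-style): start from a
# single letter containing all groups, split it on each significantly
# different pair, then absorb redundant subsets. Letters are ordered so
# that 'a' contains the group with the highest mean.
.compact_letters <- function(groups, diff_mat) {
  k <- length(groups)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!isTRUE(diff_mat[i, j])) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (x in seq_along(cols)) for (y in seq_along(cols)) {
      if (x != y && keep[x] && keep[y] &&
          all(cols[[x]] | !cols[[y]]) && !identical(cols[[x]], cols[[y]]))
        keep[y] <- FALSE
      if (x < y && keep[x] && keep[y] &&
          identical(cols[[x]], cols[[y]])) keep[y] <- FALSE
    }
    cols <- cols[keep]
  }
  ord <- order(vapply(cols, function(c) which(c)[1], 0))
  cols <- cols[ord]
  letts <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, `[`, TRUE, g))], collapse = ""), "")
  stats::setNames(letts, groups)
}

#' Two-stage group comparison with compact letter display
#'
#' Reproduces the standard environmental-survey comparison procedure:
#' each group is first screened for normality (Shapiro-Wilk at `alpha`).
#' If every group passes, a one-way ANOVA with Tukey HSD pairwise
#' comparisons is used; otherwise a Kruskal-Wallis test followed by
#' pairwise Mann-Whitney (Wilcoxon rank-sum) tests. Pairwise significance
#' at `alpha` is summarised as a compact letter display, letters assigned
#' in order of descending group mean (groups sharing a letter do not
#' differ significantly).
#'
#' @param values named list, group -> numeric vector (>= 2 groups, each
#'   with >= 3 values).
#' @param alpha significance level (default 0.05), used both for the
#'   normality gate and the pairwise comparisons.
#' @param p_adjust p-value adjustment for the pairwise Mann-Whitney stage:
#'   `"none"` (default) or any method of [stats::p.adjust()].
#' @return List of class `pte_comparison`: `test_used`
#'   (`"anova_tukey"` or `"kruskal_mannwhitney"`), `statistic`, `p_value`
#'   (omnibus), `pairwise` (matrix of pairwise p-values), `letters`,
#'   `means`.
#' @export
compare_groups <- function(values, alpha = 0.05, p_adjust = "none") {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("groups must be named", call. = FALSE)
  sizes <- lengths(values)
  if (any(sizes < 3))
    stop("each group needs >= 3 values (insufficient replication: ",
         paste(names(values)[sizes < 3], collapse = ", "), ")",
         call. = FALSE)
  means <- vapply(values, mean, 0)
  ord <- order(-means)
  values <- values[ord]
  means <- means[ord]
  groups <- names(values)
  k <- length(groups)
  # normality gate; constant vectors cannot be normal-tested -> treat as
  # non-normal (degenerate), routing to the rank-based branch
  normal <- vapply(values, function(v) {
    if (stats::sd(v) == 0 || length(v) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }, TRUE)
  long <- data.frame(value = unlist(values, use.names = FALSE),
                     group = factor(rep(groups, lengths(values)),
                                    levels = groups))
  pair_p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  if (all(normal)) {
    test_used <- "anova_tukey"
    fit <- stats::aov(value ~ group, data = long)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p_value <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    # match pairs explicitly: group names may themselves contain "-"
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      r <- c(paste(groups[j], groups[i], sep = "-"),
             paste(groups[i], groups[j], sep = "-"))
      r <- r[r %in% rownames(tk)][1]
      pair_p[groups[i], groups[j]] <- pair_p[groups[j], groups[i]] <-
        tk[r, "p adj"]
    }
  } else {
    test_used <- "kruskal_mannwhitney"
    kw <- stats::kruskal.test(value ~ group, data = long)
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
    ps <- c()
    idx <- list()
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      w <- suppressWarnings(
        stats::wilcox.test(values[[i]], values[[j]], exact = FALSE))
      ps <- c(ps, w$p.value)
      idx[[length(idx) + 1]] <- c(i, j)
    }
    ps <- stats::p.adjust(ps, method = p_adjust)
    for (m in seq_along(idx)) {
      ij <- idx[[m]]
      pair_p[ij[1], ij[2]] <- pair_p[ij[2], ij[1]] <- ps[m]
    }
  }
  diff_mat <- pair_p < alpha
  letts <- .compact_letters(groups, diff_mat)
  structure(list(test_used = test_used, statistic = statistic,
                 p_value = p_value, pairwise = pair_p, letters = letts,
                 means = means, alpha = alpha),
            class = "pte_comparison")
}

#' @export
print.pte_comparison <- function(x, ...) {
  cat(sprintf("<pte_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  print(data.frame(mean = x$means, letters = x$letters[names(x$means)]))
  invisible(x)
}

#' Mean and standard deviation per vegetable group per element
#'
#' @param plants plant data.frame with a `vegetable_group` column.
#' @param elements element set (defaults to all present).
#' @return data.frame `vegetable_group, element, n, mean, sd` (sd is `NA`
#'   for singleton groups).
#' @export
summarize_by_group <- function(plants, elements = NULL) {
  if (is.null(elements)) elements <- dataset_elements(plants)
  elements <- as_element(elements)
  rows <- lapply(elements, function(el) {
    v <- plants[[el]]
    g <- plants$vegetable_group
    data.frame(vegetable_group = sort(unique(g)),
               element = el,
               n = as.integer(table(g)[sort(unique(g))]),
               mean = as.numeric(tapply(v, g, mean,
                                        na.rm = TRUE)[sort(unique(g))]),
               sd = as.numeric(tapply(v, g, stats::sd,
                                      na.rm = TRUE)[sort(unique(g))]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
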