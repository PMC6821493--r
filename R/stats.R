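#' Two-proportion z-test
#'
#' Pairwise comparison of pattern occurrence between two conditions using
#' the pooled-proportion z statistic with a two-sided normal p value (no
#' continuity correction, no multiplicity adjustment).
#'
#' @param x1,n1 successes and trials in condition 1.
#' @param x2,n2 successes and trials in condition 2.
#' @return object of class `proportion_comparison`: `x1`, `n1`, `x2`,
#'   `n2`, `p1`, `p2`, `z`, `p_value`. When the pooled proportion is 0 or 1
#'   the data carry no information and `z = 0`, `p_value = 1`.
#' @examples
#' proportion_z_test(25, 50, 10, 50)
#' @export
proportion_z_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    z <- 0
    p <- 1
  } else {
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    z <- (p1 - p2) / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p1 = p1, p2 = p2,
         z = z, p_value = p),
    class = "proportion_comparison"
  )
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf(
    "two-proportion z-test: %d/%d (%.3f) vs %d/%d (%.3f)\n  z = %.3f, two-sided p = %.4g\n",
    x$x1, x$n1, x$p1, x$x2, x$n2, x$p2, x$z, x$p_value
  ))
  invisible(x)
}

#' Power of the two-proportion z-test
#'
#' Power to detect a difference between two pattern-occurrence proportions
#' with `n_per_group` cell couples per condition at significance `alpha`
#' (two-sided). The analytic method uses the normal approximation with the
#' null standard error at the pooled proportion and the alternative
#' standard error at (p1, p2); `method = "simulation"` estimates power by
#' repeated binomial draws run through [proportion_z_test()].
#'
#' @param p1,p2 the two proportions, in (0, 1).
#' @param n_per_group cells per condition (>= 2).
#' @param alpha two-sided significance level.
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param n_sim replicates for the simulation method.
#' @return power in \[0, 1\].
#' @examples
#' power_two_proportions(0.35, 0.65, 50)
#' @export
power_two_proportions <- function(p1, p2, n_per_group, alpha = 0.05,
                                  method = c("analytic", "simulation"),
                                  n_sim = 10000L) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, n_per_group >= 2)
  method <- match.arg(method)
  n <- n_per_group
  if (method == "analytic") {
    pbar <- (p1 + p2) / 2
    se0 <- sqrt(2 * pbar * (1 - pbar) / n)
    se1 <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
    zc <- qnorm(1 - alpha / 2)
    delta <- p1 - p2
    pnorm((delta - zc * se0) / se1) + pnorm((-delta - zc * se0) / se1)
  } else {
    x1 <- rbinom(n_sim, n, p1)
    x2 <- rbinom(n_sim, n, p2)
    rej <- vapply(seq_len(n_sim), function(i) {
      proportion_z_test(x1[i], n, x2[i], n)$p_value < alpha
    }, logical(1))
    mean(rej)
  }
}

#' Chauvenet's criterion for outlier rejection
#'
#' Rejects value i when `n * P(|Z| >= |v_i - mean| / sd) < 0.5` under the
#' normal model, in a single pass (no iteration). With zero standard
#' deviation nothing is rejected.
#'
#' @param values numeric vector, length >= 3.
#' @return integer indices of rejected values (possibly empty).
#' @examples
#' chauvenet_outliers(c(10, 10, 10, 10, 50))
#' @export
chauvenet_outliers <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 3) stop("Chauvenet's criterion needs at least 3 values")
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(integer(0))
  z <- abs(v - mean(v)) / s
  tail_prob <- 2 * pnorm(-z)
  which(length(v) * tail_prob < 0.5)
}

#' Log-transform group comparison by ANOVA
#'
#' Stabilizes variance by natural-log transform (all values must be
#' positive), then one-way ANOVA with Tukey's adjustment, or two-way ANOVA
#' with Sidak-adjusted pairwise comparisons of the first factor within
#' levels of the second.
#'
#' @param values positive numeric responses (e.g. relative mRNA amounts).
#' @param group factor of primary group labels.
#' @param group2 optional second factor; when given a two-factor ANOVA
#'   (with interaction) is fitted.
#' @return list with `anova` (the ANOVA table), `posthoc` (TukeyHSD result
#'   for one-way; Sidak-adjusted pairwise comparison table for two-way)
#'   and `f_statistic`, `p_value` for the (first) group effect.
#' @export
log_group_compare <- function(values, group, group2 = NULL) {
  v <- as.numeric(values)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all values must be positive for the log transform")
  }
  lv <- log(v)
  g <- factor(group)
  if (is.null(group2)) {
    fit <- aov(lv ~ g)
    tab <- summary(fit)[[1]]
    list(
      anova = tab,
      posthoc = TukeyHSD(fit),
      f_statistic = tab[["F value"]][1],
      p_value = tab[["Pr(>F)"]][1]
    )
  } else {
    g2 <- factor(group2)
    fit <- aov(lv ~ g * g2)
    tab <- summary(fit)[[1]]
    # Sidak-adjusted pairwise comparisons of g within each level of g2
    levs <- levels(g)
    pairs <- utils::combn(levs, 2, simplify = FALSE)
    rows <- list()
    for (l2 in levels(g2)) {
      for (pr in pairs) {
        a <- lv[g == pr[1] & g2 == l2]
        b <- lv[g == pr[2] & g2 == l2]
        if (length(a) >= 2 && length(b) >= 2) {
          tt <- t.test(a, b, var.equal = TRUE)
          rows[[length(rows) + 1]] <- data.frame(
            group2 = l2, comparison = paste(pr, collapse = " vs "),
            p_raw = tt$p.value
          )
        }
      }
    }
    post <- do.call(rbind, rows)
    if (!is.null(post)) {
      m <- nrow(post)
      post$p_sidak <- 1 - (1 - post$p_raw)^m
    }
    list(
      anova = tab,
      posthoc = post,
      f_statistic = tab[["F value"]][1],
      p_value = tab[["Pr(>F)"]][1]
    )
  }
}

#' Hierarchical clustering of sensor frequency profiles
#'
#' Systems-scale cluster analysis of a sensors x (pattern, time) proportion
#' matrix: distance is 1 minus the Pearson correlation between row
#' profiles, with average-linkage agglomeration. Missing cells are imputed
#' as 0 (flagged); a constant row has undefined correlation and is placed
#' at maximal distance (1) from every other row (flagged).
#'
#' @param freq_matrix numeric matrix, one row per sensor (>= 2 rows),
#'   columns are (pattern, time) proportions.
#' @return object of class `cluster_result`: `distance` (dist), `tree`
#'   (hclust), `leaf_order` (sensor names in dendrogram order), `flags`.
#' @export
cluster_sensors <- function(freq_matrix) {
  m <- as.matrix(freq_matrix)
  if (nrow(m) < 2) stop("need at least 2 sensors to cluster")
  if (is.null(rownames(m))) rownames(m) <- paste0("sensor", seq_len(nrow(m)))
  flags <- character(0)
  if (any(is.na(m))) {
    m[is.na(m)] <- 0
    flags <- c(flags, "missing values imputed as 0")
  }
  cc <- suppressWarnings(cor(t(m)))
  const <- apply(m, 1, function(r) sd(r) == 0 || !is.finite(sd(r)))
  if (any(const)) {
    cc[const, ] <- 0
    cc[, const] <- 0
    diag(cc) <- 1
    flags <- c(flags, paste(
      "constant row(s) at maximal distance:",
      paste(rownames(m)[const], collapse = ", ")
    ))
  }
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = "average")
  structure(
    list(distance = d, tree = tree,
         leaf_order = rownames(m)[tree$order], flags = flags),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result (1 - Pearson, average linkage)\n  leaf order:",
      paste(x$leaf_order, collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Newick string for a cluster tree
#'
#' @param x a [cluster_sensors()] result.
#' @return single Newick string (with branch lengths).
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  ape::write.tree(ape::as.phylo(x$tree))
}

#' Pivot a frequency table into a sensors x (pattern, time) matrix
#'
#' Reshapes a [tabulate_frequencies()] result (with `condition` holding the
#' sensor name) into the wide matrix consumed by [cluster_sensors()].
#'
#' @param freq a `frequency_table`.
#' @param labels pattern labels to keep (default: the six patterns,
#'   excluding `"none"`).
#' @return numeric matrix with one row per condition.
#' @export
frequency_matrix <- function(freq, labels = setdiff(pattern_labels(), "none")) {
  f <- freq[freq$label %in% labels, ]
  cols <- interaction(f$label, f$time_s, drop = TRUE, lex.order = TRUE)
  conds <- unique(f$condition)
  m <- matrix(NA_real_, length(conds), nlevels(cols),
              dimnames = list(conds, levels(cols)))
  for (i in seq_len(nrow(f))) {
    m[f$condition[i], as.character(cols[i])] <- f$proportion[i]
  }
  m
}
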