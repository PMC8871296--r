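#' Krippendorff's alpha for inter-reader agreement
#'
#' Coincidence-matrix formulation with ordinal (default) or nominal
#' difference weights, handling missing scores by pairable-value
#' counting. Units are whatever identifies a rated object (e.g. one case
#' at one reconstruction level); readers are the observers. For the
#' ordinal metric, the squared difference between categories c and k is
#' `(sum of marginal frequencies n_g for g between c and k, minus
#' (n_c + n_k)/2)^2`.
#'
#' @param ratings data frame with columns `reader`, `unit`, `score`
#'   (ordinal integers), or a units x readers matrix (NA = missing).
#' @param metric `"ordinal"` or `"nominal"`.
#' @return alpha in [-1, 1], with attribute `interpretation` (the
#'   conventional agreement bands: <=0.20 poor, 0.21-0.40 fair,
#'   0.41-0.60 moderate, 0.61-0.80 substantial, >0.80 almost perfect).
#' @export
krippendorff_alpha <- function(ratings, metric = c("ordinal", "nominal")) {
  metric <- match.arg(metric)
  if (is.data.frame(ratings)) {
    need <- c("reader", "unit", "score")
    if (!all(need %in% names(ratings))) stop("missing columns")
    m <- tapply(ratings$score, list(ratings$unit, ratings$reader),
                function(x) x[1])
  } else {
    m <- as.matrix(ratings)
  }
  if (ncol(m) < 2) stop("need at least 2 readers")
  cats <- sort(unique(as.vector(m[!is.na(m)])))
  nc <- length(cats)
  if (nc < 2) return(structure(1, interpretation = "almost perfect"))
  # coincidence matrix over pairable values within units
  o <- matrix(0, nc, nc, dimnames = list(cats, cats))
  pairable_units <- 0L
  for (u in seq_len(nrow(m))) {
    vals <- m[u, ][!is.na(m[u, ])]
    mu <- length(vals)
    if (mu < 2) next
    pairable_units <- pairable_units + 1L
    idx <- match(vals, cats)
    for (a in seq_len(mu)) for (b in seq_len(mu)) {
      if (a == b) next
      o[idx[a], idx[b]] <- o[idx[a], idx[b]] + 1 / (mu - 1)
    }
  }
  if (pairable_units < 2) stop("fewer than 2 pairable units")
  n_c <- rowSums(o)
  n <- sum(n_c)
  delta2 <- matrix(0, nc, nc)
  if (metric == "nominal") {
    delta2 <- 1 - diag(nc)
  } else {
    for (a in seq_len(nc)) for (b in seq_len(nc)) {
      if (a == b) next
      lo <- min(a, b); hi <- max(a, b)
      delta2[a, b] <- (sum(n_c[lo:hi]) - (n_c[lo] + n_c[hi]) / 2)^2
    }
  }
  d_o <- sum(o * delta2)
  d_e <- sum(outer(n_c, n_c) * delta2) / (n - 1)
  if (d_e == 0) return(structure(1, interpretation = "almost perfect"))
  alpha <- 1 - d_o / d_e
  structure(alpha, interpretation = alpha_band(alpha))
}

alpha_band <- function(a) {
  if (a <= 0.20) "poor"
  else if (a <= 0.40) "fair"
  else if (a <= 0.60) "moderate"
  else if (a <= 0.80) "substantial"
  else "almost perfect"
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: for input rank i of m,
#' `adj_i = min over j >= i of m * p_(j) / j`, capped at 1, returned in
#' the input order. Adjusted values are monotone non-decreasing in rank
#' and the procedure is idempotent.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  scaled <- m * p[ord] / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(scaled))), 1)
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Omnibus and pairwise comparisons across reconstruction levels
#'
#' Orchestrates the standard paired designs over a per-case metric table:
#' a Friedman test with post-hoc paired Wilcoxon signed-rank tests
#' (`family = "nonparametric"`), or a one-way repeated-measures ANOVA
#' with post-hoc paired t-tests (`family = "parametric"`). All k(k-1)/2
#' pairwise p-values are Benjamini-Hochberg adjusted within the family.
#' The test routines themselves are delegated to the stats package; this
#' function owns the orchestration and reporting. With exactly two
#' levels the omnibus is the paired two-sample test itself.
#'
#' @param metrics data frame with columns `case`, `level`, `value`;
#'   cases must be complete across levels (listwise deletion is applied
#'   and reported).
#' @param family `"nonparametric"` or `"parametric"`.
#' @param alpha significance level for flagging adjusted pairs.
#' @return list with `omnibus` (test name, statistic, p), `pairwise`
#'   (data frame: level_a, level_b, p, p_adj, significant), `n_cases`,
#'   `n_dropped`.
#' @export
paired_level_tests <- function(metrics, family = c("nonparametric",
                                                   "parametric"),
                               alpha = 0.05) {
  family <- match.arg(family)
  need <- c("case", "level", "value")
  if (!all(need %in% names(metrics))) stop("missing columns")
  levels_seen <- unique(metrics$level)
  k <- length(levels_seen)
  if (k < 2) stop("need >= 2 levels")
  wide <- tapply(metrics$value, list(metrics$case, metrics$level),
                 function(x) x[1])
  wide <- wide[, levels_seen, drop = FALSE]
  complete <- stats::complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  if (n < 3) stop("need >= 3 complete cases")

  paired_p <- function(x, y) {
    if (all(x == y)) return(1)
    if (family == "nonparametric")
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    else stats::t.test(x, y, paired = TRUE)$p.value
  }

  if (k == 2) {
    p <- paired_p(wide[, 1], wide[, 2])
    omnibus <- list(test = if (family == "nonparametric")
      "Wilcoxon signed rank" else "paired t", statistic = NA_real_, p = p)
  } else if (family == "nonparametric") {
    if (all(apply(wide, 1, function(r) all(r == r[1])))) {
      omnibus <- list(test = "Friedman", statistic = 0, p = 1)
    } else {
      ft <- stats::friedman.test(wide)
      omnibus <- list(test = "Friedman",
                      statistic = unname(ft$statistic), p = ft$p.value)
    }
  } else {
    long <- data.frame(value = as.vector(wide),
                       level = factor(rep(colnames(wide), each = n),
                                      levels = levels_seen),
                       case = factor(rep(rownames(wide), k)))
    if (stats::var(as.vector(wide)) == 0) {
      omnibus <- list(test = "RM-ANOVA", statistic = 0, p = 1)
    } else {
      fit <- stats::aov(value ~ level + Error(case), data = long)
      tab <- summary(fit)[["Error: Within"]][[1]]
      omnibus <- list(test = "RM-ANOVA", statistic = tab["level", "F value"],
                      p = tab["level", "Pr(>F)"])
    }
  }

  pairs <- utils::combn(levels_seen, 2)
  pw <- data.frame(level_a = pairs[1, ], level_b = pairs[2, ],
                   p = apply(pairs, 2, function(pr)
                     paired_p(wide[, pr[1]], wide[, pr[2]])),
                   stringsAsFactors = FALSE)
  pw$p_adj <- benjamini_hochberg(pw$p)
  pw$significant <- pw$p_adj < alpha
  list(omnibus = omnibus, pairwise = pw, n_cases = n,
       n_dropped = n_dropped)
}
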