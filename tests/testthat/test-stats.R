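test_that("alpha is 1 on perfect agreement and ~0 on independent ratings", {
  set.seed(61)
  scores <- sample(1:5, 20, replace = TRUE)
  perfect <- data.frame(reader = rep(1:2, each = 20),
                        unit = rep(1:20, 2), score = rep(scores, 2))
  expect_equal(as.numeric(krippendorff_alpha(perfect)), 1)
  set.seed(62)
  chance <- data.frame(reader = rep(1:2, each = 10000),
                       unit = rep(1:10000, 2),
                       score = sample(1:5, 20000, replace = TRUE))
  expect_equal(as.numeric(krippendorff_alpha(chance)), 0, tolerance = 0.05)
})

test_that("alpha matches a brute-force ordinal computation on a toy table", {
  # 2 readers x 4 units
  m <- rbind(c(1, 2), c(2, 2), c(4, 5), c(5, 5))
  got <- as.numeric(krippendorff_alpha(m))
  # independent direct computation: coincidence matrix and ordinal
  # weights assembled longhand
  cats <- sort(unique(as.vector(m)))
  o <- matrix(0, length(cats), length(cats))
  for (u in 1:nrow(m)) {
    i <- match(m[u, 1], cats); j <- match(m[u, 2], cats)
    o[i, j] <- o[i, j] + 1; o[j, i] <- o[j, i] + 1
  }
  nc <- rowSums(o); n <- sum(nc)
  d2 <- matrix(0, length(cats), length(cats))
  for (a in seq_along(cats)) for (b in seq_along(cats)) {
    if (a == b) next
    rng <- min(a, b):max(a, b)
    d2[a, b] <- (sum(nc[rng]) - (nc[min(a, b)] + nc[max(a, b)]) / 2)^2
  }
  d_o <- sum(o * d2)
  d_e <- sum(outer(nc, nc) * d2) / (n - 1)
  expect_equal(got, 1 - d_o / d_e, tolerance = 1e-12)
})

test_that("alpha is invariant to orderings and duplicate readers", {
  set.seed(63)
  df <- data.frame(reader = rep(1:3, each = 30), unit = rep(1:30, 3),
                   score = sample(1:5, 90, replace = TRUE,
                                  prob = c(1, 2, 4, 2, 1)))
  a0 <- as.numeric(krippendorff_alpha(df))
  shuf <- df[sample(nrow(df)), ]
  shuf$reader <- match(shuf$reader, c(3, 1, 2))
  expect_equal(as.numeric(krippendorff_alpha(shuf)), a0, tolerance = 1e-12)
  # missing scores are handled by pairable counting
  holes <- df; holes$score[c(5, 40)] <- NA
  expect_true(is.finite(as.numeric(krippendorff_alpha(holes))))
  expect_error(krippendorff_alpha(df[df$reader == 1, , drop = FALSE]),
               "2 readers")
})

test_that("Benjamini-Hochberg matches the brute-force step-up rule", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(64)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))^2
    adj <- benjamini_hochberg(p)
    # brute-force oracle: min over the rank tail of m * p / rank
    ord <- order(p); m <- length(p)
    brute <- numeric(m)
    for (r in seq_len(m))
      brute[ord[r]] <- min(1, m * p[ord[r:m]] / (r:m))
    expect_equal(adj, brute, tolerance = 1e-12)
    # independent reference implementation
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # monotone non-decreasing in rank
    expect_true(all(diff(adj[ord]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("level tests flag clearly separated metrics and not constants", {
  set.seed(65)
  n <- 52
  levels <- c("off", "1", "2", "3", "4")
  base <- rnorm(n, 202, 34)
  df <- do.call(rbind, lapply(seq_along(levels), function(i) {
    data.frame(case = 1:n, level = levels[i],
               value = base * c(1, 0.881, 0.762, 0.644, 0.525)[i] +
                 rnorm(n, 0, 2))
  }))
  out <- paired_level_tests(df, family = "nonparametric")
  expect_lt(out$omnibus$p, 0.001)
  expect_equal(nrow(out$pairwise), choose(5, 2))
  expect_true(all(out$pairwise$significant))
  expect_true(all(out$pairwise$p_adj < 0.001))
  # constants: omnibus at its maximum, nothing flagged
  same <- data.frame(case = rep(1:6, 3), level = rep(c("a", "b", "c"),
                                                     each = 6), value = 5)
  out0 <- paired_level_tests(same, family = "nonparametric")
  expect_equal(out0$omnibus$p, 1)
  expect_false(any(out0$pairwise$significant))
})

test_that("two-level designs reduce to the paired test, parametric family works", {
  set.seed(66)
  df <- data.frame(case = rep(1:12, 2), level = rep(c("off", "4"), each = 12),
                   value = c(rnorm(12, 10), rnorm(12, 13)))
  out <- paired_level_tests(df, family = "nonparametric")
  x <- df$value[df$level == "off"]; y <- df$value[df$level == "4"]
  direct <- suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
  expect_equal(out$omnibus$p, direct, tolerance = 1e-12)
  expect_equal(out$pairwise$p, direct, tolerance = 1e-12)
  outp <- paired_level_tests(df, family = "parametric")
  expect_equal(outp$omnibus$p, t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(paired_level_tests(df[df$case < 3, ], "nonparametric"),
               "3 complete")
})
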