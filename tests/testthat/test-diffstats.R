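test_that("signed-rank p equals full sign enumeration, ties included", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), 1)  # rounding induces occasional ties
    y <- round(rnorm(n), 1)
    if (all(x == y)) next
    r <- wilcoxonSignedRank(x, y)
    expect_equal(r$p, enum_signed_rank_p(x, y), tolerance = 1e-12)
  }
  ## a single non-zero pair gives the trivial two-sided p of 1
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  expect_equal(wilcoxonSignedRank(x, y)$p, 1)
  expect_error(wilcoxonSignedRank(1:4, 1:4), "degenerate")
})

test_that("signed-rank is antisymmetric under swapping the pair", {
  set.seed(102)
  x <- rnorm(9); y <- rnorm(9)
  a <- wilcoxonSignedRank(x, y)
  b <- wilcoxonSignedRank(y, x)
  expect_equal(a$p, b$p)
  expect_equal(b$W, a$n * (a$n + 1) / 2 - a$W)
})

test_that("signed-rank agrees with the exact reference implementation", {
  set.seed(103)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- rnorm(n)  # continuous: tie-free
    r <- wilcoxonSignedRank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r$W, unname(ref$statistic))
  }
})

test_that("Mann-Whitney p equals enumeration over labelings", {
  set.seed(104)
  for (rep in 1:8) {
    a <- rnorm(5); b <- rnorm(5)
    r <- mannWhitneyU(a, b)
    expect_equal(r$p, enum_mwu_p(a, b), tolerance = 1e-12)
  }
  ## same multiset in both groups: central statistic, p = 1
  v <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(mannWhitneyU(v, v)$p, 1)
  ## complete separation at m = n = 5: minimal two-sided p is 2/252
  a <- rnorm(5); b <- rnorm(5) + 1000
  expect_equal(mannWhitneyU(a, b)$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(mannWhitneyU(numeric(0), 1:3), "empty")
})

test_that("one-way ANOVA reduces to t^2 and matches hand arithmetic", {
  set.seed(105)
  g1 <- rnorm(8); g2 <- rnorm(7, 1)
  r <- anovaOneway(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)

  ## hand-computed fixture: groups {1,2,3}, {2,3,4}, {3,4,5}
  ## grand mean 3; SSB = 3*(1 + 0 + 1) = 6; SSW = 2+2+2 = 6
  ## F = (6/2)/(6/6) = 3; df (2, 6)
  r2 <- anovaOneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r2$F, 3, tolerance = 1e-10)
  expect_equal(r2$p, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)

  ## degenerate: zero within-group variance, unequal means
  r3 <- anovaOneway(list(c(1, 1), c(2, 2)))
  expect_equal(r3$F, Inf)
  expect_equal(r3$p, 0)
})

test_that("ANOVA null p-values are uniform under label permutation", {
  set.seed(106)
  vals <- rnorm(24)
  ps <- replicate(2000, {
    perm <- sample(vals)
    anovaOneway(list(perm[1:8], perm[9:16], perm[17:24]))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment follows the step-up transform", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(107)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bhFDR(p), bh_by_hand(p), tolerance = 1e-12)
  }
  ## significance monotone in p
  p <- runif(30)
  q <- bhFDR(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("differential screen honours thresholds and column order", {
  coh <- simulateCohort(small_config(seed = 15))
  st <- qcFilter(normalizeTable(coh@plasma_by_day$day5, "is"))$table
  d <- differentialScreen(st)
  expect_s4_class(d, "DiffResult")
  ## planted markers active at day 5 should dominate the significant set
  planted <- coh@truth$metabolite_id[coh@truth$amplitude_sd > 0]
  expect_gt(mean(planted %in% significantMetabolites(d)), 0.7)

  d0 <- differentialScreen(st, alpha = 0)
  expect_equal(sum(d0@table$significant), 0)

  perm <- sample(nMetabolites(st))
  dperm <- differentialScreen(st[, perm])
  m <- match(d@table$metabolite_id, dperm@table$metabolite_id)
  expect_equal(d@table$p, dperm@table$p[m])
  expect_equal(d@table$q, dperm@table$q[m])
})

test_that("metabolites with too few observations are excluded with a note", {
  coh <- simulateCohort(small_config(seed = 16, missing_rate = 0))
  st <- normalizeTable(coh@plasma_by_day$day1, "is")
  ctrl <- doseGroups(st)[[1]]
  st@abundances[match(ctrl, rownames(abundances(st)))[1:9], 2] <- NA
  d <- differentialScreen(st)
  row <- d@table[2, ]
  expect_true(is.na(row$p))
  expect_match(row$note, "excluded")
  expect_false(row$significant)
})

test_that("paired Wilcoxon contrast matches animals across groups", {
  set.seed(108)
  n <- 8
  base <- rnorm(n, 10)
  ab <- cbind(m1 = c(exp(base), exp(base + 1.5 + rnorm(n, 0, .1))),
              m2 = exp(rnorm(2 * n, 10)))
  rownames(ab) <- sprintf("s%02d", 1:(2 * n))
  st <- tiny_table(ab, dose = rep(c(0, 35), each = n),
                   animal = rep(sprintf("a%d", 1:n), 2),
                   day = rep(c(1, 5), each = n))
  dg <- doseGroups(st)
  d <- differentialScreen(st, design = dg, test = "wilcoxon_paired")
  expect_lt(d@table$p[1], 0.05)
  expect_gt(d@table$p[2], 0.05)
})

test_that("fold-change zoning separates opposite regulation patterns", {
  set.seed(109)
  n_per <- 5
  mk <- function(mu) exp(rnorm(n_per, mu, 0.01))
  ## m_up rises with dose, m_dn falls, m_hi only moves at top dose
  ab <- cbind(
    m_up = c(mk(5), mk(6), mk(7), mk(8)),
    m_dn = c(mk(5), mk(4), mk(3), mk(2)),
    m_hi = c(mk(5), mk(5), mk(5), mk(2)))
  rownames(ab) <- sprintf("s%02d", seq_len(4 * n_per))
  st <- tiny_table(ab, dose = rep(c(0, 10, 20, 35), each = n_per), day = 5)
  d <- differentialScreen(st, test = "anova", fdr_max = 1)
  hz <- heatmapZones(d, st, k = 3)
  expect_equal(sort(unique(hz@zone_labels)), c("a", "b", "c"))
  expect_equal(length(unique(hz@zone_labels)), 3)
  ## each pattern lands in its own zone
  expect_equal(length(unique(hz@zone_labels[c("m_up", "m_dn", "m_hi")])), 3)
  ## deterministic across runs
  hz2 <- heatmapZones(d, st, k = 3)
  expect_identical(hz@metabolite_order, hz2@metabolite_order)
  expect_identical(hz@zone_labels, hz2@zone_labels)
  expect_error(heatmapZones(d, st, k = 10), "k exceeds")
})
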