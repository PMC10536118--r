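test_that("set stages behave as set algebra", {
  mk <- function(ids, all = c("A", "B", "C", "D")) {
    new("DiffResult", contrast = "toy", test = "anova", alpha = 0.05,
        fdr_max = 0.2,
        table = data.frame(metabolite_id = all, statistic = 1,
                           p = ifelse(all %in% ids, 0.001, 0.9),
                           q = ifelse(all %in% ids, 0.01, 0.9),
                           log2fc = 1, significant = all %in% ids,
                           note = ""))
  }
  expect_setequal(unionDifferential(list(mk(c("A", "B")), mk(c("B", "C")))),
                  c("A", "B", "C"))
  expect_setequal(unionDifferential(list(mk("D"))), "D")
  expect_setequal(intersectTissues(c("A", "B", "C"), c("B", "C", "D")),
                  c("B", "C"))
  expect_warning(out <- intersectTissues(c("A"), c("B")), "disjoint")
  expect_length(out, 0)
})

test_that("plasma union covers every per-day set on simulated cohorts", {
  coh <- simulateCohort(small_config(seed = 21))
  diffs <- lapply(coh@plasma_by_day, function(tb)
    differentialScreen(qcFilter(normalizeTable(tb, "is"))$table))
  uni <- unionDifferential(diffs)
  for (d in diffs)
    expect_true(all(significantMetabolites(d) %in% uni))
  expect_gte(length(uni), max(lengths(lapply(diffs,
                                             significantMetabolites))))
})

test_that("VIP screen keeps planted markers and respects the threshold", {
  coh <- simulateCohort(small_config(seed = 22))
  lungN <- qcFilter(normalizeTable(coh@lung, "is_weight"))$table
  p5 <- qcFilter(normalizeTable(coh@plasma_by_day$day5, "is"))$table
  cand <- intersect(metaboliteData(lungN)$metabolite_id,
                    metaboliteData(p5)$metabolite_id)
  vs <- vipScreen(cand, lungN, p5)
  expect_s4_class(vs, "MarkerPanel")
  expect_equal(vs@stage, "vip")
  planted <- coh@truth$metabolite_id[coh@truth$amplitude_sd > 0]
  tab <- vs@table
  ## planted markers carry the top VIPs in at least one tissue
  expect_gt(mean(tab$passed_vip[tab$metabolite_id %in% planted]), 0.5)
  ## threshold 0 keeps everything
  vs0 <- vipScreen(cand, lungN, p5, threshold = 0)
  expect_true(all(vs0@table$passed_vip))
  expect_error(vipScreen(cand[1], lungN, p5), ">= 2")
})

test_that("cross-tissue correlation matches hand-computed Pearson", {
  lungv <- c(1, 2, 3, 4, 5)
  ab_l <- cbind(mA = exp(lungv), mB = c(5, 4, 3, 2, 1))
  rownames(ab_l) <- sprintf("L%d", 1:5)
  lung <- tiny_table(ab_l, tissue = "lung", day = 5,
                     dose = c(0, 10, 20, 35, 35),
                     animal = sprintf("a%d", 1:5), weight = 20)
  ab_p <- cbind(mA = 2 * exp(lungv), mB = c(1.2, 2.1, 2.9, 4.2, 5.1))
  rownames(ab_p) <- sprintf("P%d", 1:5)
  plas <- tiny_table(ab_p, tissue = "plasma", day = 5,
                     dose = c(0, 10, 20, 35, 35),
                     animal = sprintf("a%d", 1:5))
  corr <- crossTissueCorr(lung, plas, c("mA", "mB"))
  expect_equal(corr$r[corr$metabolite_id == "mA"], 1, tolerance = 1e-12)
  ## hand covariance formula for mB
  x <- ab_l[, "mB"]; y <- ab_p[, "mB"]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(corr$r[corr$metabolite_id == "mB"], r_hand,
               tolerance = 1e-12)
  expect_error(crossTissueCorr(lung[1:2, ], plas, c("mA", "mB")),
               "3 matched")
})

test_that("final panel selection is a deterministic VIP ranking", {
  coh <- simulateCohort(small_config(seed = 23))
  lungN <- qcFilter(normalizeTable(coh@lung, "is_weight"))$table
  p5 <- qcFilter(normalizeTable(coh@plasma_by_day$day5, "is"))$table
  cand <- intersect(metaboliteData(lungN)$metabolite_id,
                    metaboliteData(p5)$metabolite_id)
  vs <- vipScreen(cand, lungN, p5)
  corr <- crossTissueCorr(lungN, p5, cand)
  n_surv <- sum(vs@table$passed_vip)
  pan <- selectPanel(vs, corr, p5, k = n_surv)
  expect_equal(pan@stage, "final")
  expect_equal(nrow(pan@table), n_surv)
  ## ranked by final VIP, ties alphabetical
  expect_true(all(diff(pan@table$vip_final) <= 1e-12))
  expect_identical(pan@table$rank, seq_len(n_surv))
  ## filtration: every final member passed the VIP stage
  expect_true(all(panelMetabolites(pan) %in%
                  vs@table$metabolite_id[vs@table$passed_vip]))
  expect_error(selectPanel(vs, corr, p5, k = n_surv + 1), "exceeds")
  ## determinism
  pan2 <- selectPanel(vs, corr, p5, k = n_surv)
  expect_identical(pan@table, pan2@table)
})

test_that("triage map is the configured dose bijection", {
  expect_equal(as.character(triageMap(35)), "Severe")
  expect_equal(as.character(triageMap(0)), "Control")
  expect_equal(as.character(triageMap(c(10, 20))), c("Mild", "Moderate"))
  expect_error(triageMap(15), "outside")
})

test_that("well-separated classes are triaged perfectly under LOO", {
  cfg <- simConfig(seed = 31, n_metabolites = 20, amplitude_sd = 12,
                   residual_sd_log = 0.1, animal_sd_log = 0,
                   missing_rate = 0)
  coh <- simulateCohort(cfg)
  p5 <- qcFilter(normalizeTable(coh@plasma_by_day$day5, "is"))$table
  planted <- coh@truth$metabolite_id[coh@truth$amplitude_sd > 0]
  tri <- triageEvaluate(p5, planted, cv = "loo")
  expect_equal(unname(tri@per_class_accuracy), rep(1, 4))
  ## accounting identities
  expect_equal(unname(rowSums(tri@confusion)), c(11, 10, 9, 9))
  expect_equal(sum(diag(tri@confusion)) / sum(tri@confusion),
               mean(tri@predictions$true_class ==
                    tri@predictions$predicted_class))
  ## continuous dose prediction tracks the true dose ordering
  pd <- tapply(tri@predictions$predicted_dose_gy,
               tri@predictions$true_class, median)
  expect_true(all(diff(pd[c("Control", "Mild", "Moderate", "Severe")]) > 0))
})

test_that("shuffled labels triage at chance level", {
  accs <- vapply(1:5, function(s) {
    coh <- simulateCohort(small_config(seed = 40 + s))
    p5 <- qcFilter(normalizeTable(coh@plasma_by_day$day5, "is"))$table
    planted <- coh@truth$metabolite_id[coh@truth$amplitude_sd > 0]
    sm <- sampleData(p5)
    study <- which(sm$role == "study")
    set.seed(s)
    p5@samples$dose_gy[study] <- sample(sm$dose_gy[study])
    tri <- triageEvaluate(p5, planted, cv = "loo", seed = s)
    sum(diag(tri@confusion)) / sum(tri@confusion)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.15)
})

test_that("trajectories are exact on a constructed time course", {
  mk_day <- function(day, up) {
    ab <- cbind(mA = c(rep(10, 4), rep(10 * up, 4)),
                mB = rep(4, 8))
    rownames(ab) <- sprintf("d%d_s%d", day, 1:8)
    tiny_table(ab, dose = rep(c(0, 35), each = 4), day = day,
               animal = sprintf("a%d", 1:8))
  }
  ## mA doubles its ratio each day; mB never moves
  pb <- list(day2 = mk_day(2, 1.5), day3 = mk_day(3, 3),
             day5 = mk_day(5, 6))
  tr <- trajectories(pb, c("mA", "mB"))
  ra <- tr@ratios[tr@ratios$metabolite_id == "mA", ]
  expect_equal(ra$ratio_to_control[order(ra$day)], c(1.5, 3, 6))
  rb <- tr@ratios[tr@ratios$metabolite_id == "mB", ]
  expect_equal(rb$ratio_to_control, rep(1, 3))
  sa <- tr@summary[tr@summary$metabolite_id == "mA", ]
  expect_true(sa$monotone_2_to_5)
  expect_equal(sa$direction, 1L)
  sb <- tr@summary[tr@summary$metabolite_id == "mB", ]
  expect_false(sb$monotone_2_to_5)  # zero changes are not monotone
  expect_equal(sb$direction, 0L)
  expect_true(is.na(sa$first_significant_day))

  ## ratios are invariant to rescaling a whole metabolite column
  pb2 <- pb
  for (d in names(pb2)) pb2[[d]]@abundances[, "mA"] <-
      pb2[[d]]@abundances[, "mA"] * 7.7
  tr2 <- trajectories(pb2, c("mA", "mB"))
  expect_equal(tr2@ratios$ratio_to_control, tr@ratios$ratio_to_control)
})

test_that("planted onsets surface as first significant days", {
  coh <- simulateCohort(small_config(seed = 25))
  tables <- lapply(coh@plasma_by_day, function(tb)
    qcFilter(normalizeTable(tb, "is"))$table)
  diffs <- lapply(tables, differentialScreen)
  lib <- coh@truth
  planted <- lib$metabolite_id[lib$amplitude_sd > 0]
  tr <- trajectories(tables, planted, diffs)
  ## urea is planted with onset day 1 and a strong linear response
  urea <- tr@summary[tr@summary$metabolite_id == "urea" &
                     tr@summary$dose_gy == 35, ]
  expect_equal(urea$first_significant_day, 1L)
  expect_equal(urea$direction, -1L)
})
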