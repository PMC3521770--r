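test_that("positivity flags follow the strict OR rule", {
  # 6 samples x 3 antigens with hand-set cut-offs
  mc <- rbind(c(0.9, 0.1, 0.1),   # positive on ag1 only
              c(0.1, 0.1, 0.1),   # negative everywhere
              c(0.6, 0.6, 0.6))   # positive on all
  mn <- rbind(c(0.1, 0.2, 0.1),
              c(0.5, 0.1, 0.1),   # ag1 == cutoff: strict rule -> negative
              c(0.1, 0.1, 0.9))
  colnames(mc) <- colnames(mn) <- c("ag1", "ag2", "ag3")
  m <- multi_matrix(mc, mn)
  cuts <- manual_cutoffs(c(ag1 = 0.5, ag2 = 0.5, ag3 = 0.5))
  fl <- panel_positivity(m, cuts)
  expect_equal(fl$ag1, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$panel_pos, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(panel_positivity(m, cuts, c("ag1", "ghost")), "ghost")

  # all below all cut-offs -> nobody positive
  lo <- manual_cutoffs(c(ag1 = 5, ag2 = 5, ag3 = 5))
  expect_false(any(panel_positivity(m, lo)$panel_pos))
  # exactly one antigen positive -> panel positive
  one <- manual_cutoffs(c(ag1 = 0.8, ag2 = 5, ag3 = 5))
  expect_equal(panel_positivity(m, one)$panel_pos,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("panel performance counts and conventions are exact", {
  m <- toy_matrix(c(2, 3, 4), c(0.1, 0.2))
  cuts <- manual_cutoffs(c(A = 1))
  perf <- panel_performance(m, cuts)
  expect_equal(c(perf$tp, perf$fp, perf$tn, perf$fn), c(3, 0, 2, 0))
  expect_equal(perf$sens, 1)
  expect_equal(perf$spec, 1)

  # empty panel: sens 0, spec 1 by convention
  empty <- panel_performance(m, cuts, character(0))
  expect_equal(empty$sens, 0)
  expect_equal(empty$spec, 1)
  expect_equal(empty$tp + empty$fn, 3)

  # samples missing a panel cell are excluded and counted
  m$od[1, 1, 1] <- NA
  perf2 <- panel_performance(m, cuts)
  expect_equal(perf2$n_excluded, 1)
  expect_equal(perf2$tp + perf2$fn, 2)
})

test_that("additive positivity splits lead positives against the base panel", {
  # base antigen catches cancers 1-2; lead catches cancers 2-3 (one additive)
  mc <- cbind(base = c(1, 1, 0, 0), lead = c(0, 1, 1, 0))
  mn <- cbind(base = c(0, 0, 0, 0), lead = c(0, 0, 0, 0))
  m <- multi_matrix(mc, mn)
  cuts <- manual_cutoffs(c(base = 0.5, lead = 0.5))
  r <- additive_analysis(m, cuts, "base", "lead")
  expect_equal(r$overall_pos_cancer, 0.5)    # cancers 2,3
  expect_equal(r$additive_pos_cancer, 0.25)  # cancer 3 only
  expect_equal(r$overall_pos_control, 0)
  expect_equal(r$net_additive_gain, 0.25)
  expect_equal(r$additive_cancer_count, 1L)

  # a lead identical to a base antigen is never additive
  m2 <- multi_matrix(cbind(base = mc[, 1], lead = mc[, 1]),
                     cbind(base = mn[, 1], lead = mn[, 1]))
  r2 <- additive_analysis(m2, cuts, "base", "lead")
  expect_equal(r2$additive_pos_cancer, 0)
  expect_equal(r2$additive_pos_control, 0)

  expect_error(additive_analysis(m, cuts, c("base", "lead"), "lead"),
               "must not be part")
})

test_that("additivity results validate their defining inequalities", {
  r <- additivity_result("x", 0.07, 0, 0.05, 0)
  expect_equal(r$net_additive_gain, 0.05)
  expect_error(additivity_result("x", 0.05, 0, 0.07, 0), "cannot exceed")
  expect_error(additivity_result("x", 1.2, 0, 0.1, 0), "fraction")
})

test_that("combination scan counts subsets and respects OR-rule monotonicity", {
  set.seed(601)
  p <- sim_params(lapply(sprintf("ag%d", 1:7),
                         function(nm) antigen_spec(nm, pi = 0.2)),
                  n_cancer = 30, n_control = 30, seed = 601,
                  concentrations = 100)
  m <- as_assay_matrix(simulate_cohort(p))
  base <- c("ag1", "ag2")
  leads <- sprintf("ag%d", 3:7)
  cuts <- optimize_joint(m, c(base, leads), method = "coordinate")
  scan <- combination_scan(m, cuts, base, leads, max_k = 3)
  expect_equal(nrow(scan), 1 + 5 + 10 + 10)  # C(5,0)+C(5,1)+C(5,2)+C(5,3)
  base_row <- scan[scan$k == 0, ]
  expect_equal(base_row$sens,
               panel_performance(m, cuts, base)$sens)
  # adding leads never decreases sens and never increases spec
  expect_true(all(scan$sens >= base_row$sens))
  expect_true(all(scan$spec <= base_row$spec))
  # nested subsets are monotone too
  r1 <- scan[scan$leads_added == "ag3", ]
  r12 <- scan[scan$leads_added == "ag3,ag4", ]
  expect_gte(r12$sens, r1$sens)
  expect_lte(r12$spec, r1$spec)
  # full-lead-set row equals direct evaluation of the extended panel
  full <- combination_scan(m, cuts, base, leads, max_k = 5)
  full_row <- full[full$k == 5, ]
  direct <- panel_performance(m, cuts, c(base, leads))
  expect_equal(full_row$sens, direct$sens)
  expect_equal(full_row$spec, direct$spec)
})

test_that("a lead capturing one extra cancer raises sens by exactly 1/n", {
  # base catches cancers 1-2 of 5; lead catches cancer 3 only
  mc <- cbind(base = c(1, 1, 0, 0, 0), lead = c(0, 0, 1, 0, 0))
  mn <- cbind(base = numeric(4), lead = numeric(4))
  m <- multi_matrix(mc, mn)
  cuts <- manual_cutoffs(c(base = 0.5, lead = 0.5))
  scan <- combination_scan(m, cuts, "base", "lead", max_k = 1)
  expect_equal(scan$sens[scan$k == 1] - scan$sens[scan$k == 0], 1 / 5)
  expect_equal(scan$spec[scan$k == 1], scan$spec[scan$k == 0])
})

test_that("external validation is a pure application of frozen cut-offs", {
  set.seed(602)
  inst <- random_coarse_instance(n = 10, p = 2)
  m <- multi_matrix(inst$mc, inst$mn)
  cuts <- optimize_joint(m, colnames(inst$mc), method = "coordinate")
  self <- validate_external(cuts, m)
  train <- panel_performance(m, cuts)
  expect_equal(self$sens, train$sens)
  expect_equal(self$spec, train$spec)
  # matrix without the panel antigens is rejected
  other <- toy_matrix(c(1, 2), c(3, 4), antigen = "other")
  expect_error(validate_external(cuts, other), "absent")
  # matrix lacking the working concentration is rejected
  m2 <- multi_matrix(inst$mc, inst$mn, conc = 999)
  expect_error(validate_external(cuts, m2), "concentration")
})

test_that("PPV follows Bayes' rule with one-in-N reporting", {
  r <- ppv(0.5, 1, 0.024)
  expect_equal(r$ppv, 1)          # no false positives
  expect_equal(r$one_in_n, 1L)
  expect_error(ppv(0, 1, 0.024), "no one positive")
  expect_error(ppv(0.5, 0.5, 1.5), "fraction")
  # closed form
  r2 <- ppv(0.6, 0.9, 0.1)
  expect_equal(r2$ppv, 0.6 * 0.1 / (0.6 * 0.1 + 0.1 * 0.9))
  # strictly increasing in each argument on the interior
  base <- ppv(0.5, 0.9, 0.05)$ppv
  expect_gt(ppv(0.6, 0.9, 0.05)$ppv, base)
  expect_gt(ppv(0.5, 0.95, 0.05)$ppv, base)
  expect_gt(ppv(0.5, 0.9, 0.10)$ppv, base)
})
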