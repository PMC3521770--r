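test_that("candidate grid construction covers every achievable threshold once", {
  expect_equal(candidate_grid(c(1, 2)), c(0.5, 1.5, 2.5))
  expect_equal(candidate_grid(c(2, 1, 2)), c(0.5, 1.5, 2.5))  # ties collapse
  expect_equal(candidate_grid(3), c(2.5, 3.5))                # single value
  expect_error(candidate_grid(numeric(0)), "non-empty")

  # sweeping the grid enumerates exactly the (sens, spec) pairs achievable
  # by any real threshold, verified against a dense brute-force sweep
  set.seed(501)
  ods <- round(rnorm(20, 1, 0.3), 2)
  cancer <- ods[1:10]
  control <- ods[11:20]
  grid <- candidate_grid(ods)
  expect_length(grid, length(unique(ods)) + 1)
  pair_at <- function(t) c(mean(cancer > t), mean(control <= t))
  grid_pairs <- unique(t(vapply(grid, pair_at, numeric(2))))
  dense <- sort(c(ods - 1e-9, ods + 1e-9, min(ods) - 1, max(ods) + 1))
  dense_pairs <- unique(t(vapply(dense, pair_at, numeric(2))))
  expect_equal(grid_pairs[order(grid_pairs[, 1], grid_pairs[, 2]), ],
               dense_pairs[order(dense_pairs[, 1], dense_pairs[, 2]), ])
})

test_that("single-antigen optimization matches hand enumeration", {
  # grid {0.05,0.15,0.25,0.35,0.65,1.0,1.15}; hand-scored youden optimum
  # is 0.65 with sens 2/3, spec 1
  fit <- optimize_single(c(0.2, 0.9, 1.1), c(0.1, 0.3, 0.4))
  expect_equal(fit$cutoff, 0.65)
  expect_equal(fit$sens, 2 / 3)
  expect_equal(fit$spec, 1)
  expect_equal(fit$objective_value, 2 / 3 + 1)

  # perfectly separated groups: midpoint of the gap, sens = spec = 1
  fit <- optimize_single(c(5, 6), c(1, 2))
  expect_equal(fit$cutoff, 3.5)
  expect_equal(fit$sens, 1)
  expect_equal(fit$spec, 1)

  # identical distributions: tie-break pushes the cut-off above the maximum
  fit <- optimize_single(c(1, 2, 3), c(1, 2, 3))
  expect_gt(fit$cutoff, 3)
  expect_equal(fit$sens, 0)
  expect_equal(fit$spec, 1)
})

test_that("optimized (sens, spec) is invariant under common monotone transforms", {
  set.seed(502)
  for (i in 1:25) {
    cancer <- rlnorm(12, 0.5, 0.6)
    control <- rlnorm(10, 0, 0.6)
    f1 <- optimize_single(cancer, control)
    f2 <- optimize_single(log(cancer), log(control))
    expect_equal(c(f1$sens, f1$spec), c(f2$sens, f2$spec))
  }
})

test_that("objective variants are validated and the floor variant trades correctly", {
  expect_error(objective_spec(w_sens = 0), "positive")
  expect_error(objective_spec(spec_floor = 1.5), "\\[0, 1\\]")
  # floor variant: with a 100% specificity floor the optimum cannot admit
  # any false positive even when youden would
  cancer <- c(0.5, 1, 2, 3)
  control <- c(0.4, 0.6, 0.7, 0.8)
  strict <- optimize_single(cancer, control,
                            objective_spec("sens_at_spec_floor", spec_floor = 1))
  expect_equal(strict$spec, 1)
  expect_gte(strict$cutoff, 0.8)
})

test_that("a single-antigen panel reduces to optimize_single for every method", {
  set.seed(503)
  cancer <- round(rlnorm(10, 0.3, 0.5), 2)
  control <- round(rlnorm(10, 0, 0.5), 2)
  m <- toy_matrix(cancer, control)
  single <- optimize_single(cancer, control)
  for (meth in c("coordinate", "exhaustive", "restart")) {
    joint <- optimize_joint(m, "A", method = meth, n_restarts = 5, seed = 1)
    expect_equal(unname(joint$cutoffs), single$cutoff, info = meth)
    expect_equal(joint$objective_value, single$objective_value, info = meth)
    expect_equal(joint$sens, single$sens, info = meth)
  }
})

test_that("a redundant duplicate antigen adds nothing to the joint optimum", {
  set.seed(504)
  cancer <- round(rlnorm(10, 0.6, 0.4), 2)
  control <- round(rlnorm(10, 0, 0.4), 2)
  m <- multi_matrix(cbind(x = cancer, y = cancer),
                    cbind(x = control, y = control))
  joint <- optimize_joint(m, c("x", "y"), method = "exhaustive")
  single <- optimize_single(cancer, control)
  expect_equal(joint$objective_value, single$objective_value)
})

test_that("optimizer hierarchy holds: singles <= coordinate <= exhaustive", {
  set.seed(505)
  for (i in 1:40) {
    inst <- random_coarse_instance(n = 7, p = 2)
    m <- multi_matrix(inst$mc, inst$mn)
    panel <- colnames(inst$mc)
    co <- optimize_joint(m, panel, method = "coordinate")
    ex <- optimize_joint(m, panel, method = "exhaustive")
    # panel evaluated at independently optimized single cut-offs
    singles <- vapply(seq_along(panel), function(j) {
      optimize_single(inst$mc[, j], inst$mn[, j])$cutoff
    }, numeric(1))
    names(singles) <- panel
    perf <- panel_performance(m, manual_cutoffs(singles), panel)
    composed <- perf$sens + perf$spec
    expect_lte(composed, co$objective_value + 1e-12)
    expect_lte(co$objective_value, ex$objective_value + 1e-12)
  }
})

test_that("package exhaustive search agrees with an independent brute-force oracle", {
  set.seed(506)
  for (i in 1:20) {
    inst <- random_coarse_instance(n = 5, p = 2)
    m <- multi_matrix(inst$mc, inst$mn)
    ex <- optimize_joint(m, colnames(inst$mc), method = "exhaustive")
    expect_equal(ex$objective_value, joint_brute(inst$mc, inst$mn))
  }
})

test_that("optimizer guard rails: budget, seed, coverage", {
  set.seed(507)
  mc <- matrix(rlnorm(3 * 60, 0.5), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  mn <- matrix(rlnorm(3 * 60), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- multi_matrix(mc, mn)
  expect_error(optimize_joint(m, c("a", "b", "c"), method = "exhaustive",
                              budget = 1000),
               "coordinate")
  expect_error(optimize_joint(m, "a", method = "restart"), "seed")
  expect_error(optimize_joint(m, "zz", method = "coordinate"), "absent")
  # cut-offs stay within the observed range (plus the grid offsets)
  cut <- optimize_joint(m, c("a", "b"), method = "coordinate")
  for (a in c("a", "b")) {
    pooled <- m$od[, a, 1]
    expect_gte(cut$cutoffs[[a]], min(pooled) - 1)
    expect_lte(cut$cutoffs[[a]], max(pooled) + 1)
  }
})

test_that("cut-off vectors round-trip through JSON", {
  set.seed(508)
  inst <- random_coarse_instance()
  m <- multi_matrix(inst$mc, inst$mn)
  cut <- optimize_joint(m, colnames(inst$mc), method = "coordinate")
  path <- withr::local_tempfile(fileext = ".json")
  write_cutoffs(cut, path)
  back <- read_cutoffs(path)
  expect_equal(back$cutoffs, cut$cutoffs)
  expect_equal(back$concentration_nM, cut$concentration_nM)
  expect_equal(back$objective_value, cut$objective_value)
  expect_equal(back$provenance, cut$provenance)
})

test_that("working concentration is the one with the larger K-S distance", {
  od <- array(0, dim = c(6, 1, 2),
              dimnames = list(sprintf("s%03d", 1:6), "ag", c("100", "50")))
  od[1:3, 1, 1] <- c(1, 2, 3); od[4:6, 1, 1] <- c(1, 2, 3)      # null at 100
  od[1:3, 1, 2] <- c(10, 11, 12); od[4:6, 1, 2] <- c(1, 2, 3)   # separated at 50
  samples <- data.frame(sample_id = sprintf("s%03d", 1:6),
                        status = rep(c("cancer", "control"), each = 3))
  m <- assay_matrix(samples, od)
  expect_equal(unname(choose_concentrations(m, "ag")), 50)
  # ties fall back to the highest concentration
  od[1:3, 1, 1] <- c(10, 11, 12)
  m2 <- assay_matrix(samples, od)
  expect_equal(unname(choose_concentrations(m2, "ag")), 100)
})
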