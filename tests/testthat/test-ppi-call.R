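# build an estimates table directly (unit tests of the scoring layer work on
# fitness samples; the simulator-backed checks live in test-acceptance.R)
fake_estimates <- function(pairs, control_fitness, condition = "DMSO",
                           replicate = 1) {
  rows <- lapply(names(pairs), function(pp) {
    x <- pairs[[pp]]
    data.frame(Condition = condition, Methotrexate_selection = TRUE,
               Replicate = replicate, PPI_pair = pp,
               barcode_pair = paste0(pp, "_", seq_along(x)),
               Bait = sub(":.*", "", pp), Prey = sub(".*:", "", pp),
               is_control = FALSE, fitness = x, used = TRUE,
               stringsAsFactors = FALSE)
  })
  ctrl <- data.frame(Condition = condition, Methotrexate_selection = TRUE,
                     Replicate = replicate, PPI_pair = "control:control",
                     barcode_pair = paste0("ctrl_", seq_along(control_fitness)),
                     Bait = "control", Prey = "control", is_control = TRUE,
                     fitness = control_fitness, used = TRUE,
                     stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), ctrl)
}

test_that("a pair indistinguishable from the control is not significant", {
  set.seed(61)
  x <- rnorm(75, 0, 0.02)
  e <- fake_estimates(list("a:b" = x), control_fitness = x)
  sc <- score_ppis(e)
  expect_false(sc$significant)
  expect_gt(sc$p_corrected, 0.5)
})

test_that("an effect of 0.10 at sem 0.02 survives the 500-test correction", {
  set.seed(62)
  # closed-form scale: t ~ 0.10 / 0.02 = 5 at ~75 estimates
  x <- rnorm(75, 0.10, 0.02 * sqrt(75))
  ctrl <- rnorm(150, 0, 0.02 * sqrt(75))
  e <- fake_estimates(list("a:b" = x), control_fitness = ctrl)
  sc <- score_ppis(e, n_tests = 500)
  expect_lt(abs(sc$mean_fitness - 0.10), 0.05)
  expect_true(sc$significant)
})

test_that("raising the Bonferroni multiplier never adds significant calls", {
  set.seed(63)
  pairs <- setNames(lapply(1:20, function(i) rnorm(40, runif(1, 0, 0.06), 0.1)),
                    paste0("b", 1:20, ":p", 1:20))
  e <- fake_estimates(pairs, control_fitness = rnorm(60, 0, 0.1))
  for (n1 in c(1, 50, 500)) {
    s_lo <- score_ppis(e, n_tests = n1)
    s_hi <- score_ppis(e, n_tests = n1 * 10)
    expect_true(all(s_hi$significant <= s_lo$significant))
    expect_true(all(s_hi$p_corrected >= s_lo$p_corrected))
    expect_true(all(s_hi$p_corrected <= 1))
  }
})

test_that("scores are invariant to barcode and replicate permutation", {
  set.seed(64)
  pairs <- list("a:b" = rnorm(75, 0.1, 0.05), "c:d" = rnorm(75, 0, 0.05))
  e <- fake_estimates(pairs, control_fitness = rnorm(75, 0, 0.05))
  base <- score_ppis(e)
  shuf <- score_ppis(e[sample(nrow(e)), ])
  expect_equal(base, shuf)
})

test_that("groups below two estimates are skipped, not tested", {
  e <- fake_estimates(list("a:b" = 0.5), control_fitness = rnorm(10))
  sc <- score_ppis(e)
  expect_true(nzchar(sc$test_skipped))
  expect_true(is.na(sc$p_value))
  expect_false(sc$significant)
})

test_that("a blacklist removes pairs before scoring", {
  set.seed(65)
  pairs <- list("prs3:fpr1" = rnorm(75, 0.04, 0.01),
                "a:b" = rnorm(75, 0.1, 0.05))
  e <- fake_estimates(pairs, control_fitness = rnorm(75, 0, 0.05))
  sc <- score_ppis(e, blacklist = "prs3:fpr1")
  expect_false("prs3:fpr1" %in% sc$PPI_pair)
  expect_true("a:b" %in% sc$PPI_pair)
})

test_that("dynamic detection flags strong environment shifts only", {
  set.seed(66)
  ref <- fake_estimates(list("hom3:fpr1" = rnorm(75, 0.30, 0.03),
                             "stable:pair" = rnorm(75, 0.20, 0.03)),
                        control_fitness = rnorm(75, 0, 0.03),
                        condition = "DMSO")
  fk <- fake_estimates(list("hom3:fpr1" = rnorm(75, 0.03, 0.03),
                            "stable:pair" = rnorm(75, 0.20, 0.03)),
                       control_fitness = rnorm(75, 0, 0.03),
                       condition = "FK506")
  dyn <- detect_dynamic(rbind(ref, fk))
  hit <- dyn[dyn$PPI_pair == "hom3:fpr1", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "loss")
  expect_lt(hit$mean_fitness / hit$reference_fitness, 0.2)
  expect_false(dyn$significant[dyn$PPI_pair == "stable:pair"])
})

test_that("identical environments yield no dynamic calls", {
  set.seed(67)
  x <- rnorm(75, 0.2, 0.05)
  a <- fake_estimates(list("a:b" = x), rnorm(75), condition = "DMSO")
  b <- fake_estimates(list("a:b" = x), rnorm(75), condition = "NaCl")
  dyn <- detect_dynamic(rbind(a, b))
  expect_false(any(dyn$significant))
  expect_equal(dyn$delta_fitness, 0)
})

test_that("dynamic summaries count changed and undetectable interactions", {
  sc <- data.frame(PPI_pair = rep(c("a:b", "c:d"), each = 2),
                   Condition = rep(c("DMSO", "NaCl"), 2),
                   Methotrexate_selection = TRUE,
                   significant = c(TRUE, TRUE, TRUE, FALSE))
  dyn <- data.frame(PPI_pair = c("a:b", "c:d"),
                    significant = c(FALSE, TRUE))
  s <- summarize_dynamic(sc, dyn)
  expect_equal(s$n_detected, 2)
  expect_equal(s$n_changed, 1)
  expect_equal(s$frac_changed, 0.5)
  expect_equal(s$n_undetectable, 1)
})

test_that("OD growth-curve relative fitness follows the AUC ratio", {
  times <- c(0, 8, 10, 12, 14, 16, 18, 20, 22, 24, 32)
  mk <- function(strain, condition, od) {
    data.frame(strain = strain, condition = condition, time = times, od = od)
  }
  base <- seq(0.1, 1.2, length.out = length(times))
  od <- rbind(mk("ctrl", "DMSO", base), mk("ctrl", "X", base),
              mk("t", "DMSO", base + 0.5), mk("t", "X", base + 1.0))
  rf <- od_auc_relative_fitness(od, control_strain = "ctrl")
  # AUC sums the 10 readings before 32 h: differences are 5 and 10
  expect_equal(rf$auc_diff[rf$condition == "DMSO"], 5)
  expect_equal(rf$auc_diff[rf$condition == "X"], 10)
  expect_equal(rf$relative_fitness[rf$condition == "X"], 2)
  # constant offsets to every reading cancel
  od2 <- od; od2$od <- od2$od + 3
  rf2 <- od_auc_relative_fitness(od2, control_strain = "ctrl")
  expect_equal(rf2$relative_fitness, rf$relative_fitness)
  # degenerate: target identical to control
  od3 <- rbind(mk("ctrl", "DMSO", base), mk("t", "DMSO", base))
  rf3 <- od_auc_relative_fitness(od3, control_strain = "ctrl")
  expect_true(rf3$undefined)
  expect_error(od_auc_relative_fitness(od, control_strain = "absent"),
               "control")
})

test_that("luciferase response ratios behave arithmetically", {
  expect_equal(rluc_response(100, 100)$ratio, 1)
  expect_equal(rluc_response(300, 100)$ratio, 3)
  low <- rluc_response(50, 100)
  expect_lt(low$ratio, 1)
  expect_lt(low$log2_ratio, 0)
  expect_error(rluc_response(0, 100), "positive")
})
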