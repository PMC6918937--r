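test_that("the worked three-group example gives F = 3 with df (2, 6)", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$F, 3)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)
  expect_equal(a$means, c(2, 3, 4))
  expect_equal(a$p, stats::pf(3, 2, 6, lower.tail = FALSE))
})

test_that("the F statistic agrees with base R and the t-test identity", {
  for (s in 1:10) {
    groups <- with_seed(s, lapply(1:3, function(i) rnorm(6, mean = i / 2)))
    ours <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_along(groups), each = 6)))
    ref <- stats::oneway.test(y ~ g, df, var.equal = TRUE)
    expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

    two <- groups[1:2]
    tt <- stats::t.test(two[[1]], two[[2]], var.equal = TRUE)
    expect_equal(one_way_anova(two)$F, unname(tt$statistic)^2,
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged, not hidden", {
  same <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_true(is.na(same$F))
  expect_equal(same$flag, "degenerate")

  sep <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(sep$p, 0)
  expect_equal(sep$flag, "zero-within-variance")

  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "two values")
})

test_that("F is invariant to shifts and rescalings of the data", {
  groups <- with_seed(3, lapply(1:4, function(i) rnorm(5, i)))
  base <- one_way_anova(groups)$F
  shifted <- one_way_anova(lapply(groups, `+`, 17.3))$F
  scaled <- one_way_anova(lapply(groups, `*`, 0.042))$F
  expect_equal(shifted, base, tolerance = 1e-10)
  expect_equal(scaled, base, tolerance = 1e-10)
})

test_that("rhythm selection reports every combination and applies p < 0.05", {
  set.seed(12)
  tbl <- expand.grid(rhythm = c("delta", "theta", "alpha1", "alpha2", "beta"),
                     condition = c("C1", "C2"), subject = 1:6,
                     time_point = paste0("T", 0:4),
                     stringsAsFactors = FALSE)
  tbl$mean_mi <- rnorm(nrow(tbl), 0.2, 0.01)
  # implant a time effect in alpha1 / C2 only
  bump <- tbl$rhythm == "alpha1" & tbl$condition == "C2"
  tbl$mean_mi[bump] <- tbl$mean_mi[bump] +
    0.05 * as.numeric(sub("T", "", tbl$time_point[bump]))
  sel <- select_rhythm(tbl)
  expect_equal(nrow(sel), 10)           # all pairs reported
  expect_true(sel$selected[sel$rhythm == "alpha1" & sel$condition == "C2"])
  expect_equal(sel$p[sel$rhythm == "alpha1" & sel$condition == "C2"],
               min(sel$p))
  expect_error(select_rhythm(tbl[-1, ]), "incomplete")
})

test_that("a null trajectory yields no selection at a benign seed", {
  des <- experiment_design(n_subjects = 3, epochs_per_cell = 1,
                           epoch_seconds = 1, conditions = "C2",
                           channels = c("chA", "chB", "chC"))
  traj <- null_trajectory()
  rows <- list()
  for (s in 1:3) {
    for (tp in des$time_points) {
      ep <- generate_epoch_set(des, traj, s, tp, "C2", seed = 2024)
      adj <- adjacency_from_epochs(band_filter(ep, eeg_bands()$alpha1))
      rows[[length(rows) + 1]] <- data.frame(
        rhythm = "alpha1", condition = "C2", subject = s, time_point = tp,
        mean_mi = mean_mi(adj))
    }
  }
  sel <- select_rhythm(do.call(rbind, rows))
  expect_false(any(sel$selected))
})
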