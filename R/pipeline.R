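#' Run the full fatigue network pipeline on synthetic EEG
#'
#' Orchestrates every stage of the analysis: synthetic EEG generation for
#' each subject x time-point x condition cell, rhythm decomposition, the
#' (theta + alpha1 + alpha2)/beta fatigue ratio, MI adjacency matrices and
#' mean MI per rhythm, ANOVA-based rhythm selection, and the network stage
#' (threshold sweep and fixed-degree binarization with small-world analysis
#' against Maslov-Sneppen null ensembles) on the selected rhythm/condition.
#'
#' All randomness derives from `master_seed` through documented per-cell
#' child seeds, so a repeated run is bit-identical.
#'
#' @param design an [experiment_design()].
#' @param trajectory a [fatigue_trajectory()].
#' @param mi_cfg an [mi_config()].
#' @param thresholds ascending weight thresholds for the sweep.
#' @param k_values fixed mean degrees (default `c(5, 6)`).
#' @param n_nulls null-ensemble size for the fixed-degree analysis.
#' @param n_nulls_sweep null-ensemble size for the threshold sweep
#'   (defaults to `n_nulls`).
#' @param master_seed master integer seed.
#' @param network_rhythm,network_condition override the automatic choice of
#'   the rhythm/condition carried into the network stage (the default takes
#'   the most significant selected combination).
#' @param run_sweep logical; compute the threshold sweep (default `TRUE`).
#' @param out_dir optional directory; when given, stage tables are written
#'   as CSV/JSON artifacts (see Details).
#' @param artifacts which artifact groups to write when `out_dir` is set:
#'   any of `"tables"`, `"adjacency"`, `"epochs"`, `"graphs"`.
#' @param verbose print stage progress.
#' @details With `out_dir` set, the run emits `ratios.csv`, `mean_mi.csv`,
#'   `selection.json`, `sweep.csv`, `fixed_degree.csv`, `anova.csv` and
#'   `config.json`; optionally per-cell adjacency CSVs, epoch CSVs, and
#'   Pajek exports of the fixed-degree graphs.
#' @return An object of class `fatigue_run`; see [summary.fatigue_run()].
#' @examples
#' \donttest{
#' des <- experiment_design(n_subjects = 2, epochs_per_cell = 2)
#' run <- run_pipeline(des, fatigue_trajectory(), n_nulls = 10,
#'                     thresholds = seq(0.15, 0.35, 0.05))
#' summary(run)
#' }
#' @export
run_pipeline <- function(design = experiment_design(),
                         trajectory = fatigue_trajectory(),
                         mi_cfg = mi_config(),
                         thresholds = seq(0.15, 0.35, by = 0.01),
                         k_values = c(5, 6),
                         n_nulls = 250,
                         n_nulls_sweep = n_nulls,
                         master_seed = 0,
                         network_rhythm = NULL,
                         network_condition = NULL,
                         run_sweep = TRUE,
                         out_dir = NULL,
                         artifacts = "tables",
                         verbose = FALSE) {
  check_that(
    "design must be an experiment_design" = inherits(design, "experiment_design"),
    "trajectory must be a fatigue_trajectory" =
      inherits(trajectory, "fatigue_trajectory")
  )
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  bands <- eeg_bands()
  tps <- design$time_points
  conds <- design$conditions
  subs <- seq_len(design$n_subjects)

  # ---- stage 1-3: generation, decomposition, fatigue ratio, adjacency ----
  say("generating %d cells and estimating MI ...",
      length(subs) * length(tps) * length(conds))
  ratio_rows <- list()
  mi_rows <- list()
  adjacency <- list()   # [[condition]][[rhythm]][[subject]][[time]] -> matrix
  for (cond in conds) {
    adjacency[[cond]] <- lapply(names(bands), function(b)
      lapply(subs, function(s) stats::setNames(vector("list", length(tps)), tps)))
    names(adjacency[[cond]]) <- names(bands)
  }
  for (s in subs) {
    for (tp in tps) {
      for (cond in conds) {
        ep <- generate_epoch_set(design, trajectory, s, tp, cond,
                                 seed = master_seed)
        dec <- decompose(ep, bands)
        ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
          subject = s, time_point = tp, condition = cond,
          ratio = fatigue_ratio(band_power(dec))
        )
        for (b in names(bands)) {
          adj <- adjacency_from_epochs(dec[[b]], mi_cfg, rhythm = b)
          adjacency[[cond]][[b]][[s]][[tp]] <- adj$values
          mi_rows[[length(mi_rows) + 1L]] <- data.frame(
            rhythm = b, condition = cond, subject = s, time_point = tp,
            mean_mi = mean_mi(adj)
          )
        }
        if (!is.null(out_dir) && "epochs" %in% artifacts) {
          write_epochs_csv(ep, file.path(out_dir,
            sprintf("epochs_s%02d_%s_%s.csv", s, tp, cond)))
        }
      }
    }
  }
  ratios <- do.call(rbind, ratio_rows)
  mi_table <- do.call(rbind, mi_rows)

  # ---- stage 4: rhythm selection ----
  say("selecting responsive rhythm ...")
  selection <- select_rhythm(mi_table)
  if (is.null(network_rhythm) || is.null(network_condition)) {
    cand <- selection[order(selection$p), ]
    if (!any(cand$selected)) {
      warning("no rhythm/condition reached p < 0.05; ",
              "carrying the most significant one into the network stage")
    }
    network_rhythm <- network_rhythm %||% cand$rhythm[1]
    network_condition <- network_condition %||% cand$condition[1]
  }
  say("network stage on %s / %s", network_rhythm, network_condition)
  adj_sel <- adjacency[[network_condition]][[network_rhythm]]

  # ---- stage 5: network metrics ----
  sweep <- NULL
  if (run_sweep) {
    say("threshold sweep (%d thresholds, %d nulls) ...",
        length(thresholds), n_nulls_sweep)
    sweep_rows <- list()
    for (s in subs) {
      for (tp in tps) {
        sw <- threshold_sweep(adj_sel[[s]][[tp]], thresholds,
                              n_nulls = n_nulls_sweep,
                              seed = child_seed(master_seed * 31 + 7, s,
                                                match(tp, tps), 1L))
        sw$subject <- s
        sw$time_point <- tp
        sweep_rows[[length(sweep_rows) + 1L]] <- sw
      }
    }
    sweep <- do.call(rbind, sweep_rows)
  }

  say("fixed-degree analysis (K = %s, %d nulls) ...",
      paste(k_values, collapse = ", "), n_nulls)
  fk_rows <- list()
  for (s in subs) {
    for (tp in tps) {
      for (ki in seq_along(k_values)) {
        g <- binarize_by_degree(adj_sel[[s]][[tp]], k_values[ki])
        sw <- small_world(g, n_nulls = n_nulls,
                          seed = child_seed(master_seed * 131 + 17, s,
                                            match(tp, tps), ki))
        fk_rows[[length(fk_rows) + 1L]] <- data.frame(
          subject = s, time_point = tp, K = k_values[ki],
          C = sw$C, L = sw$L, C_rand = sw$C_rand, L_rand = sw$L_rand,
          sigma = sw$sigma, disconnected = sw$disconnected
        )
        if (!is.null(out_dir) && "graphs" %in% artifacts) {
          write_pajek(g, file.path(out_dir,
            sprintf("graph_s%02d_%s_K%d.net", s, tp, k_values[ki])))
        }
      }
    }
  }
  fixedk <- do.call(rbind, fk_rows)

  # ---- stage 6: group summaries and ANOVA tables ----
  fixedk_group <- stats::aggregate(
    fixedk[, c("C", "L", "sigma")],
    by = list(K = fixedk$K, time_point = fixedk$time_point), mean)
  fixedk_group <- fixedk_group[order(fixedk_group$K,
                                     match(fixedk_group$time_point, tps)), ]
  sweep_group <- NULL
  if (!is.null(sweep)) {
    # a threshold is usable for group comparison only if it leaves no
    # isolated node in any subject x time network
    ok <- stats::aggregate(sweep$valid,
                           by = list(threshold = sweep$threshold), all)
    valid_thresholds <- ok$threshold[ok$x]
    sv <- sweep[sweep$threshold %in% valid_thresholds, ]
    if (nrow(sv) > 0) {
      sweep_group <- stats::aggregate(
        sv[, c("n_edges", "C", "L", "sigma")],
        by = list(threshold = sv$threshold, time_point = sv$time_point), mean)
      sweep_group <- sweep_group[order(sweep_group$threshold,
                                       match(sweep_group$time_point, tps)), ]
    }
  }

  anova_tables <- pipeline_anovas(ratios, fixedk, tps, conds, k_values)

  run <- structure(
    list(design = design, trajectory = trajectory, mi_cfg = mi_cfg,
         thresholds = thresholds, k_values = k_values, n_nulls = n_nulls,
         n_nulls_sweep = n_nulls_sweep, master_seed = master_seed,
         ratios = ratios, mean_mi = mi_table, selection = selection,
         network_rhythm = network_rhythm,
         network_condition = network_condition,
         adjacency = adj_sel, sweep = sweep, sweep_group = sweep_group,
         fixedk = fixedk, fixedk_group = fixedk_group,
         anova = anova_tables),
    class = "fatigue_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir, artifacts)
  run
}

# Table-style ANOVAs: five-group tests per condition/K plus the pairwise
# (consecutive time points) two-group tests.
pipeline_anovas <- function(ratios, fixedk, tps, conds, k_values) {
  pairwise <- function(values, groups) {
    out <- list()
    for (i in seq_len(length(tps) - 1)) {
      g1 <- values[groups == tps[i]]
      g2 <- values[groups == tps[i + 1]]
      a <- one_way_anova(list(g1, g2))
      out[[i]] <- data.frame(contrast = paste(tps[i], tps[i + 1], sep = "-"),
                             F = a$F, p = a$p)
    }
    do.call(rbind, out)
  }
  ratio_rows <- list()
  for (cond in conds) {
    sub <- ratios[ratios$condition == cond, ]
    overall <- one_way_anova(split(sub$ratio, factor(sub$time_point, tps)))
    pw <- pairwise(sub$ratio, sub$time_point)
    pw$condition <- cond
    ratio_rows[[cond]] <- list(overall = overall, pairwise = pw)
  }
  sigma_rows <- list()
  for (K in k_values) {
    sub <- fixedk[fixedk$K == K, ]
    pw <- pairwise(sub$sigma, sub$time_point)
    pw$K <- K
    sigma_rows[[as.character(K)]] <- pw
  }
  list(ratio = ratio_rows, sigma_pairwise = do.call(rbind, sigma_rows))
}

write_run_artifacts <- function(run, out_dir, artifacts) {
  if (!"tables" %in% artifacts) return(invisible(NULL))
  utils::write.csv(run$ratios, file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(run$mean_mi, file.path(out_dir, "mean_mi.csv"),
                   row.names = FALSE)
  sel <- as.data.frame(run$selection)
  jsonlite::write_json(
    list(table = sel,
         network_rhythm = run$network_rhythm,
         network_condition = run$network_condition),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(run$sweep)) {
    utils::write.csv(run$sweep, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(run$fixedk, file.path(out_dir, "fixed_degree.csv"),
                   row.names = FALSE)
  utils::write.csv(run$anova$sigma_pairwise,
                   file.path(out_dir, "anova.csv"), row.names = FALSE)
  cfg <- list(design = unclass(run$design),
              trajectory = lapply(unclass(run$trajectory), unname),
              mi_cfg = unclass(run$mi_cfg),
              thresholds = run$thresholds, k_values = run$k_values,
              n_nulls = run$n_nulls, n_nulls_sweep = run$n_nulls_sweep,
              master_seed = run$master_seed)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if ("adjacency" %in% artifacts) {
    for (s in seq_along(run$adjacency)) {
      for (tp in names(run$adjacency[[s]])) {
        write_adjacency_csv(run$adjacency[[s]][[tp]], file.path(out_dir,
          sprintf("adjacency_%s_%s_s%02d_%s.csv", run$network_rhythm,
                  run$network_condition, s, tp)))
      }
    }
  }
  invisible(NULL)
}

#' @export
print.fatigue_run <- function(x, ...) {
  cat("Fatigue network pipeline run\n")
  cat(sprintf("  %d subjects x %d time points x %d conditions, %d epochs/cell\n",
              x$design$n_subjects, length(x$design$time_points),
              length(x$design$conditions), x$design$epochs_per_cell))
  cat(sprintf("  network stage: %s rhythm, condition %s\n",
              x$network_rhythm, x$network_condition))
  cat(sprintf("  master seed %s, %d nulls (fixed degree)\n",
              format(x$master_seed), x$n_nulls))
  invisible(x)
}

#' Summarize a pipeline run
#'
#' Prints the rhythm-selection table, the group-mean fatigue ratio and mean
#' MI over time, and the group-mean small-world index per fixed degree.
#'
#' @param object a `fatigue_run`.
#' @param ... unused.
#' @return `object`, invisibly.
#' @export
summary.fatigue_run <- function(object, ...) {
  x <- object
  tps <- x$design$time_points
  cat("== Rhythm selection (ANOVA on mean MI across time points) ==\n")
  print(data.frame(x$selection, row.names = NULL), digits = 3)
  cat(sprintf("-> network stage: %s / %s\n\n", x$network_rhythm,
              x$network_condition))
  cat("== Group-mean fatigue ratio (theta+alpha1+alpha2)/beta ==\n")
  rt <- stats::aggregate(ratio ~ condition + time_point, data = x$ratios, mean)
  print(stats::xtabs(ratio ~ condition + time_point, rt)[, tps], digits = 4)
  cat("\n== Group-mean MI,", x$network_rhythm, "rhythm ==\n")
  mm <- x$mean_mi[x$mean_mi$rhythm == x$network_rhythm, ]
  mt <- stats::aggregate(mean_mi ~ condition + time_point, data = mm, mean)
  print(stats::xtabs(mean_mi ~ condition + time_point, mt)[, tps], digits = 4)
  cat("\n== Small-world index, fixed degree ==\n")
  print(stats::xtabs(sigma ~ K + time_point, x$fixedk_group)[, tps,
                                                             drop = FALSE],
        digits = 4)
  if (!is.null(x$sweep_group)) {
    vt <- unique(x$sweep_group$threshold)
    cat(sprintf("\n%d of %d sweep thresholds leave no isolated node (%.2f-%.2f)\n",
                length(vt), length(x$thresholds), min(vt), max(vt)))
  }
  invisible(x)
}

#' Plot the time course of a pipeline run
#'
#' Four base-graphics panels: fatigue ratio, mean MI of the network rhythm,
#' and the small-world index over time for each fixed degree.
#'
#' @param x a `fatigue_run`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.fatigue_run <- function(x, ...) {
  tps <- x$design$time_points
  nt <- length(tps)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  plot_course <- function(df, value, main, ylab) {
    agg <- stats::aggregate(df[[value]],
                            by = list(condition = df$condition,
                                      time_point = df$time_point), mean)
    conds <- unique(agg$condition)
    ylim <- range(agg$x)
    graphics::plot(NA, xlim = c(1, nt), ylim = ylim, xaxt = "n",
                   xlab = "time point", ylab = ylab, main = main)
    graphics::axis(1, at = seq_len(nt), labels = tps)
    for (ci in seq_along(conds)) {
      v <- agg[agg$condition == conds[ci], ]
      graphics::lines(match(v$time_point, tps), v$x, type = "b",
                      pch = ci, lty = ci)
    }
    graphics::legend("topleft", legend = conds, pch = seq_along(conds),
                     lty = seq_along(conds), bty = "n")
  }
  plot_course(x$ratios, "ratio", "Fatigue ratio", "(th+a1+a2)/beta")
  mm <- x$mean_mi[x$mean_mi$rhythm == x$network_rhythm, ]
  plot_course(mm, "mean_mi", paste("Mean MI,", x$network_rhythm), "nats")
  for (K in x$k_values[seq_len(min(2, length(x$k_values)))]) {
    v <- x$fixedk_group[x$fixedk_group$K == K, ]
    graphics::plot(match(v$time_point, tps), v$sigma, type = "b", xaxt = "n",
                   xlab = "time point", ylab = "sigma",
                   main = sprintf("Small-world index, K = %d", K))
    graphics::axis(1, at = seq_len(nt), labels = tps)
    graphics::abline(h = 1, lty = 3)
  }
  invisible(x)
}
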