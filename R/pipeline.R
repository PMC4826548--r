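#' Cross-tabulate cluster membership against clinical covariates
#'
#' Sample-level contingency tables of cluster assignment versus vascular
#' invasion, focality, binned tumor count and Milan status (each covariate
#' read from the sample's patient), plus a patient-level table of
#' heterogeneity group versus Milan status. Row and column totals are
#' included. Missing covariate columns skip their table with a warning.
#'
#' @param assignment named cluster assignment (sample id -> 1/2).
#' @param samples sample annotation data.frame (`sample_id`, `patient_id`).
#' @param patients patient clinical data.frame.
#' @param groups optional `patient_groups` for the patient-level table.
#' @return named list of tables (with margins).
#' @export
covariate_crosstabs <- function(assignment, samples, patients, groups = NULL) {
  pat <- samples$patient_id[match(names(assignment), samples$sample_id)]
  idx <- match(pat, patients$patient_id)
  cluster <- factor(assignment, levels = 1:2,
                    labels = c("cluster1", "cluster2"))
  out <- list()
  sample_covs <- c(vascular_invasion = "vascular_invasion",
                   focality = "focality", milan = "milan")
  for (nm in names(sample_covs)) {
    col <- sample_covs[[nm]]
    if (!col %in% colnames(patients)) {
      warning("covariate column missing, table skipped: ", col)
      next
    }
    out[[paste0("cluster_x_", nm)]] <-
      stats::addmargins(table(cluster = cluster, covariate = patients[[col]][idx]))
  }
  if ("n_tumors" %in% colnames(patients)) {
    nt <- patients$n_tumors[idx]
    bins <- cut(nt, breaks = c(0, 1, 2, 3, Inf),
                labels = c("1", "2", "3", "4+"))
    out$cluster_x_n_tumors <- stats::addmargins(table(cluster = cluster,
                                                      n_tumors = bins))
  } else warning("covariate column missing, table skipped: n_tumors")
  if (!is.null(groups) && "milan" %in% colnames(patients)) {
    gm <- patients$milan[match(groups$patient_id, patients$patient_id)]
    out$group_x_milan <- stats::addmargins(table(group = groups$group,
                                                 milan = gm))
  }
  out
}

# round every numeric leaf to 12 significant digits so the JSON summary is
# byte-stable across platforms
signif_rec <- function(x, digits = 12) {
  if (is.list(x)) lapply(x, signif_rec, digits = digits)
  else if (is.numeric(x)) signif(x, digits)
  else x
}

#' Run the full heterogeneity-aware biomarker pipeline
#'
#' Executes clustering, patient grouping, training construction, mutual-
#' information feature selection, biomarker classification, survival
#' contrasts and the min/max baseline, writing every stage table as TSV plus
#' an M/A plot, Kaplan-Meier plots and a machine-readable JSON summary.
#' Identical configuration and seed give a byte-identical summary: every
#' stage draws its randomness from a substream derived from the one pipeline
#' seed, so adding a stage does not perturb earlier stages.
#'
#' Degenerate cohorts (e.g. a training class that comes out empty) complete
#' with warnings: the biomarker and survival-contrast stages are skipped and
#' flagged in the summary.
#'
#' @param config a [sim_config()]; when supplied the cohort is simulated.
#' @param cohort alternatively, a `mir_cohort` from [join_cohort()].
#' @param out_dir output directory (created if needed).
#' @param seed pipeline seed; defaults to `config$seed` when simulating.
#' @param k_features number of biomarker features to select.
#' @param n_init k-means restarts.
#' @param pool_mixed_with_poor pool MIXED patients with POOR for the
#'   patient-level survival contrast (mixed patients carry at least one
#'   poor-prognosis sample).
#' @param plots write PDF figures (M/A plot, KM curves).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_full_pipeline <- function(config = NULL, cohort = NULL, out_dir = tempfile("heteromir_"),
                              seed = NULL, k_features = 5, n_init = 25,
                              pool_mixed_with_poor = TRUE, plots = TRUE) {
  if (is.null(config) && is.null(cohort))
    stop("supply either a simulation config or a joined cohort")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L

  summary <- list(
    package_version = as.character(utils::packageVersion("heteromiR")),
    seed = seed, degenerate = FALSE, warnings = character(0))
  note <- function(msg) summary$warnings <<- c(summary$warnings, msg)

  if (!is.null(config)) {
    sim <- simulate_cohort(config)
    write_cohort(sim, out_dir)
    cohort <- join_cohort(sim$expr, sim$samples, sim$patients)
    summary$simulated <- TRUE
  } else {
    sim <- NULL
    summary$simulated <- FALSE
  }
  expr <- cohort$expr
  samples <- cohort$samples
  patients <- cohort$patients
  s2p <- stats::setNames(samples$patient_id, samples$sample_id)
  rec <- stats::setNames(patients$recurrence, patients$patient_id)

  # --- stage: cluster -------------------------------------------------------
  fit <- fit_two_means(expr, n_init = n_init,
                       seed = derive_seed(seed, "cluster"))
  model <- orient_clusters(fit, expr, s2p, rec)
  ma <- ma_statistics(model, s2p)
  utils::write.table(ma, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$cluster_sizes <- as.list(table(factor(model$assignment, levels = 1:2)))

  # --- stage: label ---------------------------------------------------------
  groups <- group_patients(model$assignment, s2p)
  utils::write.table(as.data.frame(groups), file.path(out_dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$group_counts <- as.list(attr(groups, "group_counts"))
  training <- build_training_labels(groups, model$assignment, s2p, rec)
  utils::write.table(training$train, file.path(out_dir, "training.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$training_sizes <- as.list(table(factor(training$train$class,
                                                 levels = c("POOR", "GOOD"))))
  summary$n_test_samples <- length(training$test_ids)
  disjoint <- verify_patient_disjoint(training, s2p)
  summary$patient_disjoint <- disjoint$ok

  degenerate <- any(unlist(summary$training_sizes) == 0)
  if (degenerate) {
    warning("a training class is empty: biomarker and survival-contrast stages skipped")
    note("empty training class; downstream stages skipped")
    summary$degenerate <- TRUE
  }

  # --- stage: select --------------------------------------------------------
  selected <- character(0)
  if (!degenerate) {
    expr_train <- expr[training$train$sample_id, , drop = FALSE]
    labels <- stats::setNames(training$train$class, training$train$sample_id)
    disc <- fit_discretization(expr_train)
    scores <- mi_scores(expr_train, labels, disc = disc)
    scores$mi_bits <- scores$mi / log(2)
    scores$selected <- scores$feature_id %in%
      rank_and_select(scores, k = k_features)
    utils::write.table(scores, file.path(out_dir, "mi_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    selected <- scores$feature_id[scores$selected]
    summary$selected_features <- selected
    summary$top_mi_nats <- scores$mi[seq_len(min(k_features, nrow(scores)))]
  }

  # --- stage: classify ------------------------------------------------------
  if (!degenerate) {
    bm <- fit_biomarker(expr, training, selected)
    sample_calls <- assign_samples(bm, expr)
    patient_calls <- classify_patients(sample_calls, s2p)
    pred <- data.frame(sample_id = names(sample_calls),
                       call = unname(sample_calls),
                       stringsAsFactors = FALSE)
    utils::write.table(pred, file.path(out_dir, "sample_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ppred <- data.frame(patient_id = names(patient_calls),
                        call = unname(patient_calls),
                        stringsAsFactors = FALSE)
    utils::write.table(ppred, file.path(out_dir, "patient_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$patient_call_counts <- as.list(table(
      factor(patient_calls, levels = c("POOR", "MIXED", "GOOD"))))

    # concordance of the selected-panel patient calls with the full-feature
    # cluster grouping (POOR~C1_ONLY, MIXED~MIXED, GOOD~C2_ONLY)
    full_grp <- stats::setNames(as.character(groups$group), groups$patient_id)
    map <- c(C1_ONLY = "POOR", C2_ONLY = "GOOD", MIXED = "MIXED")
    common <- intersect(names(patient_calls), names(full_grp))
    summary$concordance_selected_vs_all <-
      mean(patient_calls[common] == map[full_grp[common]])
  }

  # --- stage: survival ------------------------------------------------------
  surv_idx <- match(groups$patient_id, patients$patient_id)
  tm <- patients$time_months[surv_idx]
  ev <- patients$event[surv_idx]
  strata_cl <- build_strata(groups, scheme = "cluster")
  km_list <- lapply(split(seq_along(tm), strata_cl[groups$patient_id]),
                    function(i) km_estimate(tm[i], ev[i]))
  for (nm in names(km_list))
    utils::write.table(as.data.frame(km_list[[nm]]),
                       file.path(out_dir, paste0("km_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  present <- table(strata_cl[groups$patient_id])
  if (!degenerate && sum(present > 0) >= 2) {
    lr <- logrank_test(tm, ev, strata_cl[groups$patient_id])
    summary$logrank_groups <- list(chisq = lr$chisq, df = lr$df,
                                   p_value = lr$p_value)
  } else {
    note("fewer than 2 patient groups; log-rank skipped")
  }

  poor_like <- strata_cl[groups$patient_id] %in%
    (if (pool_mixed_with_poor) c("C1_ONLY", "MIXED") else "C1_ONLY")
  if (!degenerate && length(unique(poor_like)) == 2 && sum(ev) > 0) {
    cox <- cox_fit(tm, ev, cbind(poor_like = as.numeric(poor_like)))
    summary$cox_poor_vs_good <- list(
      hr = cox$hr[1], ci_low = cox$ci_low[1], ci_high = cox$ci_high[1],
      p_value = cox$p_value[1])
    utils::write.table(cox, file.path(out_dir, "cox_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    note("survival contrast skipped (single group or no events)")
  }
  if (!degenerate && "milan" %in% colnames(patients)) {
    milan <- stats::setNames(patients$milan, patients$patient_id)
    strata_m <- build_strata(groups, milan, scheme = "milan_cluster")
    sm <- strata_m[groups$patient_id]
    if (length(unique(sm)) >= 2 && sum(ev) > 0) {
      lrm <- logrank_test(tm, ev, sm)
      summary$logrank_milan_cluster <- list(chisq = lrm$chisq, df = lrm$df,
                                            p_value = lrm$p_value)
    }
  }

  # --- stage: minmax baseline ----------------------------------------------
  if (!degenerate && length(selected)) {
    mm <- summarize_minmax(expr, s2p, selected)
    mm_res <- run_minmax_analysis(mm, patients,
                                  seed = derive_seed(seed, "minmax"),
                                  n_init = n_init)
    if (!is.null(mm_res$cox))
      summary$minmax_cox <- list(hr = mm_res$cox$hr[1],
                                 ci_low = mm_res$cox$ci_low[1],
                                 ci_high = mm_res$cox$ci_high[1])
    utils::write.table(
      data.frame(patient_id = names(mm_res$cluster),
                 cluster = unname(mm_res$cluster)),
      file.path(out_dir, "minmax_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- crosstabs & figures --------------------------------------------------
  xt <- covariate_crosstabs(model$assignment, samples, patients, groups)
  for (nm in names(xt))
    utils::write.table(as.data.frame.matrix(xt[[nm]]),
                       file.path(out_dir, paste0("crosstab_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = TRUE,
                       col.names = NA)
  if (plots) {
    grDevices::pdf(file.path(out_dir, "ma_plot.pdf"), width = 6, height = 5)
    plot_ma(ma)
    grDevices::dev.off()
    grDevices::pdf(file.path(out_dir, "km_groups.pdf"), width = 6, height = 5)
    plot_km_strata(tm, ev, strata_cl[groups$patient_id])
    grDevices::dev.off()
  }

  summary <- signif_rec(summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# M/A scatter: M = d2 - d1 against A = (d1 + d2)/2, marked by patient purity
plot_ma <- function(ma) {
  pchs <- c(`all-cluster-1` = 15, `all-cluster-2` = 1, mixed = 17)
  graphics::plot(ma$A, ma$M, pch = pchs[ma$patient_mark],
                 xlab = "A = (d1 + d2) / 2", ylab = "M = d2 - d1",
                 main = "Distance diagnostics by sample")
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topleft", legend = names(pchs), pch = pchs, bty = "n")
}

plot_km_strata <- function(times, events, strata) {
  fit <- survival::survfit(
    survival::Surv(times, as.integer(events)) ~ strata)
  graphics::plot(fit, col = seq_along(unique(strata)), lwd = 2,
                 xlab = "Months", ylab = "Recurrence-free survival")
  graphics::legend("bottomleft", legend = sort(unique(as.character(strata))),
                   col = seq_along(unique(strata)), lwd = 2, bty = "n")
}
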