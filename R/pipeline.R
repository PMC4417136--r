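#' Attribute soil community variation to species, chemistry, space and phylogeny
#'
#' The package's main fitting function.  Runs the full inference chain on
#' one community table:
#'
#' 1. rare-OTU removal at the subsample level ([filter_rare()]);
#' 2. technical-subsample averaging ([average_subsamples()]);
#' 3. Bray-Curtis dissimilarities ([bray_curtis()]);
#' 4. NMDS stress-vs-dimensions scan and dimension choice
#'    ([stress_profile()], [choose_k()]) followed by the ordination at the
#'    chosen k ([nmds()]);
#' 5. permutation matrix-regression assessment of how much community
#'    structure the ordination represents ([ordination_fit()]);
#' 6. phylogenetic and spatial eigenvector construction
#'    ([phylo_eigenvectors()], [spatial_eigenvectors()]);
#' 7. per-axis, per-class linear models with eigenvector retention,
#'    AIC-stepwise chemistry selection and likelihood-ratio tests
#'    ([class_models()]);
#' 8. per-axis three-set variance partitioning ([partition3()]).
#'
#' @param otu an [otu_table] (subsample rows).
#' @param frame a [sample_frame] covering the table's samples.
#' @param tree species phylogeny (`phylo`) covering `frame$species`.
#' @param config a [run_config]; its `seed` drives every stochastic stage.
#' @param community label for this community (e.g. `"bacterial"`).
#' @param k fixed ordination dimensionality; if `NULL` (default) k is chosen
#'   from the stress profile by the stress-ceiling rule.
#' @return an object of class `rhizovar_fit`; see [summary.rhizovar_fit()].
#' @export
rhizo_analysis <- function(otu, frame, tree, config = run_config(),
                           community = "community", k = NULL) {
  stopifnot(inherits(otu, "otu_table"), inherits(config, "run_config"))
  validate_sample_frame(frame)
  validate_phylogeny(tree)
  if (!setequal(unique(otu$sample_id), frame$sample_id))
    stop("io stage: OTU table samples and sample frame disagree: ",
         paste(union(setdiff(unique(otu$sample_id), frame$sample_id),
                     setdiff(frame$sample_id, unique(otu$sample_id))),
               collapse = ", "))
  t0 <- proc.time()["elapsed"]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " stage failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(seed = config$seed, config = unclass(config),
                   community = community,
                   n_samples = n_samples(otu),
                   n_subsamples = nrow(otu$values),
                   n_otus_input = ncol(otu$values))

  filtered <- stage("filter_rare", filter_rare(otu, config$rare_threshold))
  manifest$n_otus_removed <- ncol(otu$values) - ncol(filtered$values)
  averaged <- stage("average_subsamples", average_subsamples(filtered))
  D <- stage("bray_curtis", bray_curtis(averaged))
  ## samples in frame order from here on
  D <- D[frame$sample_id, frame$sample_id]

  if (is.null(k)) {
    profile <- stage("stress_profile",
                     stress_profile(D, config$k_max, config$n_starts,
                                    seed = config$seed))
    k <- stage("choose_k", choose_k(profile, config$stress_ceiling))
  } else {
    profile <- NULL
  }
  manifest$k <- k
  ord <- stage("nmds", nmds(D, k, config$n_starts, seed = config$seed))
  manifest$stress <- ord$stress
  fit_stat <- stage("ordination_fit",
                    ordination_fit(ord, D, config$n_perm, seed = config$seed))

  phylo_evs <- stage("phylo_eigenvectors",
                     phylo_eigenvectors(tree, frame, config$n_phylo_screen))
  spatial_evs <- stage("spatial_eigenvectors",
                       spatial_eigenvectors(frame, config$n_spatial))

  results <- NULL
  partitions <- list()
  chem_z <- standardize_chemistry(frame)
  details <- list()
  for (a in seq_len(k)) {
    axis_label <- paste0("MDS", a)
    y <- ord$scores[, a]
    cm <- stage("class_models",
                class_models(y, frame, phylo_evs, spatial_evs,
                             alpha = config$alpha, axis_label = axis_label))
    results <- rbind(results, cm)
    chem_sel <- attr(cm, "chemistry_selected")
    retained <- attr(cm, "phylo_retained")
    details[[axis_label]] <- list(chemistry_selected = chem_sel,
                                  phylo_retained = retained)
    partitions[[axis_label]] <- stage("partition3", partition3(
      y,
      X_phylo = ev_matrix(phylo_evs, "phy")[, retained, drop = FALSE],
      X_chem = chem_z[, chem_sel, drop = FALSE],
      X_space = ev_matrix(spatial_evs, "spa")))
  }
  manifest$phylo_retained_max <-
    max(vapply(details, function(d) length(d$phylo_retained), integer(1)))
  manifest$elapsed_s <- unname(proc.time()["elapsed"] - t0)

  structure(list(community = community, config = config,
                 frame = frame, tree = tree,
                 distances = D, stress_profile = profile, ordination = ord,
                 ordination_fit = fit_stat,
                 phylo_evs = phylo_evs, spatial_evs = spatial_evs,
                 results = results, axis_details = details,
                 partitions = partitions, manifest = manifest),
            class = "rhizovar_fit")
}

#' @export
print.rhizovar_fit <- function(x, ...) {
  cat(sprintf("rhizovar_fit [%s]: %d samples, %d OTUs retained (%d removed)\n",
              x$community, x$manifest$n_samples,
              x$manifest$n_otus_input - x$manifest$n_otus_removed,
              x$manifest$n_otus_removed))
  cat(sprintf("  NMDS: k = %d, stress-1 = %.3f; ordination represents %.1f%% of community structure (P = %.3g)\n",
              x$manifest$k, x$manifest$stress,
              x$ordination_fit$r_squared_pct, x$ordination_fit$p_value))
  invisible(x)
}

#' Summarise a fitted analysis
#'
#' Prints the stress profile, the ordination-fit statistic, the per-axis
#' class results grid (adjusted R-squared with significance markers) and
#' the per-axis variance partitions.
#'
#' @param object a `rhizovar_fit`.
#' @param ... unused.
#' @export
summary.rhizovar_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$stress_profile)) {
    cat("\nStress profile:\n")
    print(object$stress_profile, row.names = FALSE)
  }
  cat("\nPer-class adjusted R-squared by axis (* = P <",
      format(object$config$alpha), "):\n")
  print(format_results_table(object$results, object$config$alpha),
        quote = FALSE)
  cat("\nVariance partitions (phylogeny / chemistry / space):\n")
  print(partition_report(object$partitions), row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
coef.rhizovar_fit <- function(object, ...) {
  object$results
}

#' Plot method: stress profile and ordination scatter
#'
#' Left panel: stress versus dimensionality with the acceptance ceiling.
#' Right panel: samples on the first two ordination axes with species means
#' and +/- 1 SE bars.
#'
#' @param x a `rhizovar_fit`.
#' @param axes which two axes to scatter.
#' @param ... unused.
#' @export
plot.rhizovar_fit <- function(x, axes = c(1, 2), ...) {
  two_panel <- !is.null(x$stress_profile)
  if (two_panel) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    plot(x$stress_profile$k, x$stress_profile$stress, type = "b",
         xlab = "dimensions", ylab = "stress-1", main = "Stress profile")
    graphics::abline(h = x$config$stress_ceiling, lty = 2)
  }
  sc <- x$ordination$scores
  if (ncol(sc) < 2) axes <- c(1, 1)
  sp <- factor(x$frame$species)
  cols <- grDevices::rainbow(nlevels(sp))[as.integer(sp)]
  plot(sc[, axes[1]], sc[, axes[2]], col = cols, pch = 16,
       xlab = colnames(sc)[axes[1]], ylab = colnames(sc)[axes[2]],
       main = sprintf("%s ordination (stress %.2f)", x$community,
                      x$ordination$stress))
  mx <- tapply(sc[, axes[1]], sp, mean)
  my <- tapply(sc[, axes[2]], sp, mean)
  sex <- tapply(sc[, axes[1]], sp, function(v) stats::sd(v) / sqrt(length(v)))
  sey <- tapply(sc[, axes[2]], sp, function(v) stats::sd(v) / sqrt(length(v)))
  graphics::arrows(mx - sex, my, mx + sex, my, angle = 90, code = 3,
                   length = 0.02)
  graphics::arrows(mx, my - sey, mx, my + sey, angle = 90, code = 3,
                   length = 0.02)
  graphics::points(mx, my, pch = 21, bg = grDevices::rainbow(nlevels(sp)),
                   cex = 1.4)
  invisible(x)
}

#' Write the fitted analysis artefacts to a directory
#'
#' Emits the results grid, ordination scores, stress profile, variance
#' partitions and a plain-text run manifest as TSV/text files.
#'
#' @param fit a `rhizovar_fit`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_analysis <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results_table(fit$results, file.path(dir, "results_table.tsv"))
  utils::write.table(
    data.frame(sample_id = fit$ordination$labels, fit$ordination$scores),
    file.path(dir, "ordination_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$stress_profile))
    utils::write.table(fit$stress_profile,
                       file.path(dir, "stress_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(partition_report(fit$partitions),
                     file.path(dir, "variance_partitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  man <- fit$manifest
  man$config <- NULL
  man$elapsed_s <- NULL     # wall-clock time would break bit-reproducibility
  writeLines(c(sprintf("%s\t%s", names(man),
                       vapply(man, function(v) paste(format(v), collapse = ","),
                              "")),
               sprintf("config.%s\t%s", names(unclass(fit$config)),
                       vapply(unclass(fit$config), format, ""))),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Benchmark the pipeline on synthetic scenarios
#'
#' For each scenario and replicate: generate a dataset with [simulate_dataset()],
#' analyse it with [rhizo_analysis()] (at a fixed, small ordination
#' dimensionality for speed), and record each predictor class's p-value and
#' adjusted R-squared on the first ordination axis.  Summaries give per-class
#' empirical rejection rates at `alpha` and median adjusted R-squared —
#' type-I error rates for channels with zero weight, power for the injected
#' channel.
#'
#' @param scenarios named list of [scenario_spec]s (their seeds are
#'   overridden per replicate from `seed`).
#' @param n_reps replicates per scenario.
#' @param seed integer master seed.
#' @param k ordination dimensionality used in the benchmark analyses.
#' @param n_starts,n_perm reduced analysis settings for throughput.
#' @param alpha rejection level used in the summary.
#' @return list with `records` (one row per scenario x rep x class) and
#'   `summary` (per scenario x class: rejection rate, median adjusted R2).
#' @export
run_benchmark <- function(scenarios, n_reps, seed = 1L, k = 2,
                          n_starts = 1, n_perm = 199, alpha = 0.05) {
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  records <- vector("list", length(scenarios) * n_reps)
  idx <- 0L
  for (sc in names(scenarios)) {
    base <- scenarios[[sc]]
    for (r in seq_len(n_reps)) {
      spec <- base
      spec$seed <- stage_seed(seed, "benchmark") %% 2000000L + 1000L * r +
        match(sc, names(scenarios))
      data <- simulate_dataset(spec)
      cfg <- run_config(n_starts = n_starts, n_perm = n_perm,
                        alpha = alpha, seed = spec$seed)
      fit <- rhizo_analysis(data$otu, data$frame, data$tree, cfg,
                            community = sc, k = k)
      res <- fit$results[fit$results$axis == "MDS1", ]
      idx <- idx + 1L
      records[[idx]] <- data.frame(scenario = sc, rep = r,
                                   class = res$class, adj_r2 = res$adj_r2,
                                   p_value = res$p_value,
                                   stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  agg <- do.call(rbind, lapply(split(records, records[c("scenario", "class")]),
    function(d) data.frame(scenario = d$scenario[1], class = d$class[1],
                           rejection_rate = mean(d$p_value < alpha),
                           median_adj_r2 = stats::median(d$adj_r2),
                           n = nrow(d))))
  rownames(agg) <- NULL
  list(records = records, summary = agg)
}
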