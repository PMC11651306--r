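# End-to-end orchestration: simulate -> features -> excitability ->
# (vclamp) -> stats, with a reproducible manifest.

#' Pipeline run configuration
#'
#' Bundles a [cohort_config] with detection criteria, stage toggles and an
#' output directory. Fully serializable: a copy of the resolved
#' configuration is written into the run's output directory.
#'
#' @param cohort a [cohort_config]
#' @param criteria a [detection_criteria]
#' @param out_dir output directory (`NULL` = in-memory only)
#' @param stages character subset of
#'   `c("simulate", "excitability", "vclamp", "stats")`
#' @return a `run_config`
#' @export
run_config <- function(cohort = cohort_config(),
                       criteria = detection_criteria(),
                       out_dir = NULL,
                       stages = c("simulate", "excitability", "stats")) {
  known <- c("simulate", "excitability", "vclamp", "stats")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(cohort = cohort, criteria = criteria, out_dir = out_dir,
                 stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or is given) a cohort, profiles every cell, and produces the
#' group-level report: per-cell table, mean +/- SEM summaries, responder
#' contingency tables with exact tests, and firing-subtype proportions.
#' Identical configuration and seed give an identical report. Cells
#' excluded by the resting-potential window are dropped from group
#' statistics and surfaced in the report's `excluded` field.
#'
#' @param config a [run_config]
#' @param cohort optional pre-generated [generate_cohort] result (skips the
#'   simulate stage)
#' @return a `pipeline_report` list: `cells`, `summary`, `proportions`,
#'   `fisher`, `excluded`, `manifest`
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(cells = NULL, summary = NULL, proportions = NULL,
                 fisher = NULL, excluded = character(0), manifest = NULL)

  if (!length(config$stages)) {
    warning("all stages disabled: empty report")
    return(structure(report, class = "pipeline_report"))
  }

  if (is.null(cohort) && "simulate" %in% config$stages)
    cohort <- generate_cohort(config$cohort, criteria = config$criteria)
  if (is.null(cohort)) stop("no cohort: enable the simulate stage or pass one")

  if ("excitability" %in% config$stages) {
    profiles <- lapply(cohort$recordings, excitability_profile,
                       criteria = config$criteria)
    cells <- profile_table(profiles)
    report$cells <- cells
    report$excluded <- cells$cell_id[!is.na(cells$included) & !cells$included]
    if (length(report$excluded))
      warning("excluded by V_rest window: ",
              paste(report$excluded, collapse = ", "))
  }

  if ("vclamp" %in% config$stages) {
    rows <- lapply(names(cohort$recordings), function(id) {
      rec <- cohort$recordings[[id]]
      cm <- cohort$truth$C_m[cohort$truth$cell_id == id]
      vs <- vclamp_summary(rec, cm)
      data.frame(cell_id = id, group = rec$group,
                 ramp_peak = if (!is.null(vs$ramp)) vs$ramp$peak else NA_real_,
                 density_0 = vs$density_0,
                 a_type_density = if (!is.null(vs$atype))
                   vs$atype$a_peak_density else NA_real_,
                 sustained_density = if (!is.null(vs$atype))
                   vs$atype$sustained_density else NA_real_)
    })
    report$vclamp <- do.call(rbind, rows)
  }

  if ("stats" %in% config$stages && !is.null(report$cells)) {
    cells <- report$cells
    keep <- is.na(cells$included) | cells$included
    cells <- cells[keep, ]
    metrics <- intersect(c("V_rest", "R_in", "C_m", "rheobase_ramp",
                           "rheobase_step", "aps_1x", "aps_2x", "aps_3x",
                           "aps_4x", "amplitude", "overshoot", "rise",
                           "fall", "half_width", "latency"),
                         names(cells))
    report$summary <- summarize_groups(cells, metrics)
    groups <- unique(cells$group)
    prop <- do.call(rbind, lapply(groups, function(g) {
      sub <- cells[cells$group == g, ]
      k <- sum(sub$responder_ramp, na.rm = TRUE)
      n <- sum(!is.na(sub$responder_ramp))
      sing <- sum(sub$subtype == "single", na.rm = TRUE)
      nsub <- sum(!is.na(sub$subtype))
      data.frame(group = g, responders = k, n = n,
                 responder_pct = if (n > 0) proportion(k, n) else NA_real_,
                 single = sing, classified = nsub,
                 single_pct = if (nsub > 0) proportion(sing, nsub) else NA_real_)
    }))
    report$proportions <- prop
    if (length(groups) >= 2 && all(prop$n > 0)) {
      g1 <- prop[1, ]; g2 <- prop[2, ]
      tab <- matrix(c(g1$responders, g1$n - g1$responders,
                      g2$responders, g2$n - g2$responders),
                    2, 2, byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      report$fisher <- data.frame(group1 = g1$group, group2 = g2$group,
                                  p = ft$p, degenerate = ft$degenerate)
    }
  }

  report$manifest <- list(
    package_version = as.character(utils::packageVersion("drgephys")),
    seed = config$cohort$seed,
    n_per_group = config$cohort$n_per_group,
    groups = config$cohort$groups,
    species = config$cohort$species,
    stages = config$stages,
    criteria = unclass(config$criteria),
    mixture = as.list(config$cohort$mixture),
    jitter_cv = config$cohort$jitter_cv)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$cells))
      utils::write.csv(report$cells, file.path(config$out_dir, "cells.csv"),
                       row.names = FALSE)
    if (!is.null(report$summary))
      utils::write.csv(report$summary, file.path(config$out_dir, "summary.csv"),
                       row.names = FALSE)
    if (!is.null(report$proportions))
      utils::write.csv(report$proportions,
                       file.path(config$out_dir, "proportions.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline report>\n")
  if (!is.null(x$cells))
    cat(sprintf("  %d cells (%d excluded by V_rest window)\n",
                nrow(x$cells), length(x$excluded)))
  if (!is.null(x$proportions)) {
    for (r in seq_len(nrow(x$proportions)))
      cat(sprintf("  %s: %d/%d responders (%g%%), %g%% single spikers\n",
                  x$proportions$group[r], x$proportions$responders[r],
                  x$proportions$n[r], x$proportions$responder_pct[r],
                  x$proportions$single_pct[r]))
  }
  if (!is.null(x$fisher))
    cat(sprintf("  Fisher %s vs %s: p = %.4g\n", x$fisher$group1,
                x$fisher$group2, x$fisher$p))
  invisible(x)
}
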