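#' Run the full maturation pipeline
#'
#' Simulate a cohort, measure every frame, and run the statistical battery:
#' the one-call equivalent of simulate / measure / score-doppler / analyze.
#' When `out_dir` is given, the measured cohort, correlation matrix, p-value
#' matrix, Doppler proportion table, per-week maturity panels and a run log
#' (seed, sizes, package version) are written there as CSV / plain text.
#'
#' @param n_dogs dogs simulated.
#' @param master_seed master seed driving every random draw.
#' @param weeks exam week grid.
#' @param out_dir optional output directory.
#' @param panel_weeks weeks at which to evaluate [maturity_panel()].
#' @return list with `cohort` (measured), `report` ([correlation_report()]),
#'   `doppler_table` (per-week detected-score percentages) and `panels`.
#' @export
#' @examples
#' \donttest{
#' res <- run_maturation_pipeline(n_dogs = 2, master_seed = 1,
#'                                weeks = seq(24, 40, 4))
#' }
run_maturation_pipeline <- function(n_dogs = 8, master_seed = 1,
                                    weeks = seq(4, 40, by = 2),
                                    out_dir = NULL,
                                    panel_weeks = intersect(c(12, 36),
                                                            weeks)) {
  config <- cohort_config(n_dogs = n_dogs, weeks = weeks,
                          master_seed = master_seed)
  cohort <- generate_cohort(config)
  measured <- measure_cohort(cohort)
  report <- correlation_report(measured)
  doppler_table <- do.call(rbind, lapply(sort(unique(measured$week)),
                                         function(w) {
    pct <- score_cohort(measured$doppler_score_detected[measured$week == w])
    data.frame(week = w, t(pct))
  }))
  panels <- lapply(panel_weeks, function(w) maturity_panel(measured, w))
  names(panels) <- paste0("week", panel_weeks)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(measured, file.path(out_dir, "cohort_measured.csv"))
    write.csv(report$matrix, file.path(out_dir, "correlations.csv"))
    write.csv(report$p_matrix, file.path(out_dir, "p_values.csv"))
    write.csv(doppler_table, file.path(out_dir, "doppler_table.csv"),
              row.names = FALSE)
    panel_txt <- unlist(lapply(panels, function(p) {
      c(sprintf("week %g: %s (%d/6)", p$week, p$verdict, p$n_true),
        sprintf("  %s: %s", names(p$indicators), p$indicators), "")
    }))
    writeLines(panel_txt, file.path(out_dir, "maturity_panels.txt"))
    writeLines(c(
      sprintf("echotestis %s", as.character(utils::packageVersion("echotestis"))),
      sprintf("master_seed: %d", master_seed),
      sprintf("n_dogs: %d", n_dogs),
      sprintf("weeks: %s", paste(weeks, collapse = ",")),
      sprintf("records: %d", nrow(measured)),
      sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    ), file.path(out_dir, "run_log.txt"))
  }
  invisible(list(cohort = measured, report = report,
                 doppler_table = doppler_table, panels = panels))
}
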