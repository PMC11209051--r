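#' Full correlation and comparison report
#'
#' Runs the statistical battery on a measured cohort: the pairwise Spearman
#' matrix over all study parameters (somatometrics, volumes, semen,
#' grayscale intensities and standardization ratios, left and right testes
#' pooled), Kruskal-Wallis comparisons of grayscale intensity across the
#' three anatomical structures and across the three age periods, the paired
#' left-right comparison, the lagged echogenicity-versus-sperm correlations
#' and the rising-phase slope fits.
#'
#' @param measured measured cohort from [measure_cohort()].
#' @param lags lags (weeks) for [lagged_correlation()].
#' @param p_adjust p-value adjustment for the correlation matrix
#'   (`"none"`, the study convention, or any [stats::p.adjust()] method
#'   such as `"holm"`).
#' @return object of class `correlation_report` with elements `matrix`,
#'   `p_matrix`, `n_matrix`, `kw_structures`, `kw_periods`, `lr_compare`,
#'   `lagged`, `slopes`.
#' @export
correlation_report <- function(measured, lags = c(0, 2, 4),
                               p_adjust = "none") {
  d <- measured
  d$scrotum_volume <- volume_clinical(d$scrotal_l, d$scrotal_w, d$scrotal_h)
  d$testis_volume <- volume_clinical(d$testis_l, d$testis_w, d$testis_h)
  d$us_volume <- volume_us(d$us_l, d$us_w, d$us_h)
  params <- c("weight", "height", "total_sperm", "motility",
              "scrotum_volume", "testis_volume", "us_volume",
              "gi_region", "het_region", "gi_mt", "gi_capsule",
              "ratio_mt", "ratio_cap")
  params <- intersect(params, names(d))
  k <- length(params)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(params, params))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- try(spearman_rank(d[[params[i]]], d[[params[j]]]), silent = TRUE)
      if (!inherits(s, "try-error")) {
        rho[i, j] <- rho[j, i] <- s$rho
        p[i, j] <- p[j, i] <- s$p
        nmat[i, j] <- nmat[j, i] <- s$n
      }
    }
  }
  if (p_adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }

  kw_structures <- kruskal_wallis(list(
    parenchyma = d$gi_region[!is.na(d$gi_region)],
    mediastinum = d$gi_mt[!is.na(d$gi_mt)],
    capsule = d$gi_capsule[!is.na(d$gi_capsule)]
  ))
  d <- assign_periods(d)
  kw_periods <- lapply(c(parenchyma = "gi_region", mediastinum = "gi_mt",
                         capsule = "gi_capsule"), function(col) {
    groups <- split(d[[col]][!is.na(d[[col]])],
                    d$period[!is.na(d[[col]])])
    kruskal_wallis(groups[lengths(groups) > 0])
  })

  slopes <- list(
    parenchyma = fit_gi_slope(measured, "parenchyma"),
    mediastinum = fit_gi_slope(measured, "mediastinum")
  )

  structure(list(matrix = rho, p_matrix = p, n_matrix = nmat,
                 kw_structures = kw_structures, kw_periods = kw_periods,
                 lr_compare = left_right_compare(measured),
                 lagged = lagged_correlation(measured, lags = lags),
                 slopes = slopes),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat("<correlation_report>\n\nSpearman rho (pooled testes):\n")
  print(round(x$matrix, digits))
  cat(sprintf("\nKruskal-Wallis across structures: H = %.2f, p = %.3g\n",
              x$kw_structures$statistic, x$kw_structures$p))
  cat("Kruskal-Wallis across periods:\n")
  for (nm in names(x$kw_periods)) {
    cat(sprintf("  %-12s H = %.2f, p = %.3g\n", nm,
                x$kw_periods[[nm]]$statistic, x$kw_periods[[nm]]$p))
  }
  cat("\nGI slope (rising phase):\n")
  for (nm in names(x$slopes)) {
    cat(sprintf("  %-12s %.3f +/- %.3f GI units/week\n", nm,
                x$slopes[[nm]]$slope, x$slopes[[nm]]$se))
  }
  cat("\nGI vs total sperm, by lag:\n")
  print(x$lagged, row.names = FALSE)
  cat(sprintf("\nLeft-right comparison: min p = %.3f over %d parameters\n",
              suppressWarnings(min(x$lr_compare$p, na.rm = TRUE)),
              nrow(x$lr_compare)))
  invisible(x)
}
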