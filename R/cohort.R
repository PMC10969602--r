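#' The six study shim methods
#'
#' Second- to fifth-order spherical-harmonic shims (unbounded coefficients,
#' the scanner-shim idealisation) and the two multi-coil layouts (currents
#' bounded per channel).
#'
#' @param ids Subset of `c("SH2", "SH3", "SH4", "SH5", "IPRES32", "UNIC51")`.
#' @return A tibble with columns `method`, `type`, `degree`.
#' @export
study_methods <- function(ids = c("SH2", "SH3", "SH4", "SH5", "IPRES32",
                                  "UNIC51")) {
  all <- tibble::tibble(
    method = c("SH2", "SH3", "SH4", "SH5", "IPRES32", "UNIC51"),
    type = c(rep("sh", 4), "coil", "coil"),
    degree = c(2L, 3L, 4L, 5L, NA_integer_, NA_integer_)
  )
  ids <- match.arg(ids, all$method, several.ok = TRUE)
  all[match(ids, all$method), ]
}

#' Shim one subject with every method
#'
#' Runs each requested shim method on the subject's field map and scores the
#' residual: whole-brain SD before/after, MRSI coverage at each requested
#' resolution, and per-ROI coverage. Spherical-harmonic bases are nested
#' (degree k's columns are a subset of degree k+1's), so residual SDs are
#' monotone over SH order by construction.
#'
#' @param subject A `shim_subject` (from [generate_subject()]) or a list with
#'   elements `field`, `mask` and optionally `roi_pfc`, `roi_mtl`.
#' @param methods A [study_methods()] tibble.
#' @param resolutions Named list of MRSI voxel sizes in mm.
#' @param model A [linewidth_model()].
#' @param helmet A [helmet_model()] for the coil layouts.
#' @param current_bound_a Per-channel coil current bound (A).
#' @param n_segments Biot-Savart chord count.
#' @return A tibble with one row per method x resolution: `subject_id`,
#'   `method`, `sd_before_hz`, `sd_after_hz`, `resolution`, `voxel_cc`,
#'   `coverage_pct`, `coverage_pfc_pct`, `coverage_mtl_pct`.
#' @export
run_subject <- function(subject,
                        methods = study_methods(),
                        resolutions = list("1.44cc" = c(12, 12, 10),
                                           "0.092cc" = c(4.8, 4.8, 4)),
                        model = linewidth_model(),
                        helmet = helmet_model(),
                        current_bound_a = 3,
                        n_segments = 256L) {
  field <- subject$field
  mask <- subject$mask
  check_same_geometry(field, mask, "field and mask")
  rois <- list()
  if (!is.null(subject$roi_pfc)) rois$pfc <- subject$roi_pfc
  if (!is.null(subject$roi_mtl)) rois$mtl <- subject$roi_mtl
  sid <- if (!is.null(field$subject_id)) field$subject_id else "subject"
  grids <- lapply(resolutions, function(v) block_partition(mask$spacing, v))

  sh_full <- if (any(methods$type == "sh")) {
    sh_basis(mask, max_degree = max(methods$degree, na.rm = TRUE))
  } else NULL

  rows <- list()
  for (i in seq_len(nrow(methods))) {
    m <- methods[i, ]
    if (m$type == "sh") {
      keep <- sh_full$meta$degree <= m$degree
      bas <- basis_matrix(sh_full$values[, keep, drop = FALSE],
                          sh_full$channel_labels[keep], sh_full$units,
                          sh_full$voxel_index)
      # degree 0 already supplies the global frequency term
      res <- solve_shim(bas, field, mask = mask, lower = -Inf, upper = Inf,
                        include_f0 = FALSE)
    } else {
      layout <- switch(m$method,
                       IPRES32 = layout_ipres32(helmet, current_bound_a),
                       UNIC51 = layout_unic51(helmet, current_bound_a))
      bas <- assemble_coil_basis(layout, mask, n_segments = n_segments)
      res <- solve_shim(bas, field, mask = mask, include_f0 = TRUE)
    }
    shimmed <- residual_field(res, mask)
    for (rn in names(grids)) {
      cov <- compute_coverage(shimmed, mask, grid = grids[[rn]],
                              model = model, rois = rois)
      roi_cov <- setNames(cov$roi_coverage$coverage_pct,
                          cov$roi_coverage$roi)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid,
        method = m$method,
        sd_before_hz = res$sd_before,
        sd_after_hz = res$sd_after,
        resolution = rn,
        voxel_cc = grids[[rn]]$realized_cc,
        coverage_pct = cov$coverage_pct,
        coverage_pfc_pct = if ("pfc" %in% names(roi_cov)) roi_cov[["pfc"]]
                           else NA_real_,
        coverage_mtl_pct = if ("mtl" %in% names(roi_cov)) roi_cov[["mtl"]]
                           else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Cohort summary table
#'
#' Per-method, per-resolution mean and population SD across subjects of the
#' residual field SD and the coverage metrics — the layout of the study's
#' summary table (one row per shim method, mean +/- SD entries).
#'
#' @param results Row-bound [run_subject()] tibbles for >= 2 subjects.
#' @return A tibble of class `cohort_summary`.
#' @export
summarize_cohort <- function(results) {
  if (length(unique(results$subject_id)) < 2) {
    stop("cohort summary needs >= 2 subjects", call. = FALSE)
  }
  complete <- results |>
    dplyr::count(.data$method, .data$resolution) |>
    dplyr::pull(.data$n)
  if (length(unique(complete)) != 1L) {
    stop("incomplete subject x method grid", call. = FALSE)
  }
  out <- results |>
    dplyr::group_by(.data$method, .data$resolution, .data$voxel_cc) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      sd_after_mean_hz = mean(.data$sd_after_hz),
      sd_after_sd_hz = sd_pop(.data$sd_after_hz),
      coverage_mean_pct = mean(.data$coverage_pct),
      coverage_sd_pct = sd_pop(.data$coverage_pct),
      coverage_pfc_mean_pct = mean(.data$coverage_pfc_pct),
      coverage_mtl_mean_pct = mean(.data$coverage_mtl_pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$method,
                          levels = c("SH2", "IPRES32", "SH3", "SH4", "SH5",
                                     "UNIC51")),
                   .data$resolution)
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Format a cohort summary as a mean +/- SD coverage table
#'
#' One row per shim method, one `mean +/- SD` column per resolution.
#'
#' @param summary A [summarize_cohort()] tibble.
#' @param digits Rounding for the formatted entries.
#' @return A tibble of character columns.
#' @export
cohort_table <- function(summary, digits = 0) {
  summary |>
    dplyr::mutate(entry = sprintf("%s ± %s",
                                  formatC(round(.data$coverage_mean_pct,
                                                digits), format = "fg"),
                                  formatC(round(.data$coverage_sd_pct,
                                                digits), format = "fg"))) |>
    dplyr::select(dplyr::all_of(c("method", "resolution", "entry"))) |>
    tidyr::pivot_wider(names_from = "resolution", values_from = "entry")
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Tests for differences in a metric across shim methods. The omnibus test is
#' a one-way ANOVA over method groups; every pairwise comparison is a
#' two-sample t-test (paired across subjects by default, the natural design
#' when every subject is shimmed with every method) with Bonferroni
#' multiplier `choose(n_methods, 2)`. With zero variance everywhere and equal
#' means, F is defined as 0 and p as 1.
#'
#' @param data Long tibble with one row per subject x method.
#' @param value Name of the metric column.
#' @param group Name of the method column.
#' @param subject Name of the subject column (needed for paired tests).
#' @param paired Use paired pairwise t-tests.
#' @param alpha Significance level recorded on the result.
#' @return An object of class `stat_test_result`: `f_statistic`, `p_value`,
#'   `pairwise` (tibble with `p_adjusted = min(1, p * n_pairs)`), `alpha`.
#' @export
anova_bonferroni <- function(data, value = "sd_after_hz", group = "method",
                             subject = "subject_id", paired = TRUE,
                             alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 methods", call. = FALSE)
  if (min(table(g)) < 2) stop("need >= 2 subjects per method", call. = FALSE)
  grand <- mean(v)
  ss_tot <- sum((v - grand)^2)
  if (ss_tot < 1e-12 * max(1, grand^2)) {
    f_stat <- 0
    p_val <- 1
  } else {
    fit <- stats::aov(v ~ g)
    tab <- summary(fit)[[1]]
    f_stat <- tab[["F value"]][1]
    p_val <- tab[["Pr(>F)"]][1]
    if (!is.finite(f_stat)) { f_stat <- 0; p_val <- 1 }
  }
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    if (paired) {
      if (is.null(subject) || !subject %in% names(data)) {
        stop("`subject` column required for paired tests", call. = FALSE)
      }
      d1 <- data[data[[group]] == g1, ]
      d2 <- data[data[[group]] == g2, ]
      d1 <- d1[order(d1[[subject]]), ][[value]]
      d2 <- d2[order(d2[[subject]]), ][[value]]
      diffs <- d1 - d2
      p_raw <- if (sd_pop(diffs) < 1e-12) {
        if (abs(mean(diffs)) < 1e-12) 1 else 0
      } else stats::t.test(d1, d2, paired = TRUE)$p.value
    } else {
      d1 <- data[data[[group]] == g1, ][[value]]
      d2 <- data[data[[group]] == g2, ][[value]]
      p_raw <- if (sd_pop(d1) < 1e-12 && sd_pop(d2) < 1e-12) {
        if (abs(mean(d1) - mean(d2)) < 1e-12) 1 else 0
      } else stats::t.test(d1, d2)$p.value
    }
    tibble::tibble(group1 = g1, group2 = g2, p_raw = p_raw,
                   p_adjusted = min(1, p_raw * n_pairs))
  })
  structure(list(f_statistic = f_stat, p_value = p_val, pairwise = pw,
                 n_pairs = n_pairs, alpha = alpha, metric = value,
                 paired = paired),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<stat_test_result> %s: F = %.3f, p = %.3g (%d pairwise, Bonferroni x%d)\n",
              x$metric, x$f_statistic, x$p_value, x$n_pairs, x$n_pairs))
  sig <- x$pairwise$p_adjusted < x$alpha
  cat("  significant pairs:", sum(sig), "of", x$n_pairs, "\n")
  invisible(x)
}

#' @rdname tidy_stat
#' @exportS3Method
tidy.stat_test_result <- function(x, ...) x$pairwise

#' Tidy and summarise an ANOVA/Bonferroni result
#'
#' `tidy()` returns the pairwise comparison table; `glance()` the omnibus
#' one-row summary.
#'
#' @param x A `stat_test_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_stat
#' @exportS3Method
glance.stat_test_result <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 n_pairs = x$n_pairs, alpha = x$alpha, metric = x$metric)
}

#' Run the full simulated shimming study
#'
#' Generates a seeded synthetic cohort (or accepts a pre-built list of
#' subjects), shims every subject with every method, and assembles the
#' cohort summary plus ANOVA/Bonferroni statistics for the residual SD and
#' the coverage at each resolution. Fixed seeds give byte-identical outputs.
#'
#' @param n Cohort size (default 24).
#' @param master_seed Master RNG seed for cohort generation.
#' @param base Base [subject_config()].
#' @param subjects Optional list of `shim_subject`s; overrides `n` /
#'   `master_seed` / `base`.
#' @param methods,resolutions,model,helmet,current_bound_a,n_segments As in
#'   [run_subject()].
#' @param paired Paired pairwise t-tests (every subject sees every method).
#' @param out_dir Optional directory: writes `cohort_results.csv`,
#'   `cohort_summary.csv`, `coverage_table.csv` and `stats.json`.
#' @param verbose Print per-subject progress.
#' @return An object of class `shim_study`: `results` (per subject x method x
#'   resolution tibble), `summary` ([summarize_cohort()]), `stats` (named
#'   list of [anova_bonferroni()] results), `config`.
#' @export
run_study <- function(n = 24, master_seed = 42, base = subject_config(),
                      subjects = NULL,
                      methods = study_methods(),
                      resolutions = list("1.44cc" = c(12, 12, 10),
                                         "0.092cc" = c(4.8, 4.8, 4)),
                      model = linewidth_model(),
                      helmet = helmet_model(),
                      current_bound_a = 3,
                      n_segments = 256L,
                      paired = TRUE,
                      out_dir = NULL,
                      verbose = FALSE) {
  if (is.null(subjects)) {
    subjects <- generate_cohort(n = n, base = base, master_seed = master_seed)
  }
  results <- purrr::map_dfr(subjects, function(sub) {
    sid <- sub$field$subject_id
    out <- tryCatch(
      run_subject(sub, methods = methods, resolutions = resolutions,
                  model = model, helmet = helmet,
                  current_bound_a = current_bound_a,
                  n_segments = n_segments),
      error = function(e) stop("subject ", sid, " failed: ",
                               conditionMessage(e), call. = FALSE))
    if (verbose) message("done: ", sid)
    out
  })
  summary <- summarize_cohort(results)
  stats <- list(
    sd_after = anova_bonferroni(
      dplyr::filter(results, .data$resolution == names(resolutions)[1]),
      value = "sd_after_hz", paired = paired)
  )
  for (rn in names(resolutions)) {
    stats[[paste0("coverage_", rn)]] <- anova_bonferroni(
      dplyr::filter(results, .data$resolution == rn),
      value = "coverage_pct", paired = paired)
  }
  study <- structure(list(results = results, summary = summary,
                          stats = stats,
                          config = list(n = length(subjects),
                                        master_seed = master_seed,
                                        methods = methods$method,
                                        resolutions = resolutions)),
                     class = "shim_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(out_dir, "cohort_results.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    write.csv(cohort_table(summary),
              file.path(out_dir, "coverage_table.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(stats, function(s) list(
        f_statistic = s$f_statistic, p_value = s$p_value,
        pairwise = s$pairwise)),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  study
}

#' @export
print.shim_study <- function(x, ...) {
  cat("<shim_study> ", x$config$n, " subjects, ",
      length(x$config$methods), " methods\n", sep = "")
  print(x$summary)
  invisible(x)
}
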