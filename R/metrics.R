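# Integral aerodynamic measures, cross-sectional-area profiles, WSS
# surface histograms, cohort summaries and the average-geometry-versus-
# individuals comparison report.

triangle_areas <- function(g) {
  s <- as_surface(g)
  A <- s$vertices[s$triangles[, 1], , drop = FALSE]
  B <- s$vertices[s$triangles[, 2], , drop = FALSE]
  C <- s$vertices[s$triangles[, 3], , drop = FALSE]
  e1 <- B - A
  e2 <- C - A
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Station volume weights A_i * dl_i (trapezoidal node weights) for one side.
station_volume_weights <- function(profile) {
  arc <- profile$arc_mm
  S <- length(arc)
  dl <- numeric(S)
  dl[1] <- (arc[2] - arc[1]) / 2
  dl[S] <- (arc[S] - arc[S - 1]) / 2
  if (S > 2) dl[2:(S - 1)] <- (arc[3:S] - arc[1:(S - 2)]) / 2
  profile$area_mm2 * dl
}

#' Integral aerodynamic measures of one solved geometry
#'
#' Volume-averaged and 99.9th-percentile station velocity (volume-weighted
#' empirical CDF with linear interpolation), area-weighted mean and
#' 99.9th-percentile wall shear stress over wall triangles (triangle value
#' = mean of its vertices), plus resistances and airflow partitioning from
#' the flow solution.  Maxima are reported alongside the percentiles.
#'
#' @param g A `duct_geometry`.
#' @param solution A `flow_solution` with wall fields attached (see
#'   [simulate_phases()] or [wall_fields()]).
#' @return A one-row data.frame of class `integral_measures` with columns
#'   `phase`, `R_left`, `R_right`, `R_total` (Pa·s/ml), `AP_pct`,
#'   `u_avg`, `u_p999`, `u_max` (m/s), `wss_avg`, `wss_p999`, `wss_max`
#'   (Pa).
#' @export
integral_measures <- function(g, solution) {
  if (is.null(solution$wall))
    stop("solution carries no wall fields; run wall_fields() first")
  u <- c(solution$u_stations_ms$left, solution$u_stations_ms$right)
  w <- c(station_volume_weights(g$profiles$left),
         station_volume_weights(g$profiles$right))
  u_avg <- sum(u * w) / sum(w)
  u_p999 <- weighted_quantile(u, w, 0.999)

  tri_wss <- rowMeans(matrix(solution$wall$wss_pa[g$triangles],
                             ncol = 3))
  areas <- triangle_areas(g)
  wss_avg <- sum(tri_wss * areas) / sum(areas)
  wss_p999 <- weighted_quantile(tri_wss, areas, 0.999)

  out <- data.frame(
    phase = solution$direction,
    R_left = solution$R_left, R_right = solution$R_right,
    R_total = solution$R_total, AP_pct = solution$AP_pct,
    u_avg = u_avg, u_p999 = u_p999, u_max = max(u),
    wss_avg = wss_avg, wss_p999 = wss_p999, wss_max = max(tri_wss),
    stringsAsFactors = FALSE)
  class(out) <- c("integral_measures", class(out))
  out
}

#' Cross-sectional area profile on the 5% grid
#'
#' Samples each side's area profile at 5% increments of the normalised
#' nostril-to-choana distance by linear interpolation of the station areas;
#' the minimal cross-sectional area is taken over the full station grid,
#' not only the 5% grid.
#'
#' @param g A `duct_geometry`.
#' @return A list with `table` (data.frame side, s, area_mm2) and `min_csa`
#'   (data.frame side, area_mm2, s).
#' @export
csa_profile <- function(g) {
  s_grid <- seq(0, 1, by = 0.05)
  tabs <- lapply(c("left", "right"), function(side) {
    p <- g$profiles[[side]]
    data.frame(side = side, s = s_grid,
               area_mm2 = stats::approx(p$s, p$area_mm2, xout = s_grid)$y)
  })
  mins <- lapply(c("left", "right"), function(side) {
    p <- g$profiles[[side]]
    i <- which.min(p$area_mm2)
    data.frame(side = side, area_mm2 = p$area_mm2[i], s = p$s[i])
  })
  structure(list(table = do.call(rbind, tabs),
                 min_csa = do.call(rbind, mins)),
            class = "csa_profile")
}

#' Wall-shear-stress surface histogram
#'
#' Assigns each wall triangle to the bin of its mean-vertex WSS
#' (right-closed bins, the first bin covering (0, 0.01] Pa by default) and
#' reports the percentage of total wall surface area per bin.
#'
#' @param field A `wall_field` (or numeric vector) of WSS on `g`.
#' @param g A `duct_geometry` (or any surface with triangles).
#' @param bin_edges Increasing bin edges in Pa; the default spans
#'   `(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, Inf]`.
#' @return A data.frame with `bin_lo`, `bin_hi`, `area_pct`; for strictly
#'   positive fields the fractions sum to 100.
#' @export
wss_histogram <- function(field, g,
                          bin_edges = c(0, 0.01, 0.02, 0.05, 0.1, 0.2,
                                        0.5, Inf)) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  s <- as_surface(g)
  vals <- field_values(field)
  if (length(vals) != nrow(s$vertices))
    stop("field length does not match vertex count")
  tri_vals <- rowMeans(matrix(vals[s$triangles], ncol = 3))
  areas <- triangle_areas(s)
  bin <- cut(tri_vals, bin_edges, right = TRUE)
  pct <- 100 * vapply(levels(bin), function(l)
    sum(areas[!is.na(bin) & bin == l]), numeric(1)) / sum(areas)
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1],
             area_pct = unname(pct))
}

measure_columns <- function() {
  c("R_left", "R_right", "R_total", "AP_pct",
    "u_avg", "u_p999", "u_max", "wss_avg", "wss_p999", "wss_max")
}

#' Cohort summary of integral measures
#'
#' Mean, median and sample SD per measure and phase over the subjects,
#' Tukey boxplot statistics (quartiles, 1.5 IQR whiskers clipped to the
#' data), and the position of the average geometry's value within the
#' cohort distribution (below/above the median, inside/outside the IQR).
#'
#' @param measures A data.frame of per-subject [integral_measures()] rows
#'   (stacked; a `phase` column distinguishes phases).
#' @param avg_measures The average geometry's [integral_measures()] rows
#'   for the same phases.
#' @return A data.frame of class `corpus_summary`, one row per
#'   phase-measure combination.
#' @export
corpus_summary <- function(measures, avg_measures) {
  if (nrow(measures) < 2) stop("need at least two subjects")
  phases <- unique(measures$phase)
  if (!setequal(phases, unique(avg_measures$phase)))
    stop("phase mismatch between cohort and average-geometry measures")
  rows <- list()
  for (ph in phases) {
    sub <- measures[measures$phase == ph, , drop = FALSE]
    avg <- avg_measures[avg_measures$phase == ph, , drop = FALSE]
    for (mcol in intersect(measure_columns(), names(sub))) {
      x <- sub[[mcol]]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      lo_w <- min(x[x >= q[1] - 1.5 * iqr])
      hi_w <- max(x[x <= q[3] + 1.5 * iqr])
      av <- avg[[mcol]][1]
      rows[[length(rows) + 1]] <- data.frame(
        phase = ph, measure = mcol,
        mean = mean(x), median = q[2], sd = stats::sd(x),
        q1 = q[1], q3 = q[3], whisker_lo = lo_w, whisker_hi = hi_w,
        avg_geometry = av,
        below_median = av < q[2],
        within_iqr = av >= q[1] & av <= q[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("corpus_summary", class(out))
  out
}

#' Expiration-over-inspiration resistance increase
#'
#' Per-subject percentage increase of the expiratory over the inspiratory
#' total resistance, `(R_exp / R_insp - 1) * 100`, computed from unrounded
#' resistances.  Both the mean and the median of the per-subject ratios
#' are reported (the two plausible cohort conventions), along with the
#' ratio of cohort means.
#'
#' @param R_insp,R_exp Vectors of per-subject total resistances (Pa·s/ml).
#' @return A list: `per_subject_pct`, `mean_of_ratios_pct`,
#'   `median_of_ratios_pct`, `ratio_of_means_pct`.
#' @export
expiration_ratio <- function(R_insp, R_exp) {
  stopifnot(length(R_insp) == length(R_exp))
  if (any(R_insp <= 0)) stop("inspiration resistances must be positive")
  r <- (R_exp / R_insp - 1) * 100
  list(per_subject_pct = r,
       mean_of_ratios_pct = mean(r),
       median_of_ratios_pct = stats::median(r),
       ratio_of_means_pct = (mean(R_exp) / mean(R_insp) - 1) * 100)
}

#' Report-table rounding conventions
#'
#' Rounds a summary or measure table to the reporting precision: 3
#' decimals for resistances, 2 for velocities and wall shear stresses,
#' 1 for airflow partitioning percentages.
#'
#' @param x A data.frame with measure columns (or a `corpus_summary`).
#' @return The rounded data.frame.
#' @export
round_for_report <- function(x) {
  digits_for <- function(m) {
    if (grepl("^R_", m)) 3L
    else if (grepl("^AP", m)) 1L
    else 2L
  }
  if ("measure" %in% names(x)) {
    num <- vapply(x, is.numeric, logical(1))
    for (i in seq_len(nrow(x)))
      x[i, num] <- round(x[i, num], digits_for(x$measure[i]))
  } else {
    for (m in intersect(measure_columns(), names(x)))
      x[[m]] <- round(x[[m]], digits_for(m))
  }
  x
}

#' Average-geometry-versus-cohort comparison report
#'
#' Assembles the full comparison between the average geometry and the
#' individual geometries: a cohort summary table, cross-sectional-area
#' boxplot data per 5% increment with the average-geometry curve,
#' vertex-wise statistics of mapped wall fields against the average
#' geometry's own fields, WSS surface-area histograms, and a JSON verdict
#' block placing the average geometry within the cohort distribution per
#' measure.
#'
#' @param cohort A list with components `measures` (stacked per-subject
#'   [integral_measures()]), `avg_measures`, `csa_list` (per-subject
#'   [csa_profile()]s), `avg_csa`, `stats` (named list of
#'   [vertexwise_stats()] per field/phase), `avg_fields` (matching named
#'   list of average-geometry vertex fields), `histograms` (per-subject
#'   list of per-phase WSS histograms), `avg_histograms`, and optionally
#'   `config`.
#' @param out_dir Output directory for the report bundle (created if
#'   needed).
#' @return The verdict structure, invisibly; files `table1.csv`,
#'   `csa_profile.csv`, `histograms.csv`, `vertex_stats.csv`,
#'   `verdict.json` and `schema.md` are written to `out_dir`.
#' @export
comparison_report <- function(cohort, out_dir) {
  required <- c("measures", "avg_measures", "csa_list", "avg_csa",
                "stats", "avg_fields", "histograms", "avg_histograms")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0)
    stop("comparison_report inputs incomplete; missing: ",
         paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summ <- corpus_summary(cohort$measures, cohort$avg_measures)
  utils::write.csv(round_for_report(summ),
                   file.path(out_dir, "table1.csv"), row.names = FALSE)

  # CSA boxplot data per 5% increment (pooled over sides, as for a
  # bilateral cohort) plus the average-geometry curve.
  csa_all <- do.call(rbind, lapply(seq_along(cohort$csa_list), function(i) {
    tb <- cohort$csa_list[[i]]$table
    tb$subject <- i
    tb
  }))
  s_grid <- sort(unique(csa_all$s))
  csa_rows <- lapply(s_grid, function(sv) {
    x <- csa_all$area_mm2[csa_all$s == sv]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    avg_x <- mean(cohort$avg_csa$table$area_mm2[cohort$avg_csa$table$s == sv])
    data.frame(s = sv, q1 = q[1], median = q[2], q3 = q[3],
               min = min(x), max = max(x), avg_geometry = avg_x)
  })
  utils::write.csv(do.call(rbind, csa_rows),
                   file.path(out_dir, "csa_profile.csv"), row.names = FALSE)

  # Vertex-wise stats vs. the average geometry's own field.
  vs_rows <- lapply(names(cohort$stats), function(key) {
    st <- cohort$stats[[key]]
    av <- cohort$avg_fields[[key]]
    if (is.null(av))
      stop("comparison_report inputs incomplete; missing avg_fields[['",
           key, "']]")
    data.frame(field = key, vertex_id = seq_along(st$mean),
               mean = st$mean, median = st$median, sd = st$sd,
               cov = st$cov, masked = st$cov_mask,
               avg_geometry = av, diff_mean = av - st$mean)
  })
  vs <- do.call(rbind, vs_rows)
  utils::write.csv(vs, file.path(out_dir, "vertex_stats.csv"),
                   row.names = FALSE)

  # WSS histograms: cohort quartiles per bin plus the average geometry.
  hist_rows <- list()
  for (ph in names(cohort$avg_histograms)) {
    per_subj <- lapply(cohort$histograms, function(h) h[[ph]])
    bins <- per_subj[[1]][, c("bin_lo", "bin_hi")]
    for (bidx in seq_len(nrow(bins))) {
      x <- vapply(per_subj, function(h) h$area_pct[bidx], numeric(1))
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      hist_rows[[length(hist_rows) + 1]] <- data.frame(
        phase = ph, bin_lo = bins$bin_lo[bidx], bin_hi = bins$bin_hi[bidx],
        q1 = q[1], median = q[2], q3 = q[3],
        avg_geometry = cohort$avg_histograms[[ph]]$area_pct[bidx])
    }
  }
  utils::write.csv(do.call(rbind, hist_rows),
                   file.path(out_dir, "histograms.csv"), row.names = FALSE)

  verdict <- list(
    n_subjects = sum(cohort$measures$phase == cohort$measures$phase[1]),
    measures = lapply(seq_len(nrow(summ)), function(i) {
      list(phase = summ$phase[i], measure = summ$measure[i],
           avg_geometry = summ$avg_geometry[i],
           cohort_mean = summ$mean[i], cohort_median = summ$median[i],
           q1 = summ$q1[i], q3 = summ$q3[i],
           below_median = summ$below_median[i],
           within_iqr = summ$within_iqr[i])
    }),
    vertex_fields = lapply(names(cohort$stats), function(key) {
      st <- cohort$stats[[key]]
      av <- cohort$avg_fields[[key]]
      list(field = key,
           max_abs_diff_mean = max(abs(av - st$mean)),
           rms_diff_mean = sqrt(mean((av - st$mean)^2)))
    }),
    extras = cohort$extras %||% NULL,
    config = cohort$config %||% NULL)
  jsonlite::write_json(verdict, file.path(out_dir, "verdict.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  writeLines(c(
    "# Report bundle schema",
    "",
    "- table1.csv: phase, measure, mean, median, sd, q1, q3, whisker_lo,",
    "  whisker_hi, avg_geometry, below_median, within_iqr.  Resistances in",
    "  Pa.s/ml (3 decimals), velocities m/s and WSS Pa (2 decimals),",
    "  airflow partitioning % (1 decimal).",
    "- csa_profile.csv: s (normalised nostril->choana distance, 5% grid),",
    "  cohort quartiles/min/max of cross-sectional area (mm2) over all",
    "  cavities, avg_geometry curve.",
    "- vertex_stats.csv: per field/phase and vertex: cohort mean, median,",
    "  sd, cov (NA where masked), the average geometry's own value and the",
    "  difference to the cohort mean.",
    "- histograms.csv: per phase and WSS bin (Pa): cohort quartiles of the",
    "  surface-area percentage and the average geometry's value.",
    "- verdict.json: per-measure position of the average geometry within",
    "  the cohort distribution; vertex-field difference summaries."),
    file.path(out_dir, "schema.md"))
  invisible(verdict)
}
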