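# End-to-end pipeline: corpus -> mirror augmentation -> shape model ->
# average geometry -> flow simulation of all members and the average ->
# field mapping -> vertex statistics -> comparison report.

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full averaging-study pipeline
#'
#' Generates a synthetic corpus, mirror-augments it, fits the statistical
#' shape model, extracts the average geometry, solves inspiration and
#' expiration for every original member and the average geometry, maps the
#' wall fields onto the average geometry's triangulation, computes
#' vertex-wise statistics and integral measures, and writes the comparison
#' report bundle.  Fully reproducible from `(config, seed)`; the resolved
#' configuration is echoed into the bundle.
#'
#' @param config A `noseflow_config` (see [default_config()],
#'   [read_config()]).
#' @param out_dir Report bundle directory.
#' @param verbose Emit stage messages?
#' @return A list with the fitted `model`, `mean_geometry`, per-subject
#'   `measures`, the average geometry's `avg_measures`, the
#'   `expiration_ratio` list, the `verdict` structure and `out_dir`.
#' @export
pipeline_run <- function(config = default_config(),
                         out_dir = file.path(tempdir(), "noseflow_report"),
                         verbose = TRUE) {
  say <- if (verbose) stage_msg else function(...) invisible(NULL)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("config", "resolving configuration (seed ", config$corpus$seed, ")")
  template <- run_stage("template", do.call(duct_template, config$template))
  spec <- run_stage("variation", do.call(shape_variation,
                                         c(config$variation,
                                           list(seed = config$corpus$seed))))

  say("corpus", "generating ", config$corpus$n_subjects, " subjects")
  corpus <- run_stage("corpus",
                      generate_corpus(template, spec,
                                      config$corpus$n_subjects))
  augmented <- run_stage("augment", mirror_augment(corpus))

  say("ssm", "fitting shape model on ", length(augmented$members),
      " shapes")
  model <- run_stage("ssm", nasal_ssm(augmented))
  mean_geom <- run_stage("mean_shape", mean_shape(model))

  fluid <- do.call(fluid_properties, config$fluid)
  flow <- config$phase$flow_mls
  say("flow", "simulating both phases at ", flow, " ml/s (losses ",
      if (config$losses) "on" else "off", ")")
  sims <- run_stage("flow", lapply(corpus$members, simulate_phases,
                                   fluid = fluid, flow_mls = flow,
                                   losses = config$losses))
  avg_sim <- run_stage("flow", simulate_phases(mean_geom, fluid, flow,
                                               config$losses))

  say("metrics", "integral measures and profiles")
  measures <- run_stage("metrics", do.call(rbind, lapply(
    seq_along(sims), function(i) {
      m <- rbind(integral_measures(corpus$members[[i]],
                                   sims[[i]]$inspiration),
                 integral_measures(corpus$members[[i]],
                                   sims[[i]]$expiration))
      cbind(subject = i, m)
    })))
  avg_measures <- run_stage("metrics", rbind(
    integral_measures(mean_geom, avg_sim$inspiration),
    integral_measures(mean_geom, avg_sim$expiration)))
  csa_list <- lapply(corpus$members, csa_profile)
  avg_csa <- csa_profile(mean_geom)

  edges <- config$histogram$bin_edges
  histograms <- lapply(seq_along(sims), function(i) {
    lapply(sims[[i]], function(sol)
      wss_histogram(sol$wall$wss_pa, corpus$members[[i]], edges))
  })
  avg_histograms <- lapply(avg_sim, function(sol)
    wss_histogram(sol$wall$wss_pa, mean_geom, edges))

  say("mapping", "mapping wall fields onto the average geometry")
  field_keys <- expand.grid(field = c("wss", "pressure"),
                            phase = c("inspiration", "expiration"),
                            stringsAsFactors = FALSE)
  stats <- list()
  avg_fields <- list()
  for (r in seq_len(nrow(field_keys))) {
    fn <- field_keys$field[r]
    ph <- field_keys$phase[r]
    key <- paste(fn, ph, sep = "_")
    col <- if (fn == "wss") "wss_pa" else "wall_pressure_pa"
    mapped <- lapply(seq_along(sims), function(i)
      map_field_nearest(sims[[i]][[ph]]$wall[[col]],
                        corpus$members[[i]], mean_geom))
    eps <- if (fn == "wss") config$mapping$eps_wss_pa
           else config$mapping$eps_pressure_pa
    stats[[key]] <- run_stage("stats", vertexwise_stats(mapped, eps))
    avg_fields[[key]] <- avg_sim[[ph]]$wall[[col]]
  }

  exp_ratio <- expiration_ratio(
    measures$R_total[measures$phase == "inspiration"],
    measures$R_total[measures$phase == "expiration"])
  avg_ratio <- expiration_ratio(
    avg_measures$R_total[avg_measures$phase == "inspiration"],
    avg_measures$R_total[avg_measures$phase == "expiration"])

  say("report", "writing bundle to ", out_dir)
  verdict <- run_stage("report", comparison_report(
    list(measures = measures, avg_measures = avg_measures,
         csa_list = csa_list, avg_csa = avg_csa,
         stats = stats, avg_fields = avg_fields,
         histograms = histograms, avg_histograms = avg_histograms,
         extras = list(
           expiration_ratio_cohort_mean_pct = exp_ratio$mean_of_ratios_pct,
           expiration_ratio_cohort_median_pct =
             exp_ratio$median_of_ratios_pct,
           expiration_ratio_avg_geometry_pct =
             avg_ratio$mean_of_ratios_pct),
         config = unclass(config)),
    out_dir))
  write_config_echo(config, file.path(out_dir, "config.yaml"))

  invisible(list(model = model, mean_geometry = mean_geom,
                 corpus = corpus, simulations = sims,
                 avg_simulation = avg_sim,
                 measures = measures, avg_measures = avg_measures,
                 expiration_ratio = exp_ratio,
                 avg_expiration_ratio = avg_ratio,
                 verdict = verdict, out_dir = out_dir))
}
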