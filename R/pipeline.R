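# End-to-end pipeline --------------------------------------------------------
#
# cohort generation -> morphometrics -> per-case 2D reduction -> rigid +
# compliant protocol runs -> indicator battery at several cut heights ->
# relative changes -> cohort statistics -> artifacts + reproducibility
# manifest.  All randomness flows from the single master seed through the
# documented splitting rule; artifacts are plain CSV/JSON/VTK so a rerun with
# the same config reproduces identical digests.

#' Default pipeline configuration
#'
#' @param seed master seed
#' @param n_cases cohort size
#' @param output_dir artifact directory
#' @param cut_heights sac cut heights (mm) for the sensitivity re-test
#' @param protocol list of [protocol_config()] overrides (e.g. dt)
#' @param coupling list of [coupling_config()] overrides
#' @param case2d list of [make_case_2d()] resolution overrides
#' @param stages character subset of
#'   c("cohort", "mount", "simulate", "indicators", "stats")
#' @return nested configuration list
#' @export
pipeline_config <- function(seed = 1, n_cases = 2, output_dir = tempfile("sacflow_"),
                            cut_heights = c(7.9, 8, 8.1),
                            protocol = list(), coupling = list(),
                            case2d = list(),
                            stages = c("cohort", "mount", "simulate",
                                       "indicators", "stats")) {
  list(seed = seed, n_cases = n_cases, output_dir = output_dir,
       cut_heights = cut_heights, protocol = protocol, coupling = coupling,
       case2d = case2d, stages = stages)
}

validate_config <- function(cfg) {
  need <- c("seed", "n_cases", "output_dir", "cut_heights", "stages")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    abort_sf(paste("config missing fields:", paste(miss, collapse = ", ")),
             "sacflow_config_error")
  if (!is.numeric(cfg$seed) || !is.numeric(cfg$n_cases) || cfg$n_cases < 1)
    abort_sf("config: seed numeric and n_cases >= 1 required",
             "sacflow_config_error")
  bad <- setdiff(cfg$stages, c("cohort", "mount", "simulate", "indicators",
                               "stats"))
  if (length(bad))
    abort_sf(paste("unknown stages:", paste(bad, collapse = ", ")),
             "sacflow_config_error")
  invisible(cfg)
}

# 2D reduction of a 3D bulge: dome circle radius from the volume-equivalent
# diameter, neck width from the realized neck ring, clipped for mesh sanity
case2d_from_bulge <- function(bulge, case_args = list()) {
  d <- compute_descriptors(bulge)
  ring <- bulge$vertices[bulge$neck_ring, , drop = FALSE]
  per <- sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
  neck_d <- per / pi
  sac_r <- min(max(d$D_eq / 2, 1.2), 2.6)
  neck_w <- min(max(neck_d, 1.0), 2.4, 1.8 * sac_r)
  do.call(make_case_2d, c(list(sac_radius_mm = sac_r,
                               neck_width_mm = neck_w), case_args))
}

#' Run the full desk-scale pipeline
#'
#' @param config [pipeline_config()] list
#' @param quiet suppress progress messages
#' @return `run_manifest`: per-stage timing, artifact digests, cohort table,
#'   statistics report
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[["elapsed"]]
  stage_time <- c()
  artifacts <- character()
  note <- function(...) if (!quiet) message(sprintf(...))

  seeds <- split_seed(config$seed, max(config$n_cases, 1))
  cohort <- NULL; desc <- NULL
  if ("cohort" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    cohort <- generate_cohort(config$n_cases, seed = config$seed)
    desc <- cohort_descriptors(cohort)
    f <- file.path(config$output_dir, "descriptors.csv")
    write.csv(desc, f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    stage_time["cohort"] <- proc.time()[["elapsed"]] - t0
    note("cohort: %d cases", config$n_cases)
  }

  cases <- NULL
  if ("mount" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    # 3D mount audit on case 1 (the 2D reduction uses descriptors only)
    artery <- make_artery()
    m1 <- mount_bulge(cohort[[1]]$mesh, artery)
    f <- file.path(config$output_dir, "case1_mounted.stl")
    write_stl(m1$surface, f)
    artifacts <- c(artifacts, f)
    cases <- lapply(cohort, function(cs)
      case2d_from_bulge(cs$mesh, config$case2d))
    stage_time["mount"] <- proc.time()[["elapsed"]] - t0
    note("mount: 3D stitch audit ok (chi = %d), %d 2D cases",
         m1$report$euler, length(cases))
  }

  runs <- list()
  if ("simulate" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    wf <- build_waveform()
    ccfg <- do.call(coupling_config, config$coupling)
    for (i in seq_along(cases)) {
      pr_r <- do.call(protocol_config, c(list(mode = "rigid"), config$protocol))
      pr_c <- do.call(protocol_config, c(list(mode = "compliant"),
                                         config$protocol))
      note("case %d rigid ...", i)
      fr <- run_protocol(cases[[i]], pr_r, wf, ccfg, quiet = quiet)
      note("case %d compliant ...", i)
      fc <- run_protocol(cases[[i]], pr_c, wf, ccfg, quiet = quiet)
      runs[[i]] <- list(rigid = fr, compliant = fc)
      for (mode in c("rigid", "compliant")) {
        f <- file.path(config$output_dir,
                       sprintf("case%d_%s_history.csv", i, mode))
        write.csv(runs[[i]][[mode]]$hist, f, row.names = FALSE)
        artifacts <- c(artifacts, f)
      }
    }
    stage_time["simulate"] <- proc.time()[["elapsed"]] - t0
  }

  table_long <- NULL; deltas <- NULL
  if ("indicators" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    rows <- list(); drows <- list()
    for (i in seq_along(runs)) {
      for (h in config$cut_heights) {
        ir <- compute_flow_indicators(runs[[i]]$rigid, cut_height_mm = h)
        ic <- compute_flow_indicators(runs[[i]]$compliant, cut_height_mm = h)
        for (nm in names(ir))
          rows[[length(rows) + 1]] <- data.frame(
            case = i, cut_height = h, indicator = nm,
            rigid = ir[[nm]], compliant = ic[[nm]])
        if (abs(h - 8) < 1e-9) {
          dr <- relative_change(ir, ic)
          drows[[i]] <- data.frame(case = i, t(unclass(dr)))
        }
      }
    }
    table_long <- do.call(rbind, rows)
    deltas <- do.call(rbind, drows)
    f1 <- file.path(config$output_dir, "indicators.csv")
    f2 <- file.path(config$output_dir, "deltas.csv")
    write.csv(table_long, f1, row.names = FALSE)
    write.csv(deltas, f2, row.names = FALSE)
    artifacts <- c(artifacts, f1, f2)
    stage_time["indicators"] <- proc.time()[["elapsed"]] - t0
  }

  stats_rep <- NULL
  if ("stats" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    if (length(runs) < 5) {
      warning("fewer than 5 cases: signed-rank tests are degenerate-flagged")
    }
    sens <- tryCatch(sensitivity_rerun(table_long), error = function(e) NULL)
    tests <- lapply(split(table_long[abs(table_long$cut_height - 8) < 1e-9, ],
                          table_long$indicator[abs(table_long$cut_height - 8) < 1e-9]),
                    function(sub) signed_rank_test(sub$compliant, sub$rigid))
    stats_rep <- list(
      tests = lapply(tests, function(t_) t_[c("statistic", "p", "degenerate")]),
      sensitivity = if (!is.null(sens)) sens$report)
    f <- file.path(config$output_dir, "stats.json")
    jsonlite::write_json(stats_rep, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <- c(artifacts, f)
    stage_time["stats"] <- proc.time()[["elapsed"]] - t0
  }

  digests <- tools::md5sum(artifacts)
  manifest <- list(config = config, seeds = seeds,
                   stage_seconds = as.list(stage_time),
                   total_seconds = proc.time()[["elapsed"]] - t_all,
                   artifacts = as.list(digests),
                   r_version = R.version.string)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  structure(list(manifest = manifest, cohort_table = table_long,
                 deltas = deltas, stats = stats_rep, runs = runs,
                 descriptors = desc),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("sacflow pipeline run\n")
  for (nm in names(x$manifest$stage_seconds))
    cat(sprintf("  %-11s %7.1f s\n", nm, x$manifest$stage_seconds[[nm]]))
  cat(sprintf("  artifacts: %d files in %s\n",
              length(x$manifest$artifacts), x$manifest$config$output_dir))
  invisible(x)
}
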