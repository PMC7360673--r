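#' End-to-end analysis pipeline
#'
#' `validate_config()` turns a YAML/JSON/list run configuration into a fully
#' defaulted, validated `plv_run_config`; `run_pipeline()` executes
#' simulate/load -> preprocess -> connectivity -> inference -> report as a
#' reproducible, seeded run. Each analysis (seed-based CBPT, RSN tests,
#' clinical table) can be enabled independently.
#'
#' @name pipeline
NULL

config_defaults <- function() {
  list(rng_seed = 1L,
       cohort = NULL,
       simulate = NULL,
       bands = list(alpha_mu = c(8, 13), low_beta = c(12, 20),
                    upper_beta = c(20, 30)),
       analyses = NULL,          # resolved in validate_config
       seeds = NULL,
       rsns = NULL,
       pair_policy = "all_pairs",
       pad = 2,
       max_epochs = Inf,
       cbpt = list(cluster_forming_alpha = 0.05, n_permutations = 5000,
                   t_variant = "pooled", null_statistic = "max_abs_mass",
                   min_relabelings = 100),
       clinical = NULL,          # list(tsv, types) or NULL -> simulated
       out_dir = NULL)
}

#' Validate a run configuration
#'
#' Accepts a YAML or JSON file path, or a named list. Unknown keys are
#' rejected and all schema violations are reported together.
#'
#' @param config path or named list.
#' @return a fully defaulted `plv_run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  errs <- character(0)
  note <- function(msg) errs[[length(errs) + 1]] <<- msg

  defs <- config_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    note(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defs, config[setdiff(names(config), unknown)],
                    keep.null = TRUE)
  # container keys replace the defaults wholesale (modifyList would merge
  # e.g. a user band list into the default three-band set)
  for (key in c("bands", "seeds", "rsns", "analyses", "simulate", "clinical"))
    if (key %in% names(config)) cfg[[key]] <- config[[key]]

  if (!is.null(cfg$cohort) && !dir.exists(cfg$cohort))
    note(sprintf("cohort directory does not exist: %s", cfg$cohort))
  if (is.null(cfg$cohort) && is.null(cfg$simulate))
    cfg$simulate <- list()   # simulate with full defaults

  bands <- list()
  for (bn in names(cfg$bands)) {
    b <- unlist(cfg$bands[[bn]])
    if (length(b) != 2 || !is.numeric(b) || b[1] <= 0 || b[2] <= b[1])
      note(sprintf("band '%s': need numeric edges 0 < lo < hi", bn))
    else bands[[bn]] <- band_spec(bn, b[1], b[2])
  }
  cfg$bands <- bands

  if (!is.null(cfg$cbpt)) {
    unknown_c <- setdiff(names(cfg$cbpt),
                         c("cluster_forming_alpha", "n_permutations",
                           "t_variant", "null_statistic", "rng_seed",
                           "min_relabelings"))
    if (length(unknown_c))
      note(paste("unknown cbpt key(s):", paste(unknown_c, collapse = ", ")))
    np <- cfg$cbpt$n_permutations
    if (!is.null(np) && !identical(np, "exhaustive") && np < 100)
      note(sprintf("cbpt n_permutations = %s below the >= 100 floor", np))
    a <- cfg$cbpt$cluster_forming_alpha
    if (!is.null(a) && !(a > 0 && a < 1))
      note("cbpt cluster_forming_alpha must lie in (0, 1)")
  }
  if (!cfg$pair_policy %in% c("all_pairs", "between_spheres"))
    note("pair_policy must be all_pairs or between_spheres")

  enabled <- cfg$analyses
  if (is.null(enabled)) {
    enabled <- "clinical"
    if (!is.null(cfg$seeds)) enabled <- c("seed", enabled)
    if (!is.null(cfg$rsns)) enabled <- c("rsn", enabled)
  }
  bad_an <- setdiff(enabled, c("seed", "rsn", "clinical"))
  if (length(bad_an))
    note(paste("unknown analysis:", paste(bad_an, collapse = ", ")))
  if (length(enabled) == 0)
    note("no analyses enabled: need at least one of seed, rsn, clinical")
  if ("seed" %in% enabled && is.null(cfg$seeds))
    note("seed analysis enabled but no seeds defined")
  if ("rsn" %in% enabled && is.null(cfg$rsns))
    note("rsn analysis enabled but no RSNs defined")
  cfg$analyses <- enabled

  if (!is.null(cfg$clinical) && !is.null(cfg$clinical$tsv)) {
    if (!file.exists(cfg$clinical$tsv))
      note(sprintf("clinical table not found: %s", cfg$clinical$tsv))
    if (is.null(cfg$clinical$types) || !file.exists(cfg$clinical$types))
      note("clinical table needs an existing JSON typing sidecar ('types')")
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  class(cfg) <- "plv_run_config"
  cfg
}

# Build the cohort stage: either load a written cohort directory or simulate.
stage_cohort <- function(cfg) {
  if (!is.null(cfg$cohort)) {
    man <- read.delim(file.path(cfg$cohort, "manifest.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
    spec <- readRDS(file.path(cfg$cohort, "spec.rds"))
    return(structure(list(spec = spec, manifest = man, truth = NULL,
                          dir = cfg$cohort), class = "plv_cohort"))
  }
  sim <- cfg$simulate
  args <- list()
  direct <- intersect(names(sim),
                      c("n_robust", "n_frail", "fs", "epoch_len",
                        "epochs_min", "epochs_fixed", "sigma_obs", "walk_sd",
                        "jitter_hold", "rng_seed", "base_coupling",
                        "band_assignment"))
  args[direct] <- sim[direct]
  if (is.null(args$rng_seed)) args$rng_seed <- child_seed(cfg$rng_seed, 1)
  if (!is.null(sim$grid))
    args$grid <- build_regular_grid(unlist(sim$grid$lower),
                                    unlist(sim$grid$upper),
                                    spacing = sim$grid$spacing %||% 10)
  grid <- args$grid %||% cohort_spec()$grid
  if (!is.null(sim$effect)) {
    ef <- sim$effect
    band <- cfg$bands[[ef$band %||% "upper_beta"]]
    args$effect <- effect_spec(
      seed_roi(ef$seed_name %||% "effect_seed", unlist(ef$seed_indices),
               grid = grid),
      unlist(ef$target_indices), band = band,
      rho_robust = ef$rho_robust %||% 0.5,
      delta_rho = ef$delta_rho %||% 0.15)
  }
  args$bands <- cfg$bands
  simulate_cohort(do.call(cohort_spec, args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_seeds <- function(cfg, grid) {
  lapply(cfg$seeds, function(s) {
    if (!is.null(s$source_indices))
      seed_roi(s$name, unlist(s$source_indices),
               laterality = s$laterality %||% "bilateral", grid = grid)
    else if (!is.null(s$center))
      seed_roi(s$name,
               sources_in_sphere(grid, unlist(s$center), s$radius %||% 15),
               laterality = s$laterality %||% "bilateral", grid = grid)
    else stop(sprintf("seed '%s' needs source_indices or center", s$name))
  })
}

resolve_rsns <- function(cfg, grid) {
  if (is.character(cfg$rsns))
    return(Filter(function(x) inherits(x, "plv_rsn"),
                  read_roi_definitions(cfg$rsns, grid)))
  lapply(cfg$rsns, function(r)
    build_rsn(grid, r$name, lapply(r$centers, unlist),
              radius = r$radius %||% 15))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate/load, band filtering and
#' phase extraction, connectivity reduction, group inference, clinical
#' summary) and assembles a run report. Identical config + seed give a
#' bit-identical report. Connectivity is computed streaming: one subject in
#' memory at a time, and only the PLV rows the enabled analyses need.
#'
#' @param config a `plv_run_config` (or anything [validate_config()]
#'   accepts).
#' @return object of class `plv_run_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "plv_run_config")) config <- validate_config(config)
  t0 <- Sys.time()
  log <- character(0)
  say <- function(fmt, ...) log[[length(log) + 1]] <<- sprintf(fmt, ...)

  cohort <- tryCatch(stage_cohort(config),
                     error = function(e) stop_stage("cohort", conditionMessage(e)))
  spec <- cohort$spec
  grid <- spec$grid
  say("cohort: %d subjects on %d sources", nrow(cohort$manifest),
      grid$n_sources)

  seeds <- rsns <- list()
  need_conn <- any(c("seed", "rsn") %in% config$analyses)
  if ("seed" %in% config$analyses)
    seeds <- tryCatch(resolve_seeds(config, grid),
                      error = function(e) stop_stage("seeds", conditionMessage(e)))
  if ("rsn" %in% config$analyses)
    rsns <- tryCatch(resolve_rsns(config, grid),
                     error = function(e) stop_stage("rsns", conditionMessage(e)))

  seed_res <- rsn_res <- NULL
  if (need_conn) {
    rows_needed <- sort(unique(c(
      unlist(lapply(seeds, `[[`, "source_indices")),
      unlist(lapply(rsns, `[[`, "source_indices")))))
    n_sub <- nrow(cohort$manifest)
    firs <- lapply(config$bands, design_bandpass_fir, fs = spec$fs)
    plv_store <- lapply(config$bands, function(b)
      array(NA_real_, c(n_sub, length(rows_needed), grid$n_sources)))
    conn <- tryCatch({
      for (k in seq_len(n_sub)) {
        sub <- cohort_subject(cohort, k)
        phs <- suppressWarnings(band_phases_multi(
          sub$data, spec$fs, config$bands,
          epoch_len = spec$epoch_len, pad = config$pad,
          max_epochs = config$max_epochs, firs = firs,
          subject_id = cohort$manifest$subject_id[k],
          phase_array = FALSE))
        for (bn in names(config$bands))
          plv_store[[bn]][k, , ] <- plv_rows(phs[[bn]], rows_needed)
      }
      TRUE
    }, error = function(e) stop_stage("connectivity", conditionMessage(e)))
    say("connectivity: PLV rows for %d sources x %d bands",
        length(rows_needed), length(config$bands))

    groups <- factor(cohort$manifest$group, levels = c("robust", "frail"))
    adjacency <- build_adjacency(grid)
    row_of <- setNames(seq_along(rows_needed), rows_needed)

    if ("seed" %in% config$analyses) {
      seed_res <- list()
      cb <- config$cbpt
      for (sd in seeds) for (bn in names(config$bands)) {
        fc <- t(vapply(seq_len(n_sub), function(k) {
          rows <- plv_store[[bn]][k, row_of[as.character(sd$source_indices)], ,
                                  drop = FALSE]
          seed_fc(matrix(rows, nrow = length(sd$source_indices)), sd)$values
        }, numeric(grid$n_sources - length(sd$source_indices))))
        distant <- setdiff(seq_len(grid$n_sources), sd$source_indices)
        cfg_cb <- cbpt_config(
          cluster_forming_alpha = cb$cluster_forming_alpha %||% 0.05,
          n_permutations = cb$n_permutations %||% 5000,
          rng_seed = cb$rng_seed %||% child_seed(config$rng_seed, 2),
          t_variant = cb$t_variant %||% "pooled",
          null_statistic = cb$null_statistic %||% "max_abs_mass",
          min_relabelings = cb$min_relabelings %||% 100)
        res <- cluster_permutation_test(fc, groups, adjacency,
                                        config = cfg_cb,
                                        source_index = distant)
        seed_res[[paste(sd$name, bn, sep = ".")]] <-
          list(seed = sd$name, laterality = sd$laterality, band = bn,
               result = res)
      }
      say("seed analysis: %d seed x band combinations (tested separately, no cross-analysis correction)",
          length(seed_res))
    }
    if ("rsn" %in% config$analyses) {
      rsn_res <- list()
      for (rs in rsns) for (bn in names(config$bands)) {
        vals <- vapply(seq_len(n_sub), function(k) {
          sub_m <- matrix(1, grid$n_sources, grid$n_sources)
          ri <- row_of[as.character(rs$source_indices)]
          sub_m[rs$source_indices, ] <- plv_store[[bn]][k, ri, ]
          pm <- structure(list(values = sub_m,
                               subject_id = cohort$manifest$subject_id[k],
                               band = bn, n_sources = grid$n_sources),
                          class = "plv_matrix")
          rsn_fc(pm, rs, pair_policy = config$pair_policy)$value
        }, numeric(1))
        rsn_res[[paste(rs$name, bn, sep = ".")]] <-
          rsn_group_test(vals, groups, network = rs$name, band = bn)
      }
      say("rsn analysis: %d network x band combinations", length(rsn_res))
    }
  }

  clin_res <- NULL
  if ("clinical" %in% config$analyses) {
    clin_res <- tryCatch({
      tab <- if (!is.null(config$clinical) && !is.null(config$clinical$tsv)) {
        read_clinical_table(config$clinical$tsv, config$clinical$types)
      } else {
        simulate_clinical(
          spec$n_robust, spec$n_frail,
          list(list(name = "gender", type = "categorical",
                    levels = c("female", "male"),
                    p_robust = 21 / 34, p_frail = 15 / 20),
               list(name = "age", type = "continuous",
                    robust = c(78.5, 4), frail = c(81, 4)),
               list(name = "gait_speed", type = "continuous",
                    robust = c(1.0, 0.2), frail = c(0.7, 0.2))),
          rng_seed = child_seed(config$rng_seed, 3))
      }
      summarize_clinical(tab)
    }, error = function(e) stop_stage("clinical", conditionMessage(e)))
    say("clinical: %d variables", nrow(clin_res))
  }

  report <- structure(list(
    config = config,
    seed_results = seed_res,
    rsn_results = rsn_res,
    clinical = clin_res,
    manifest = cohort$manifest,
    truth = cohort$truth,
    log = log,
    version = as.character(utils::packageVersion("plvfc")),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "plv_run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.plv_run_report <- function(x, ...) {
  cat("plvfc run report\n")
  for (l in x$log) cat(" ", l, "\n")
  if (!is.null(x$seed_results)) {
    cat("  seed-based clusters:\n")
    for (nm in names(x$seed_results)) {
      r <- x$seed_results[[nm]]
      sig <- Filter(function(cl) cl$p_value < 0.05, r$result$clusters)
      cat(sprintf("    %-28s %d cluster(s), %d with p < 0.05\n", nm,
                  length(r$result$clusters), length(sig)))
      for (cl in sig)
        cat(sprintf("      %s, %d sources, T-statsum %.2f, p = %.4f\n",
                    cl$sign, length(cl$members), cl$mass, cl$p_value))
    }
  }
  if (!is.null(x$rsn_results)) {
    cat("  RSN tests (uncorrected):\n")
    for (nm in names(x$rsn_results)) {
      r <- x$rsn_results[[nm]]
      cat(sprintf("    %-28s t = %+.2f, p = %.4f\n", nm, r$t, r$p))
    }
  }
  if (!is.null(x$clinical)) {
    cat("  clinical summary:\n")
    print.data.frame(cbind(x$clinical[, c("variable", "type")],
                           round(x$clinical["p"], 4)), row.names = FALSE)
  }
  cat(sprintf("  wall clock: %.1f s (plvfc %s)\n", x$wall_clock_s, x$version))
  invisible(x)
}

#' Write a run report to disk
#'
#' JSON report (config echo, cluster lists, RSN tests, seeds) plus TSV
#' summary tables.
#'
#' @param report a `plv_run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    version = report$version,
    rng_seed = report$config$rng_seed,
    analyses = report$config$analyses,
    log = report$log,
    seed_results = lapply(report$seed_results, function(r) list(
      seed = r$seed, band = r$band,
      n_permutations = r$result$n_permutations,
      rng_seed = r$result$config$rng_seed,
      clusters = lapply(r$result$clusters, function(cl)
        list(source_index = cl$source_index, mass = cl$mass,
             sign = cl$sign, p_value = cl$p_value)))),
    rsn_results = lapply(report$rsn_results, unclass),
    note = "seed/band/laterality analyses are tested separately without cross-analysis correction")
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$clinical))
    write.table(report$clinical, file.path(out_dir, "clinical.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$rsn_results)) {
    tab <- do.call(rbind, lapply(report$rsn_results, function(r)
      data.frame(network = r$network, band = r$band,
                 mean_robust = r$mean_group1, mean_frail = r$mean_group2,
                 t = r$t, p = r$p)))
    write.table(tab, file.path(out_dir, "rsn_tests.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}
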