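#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. Every stochastic stage derives its seed from the single
#' top-level `seed`, which is mandatory, so a run is fully reproducible
#' from the configuration alone. All defaults are resolved here and
#' mirrored into the run manifest; no stage applies a silent default.
#'
#' @param input Either a path to a long-format cohort CSV (raw 0-4 items;
#'   missing values as empty cells) or a data frame; `NULL` to simulate.
#' @param simulate_n Cohort size when simulating (used if `input` is
#'   `NULL`).
#' @param seed Integer seed (required).
#' @param timepoints Timepoints to analyze.
#' @param gamma,n_lambda,lambda_min_ratio,method Network-estimation
#'   settings.
#' @param n_perm,paired Network-comparison settings.
#' @param boot_grid,boot_B Stability-bootstrap settings.
#' @param stability_statistic Centrality statistic for the bootstrap.
#' @param output_dir Directory for tables, JSON documents and the
#'   manifest; `NULL` to keep results in memory only.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, simulate_n = 1000, seed = NULL,
                       timepoints = c("W2", "M3", "M6", "M12"),
                       gamma = 0.5, n_lambda = 100,
                       lambda_min_ratio = 0.01, method = "pearson",
                       n_perm = 1000, paired = TRUE,
                       boot_grid = seq(0.1, 0.7, by = 0.1), boot_B = 1000,
                       stability_statistic = "expected_influence",
                       output_dir = NULL) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("run_config requires an explicit integer seed", call. = FALSE)
  }
  cfg <- list(input = input, simulate_n = simulate_n,
              seed = as.integer(seed), timepoints = timepoints,
              gamma = gamma, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio, method = method,
              n_perm = n_perm, paired = paired, boot_grid = boot_grid,
              boot_B = boot_B, stability_statistic = stability_statistic,
              output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full symptom-network analysis
#'
#' Executes, from one configuration: per-timepoint network estimation and
#' centrality, all pairwise network comparison tests, case-dropping
#' bootstrap stability per timepoint, and the eight adjusted outcome
#' regressions (four outcomes at M6 and M12). When `output_dir` is set,
#' centrality and regression tables are written as CSV, networks and
#' comparison results as JSON, plus a manifest recording the resolved
#' configuration and per-stage seeds.
#'
#' @param config A [run_config()].
#' @return A result bundle (list): `cohort`, `networks`, `centrality`,
#'   `comparisons`, `stability`, `regressions`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  bundle <- list()
  on_fail <- function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (is.null(config$input)) {
      truth <- make_true_network(seed = config$seed)
      raw <- simulate_cohort(truth, config$simulate_n,
                             timepoints = config$timepoints,
                             seed = config$seed + 1L)
    } else if (is.character(config$input)) {
      raw <- utils::read.csv(config$input, stringsAsFactors = FALSE)
    } else {
      raw <- as.data.frame(config$input)
    }
    cohort <- recode_cohort(raw)
    if ("gcs" %in% names(cohort)) {
      cohort <- filter_cohort(cohort, required_timepoints =
                                config$timepoints)
    }
    bundle$cohort <- cohort

    stage <- "estimate"
    nodes <- lapply(setNames(config$timepoints, config$timepoints),
                    function(tp) build_network_nodes(cohort, tp))
    bundle$networks <- lapply(nodes, select_network,
                              gamma = config$gamma,
                              n_lambda = config$n_lambda,
                              lambda_min_ratio = config$lambda_min_ratio,
                              method = config$method)

    stage <- "centrality"
    bundle$centrality <- lapply(bundle$networks, expected_influence)

    stage <- "compare"
    prs <- utils::combn(config$timepoints, 2, simplify = FALSE)
    bundle$comparisons <- lapply(seq_along(prs), function(k) {
      a <- prs[[k]][1]; b <- prs[[k]][2]
      na <- nodes[[a]]; nb <- nodes[[b]]
      if (config$paired) {
        common <- intersect(rownames(na), rownames(nb))
        na <- na[common, , drop = FALSE]
        nb <- nb[common, , drop = FALSE]
      }
      nct_compare(na, nb, n_perm = config$n_perm, paired = config$paired,
                  seed = config$seed + 100L + k, gamma = config$gamma,
                  n_lambda = config$n_lambda,
                  lambda_min_ratio = config$lambda_min_ratio,
                  method = config$method)
    })
    names(bundle$comparisons) <- vapply(prs, paste, "", collapse = "_vs_")

    stage <- "stability"
    bundle$stability <- lapply(seq_along(nodes), function(k) {
      case_drop_bootstrap(nodes[[k]],
                          statistic = config$stability_statistic,
                          grid = config$boot_grid, B = config$boot_B,
                          seed = config$seed + 200L + k,
                          gamma = config$gamma,
                          n_lambda = config$n_lambda,
                          lambda_min_ratio = config$lambda_min_ratio,
                          method = config$method)
    })
    names(bundle$stability) <- names(nodes)

    stage <- "regress"
    specs <- expand.grid(outcome = .outcome_names,
                         timepoint = c("M6", "M12"),
                         stringsAsFactors = FALSE)
    bundle$regressions <- lapply(seq_len(nrow(specs)), function(k) {
      fit_outcome_model(regression_spec(specs$outcome[k],
                                        specs$timepoint[k]), cohort)
    })
    names(bundle$regressions) <- paste(specs$outcome, specs$timepoint,
                                       sep = "_")

    stage <- "report"
    bundle$manifest <- list(
      package_version = as.character(utils::packageVersion("rpqnet")),
      config = config[setdiff(names(config), "input")],
      input = if (is.character(config$input)) config$input
              else if (is.null(config$input)) "simulated" else "in-memory",
      stage_seeds = list(
        simulate = config$seed + 1L,
        comparisons = config$seed + 100L + seq_along(prs),
        stability = config$seed + 200L + seq_along(nodes)
      ),
      n_subjects = length(unique(cohort$subject_id))
    )
    if (!is.null(config$output_dir)) {
      .write_bundle(bundle, config$output_dir)
    }
    bundle
  }, error = on_fail)
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(bundle$networks)) {
    write_network_json(bundle$networks[[tp]],
                       file.path(dir, paste0("network_", tp, ".json")))
    network_edgelist(bundle$networks[[tp]],
                     file.path(dir, paste0("edges_", tp, ".csv")))
    write.csv(bundle$centrality[[tp]],
              file.path(dir, paste0("centrality_", tp, ".csv")),
              row.names = FALSE)
    grDevices::png(file.path(dir, paste0("network_", tp, ".png")),
                   width = 900, height = 900, res = 140)
    plot(bundle$networks[[tp]], main = tp)
    grDevices::dev.off()
  }
  for (cmp in names(bundle$comparisons)) {
    r <- bundle$comparisons[[cmp]]
    jsonlite::write_json(
      list(M_obs = r$M_obs, p_structure = r$p_structure,
           S_obs = r$S_obs, p_strength = r$p_strength,
           n_perm = r$n_perm, paired = r$paired,
           edge_diffs = r$edge_diffs),
      file.path(dir, paste0("nct_", cmp, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(r$edge_diffs, file.path(dir, paste0("nct_", cmp, ".csv")),
              row.names = FALSE)
  }
  for (tp in names(bundle$stability)) {
    s <- bundle$stability[[tp]]
    write.csv(s$samples,
              file.path(dir, paste0("stability_", tp, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(bundle$stability, function(s)
      list(statistic = s$statistic, cs = s$cs, B = s$B,
           n_failed = s$n_failed)),
    file.path(dir, "stability_summary.json"), auto_unbox = TRUE,
    digits = NA)
  for (rg in names(bundle$regressions)) {
    write.csv(as.data.frame(bundle$regressions[[rg]]),
              file.path(dir, paste0("regression_", rg, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
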