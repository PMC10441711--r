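#' Configuration for an end-to-end pipeline run
#'
#' Either `input` (a cohort CSV path) or `scenario = "elsi-like"` (generate
#' a synthetic cohort from [elsi_like_truth()]) must be supplied. Bootstrap
#' budgets default to the full-scale analysis values (500 edge resamples,
#' 100 community bootstraps, 500 case-dropping subsamples per proportion);
#' scale them down for quick runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param input Optional cohort CSV path.
#' @param scenario Optional scenario name (`"elsi-like"`).
#' @param n Cohort size for synthetic scenarios (default 9412, of which
#'   ~93.6% remain complete).
#' @param seed Master seed; recorded in every artifact.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule Edge symmetrisation rule.
#' @param nlambda,lambda_min_ratio Lambda-grid settings.
#' @param B_edges Edge-bootstrap resamples.
#' @param n_boot_communities Community bootstrap count.
#' @param B_cs,cs_proportions Case-dropping settings.
#' @param stability_strata Strata (by name) on which to run the bootstrap
#'   stability suite; defaults to the two sex strata.
#' @param min_stratum_n Minimum n for estimating a stratum network.
#' @param steps Walktrap walk length.
#' @param dump_strata Also write each stratum's rows as CSV.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, input = NULL, scenario = NULL, n = 9412,
                       seed = 1L, gamma = 0.25, rule = "AND", nlambda = 100,
                       lambda_min_ratio = 0.01, B_edges = 500,
                       n_boot_communities = 100, B_cs = 500,
                       cs_proportions = c(seq(0.9, 0.3, by = -0.1), 0.25),
                       stability_strata = c("female", "male"),
                       min_stratum_n = 200, steps = 4,
                       dump_strata = FALSE) {
  if (is.null(input) && is.null(scenario)) {
    stop("supply either an input CSV or a scenario name")
  }
  if (!is.null(scenario) && scenario != "elsi-like") {
    stop("unknown scenario: ", scenario)
  }
  stopifnot(n > 0, B_edges > 0, n_boot_communities > 0, B_cs > 0,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full multimorbidity-network pipeline
#'
#' Executes, in order: cohort acquisition (CSV or synthetic scenario), IPW
#' construction, multimorbidity classification, the regression suite
#' (hospitalisation PRs; readmission and length-of-stay betas), per-stratum
#' network estimation (five marginal strata), Walktrap communities with
#' naming, node predictability and centralities, and — on the configured
#' strata — the community bootstrap, the edge-weight bootstrap, and the
#' case-dropping CS analysis. All artifacts are written under
#' `config$out_dir` together with a machine-readable `manifest.json`
#' (seed, counts, per-file MD5 checksums) and a Markdown summary; a rerun
#' with the same config reproduces the manifest exactly.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  seeds <- substream_seeds(config$seed, 10L)

  full <- stage("cohort", {
    if (!is.null(config$input)) {
      read_cohort_csv(config$input)
    } else {
      truth <- elsi_like_truth()
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_ground_truth_json(truth,
                              file.path(config$out_dir, "ground_truth.json"),
                              seed = config$seed)
      coh <- generate_cohort(truth, config$n, seed = seeds[1])
      apply_missingness(coh, truth$missing_model, seed = seeds[2])
    }
  })
  write_cohort_csv(full, file.path(config$out_dir, "cohort_full.csv"))

  cc <- stage("preprocess", {
    suppressMessages(classify_mm(fit_ipw_weights(full)))
  })
  write_cohort_csv(cc, file.path(config$out_dir, "cohort_complete.csv"))

  reg <- stage("regression", run_regression_suite(cc))
  utils::write.csv(reg, file.path(config$out_dir, "regression_results.csv"),
                   row.names = FALSE)
  writeLines(format_regression_tables(reg),
             file.path(config$out_dir, "regression_tables.txt"))

  networks <- stage("networks", {
    estimate_stratified_networks(cc, min_n = config$min_stratum_n,
                                 gamma = config$gamma, rule = config$rule,
                                 nlambda = config$nlambda,
                                 lambda_min_ratio = config$lambda_min_ratio)
  })
  partitions <- list()
  metrics <- list()
  for (nm in names(networks)) {
    net <- networks[[nm]]
    part <- walktrap_communities(net, steps = config$steps)
    partitions[[nm]] <- part
    strata <- stratify(cc, "network")
    X <- network_matrix(strata[[nm]])
    metrics[[nm]] <- node_metrics(X, net, part)
    prefix <- file.path(config$out_dir, paste0("network_", nm))
    write_network(net, prefix, partition = part)
    utils::write.csv(metrics[[nm]], paste0(prefix, "_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(centrality_zscores(metrics[[nm]]),
                         paste0(prefix, "_metrics_z.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$dump_strata) {
      write_cohort_csv(strata[[nm]],
                       file.path(config$out_dir,
                                 paste0("stratum_", nm, ".csv")))
    }
  }

  stability <- list()
  strata <- stratify(cc, "network")
  for (i in seq_along(config$stability_strata)) {
    nm <- config$stability_strata[i]
    if (is.null(strata[[nm]])) next
    X <- network_matrix(strata[[nm]])
    stab <- stage(paste0("stability:", nm), {
      cb <- community_bootstrap(
        X, n_boot = config$n_boot_communities, seed = seeds[3] + i,
        steps = config$steps, gamma = config$gamma, rule = config$rule,
        nlambda = config$nlambda,
        lambda_min_ratio = config$lambda_min_ratio)
      eb <- nonparametric_bootstrap(
        X, B = config$B_edges, seed = seeds[4] + i, gamma = config$gamma,
        rule = config$rule, nlambda = config$nlambda,
        lambda_min_ratio = config$lambda_min_ratio)
      cs <- case_dropping_cs(
        X, B = config$B_cs, proportions = config$cs_proportions,
        seed = seeds[5] + i, gamma = config$gamma, rule = config$rule,
        nlambda = config$nlambda,
        lambda_min_ratio = config$lambda_min_ratio)
      list(communities = cb, edges = eb, cs = cs)
    })
    stability[[nm]] <- stab
    prefix <- file.path(config$out_dir, paste0("stability_", nm))
    utils::write.csv(stab$edges$ci, paste0(prefix, "_edge_ci.csv"),
                     row.names = FALSE)
    utils::write.csv(cs_table(stab$cs), paste0(prefix, "_cs.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(node = names(stab$communities$agreement),
                 consensus = stab$communities$consensus,
                 agreement = stab$communities$agreement,
                 row.names = NULL),
      paste0(prefix, "_communities.csv"), row.names = FALSE)
  }

  manifest <- stage("report", {
    write_report(config, full, cc, reg, networks, partitions, metrics,
                 stability)
  })
  invisible(manifest)
}

format_regression_tables <- function(reg) {
  fmt <- function(r) {
    if (is.na(r$ci_low)) {
      sprintf("  %-16s %-8s %s (ref)", r$term, r$level,
              format(r$estimate, nsmall = 2))
    } else {
      sprintf("  %-16s %-8s %.2f (%.2f, %.2f)", r$term, r$level,
              r$estimate, r$ci_low, r$ci_high)
    }
  }
  out <- character(0)
  for (subset in unique(reg$subset)) {
    for (outc in unique(reg$outcome)) {
      out <- c(out, paste0("== ", toupper(subset), " / ", outc, " =="))
      for (stratum in unique(reg$stratum)) {
        sub <- reg[reg$subset == subset & reg$outcome == outc &
                     reg$stratum == stratum, ]
        if (!nrow(sub)) next
        out <- c(out, paste0(" stratum: ", stratum))
        for (i in seq_len(nrow(sub))) out <- c(out, fmt(sub[i, ]))
      }
      out <- c(out, "")
    }
  }
  out
}

#' Serialise an estimated network
#'
#' Writes a weighted edge-list CSV (`node_i,node_j,weight`), a GraphML file,
#' and a JSON file carrying thresholds, the EBIC gamma, sample size, rule,
#' dropped nodes, and (optionally) community membership.
#'
#' @param network An `ising_network`.
#' @param path_prefix Output path without extension.
#' @param partition Optional `community_partition` to embed.
#' @return The three file paths, invisibly.
#' @export
write_network <- function(network, path_prefix, partition = NULL) {
  W <- network$weights
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  el <- data.frame(node_i = network$nodes[idx[, 1]],
                   node_j = network$nodes[idx[, 2]],
                   weight = W[idx], stringsAsFactors = FALSE)
  csv <- paste0(path_prefix, "_edges.csv")
  utils::write.csv(el, csv, row.names = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  gml <- paste0(path_prefix, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  js <- paste0(path_prefix, ".json")
  payload <- list(nodes = network$nodes,
                  thresholds = as.list(network$thresholds),
                  gamma = network$gamma, n = network$n, rule = network$rule,
                  dropped_nodes = as.list(network$dropped_nodes),
                  edges = el)
  if (!is.null(partition)) {
    payload$communities <- as.list(partition$membership)
    payload$modularity <- partition$modularity
  }
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, gml, js))
}

write_report <- function(config, full, cc, reg, networks, partitions,
                         metrics, stability) {
  group_names <- lapply(partitions, name_communities)
  manifest <- list(
    package = "mmnet",
    version = as.character(utils::packageVersion("mmnet")),
    seed = config$seed,
    scenario = if (is.null(config$scenario)) "csv-input" else config$scenario,
    gamma = config$gamma, rule = config$rule,
    n_full = nrow(full), n_complete = nrow(cc),
    n_dropped = attr(cc, "n_dropped"),
    stratum_counts = as.list(table(cc$sex)),
    age_counts = as.list(table(cc$age_group)),
    mm2_n = sum(cc$mm2), mm3_n = sum(cc$mm3),
    networks = lapply(names(networks), function(nm) {
      net <- networks[[nm]]
      list(stratum = nm, n = net$n,
           nodes = length(net$nodes),
           edges = sum(net$weights[upper.tri(net$weights)] != 0),
           dropped = as.list(net$dropped_nodes),
           communities = length(unique(partitions[[nm]]$membership)),
           modularity = partitions[[nm]]$modularity,
           group_names = as.list(unname(group_names[[nm]])))
    }),
    stability = lapply(names(stability), function(nm) {
      st <- stability[[nm]]
      list(stratum = nm,
           community_stable = st$communities$stable,
           mean_agreement = mean(st$communities$agreement, na.rm = TRUE),
           edge_boot_failures = st$edges$failures,
           cs = lapply(st$cs$cs, function(z) z$note))
    })
  )
  # per-file checksums of everything written so far
  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% c("manifest.json", "report.md")]
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  lines <- c(
    "# Multimorbidity network pipeline report", "",
    sprintf("- seed: %d; scenario: %s", config$seed, manifest$scenario),
    sprintf("- cohort: %d rows, %d complete (%d removed)",
            manifest$n_full, manifest$n_complete, manifest$n_dropped),
    sprintf("- complete cases by sex: female %d, male %d",
            manifest$stratum_counts$female, manifest$stratum_counts$male),
    sprintf("- multimorbidity: MM2 n = %d, MM3 n = %d",
            manifest$mm2_n, manifest$mm3_n), "",
    "## Networks")
  for (net in manifest$networks) {
    lines <- c(lines, sprintf(
      "- %s: n = %d, %d nodes, %d edges, %d communities (Q = %.3f)",
      net$stratum, net$n, net$nodes, net$edges, net$communities,
      net$modularity))
    for (gn in net$group_names) lines <- c(lines, paste0("    - ", gn))
  }
  if (length(manifest$stability)) {
    lines <- c(lines, "", "## Stability")
    for (st in manifest$stability) {
      lines <- c(lines, sprintf(
        "- %s: community bootstrap %s (mean agreement %.3f); CS: %s",
        st$stratum, if (st$community_stable) "stable" else "unstable",
        st$mean_agreement,
        paste(names(st$cs), unlist(st$cs), sep = "=", collapse = ", ")))
    }
  }
  writeLines(lines, file.path(config$out_dir, "report.md"))
  manifest
}
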