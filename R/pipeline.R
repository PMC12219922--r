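#' Suppress small cells in a count column
#'
#' Replaces positive counts below \code{threshold} with \code{NA} so that no
#' emitted table contains a reportable person count under the suppression
#' floor.
#'
#' @param x Integer vector of counts.
#' @param threshold Suppression floor (default 5).
#' @return \code{x} with values in \code{(0, threshold)} set to \code{NA}.
#' @export
suppress_small_counts <- function(x, threshold = 5) {
  x[x > 0 & x < threshold] <- NA
  x
}

#' Single-disease prevalence per stratum
#'
#' Percentage of the stratum denominator (at the disease's own age cut-off)
#' with an incident case of each disease; used as the node-size attribute of
#' reported networks.
#'
#' @param cohort An \code{mm_cohort}.
#' @param sex,age_group Stratum selector.
#' @param scope Denominator scope.
#' @return Named numeric vector over the stratum's disease list.
#' @export
single_disease_prevalence <- function(cohort, sex, age_group = NULL,
                                      scope = c("general-population",
                                                "multimorbid-cohort")) {
  scope <- match.arg(scope)
  diseases <- sex_disease_list(cohort$registry, sex)
  p <- cohort$persons
  keep <- p$multimorbid & p$sex == sex
  if (!is.null(age_group)) keep <- keep & !is.na(p$age_group) & p$age_group == age_group
  cs <- cohort$qualifying_cases
  cs <- cs[cs$person_id %in% p$person_id[keep], ]
  counts <- table(factor(cs$disease, levels = diseases))
  out <- vapply(diseases, function(d) {
    co <- effective_cutoff(
      cohort$registry$age_cutoff[cohort$registry$disease == d]
    )
    denom <- suppressWarnings(
      eligible_denominator(cohort, sex, age_group, age_cutoff = co,
                           scope = scope)
    )
    if (denom == 0) return(NA_real_)
    100 * as.integer(counts[[d]]) / denom
  }, numeric(1))
  names(out) <- diseases
  out
}

pipeline_defaults <- function() {
  list(
    alpha = 0.05,
    p_threshold = NULL,
    m_tests = NULL,
    denominator_scope = "general-population",
    age_reference = "end-of-observation",
    min_years = 10,
    gap_tolerance = 0,
    weight_kinds = c("prevalence", "lift"),
    suppress_below = 5
  )
}

#' Run the full temporal multimorbidity pipeline
#'
#' Executes simulate (or ingest), inclusion, stratification, directed pair
#' statistics, link filtering, network construction, link-community detection
#' (on the lift network) and cluster prevalence for all six sex/age strata,
#' and optionally writes the artifact bundle: edge tables, node metrics,
#' GraphML files, community and cluster-prevalence tables, the
#' participant-flow report and a JSON run manifest recording the
#' configuration, seed, thresholds and record counts at every filter stage.
#'
#' @param config A named list or a path to a YAML file. Must contain exactly
#'   one of \code{simulate} (arguments for [synthetic_config()]) or
#'   \code{input_dir} (a directory readable by [read_cohort_extract()]).
#'   Optional entries: \code{alpha}, \code{p_threshold}, \code{m_tests},
#'   \code{denominator_scope}, \code{age_reference}, \code{min_years},
#'   \code{gap_tolerance}, \code{weight_kinds}, \code{suppress_below},
#'   \code{output_dir}.
#' @param output_dir Overrides \code{config$output_dir}; \code{NULL} skips
#'   writing.
#' @return Invisibly, a list with the cohort, per-stratum link tables,
#'   networks, communities, cluster prevalence, participant flow and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(output_dir)) output_dir <- cfg$output_dir

  has_sim <- !is.null(cfg$simulate)
  has_in <- !is.null(cfg$input_dir)
  if (has_sim == has_in) {
    stop("config must contain exactly one of 'simulate' or 'input_dir'")
  }

  registry <- if (!is.null(cfg$registry_path)) {
    disease_registry(cfg$registry_path)
  } else {
    disease_registry()
  }

  if (has_sim) {
    sim_cfg <- do.call(synthetic_config, cfg$simulate)
    extract <- generate_cohort(sim_cfg, registry)
  } else {
    extract <- read_cohort_extract(cfg$input_dir)
  }

  inclusion <- apply_inclusion(extract, registry, min_years = cfg$min_years,
                               gap_tolerance = cfg$gap_tolerance,
                               left_censor = cfg$left_censor)
  cohort <- assign_stratum(inclusion, age_reference = cfg$age_reference)

  strata <- analysis_strata()
  link_tables <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    pt <- count_directed_pairs(cohort, strata$sex[s], strata$age_group[s])
    link_tables[[s]] <- pair_links(pt, cohort, scope = cfg$denominator_scope)
  }
  all_links <- do.call(rbind, link_tables)
  n_tests <- sum(!is.na(all_links$p_value))
  all_links <- filter_links(all_links, alpha = cfg$alpha,
                            m_tests = cfg$m_tests,
                            p_threshold = cfg$p_threshold)
  p_threshold <- attr(all_links, "p_threshold")

  networks <- list()
  metrics_rows <- list()
  comm_rows <- list()
  prev_rows <- list()
  for (s in seq_len(nrow(strata))) {
    sx <- strata$sex[s]; ag <- strata$age_group[s]
    sl <- all_links[all_links$sex == sx & all_links$age_group == ag, ]
    node_prev <- single_disease_prevalence(cohort, sx, ag,
                                           scope = cfg$denominator_scope)
    for (wk in cfg$weight_kinds) {
      net <- build_network(sl, diseases = sex_disease_list(registry, sx),
                           weight_kind = wk, sex = sx, age_group = ag,
                           node_prevalence = node_prev)
      networks[[paste(wk, sx, ag, sep = "_")]] <- net
      nm <- node_metrics(net)
      metrics_rows[[length(metrics_rows) + 1L]] <- cbind(
        sex = sx, age_group = ag, weight_kind = wk,
        density = network_density(net), nm, stringsAsFactors = FALSE
      )
    }
    lift_net <- networks[[paste("lift", sx, ag, sep = "_")]]
    comms <- cut_link_communities(suppressMessages(cluster_links(lift_net)))
    ct <- community_table(comms)
    if (nrow(ct) > 0) {
      comm_rows[[length(comm_rows) + 1L]] <- cbind(
        sex = sx, age_group = ag, ct, stringsAsFactors = FALSE
      )
      for (com in comms$communities) {
        pr <- cluster_prevalence(cohort, com, sex = sx, age_group = ag,
                                 scope = cfg$denominator_scope,
                                 suppress_below = cfg$suppress_below)
        prev_rows[[length(prev_rows) + 1L]] <- cbind(
          sex = sx, age_group = ag, pr, stringsAsFactors = FALSE
        )
      }
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  communities <- if (length(comm_rows)) do.call(rbind, comm_rows) else NULL
  prevalence <- if (length(prev_rows)) do.call(rbind, prev_rows) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("morbnet")),
    config = cfg[setdiff(names(cfg), "output_dir")],
    seed = if (has_sim) cfg$simulate$rng_seed else NULL,
    p_threshold = p_threshold,
    m_tests = n_tests,
    filter_cascade = list(
      persons_in_extract = cohort$flow$n[1],
      eligible_population = cohort$flow$n[cohort$flow$stage == "eligible_population"],
      multimorbid_cohort = cohort$flow$n[cohort$flow$stage == "multimorbid_cohort"],
      links_tested = n_tests,
      links_retained = sum(all_links$retained),
      communities_found = if (is.null(communities)) 0L else nrow(communities),
      clusters_reported = if (is.null(prevalence)) 0L else sum(!prevalence$suppressed)
    )
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    edges_out <- all_links
    edges_out$n_ij <- suppress_small_counts(edges_out$n_ij, cfg$suppress_below)
    edges_out$n_ji <- suppress_small_counts(edges_out$n_ji, cfg$suppress_below)
    utils::write.csv(edges_out, file.path(output_dir, "edges.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(output_dir, "node_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$flow, file.path(output_dir, "participant_flow.csv"),
                     row.names = FALSE)
    if (!is.null(communities)) {
      utils::write.csv(communities, file.path(output_dir, "communities.csv"),
                       row.names = FALSE)
    }
    if (!is.null(prevalence)) {
      utils::write.csv(prevalence,
                       file.path(output_dir, "cluster_prevalence.csv"),
                       row.names = FALSE)
    }
    gml_dir <- file.path(output_dir, "graphml")
    dir.create(gml_dir, showWarnings = FALSE)
    for (nm in names(networks)) {
      export_graphml(networks[[nm]],
                     file.path(gml_dir, paste0(gsub("[^A-Za-z0-9_+-]", "_", nm),
                                               ".graphml")))
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }

  invisible(list(
    cohort = cohort, links = all_links, networks = networks,
    communities = communities, cluster_prevalence = prevalence,
    flow = cohort$flow, manifest = manifest
  ))
}
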