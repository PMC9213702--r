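#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' FDR 0.01 at MSP, reaction and association level, BMI cut 30, Wilcoxon
#' alpha 0.05 for the BMI split, and 10 species per community model. With
#' no input paths the pipeline generates its inputs with
#' [synthetic_config()] under the given seed; alternatively point
#' `gems_dir`, `abundance_path`, `metadata_path` and `diet_path` (and
#' optionally `wellness_abundance_path`, `wellness_metadata_path`,
#' `metabolome_path`) at files in the package's formats.
#'
#' @param seed integer seed controlling the synthetic inputs and any
#'   sampling the pipeline performs.
#' @param fdr_msp,fdr_reaction,fdr_association FDR thresholds.
#' @param bmi_cut,alpha_bmi BMI stratification parameters.
#' @param top_n species per community model.
#' @param community_diseases diseases whose cohorts get community models.
#' @param community_samples_per_group community models built per
#'   case/control group (keeps run time proportionate; `Inf` for all).
#' @param out_dir optional directory for per-stage TSV outputs and the run
#'   manifest.
#' @param synthetic a [synthetic_config()] (defaults to one built from
#'   `seed`).
#' @param gems_dir,abundance_path,metadata_path,diet_path,anaerobic,
#'   wellness_abundance_path,wellness_metadata_path,metabolome_path file
#'   inputs; all of the first four must be set to switch off synthetic
#'   generation.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            fdr_msp = 0.01, fdr_reaction = 0.01,
                            fdr_association = 0.01,
                            bmi_cut = 30, alpha_bmi = 0.05,
                            top_n = 10,
                            community_diseases = c("T2D", "ACVD"),
                            community_samples_per_group = 8,
                            out_dir = NULL,
                            synthetic = NULL,
                            gems_dir = NULL, abundance_path = NULL,
                            metadata_path = NULL, diet_path = NULL,
                            anaerobic = TRUE,
                            wellness_abundance_path = NULL,
                            wellness_metadata_path = NULL,
                            metabolome_path = NULL) {
  thresholds <- c(fdr_msp, fdr_reaction, fdr_association)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("FDR thresholds must lie in (0, 1)")
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat key schema mirroring the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stage sequence: ingest or generate inputs; per-disease MSP
#' differential abundance with the two-step selection rule and the unique
#' union; diet-constrained FBA of the selected species with group-average
#' exchange fluxes; reaction-abundance profiling with per-disease
#' differential reactions, cross-disease intersection,
#' direction-consistency, presence-gap filtering and KO mapping;
#' personalized community models with community FBA and group-average net
#' exchange; and reaction-metabolite association plus the BMI-stratified
#' comparison on the wellness cohort. Re-running with an identical config
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return a list with one element per stage plus `manifest`, a tibble of
#'   per-stage row counts and parameters.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  file_mode <- !is.null(config$abundance_path)
  if (file_mode) {
    for (p in c(config$gems_dir, config$abundance_path, config$metadata_path,
                config$diet_path, config$wellness_abundance_path,
                config$wellness_metadata_path, config$metabolome_path))
      if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }

  inputs <- pipeline_stage("ingest", {
    if (file_mode) {
      gem_files <- list.files(config$gems_dir, pattern = "\\.json$",
                              full.names = TRUE)
      list(gems = lapply(gem_files, read_gem),
           abundance = read_tsv_quiet(config$abundance_path),
           metadata = read_tsv_quiet(config$metadata_path),
           diet = read_diet(config$diet_path, anaerobic = config$anaerobic),
           wellness = if (!is.null(config$wellness_abundance_path))
             list(abundance = read_tsv_quiet(config$wellness_abundance_path),
                  metadata = read_tsv_quiet(config$wellness_metadata_path)),
           metabolome = if (!is.null(config$metabolome_path))
             read_tsv_quiet(config$metabolome_path),
           truth = NULL)
    } else {
      syn <- generate_all(config$synthetic)
      list(gems = syn$gems, abundance = syn$abundance,
           metadata = syn$metadata, diet = syn$diet,
           wellness = list(abundance = syn$wellness$abundance,
                           metadata = syn$wellness$metadata),
           metabolome = syn$metabolome, truth = syn$truth)
    }
  })
  gems <- inputs$gems
  gem_ids <- vapply(gems, `[[`, "", "id")
  diseases <- sort(unique(inputs$metadata$disease[inputs$metadata$disease != "none"]))

  msp <- pipeline_stage("msp-diff", {
    per_disease <- lapply(stats::setNames(diseases, diseases), function(dis) {
      cohorts_d <- unique(inputs$metadata$cohort[inputs$metadata$disease == dis])
      meta_d <- dplyr::filter(inputs$metadata, .data$cohort %in% cohorts_d)
      tbl_d <- dplyr::filter(inputs$abundance,
                             .data$sample_id %in% meta_d$sample_id)
      list(all = differential_abundance(tbl_d, meta_d),
           selected = select_significant_msps(tbl_d, meta_d, config$fdr_msp),
           meta = meta_d, table = tbl_d)
    })
    selected_union <- unique_union(lapply(per_disease, function(x)
      x$selected$feature_id))
    # direction per MSP from the disease where it is most significant
    all_sel <- dplyr::bind_rows(lapply(per_disease, `[[`, "selected"),
                                .id = "disease")
    model_groups <- all_sel |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::slice_min(.data$fdr, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(model_id = .data$feature_id,
                       group = .data$direction)
    list(per_disease = per_disease, selected_union = selected_union,
         model_groups = model_groups)
  })

  fluxes <- pipeline_stage("fba", {
    sel_with_model <- intersect(msp$selected_union, gem_ids)
    results <- lapply(gems[gem_ids %in% sel_with_model], function(g)
      fba(g, inputs$diet))
    names(results) <- vapply(results, `[[`, "", "model_id")
    ok <- vapply(results, function(r) r$status == "optimal", TRUE)
    profiles <- purrr::map_dfr(results[ok], function(r) {
      g <- gems[[which(gem_ids == r$model_id)]]
      dplyr::mutate(exchange_profile(g, r), model_id = r$model_id)
    })
    growth <- tibble::tibble(
      model_id = names(results),
      growth_rate = vapply(results, `[[`, 0, "growth_rate"))
    groups <- dplyr::filter(msp$model_groups,
                            .data$model_id %in% profiles$model_id)
    avg <- if (nrow(profiles) && nrow(groups))
      group_average_flux(profiles, groups) else NULL
    jac <- if (sum(gem_ids %in% sel_with_model) >= 2)
      jaccard_pairs(gems[gem_ids %in% sel_with_model]) else NULL
    list(growth = growth, profiles = profiles, group_average = avg,
         jaccard = jac)
  })

  reacto <- pipeline_stage("reactobiome", {
    presence <- reaction_presence(gems)
    per_disease <- lapply(msp$per_disease, function(x) {
      ra <- compute_reaction_abundance(presence, x$table)
      differential_reactions(ra, x$meta)
    })
    shared <- intersect_significant(per_disease, config$fdr_reaction)
    consistent <- consistent_direction(per_disease, shared)
    komap <- ko_map(gems)
    kos <- map_to_kos(shared, komap)
    gap_kept <- presence_gap_filter(presence, msp$model_groups)
    list(presence = presence, per_disease = per_disease, shared = shared,
         consistent = consistent, komap = komap, kos = kos,
         consistent_gap = intersect(consistent, gap_kept),
         gap_kept = gap_kept)
  })

  community <- pipeline_stage("community", {
    with_local_seed(config$seed * 7 + 5, {
      abun <- table_to_matrix(inputs$abundance)
      cohorts <- unique(inputs$metadata$cohort[
        inputs$metadata$disease %in% config$community_diseases])
      chosen <- inputs$metadata |>
        dplyr::filter(.data$cohort %in% cohorts) |>
        dplyr::group_by(.data$cohort, .data$group) |>
        dplyr::slice_sample(n = min(config$community_samples_per_group, 1e6)) |>
        dplyr::ungroup()
      sims <- lapply(chosen$sample_id, function(s) {
        sel <- select_top_n(abun[s, ], n = config$top_n,
                            gems_available = gem_ids)
        cm <- make_community(gems[match(sel$model_id, gem_ids)],
                             stats::setNames(sel$weight, sel$model_id))
        community_fba(cm, inputs$diet)
      })
      names(sims) <- chosen$sample_id
      growth <- tibble::tibble(
        sample_id = chosen$sample_id,
        group = chosen$group,
        cohort = chosen$cohort,
        community_growth = vapply(sims, `[[`, 0, "community_growth"))
      net <- purrr::map_dfr(sims[vapply(sims, function(x)
        x$status == "optimal", TRUE)], `[[`, "net_exchange",
        .id = "sample_id")
      net_avg <- net |>
        dplyr::left_join(chosen[, c("sample_id", "group")], by = "sample_id") |>
        dplyr::group_by(.data$group, .data$metabolite_id) |>
        dplyr::summarise(mean_net = mean(.data$net), .groups = "drop")
      list(growth = growth, net_exchange_avg = net_avg, results = sims)
    })
  })

  assoc <- pipeline_stage("associate", {
    if (is.null(inputs$wellness) || is.null(inputs$metabolome)) return(NULL)
    presence <- reacto$presence
    ra_well <- compute_reaction_abundance(presence, inputs$wellness$abundance)
    focus <- if (length(reacto$consistent)) reacto$consistent else
      colnames(table_to_matrix(ra_well))
    fits <- fit_associations(ra_well, inputs$metabolome,
                             inputs$wellness$metadata,
                             fdr_threshold = config$fdr_association)
    bmi <- bmi_stratified_test(ra_well, inputs$wellness$metadata,
                               reactions = focus,
                               bmi_cut = config$bmi_cut,
                               alpha = config$alpha_bmi)
    list(associations = fits, bmi = bmi)
  })

  manifest <- tibble::tibble(
    stage = c("ingest", "msp-diff", "fba", "reactobiome", "community",
              "associate"),
    rows = c(nrow(inputs$abundance),
             length(msp$selected_union),
             nrow(fluxes$growth),
             length(reacto$shared),
             nrow(community$growth),
             if (is.null(assoc)) 0L else sum(assoc$associations$significant)),
    note = c("samples", "unique selected MSPs", "modelled MSPs",
             "reactions significant in all diseases", "community models",
             "significant associations"))

  out <- list(inputs = inputs, msp = msp, fluxes = fluxes,
              reactobiome = reacto, community = community,
              association = assoc, manifest = manifest,
              parameters = config[c("seed", "fdr_msp", "fdr_reaction",
                                    "fdr_association", "bmi_cut",
                                    "alpha_bmi", "top_n")])
  if (!is.null(config$out_dir)) pipeline_write_outputs(out, config$out_dir)
  out
}

pipeline_write_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dis in names(out$msp$per_disease))
    write_tsv_quiet(out$msp$per_disease[[dis]]$all,
                    file.path(dir, paste0("msp_diff_", dis, ".tsv")))
  write_tsv_quiet(tibble::tibble(feature_id = out$msp$selected_union),
                  file.path(dir, "msp_selected_union.tsv"))
  write_tsv_quiet(out$fluxes$growth, file.path(dir, "growth_rates.tsv"))
  if (!is.null(out$fluxes$group_average))
    write_tsv_quiet(out$fluxes$group_average,
                    file.path(dir, "group_average_flux.tsv"))
  write_tsv_quiet(tibble::tibble(reaction_id = out$reactobiome$shared),
                  file.path(dir, "reactions_shared_significant.tsv"))
  write_tsv_quiet(out$community$growth, file.path(dir, "community_growth.tsv"))
  if (!is.null(out$association)) {
    write_tsv_quiet(out$association$associations,
                    file.path(dir, "associations.tsv"))
    write_tsv_quiet(out$association$bmi, file.path(dir, "bmi_split.tsv"))
  }
  write_tsv_quiet(out$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
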