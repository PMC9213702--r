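#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic data: cohort sizes, the planted
#' differential structure at species level, the marker ("tartrate-like")
#' reaction subsystem preferentially carried by disease-enriched species,
#' and the planted reaction-metabolite associations. Defaults are chosen to
#' emulate a case/control metagenome study in which a zero-inflated,
#' strongly shifted subset of species separates patients from controls:
#' 60 cases and 60 controls per disease, 40 species with ~50 reactions per
#' model, an 8-fold abundance shift with 70% zero-inflation in the depleted
#' group (so the zero-median selection rule is satisfiable), an 0.8
#' presence-fraction gap for the marker subsystem, and linear
#' reaction-metabolite associations of effect 1.5 against noise SD 1.
#'
#' @param n_species number of species (each gets a toy model).
#' @param n_samples_case,n_samples_control samples per group per disease.
#' @param diseases disease labels; each gets an independent cohort sharing
#'   the same planted species.
#' @param n_planted_differential planted differential species (half
#'   disease-enriched, half control-enriched).
#' @param effect_size multiplicative abundance shift of planted species in
#'   their enriched group.
#' @param zero_inflation_prob probability that a planted species is zeroed
#'   in its depleted group.
#' @param marker_reaction_set reaction ids of the marker subsystem.
#' @param marker_kos KEGG-ortholog ids annotating the marker reactions.
#' @param marker_presence_gap target presence-fraction difference of the
#'   marker subsystem between disease- and control-enriched species.
#' @param n_samples_wellness size of the healthy (wellness-style) cohort
#'   used for metabolome association and BMI stratification.
#' @param obese_fraction fraction of wellness samples drawn obese
#'   (BMI > 30).
#' @param bmi_effect multiplicative abundance boost of marker-carrying
#'   species in obese wellness samples (plants the BMI association).
#' @param n_metabolites plasma metabolites in the synthetic metabolome.
#' @param n_planted_associations planted reaction-metabolite pairs (half
#'   positive, half negative).
#' @param association_effect linear effect size of planted associations
#'   (per SD of transformed reaction abundance).
#' @param noise_sd Gaussian noise SD of the metabolome.
#' @param seed integer seed; every generator output is a deterministic
#'   function of (config, seed).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 40,
                             n_samples_case = 60,
                             n_samples_control = 60,
                             diseases = c("obesity", "T2D", "ACVD"),
                             n_planted_differential = 10,
                             effect_size = 8,
                             zero_inflation_prob = 0.7,
                             marker_reaction_set = c("TARTDH1", "TARTDH2",
                                                     "TARTDC", "TARTH",
                                                     "MDHOX"),
                             marker_kos = c(TARTDH1 = "K07246",
                                            TARTDH2 = "K07246",
                                            TARTDC = "K13775",
                                            TARTH = "K13775",
                                            MDHOX = "K13775"),
                             marker_presence_gap = 0.8,
                             n_samples_wellness = 101,
                             obese_fraction = 0.3,
                             bmi_effect = 3,
                             n_metabolites = 200,
                             n_planted_associations = 10,
                             association_effect = 1.5,
                             noise_sd = 1,
                             seed = 1L) {
  stopifnot(n_species >= 4, n_samples_case >= 2, n_samples_control >= 2,
            n_planted_differential >= 2,
            n_planted_differential <= n_species,
            effect_size > 0,
            zero_inflation_prob >= 0, zero_inflation_prob <= 1,
            marker_presence_gap >= 0, marker_presence_gap <= 1,
            n_metabolites >= 1, n_planted_associations <= n_metabolites,
            noise_sd >= 0, is.finite(seed))
  structure(as.list(environment()), class = "synthetic_config")
}

# run code under a derived seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

synthetic_species_ids <- function(n) sprintf("msp_%03d", seq_len(n))

#' Generate functional toy species models with a planted marker subsystem
#'
#' Every model shares one metabolite namespace and a common core
#' (fermentable-sugar uptake, a central chain to pyruvate, amino-acid
#' synthesis from glutamate with ammonia release, and biomass), plus random
#' optional modules: extra sugar routes (fructose, sucrose, starch), and
#' growth-coupled secretion of short-chain fatty acids (acetate, butyrate,
#' propionate), proline and indole via biomass byproduct coefficients.
#' Disease-designated species secrete more acetate/propionate and consume
#' more glutamate; control-designated species secrete more butyrate — the
#' flux contrasts the group-average comparison is meant to recover. The
#' marker ("tartrate-like") subsystem — tartrate uptake feeding the central
#' chain through five reactions annotated with two KEGG orthologs — is
#' placed in disease-enriched species at rate `(1 + gap)/2` and in others
#' at `(1 - gap)/2`, realizing the configured presence gap in expectation.
#' Filler interconversions between dummy metabolites differentiate the
#' models' reaction sets without affecting growth.
#'
#' Every emitted model is functional: it grows on [high_fibre_diet()].
#'
#' @param config a [synthetic_config()].
#' @return a list with `gems` (list of `gem`), and `truth`, a manifest
#'   describing every planted property (species roles, marker carriage,
#'   byproduct coefficients, the marker reaction set and its KO map).
#' @export
generate_toy_gems <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed * 7 + 1, {
    n <- config$n_species
    ids <- synthetic_species_ids(n)
    n_pl <- config$n_planted_differential
    n_dis <- ceiling(n_pl / 2)
    roles <- rep("neutral", n)
    roles[seq_len(n_dis)] <- "disease"
    roles[n_dis + seq_len(n_pl - n_dis)] <- "control"
    p_marker <- ifelse(roles == "disease",
                       (1 + config$marker_presence_gap) / 2,
                       (1 - config$marker_presence_gap) / 2)
    has_marker <- stats::runif(n) < p_marker
    phyla <- sample(c("Firmicutes", "Bacteroidetes", "Actinobacteria",
                      "Proteobacteria"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.1, 0.1))
    gamma <- tibble::tibble(
      species_id = ids,
      role = roles,
      has_marker = has_marker,
      ac = stats::runif(n, 0.8, 1.2) * ifelse(roles == "disease", 2.0, 0.8),
      ppa = stats::runif(n, 0.4, 0.8) * ifelse(roles == "disease", 2.0, 0.8),
      but = stats::runif(n, 0.4, 0.8) * ifelse(roles == "control", 2.0, 0.5),
      pro = stats::runif(n, 0.1, 0.3) * ifelse(roles == "disease", 2.0, 1.0),
      ind = stats::runif(n, 0.05, 0.15),
      aa = ifelse(roles == "disease", 0.8, 0.4))
    gems <- lapply(seq_len(n), function(i)
      toy_gem(ids[i], phyla[i], gamma[i, ], config))
    truth <- list(
      species = gamma,
      marker_reactions = sort(config$marker_reaction_set),
      marker_kos = config$marker_kos,
      disease_species = ids[roles == "disease"],
      control_species = ids[roles == "control"])
    list(gems = gems, truth = truth)
  })
}

# one toy species model; gm is the one-row byproduct/role tibble
toy_gem <- function(id, phylum, gm, config) {
  met <- function(mid, name, comp) tibble::tibble(id = mid, name = name,
                                                  compartment = comp)
  rxn <- function(rid, stoich, lb = 0, ub = 1000, ko = character(),
                  subsystem = NA_character_)
    list(id = rid, stoich = stoich, lb = lb, ub = ub, ko = ko,
         subsystem = subsystem)

  mets <- dplyr::bind_rows(
    met("glc_e", "glucose", "e"), met("glc_c", "glucose", "c"),
    met("glu_e", "glutamate", "e"), met("glu_c", "glutamate", "c"),
    met("pyr_c", "pyruvate", "c"), met("aa_c", "amino-acid pool", "c"),
    met("nh3_c", "ammonia", "c"), met("nh3_e", "ammonia", "e"))
  rxns <- list(
    rxn("EX_glc", c(glc_e = -1), lb = -1000),
    rxn("T_glc", c(glc_e = -1, glc_c = 1)),
    rxn("GLYC", c(glc_c = -1, pyr_c = 2), ko = "K00001",
        subsystem = "Glycolysis"),
    rxn("EX_glu", c(glu_e = -1), lb = -1000),
    rxn("T_glu", c(glu_e = -1, glu_c = 1)),
    rxn("AAS", c(glu_c = -1, aa_c = 1, nh3_c = 0.5), ko = "K00002",
        subsystem = "Amino acid metabolism"),
    rxn("T_nh3", c(nh3_c = -1, nh3_e = 1)),
    rxn("EX_nh3", c(nh3_e = -1), lb = -1000))
  exchanges <- c("EX_glc", "EX_glu", "EX_nh3")
  biomass_stoich <- c(pyr_c = -1, aa_c = -gm$aa, nh3_c = 0)

  add_secretion <- function(tag, gamma_val, name) {
    ce <- paste0(tag, "_c"); ee <- paste0(tag, "_e")
    mets <<- dplyr::bind_rows(mets, met(ce, name, "c"), met(ee, name, "e"))
    rxns <<- c(rxns, list(
      rxn(paste0("T_", tag), stats::setNames(c(-1, 1), c(ce, ee))),
      rxn(paste0("EX_", tag), stats::setNames(-1, ee), lb = -1000)))
    exchanges <<- c(exchanges, paste0("EX_", tag))
    biomass_stoich[ce] <<- gamma_val
  }
  add_secretion("ac", gm$ac, "acetate")
  add_secretion("ppa", gm$ppa, "propionate")
  add_secretion("but", gm$but, "butyrate")
  add_secretion("pro", gm$pro, "proline")
  add_secretion("ind", gm$ind, "indole")

  # optional extra sugar routes
  if (stats::runif(1) < 0.6) {
    mets <- dplyr::bind_rows(mets, met("fru_e", "fructose", "e"))
    rxns <- c(rxns, list(rxn("EX_fru", c(fru_e = -1), lb = -1000),
                         rxn("T_fru", c(fru_e = -1, glc_c = 1))))
    exchanges <- c(exchanges, "EX_fru")
  }
  if (stats::runif(1) < 0.6) {
    mets <- dplyr::bind_rows(mets, met("sucr_e", "sucrose", "e"))
    rxns <- c(rxns, list(rxn("EX_sucr", c(sucr_e = -1), lb = -1000),
                         rxn("SUH", c(sucr_e = -1, glc_c = 2))))
    exchanges <- c(exchanges, "EX_sucr")
  }
  if (stats::runif(1) < 0.4) {
    mets <- dplyr::bind_rows(mets, met("starch_e", "starch", "e"))
    rxns <- c(rxns, list(rxn("EX_starch", c(starch_e = -1), lb = -1000),
                         rxn("AMY", c(starch_e = -1, glc_c = 3))))
    exchanges <- c(exchanges, "EX_starch")
  }

  if (gm$has_marker) {
    mets <- dplyr::bind_rows(mets,
      met("tar_e", "tartrate", "e"), met("tar_c", "tartrate", "c"),
      met("mal_c", "malate-like", "c"), met("glx_c", "glyoxylate-like", "c"))
    mk <- config$marker_kos
    sub <- "Glyoxylate and dicarboxylate metabolism"
    marker <- config$marker_reaction_set
    rxns <- c(rxns, list(
      rxn("EX_tar", c(tar_e = -1), lb = -1000),
      rxn("T_tar", c(tar_e = -1, tar_c = 1)),
      rxn(marker[1], c(tar_c = -1, mal_c = 1), ko = mk[[marker[1]]], subsystem = sub),
      rxn(marker[2], c(tar_c = -1, mal_c = 1, nh3_c = 0.1),
          ko = mk[[marker[2]]], subsystem = sub),
      rxn(marker[3], c(tar_c = -1, glx_c = 1), ko = mk[[marker[3]]], subsystem = sub),
      rxn(marker[4], c(glx_c = -1, mal_c = 1), ko = mk[[marker[4]]], subsystem = sub),
      rxn(marker[5], c(mal_c = -1, pyr_c = 1), ko = mk[[marker[5]]], subsystem = sub)))
    exchanges <- c(exchanges, "EX_tar")
  }

  # blocked filler interconversions to differentiate reaction content
  n_dummy_mets <- 12
  pool <- t(utils::combn(n_dummy_mets, 2))
  pick <- sample(nrow(pool), 12)
  used <- sort(unique(as.vector(pool[pick, ])))
  mets <- dplyr::bind_rows(mets, purrr::map_dfr(used, function(k)
    met(sprintf("dum%02d_c", k), sprintf("filler %d", k), "c")))
  for (k in pick) {
    a <- sprintf("dum%02d_c", pool[k, 1]); b <- sprintf("dum%02d_c", pool[k, 2])
    rxns <- c(rxns, list(rxn(sprintf("FIL_%02d_%02d", pool[k, 1], pool[k, 2]),
                             stats::setNames(c(-1, 1), c(a, b)), lb = -1000)))
  }

  biomass_stoich <- biomass_stoich[biomass_stoich != 0]
  rxns <- c(rxns, list(rxn("BIOMASS", biomass_stoich)))
  gem(id = id,
      taxonomy = c(phylum = phylum),
      metabolites = mets,
      reactions = rxns,
      biomass_reaction = "BIOMASS",
      exchanges = exchanges)
}

#' Generate case/control abundance cohorts with planted differential species
#'
#' Baseline abundances are log-normal (the standard stand-in for microbial
#' rank-abundance curves), renormalized per sample. Planted disease-enriched
#' species are multiplied by `effect_size` in cases and zeroed with
#' probability `zero_inflation_prob` in controls; planted control-enriched
#' species get the mirror treatment — so the zero-median selection rule can
#' fire. Each disease label gets an independent cohort over the same
#' species and the same planted set. BMI is drawn with a planted upward
#' shift for obesity cases; other groups sit in the normal range.
#'
#' @param config a [synthetic_config()].
#' @param truth the truth manifest from [generate_toy_gems()].
#' @return list with `abundance` (tibble `sample_id` + species columns over
#'   all cohorts), `metadata` (tibble: `sample_id`, `group`, `disease`,
#'   `cohort`, `bmi`, `age`, `sex`) and `truth` (planted species by
#'   direction).
#' @export
generate_abundance <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed * 7 + 2, {
    ids <- truth$species$species_id
    n <- length(ids)
    base_meanlog <- stats::rnorm(n, 0, 1.5)
    rows <- list(); meta <- list()
    for (dis in config$diseases) {
      for (grp in c("case", "control")) {
        n_s <- if (grp == "case") config$n_samples_case else config$n_samples_control
        m <- matrix(exp(stats::rnorm(n_s * n,
                                     rep(base_meanlog, each = n_s), 0.5)),
                    n_s, n)
        colnames(m) <- ids
        dis_sp <- truth$disease_species
        ctl_sp <- truth$control_species
        if (grp == "case") {
          m[, dis_sp] <- m[, dis_sp] * config$effect_size
          drop <- matrix(stats::runif(n_s * length(ctl_sp)) <
                           config$zero_inflation_prob, n_s, length(ctl_sp))
          m[, ctl_sp][drop] <- 0
        } else {
          m[, ctl_sp] <- m[, ctl_sp] * config$effect_size
          drop <- matrix(stats::runif(n_s * length(dis_sp)) <
                           config$zero_inflation_prob, n_s, length(dis_sp))
          m[, dis_sp][drop] <- 0
        }
        m <- m / rowSums(m)
        sample_ids <- sprintf("%s_%s_%03d", dis, grp, seq_len(n_s))
        rownames(m) <- sample_ids
        rows[[paste(dis, grp)]] <- m
        bmi_mean <- if (dis == "obesity" && grp == "case") 33.6 else 24
        meta[[paste(dis, grp)]] <- tibble::tibble(
          sample_id = sample_ids,
          group = grp,
          disease = ifelse(grp == "case", dis, "none"),
          cohort = paste0("synthetic_", dis),
          bmi = pmax(stats::rnorm(n_s, bmi_mean, 2.5), 16),
          age = stats::rnorm(n_s, 55, 8),
          sex = sample(c("F", "M"), n_s, replace = TRUE))
      }
    }
    list(abundance = matrix_to_table(do.call(rbind, rows)),
         metadata = dplyr::bind_rows(meta),
         truth = list(planted_disease = truth$disease_species,
                      planted_control = truth$control_species))
  })
}

#' Generate a healthy wellness-style cohort with a planted BMI effect
#'
#' Produces abundance and metadata for a single healthy cohort whose BMI
#' spans the obesity boundary. In obese samples (BMI > 30) the abundance of
#' marker-carrying species is multiplied by `bmi_effect`, planting the
#' reaction-BMI association the stratified test should recover.
#'
#' @param config a [synthetic_config()].
#' @param truth the truth manifest from [generate_toy_gems()].
#' @return list with `abundance`, `metadata`, and `truth` (obese boost and
#'   boosted species).
#' @export
generate_wellness <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed * 7 + 3, {
    ids <- truth$species$species_id
    n <- length(ids)
    n_s <- config$n_samples_wellness
    base_meanlog <- stats::rnorm(n, 0, 1.5)
    obese <- stats::runif(n_s) < config$obese_fraction
    bmi <- ifelse(obese, stats::rnorm(n_s, 34, 2), stats::rnorm(n_s, 24, 2.5))
    bmi <- pmax(bmi, 16)
    m <- matrix(exp(stats::rnorm(n_s * n, rep(base_meanlog, each = n_s), 0.5)),
                n_s, n, dimnames = list(sprintf("well_%03d", seq_len(n_s)), ids))
    carriers <- truth$species$species_id[truth$species$has_marker]
    m[obese, carriers] <- m[obese, carriers] * config$bmi_effect
    m <- m / rowSums(m)
    meta <- tibble::tibble(
      sample_id = rownames(m), group = "control", disease = "none",
      cohort = "synthetic_wellness", bmi = bmi,
      age = stats::runif(n_s, 50, 65),
      sex = sample(c("F", "M"), n_s, replace = TRUE))
    list(abundance = matrix_to_table(m), metadata = meta,
         truth = list(boosted_species = carriers,
                      bmi_effect = config$bmi_effect))
  })
}

#' Generate a synthetic plasma metabolome with planted associations
#'
#' Picks `n_planted_associations` (reaction, metabolite) pairs — half with
#' positive, half with negative sign — and sets
#' `metabolite = effect * standardized log reaction abundance + covariate
#' terms + Gaussian noise`; all other metabolites are covariate signal plus
#' noise only.
#'
#' @param config a [synthetic_config()].
#' @param ra reaction-abundance table of the cohort to link (tibble with
#'   `sample_id`).
#' @param meta matching metadata (for the covariate terms).
#' @return list with `metabolome` (tibble `sample_id` + metabolite
#'   columns) and `truth` (tibble `reaction_id`, `metabolite_id`, `sign`).
#' @export
generate_metabolome <- function(config, ra, meta) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed * 7 + 4, {
    Z <- table_to_matrix(ra)
    meta <- meta[match(rownames(Z), meta$sample_id), ]
    n_s <- nrow(Z)
    usable <- colnames(Z)[apply(Z, 2, stats::sd) > 0]
    k <- config$n_planted_associations
    marker_first <- intersect(sort(config$marker_reaction_set), usable)
    reactions <- c(marker_first, sample(setdiff(usable, marker_first)))
    reactions <- reactions[((seq_len(k) - 1) %% length(reactions)) + 1]
    met_ids <- sprintf("met_%03d", seq_len(config$n_metabolites))
    planted_mets <- sample(met_ids, k)
    signs <- rep(c(1, -1), length.out = k)
    nonzero <- Z[Z > 0]
    eps <- if (length(nonzero)) min(nonzero) / 2 else 1e-9
    covar <- 0.01 * meta$age + 0.02 * meta$bmi +
      0.2 * as.numeric(meta$sex == "M")
    M <- matrix(stats::rnorm(n_s * config$n_metabolites, 0, config$noise_sd),
                n_s, config$n_metabolites,
                dimnames = list(rownames(Z), met_ids))
    M <- M + covar
    for (i in seq_len(k)) {
      z <- log(Z[, reactions[i]] + eps)
      zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
      M[, planted_mets[i]] <- M[, planted_mets[i]] +
        signs[i] * config$association_effect * zs
    }
    list(metabolome = matrix_to_table(M),
         truth = tibble::tibble(reaction_id = reactions,
                                metabolite_id = planted_mets,
                                sign = ifelse(signs > 0, "positive", "negative")))
  })
}

#' Generate the complete synthetic input set
#'
#' Runs every generator in order and (optionally) writes all inputs to
#' disk: one JSON model per species, abundance/metadata/metabolome TSVs,
#' the diet TSV, and a `truth.json` manifest describing every planted
#' effect.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; created if needed.
#' @return (invisibly when writing) a list with `gems`, `abundance`,
#'   `metadata`, `wellness`, `metabolome`, `diet` and `truth`.
#' @export
generate_all <- function(config, out_dir = NULL) {
  gg <- generate_toy_gems(config)
  ab <- generate_abundance(config, gg$truth)
  wl <- generate_wellness(config, gg$truth)
  dt <- high_fibre_diet()
  presence <- reaction_presence(gg$gems)
  ra_well <- compute_reaction_abundance(presence, wl$abundance)
  mb <- generate_metabolome(config, ra_well, wl$metadata)
  truth <- c(gg$truth[c("marker_reactions", "marker_kos",
                        "disease_species", "control_species")],
             list(species = gg$truth$species,
                  wellness = wl$truth,
                  associations = mb$truth))
  out <- list(gems = gg$gems, abundance = ab$abundance,
              metadata = ab$metadata, wellness = wl,
              metabolome = mb$metabolome, diet = dt, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "gems"), recursive = TRUE, showWarnings = FALSE)
    for (g in gg$gems)
      write_gem(g, file.path(out_dir, "gems", paste0(g$id, ".json")))
    write_tsv_quiet(ab$abundance, file.path(out_dir, "abundance.tsv"))
    write_tsv_quiet(ab$metadata, file.path(out_dir, "metadata.tsv"))
    write_tsv_quiet(wl$abundance, file.path(out_dir, "wellness_abundance.tsv"))
    write_tsv_quiet(wl$metadata, file.path(out_dir, "wellness_metadata.tsv"))
    write_tsv_quiet(mb$metabolome, file.path(out_dir, "metabolome.tsv"))
    write_diet(dt, file.path(out_dir, "diet.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
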