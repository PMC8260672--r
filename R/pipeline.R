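# End-to-end survey orchestration: read inputs (or take a synthetic bundle),
# gate, filter, classify, count, census, reconstruct ancestral counts, run the
# ordination and trait models, and write every table plus a provenance
# manifest. The pipeline is a pure function of (inputs, config, seed):
# rerunning with the same configuration reproduces byte-identical outputs.

#' Build a survey run configuration
#'
#' @param outdir output directory.
#' @param bundle in-memory bundle (e.g. from [simulate_survey()]); mutually
#'   exclusive with `input_dir`.
#' @param input_dir directory holding `<species>.domains.tsv`,
#'   `<species>.search.tsv`, `<species>.tm.tsv`, `tree.nwk`, `traits.csv`
#'   (the layout written by [write_survey_bundle()]).
#' @param thresholds a [threshold_config()].
#' @param rules a [prr_rules()].
#' @param model_list traits for [run_trait_models()].
#' @param pca_scale standardize variables in the PCA?
#' @param seed seed recorded in the manifest (the survey itself is
#'   deterministic; the seed feeds any simulation step the caller attaches).
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, bundle = NULL, input_dir = NULL,
                       thresholds = threshold_config(), rules = prr_rules(),
                       model_list = c("clade", "symbiotic", "colonial",
                                      "sessile"),
                       pca_scale = FALSE, seed = 1L) {
  if (is.null(bundle) && is.null(input_dir))
    stopf("run_config needs either `bundle` or `input_dir`")
  if (!is.null(input_dir)) {
    needed <- c(file.path(input_dir, "tree.nwk"),
                file.path(input_dir, "traits.csv"))
    miss <- needed[!file.exists(needed)]
    if (length(miss) > 0L)
      stopf("missing input file(s): %s", paste(miss, collapse = ", "))
  }
  structure(list(outdir = outdir, bundle = bundle, input_dir = input_dir,
                 thresholds = thresholds, rules = rules,
                 model_list = model_list, pca_scale = pca_scale,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_survey_inputs <- function(input_dir) {
  dom_files <- sort(list.files(input_dir, pattern = "\\.domains\\.tsv$",
                               full.names = TRUE))
  if (length(dom_files) == 0L)
    stopf("no *.domains.tsv files in %s", input_dir)
  species <- sub("\\.domains\\.tsv$", "", basename(dom_files))
  per_sp <- lapply(seq_along(species), function(i) {
    sp <- species[i]
    list(domain_hits = read_domain_table(dom_files[i], "generic_tsv",
                                         species = sp),
         search_hits = read_search_table(
           file.path(input_dir, paste0(sp, ".search.tsv"))),
         tm = read_tm_table(file.path(input_dir, paste0(sp, ".tm.tsv"))))
  })
  traits <- read_trait_table(file.path(input_dir, "traits.csv"))
  list(species = data.frame(species_id = species,
                            clade = traits$clade[
                              match(species, traits$species_id)],
                            stringsAsFactors = FALSE),
       domain_hits = do.call(rbind, lapply(per_sp, `[[`, "domain_hits")),
       search_hits = do.call(rbind, lapply(per_sp, `[[`, "search_hits")),
       tm = do.call(rbind, lapply(per_sp, `[[`, "tm")),
       tree = read_newick(file.path(input_dir, "tree.nwk")),
       traits = traits)
}

#' Run the full repertoire survey
#'
#' Executes every stage in order — search gate, per-domain filtering,
#' nine-category classification, per-species counting, NACHT and CTLD
#' domain-combination censuses, ancestral state reconstruction of the four
#' receptor type totals, PCA and the quasi-Poisson trait models — and writes
#' all result tables plus `manifest.json` (package version, configuration
#' hash, output checksums) to `config$outdir`. Any stage failure aborts with
#' the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with all in-memory results: `calls`, `counts`,
#'   `census_nacht`, `census_ctld`, `asr`, `pca`, `glm`, `arches`,
#'   `manifest`.
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  bundle <- config$bundle %||%
    stage("read_inputs", read_survey_inputs(config$input_dir))

  gated <- stage("gate", gate_candidates(bundle$search_hits,
                                         config$thresholds))
  arches <- stage("filter", suppressWarnings(
    build_architectures(bundle$domain_hits, bundle$tm, config$thresholds,
                        gated = gated)))
  arches_gated <- Filter(function(a) a$passed_search_gate, arches)
  calls <- stage("classify", classify_proteins(arches_gated, config$rules))
  counts <- stage("count", count_species(calls,
                                         manifest = bundle$species$species_id))

  with_focal <- function(vocab) {
    Filter(function(a) any(match_domain(a$domains$domain_name,
                                        config$rules[[vocab]])),
           arches_gated)
  }
  census_nacht <- stage("census_nacht",
                        domain_combination_census(with_focal("nacht_names"),
                                                  "NACHT", config$rules))
  census_ctld <- stage("census_ctld",
                       domain_combination_census(with_focal("ctld_names"),
                                                 "CTLD", config$rules))

  type_traits <- lapply(c(TLR = "TLR", RLR = "RLR", NLR = "NLR",
                          CTL = "CTL"), function(ty)
    stats::setNames(counts[[ty]], counts$species_id))
  asr <- stage("asr", asr_batch(bundle$tree, type_traits))

  cm <- as.matrix(counts[, c("TLR", "RLR", "NLR", "CTL")])
  rownames(cm) <- counts$species_id
  pca <- stage("pca", prr_pca(cm, scale = config$pca_scale))
  totals <- stats::setNames(counts$grand_total, counts$species_id)
  glm_tab <- stage("glm", suppressWarnings(
    run_trait_models(totals, bundle$traits, config$model_list)))

  manifest <- stage("write", write_survey_outputs(
    config, calls, counts, census_nacht, census_ctld, asr, pca, glm_tab))

  invisible(list(calls = calls, counts = counts,
                 census_nacht = census_nacht, census_ctld = census_ctld,
                 asr = asr, pca = pca, glm = glm_tab, arches = arches,
                 manifest = manifest))
}

write_survey_outputs <- function(config, calls, counts, census_nacht,
                                 census_ctld, asr, pca, glm_tab) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wcsv <- function(df, name, rn = FALSE) {
    utils::write.csv(df, file.path(out, name), row.names = rn)
  }
  wtsv(calls, "calls.tsv")
  wcsv(counts, "species_counts.csv")
  census_df <- function(cen) data.frame(domain_name = names(cen$census),
                                        n_proteins = unname(cen$census),
                                        stringsAsFactors = FALSE)
  wtsv(census_df(census_nacht), "census_nacht.tsv")
  wtsv(census_df(census_ctld), "census_ctld.tsv")
  wcsv(asr_table(asr), "asr_estimates.csv")
  wcsv(as.data.frame(pca$scores), "pca_scores.csv", rn = TRUE)
  wcsv(as.data.frame(pca$loadings), "pca_loadings.csv", rn = TRUE)
  wcsv(data.frame(component = seq_along(pca$explained_variance),
                  variance = pca$explained_variance,
                  proportion = pca$prop_variance), "pca_variance.csv")
  wcsv(glm_tab, "glm_summary.csv")

  cfg_repr <- utils::capture.output(utils::str(
    config[c("model_list", "pca_scale", "seed")], give.attr = FALSE))
  cfg_path <- file.path(out, "config.txt")
  writeLines(c(cfg_repr,
               sprintf("thresholds: %s",
                       paste(sprintf("%s=%g",
                                     names(config$thresholds)[1:3],
                                     unlist(config$thresholds[1:3])),
                             collapse = " "))), cfg_path)
  outputs <- c("calls.tsv", "species_counts.csv", "census_nacht.tsv",
               "census_ctld.tsv", "asr_estimates.csv", "pca_scores.csv",
               "pca_loadings.csv", "pca_variance.csv", "glm_summary.csv")
  manifest <- list(
    package = "prrsurvey",
    version = as.character(utils::packageVersion("prrsurvey")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    output_md5 = as.list(tools::md5sum(file.path(out, outputs))))
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Explain the filtering and classification of one protein
#'
#' Audit helper: reports, hit by hit, which threshold applied, whether the
#' hit was retained and under which rule (including the clan-unconfirmed
#' helicase context exception), then the classification branch taken.
#'
#' @param hits domain-hit rows of one protein.
#' @param tm TM table or `NULL`.
#' @param cfg a [threshold_config()].
#' @param rules a [prr_rules()].
#' @return character vector of decision lines, invisibly; also printed.
#' @export
explain_protein <- function(hits, tm = NULL, cfg = threshold_config(),
                            rules = prr_rules()) {
  arch <- filter_architecture(hits, tm, cfg)
  is_rep <- is_repeat_domain(hits$domain_name, cfg)
  thr <- ifelse(is_rep, cfg$repeat_ievalue_max, cfg$nonrepeat_ievalue_max)
  kept_key <- paste(arch$domains$domain_name, arch$domains$env_start)
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    verdict <- if (paste(h$domain_name, h$env_start) %in% kept_key)
      "retained" else if (h$i_evalue >= thr[i])
      sprintf("dropped (i_evalue %.3g >= %.3g)", h$i_evalue, thr[i])
    else if (!h$clan_confirmed)
      "dropped (clan not confirmed, no repressor-domain context)"
    else "dropped (merged into stronger same-family hit)"
    sprintf("%s [%s] %.3g vs %.3g (%s): %s", h$domain_name,
            if (is_rep[i]) "repeat" else "non-repeat", h$i_evalue, thr[i],
            if (h$clan_confirmed) "clan ok" else "no clan", verdict)
  }, character(1))
  call <- classify_protein(arch, rules)
  lines <- c(sprintf("protein %s (%d TM helices)", arch$protein_id,
                     arch$n_tm_helices),
             lines,
             sprintf("category: %s%s", call$category,
                     if (length(call$also_matches) > 0L)
                       paste0(" (also matches: ",
                              paste(call$also_matches, collapse = ", "), ")")
                     else ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
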