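# Nine-category PRR classification from filtered domain architectures.
#
# Categories (mutually exclusive, one per protein):
#   PROTO_TLR      TIR + LRR + transmembrane segment
#   TLR_LIKE       TIR + transmembrane segment
#   RIG_MDA5_LIKE  DExD/H helicase + CARD + C-terminal regulatory domain
#   LGP2_LIKE      DExD/H helicase + RIG-I repressor domain, no CARD
#   PROTO_NLR      NACHT + LRR
#   NLR_LIKE       NACHT
#   CTL_TM         C-type lectin domain + transmembrane segment
#   CTL_EXTRACELLULAR  CTLD + a domain indicative of extracellular localization
#   CTL_UNKNOWN    CTLD only
#
# Mutual exclusivity is enforced by a gate cascade: the first receptor-defining
# domain present (TIR -> helicase -> NACHT -> CTLD) claims the protein for its
# branch; a protein whose branch rules are not met classifies NONE rather than
# falling through, so e.g. a NACHT+TIR fusion is never counted as an NLR.
# Full-rule matches of the other branches are recorded in `also_matches`.

PRR_CATEGORIES <- c("PROTO_TLR", "TLR_LIKE", "RIG_MDA5_LIKE", "LGP2_LIKE",
                    "PROTO_NLR", "NLR_LIKE", "CTL_TM", "CTL_EXTRACELLULAR",
                    "CTL_UNKNOWN")
PRR_TYPE_OF <- c(PROTO_TLR = "TLR", TLR_LIKE = "TLR",
                 RIG_MDA5_LIKE = "RLR", LGP2_LIKE = "RLR",
                 PROTO_NLR = "NLR", NLR_LIKE = "NLR",
                 CTL_TM = "CTL", CTL_EXTRACELLULAR = "CTL",
                 CTL_UNKNOWN = "CTL")

#' Default classification rule set
#'
#' Domain-name vocabularies (case-insensitive glob patterns) for every family
#' class the receptor rules mention, plus the list of domain families treated
#' as indicative of extracellular localization (cysteine-rich secretory
#' domain, CUB, F5/8 type C, ShK, von Willebrand factors, thrombospondin,
#' trefoil, fibrinogen beta/gamma C-terminal globular, NIDO, PKD, coagulation
#' factor Xa inhibitory domain, U-PAR/Ly6, complement Clr-like EGF, Xlink).
#' Family naming drifts across annotation releases, so the vocabularies are a
#' versioned, overridable configuration rather than hard-coded constants.
#'
#' @param ... named vocabulary overrides (each a character vector of
#'   patterns).
#' @return an object of class `prr_rules`.
#' @export
prr_rules <- function(...) {
  defaults <- list(
    tir_names = c("TIR", "TIR_*", "TIR2"),
    lrr_names = c("LRR*"),
    nacht_names = c("NACHT"),
    helicase_names = c("DEAD", "Helicase_C", "ResIII", "DEXDc"),
    card_names = c("CARD", "CARD_*"),
    rig_ctd_names = c("RIG-I_C*"),
    rig_rd_names = c("RIG-I_C-RD"),
    ctld_names = c("Lectin_C", "CTLD"),
    collagen_names = c("Collagen*"),
    rdrp_names = c("RdRP*", "Mitovir_RNA_pol", "RNA_dep_RNAP"),
    transposon_names = c("RVT*", "rve", "Integrase*", "hATC",
                         "Dimer_Tnp_hAT"),
    extracellular_indicative = c(
      "CAP", "SCP",                       # cysteine-rich secretory domain
      "CUB",
      "F5_F8_type_C",
      "ShKT",
      "VWA", "VWC", "VWD", "vWF*",        # von Willebrand factors
      "TSP_1", "TSP_3", "TSP_C",          # thrombospondin
      "Trefoil",
      "Fibrinogen_C",
      "NIDO",
      "PKD", "PKD_*",
      "Antistasin",                       # factor Xa inhibitory domain
      "UPAR_LY6",
      "cEGF",                             # complement Clr-like EGF
      "Xlink"))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L)
    stopf("unknown rule vocabulary: %s", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "prr_rules")
}

#' Classify one protein architecture into a PRR category
#'
#' @param arch a `prr_architecture` from [filter_architecture()]; must have
#'   passed the search gate.
#' @param rules a [prr_rules()] rule set.
#' @return an object of class `prr_call`: list with `protein_id`,
#'   `species_id`, `category`, `flags` (subset of `MBL_LIKE`, `RDRP_FUSION`,
#'   `TRANSPOSON_DOMAIN`), `also_matches`, and `evidence` (retained
#'   `(domain_name, i_evalue)` pairs supporting the call).
#' @export
classify_protein <- function(arch, rules = prr_rules()) {
  stopifnot(inherits(arch, "prr_architecture"))
  if (!arch$passed_search_gate)
    stopf("protein '%s' failed the search gate and must not be classified",
          arch$protein_id)
  dn <- arch$domains$domain_name
  has <- function(v) any(match_domain(dn, rules[[v]]))
  tm <- arch$n_tm_helices >= 1L

  # full-rule match of every category, independent of gating
  sat <- c(
    PROTO_TLR = has("tir_names") && has("lrr_names") && tm,
    TLR_LIKE = has("tir_names") && tm,
    RIG_MDA5_LIKE = has("helicase_names") && has("card_names") &&
      has("rig_ctd_names"),
    LGP2_LIKE = has("helicase_names") && has("rig_rd_names") &&
      !has("card_names"),
    PROTO_NLR = has("nacht_names") && has("lrr_names"),
    NLR_LIKE = has("nacht_names"),
    CTL_TM = has("ctld_names") && tm,
    CTL_EXTRACELLULAR = has("ctld_names") && !tm &&
      any(match_domain(dn, rules$extracellular_indicative)),
    CTL_UNKNOWN = has("ctld_names") && !tm &&
      !any(match_domain(dn, rules$extracellular_indicative)))

  category <- "NONE"
  if (has("tir_names")) {
    category <- if (sat[["PROTO_TLR"]]) "PROTO_TLR"
      else if (sat[["TLR_LIKE"]]) "TLR_LIKE" else "NONE"
  } else if (has("helicase_names")) {
    category <- if (sat[["RIG_MDA5_LIKE"]]) "RIG_MDA5_LIKE"
      else if (sat[["LGP2_LIKE"]]) "LGP2_LIKE" else "NONE"
  } else if (has("nacht_names")) {
    category <- if (sat[["PROTO_NLR"]]) "PROTO_NLR" else "NLR_LIKE"
  } else if (has("ctld_names")) {
    category <- if (sat[["CTL_TM"]]) "CTL_TM"
      else if (sat[["CTL_EXTRACELLULAR"]]) "CTL_EXTRACELLULAR"
      else "CTL_UNKNOWN"
  }

  flags <- character(0)
  if (has("ctld_names") && has("collagen_names"))
    flags <- c(flags, "MBL_LIKE")
  if (category == "LGP2_LIKE" && has("rdrp_names"))
    flags <- c(flags, "RDRP_FUSION")
  if ((has("nacht_names") || has("ctld_names")) && has("transposon_names"))
    flags <- c(flags, "TRANSPOSON_DOMAIN")

  ev_vocab <- switch(category,
    PROTO_TLR = c("tir_names", "lrr_names"),
    TLR_LIKE = "tir_names",
    RIG_MDA5_LIKE = c("helicase_names", "card_names", "rig_ctd_names"),
    LGP2_LIKE = c("helicase_names", "rig_rd_names"),
    PROTO_NLR = c("nacht_names", "lrr_names"),
    NLR_LIKE = "nacht_names",
    CTL_TM = "ctld_names",
    CTL_EXTRACELLULAR = c("ctld_names", "extracellular_indicative"),
    CTL_UNKNOWN = "ctld_names",
    NONE = character(0))
  ev_idx <- if (length(ev_vocab) > 0L) {
    Reduce(`|`, lapply(ev_vocab, function(v) match_domain(dn, rules[[v]])))
  } else rep(FALSE, length(dn))
  evidence <- arch$domains[ev_idx, c("domain_name", "i_evalue"), drop = FALSE]
  rownames(evidence) <- NULL

  structure(list(protein_id = arch$protein_id, species_id = arch$species_id,
                 category = category, flags = flags,
                 also_matches = setdiff(names(sat)[sat], category),
                 evidence = evidence),
            class = "prr_call")
}

#' Classify a list of architectures
#'
#' @param arches list of `prr_architecture` objects (e.g. from
#'   [build_architectures()]); architectures that failed the search gate are
#'   skipped (they are not classifiable).
#' @param rules a [prr_rules()].
#' @return `data.frame` with one row per gated protein: `protein_id`,
#'   `species_id`, `category`, `flags` (comma-joined), `also_matches`
#'   (comma-joined), `n_domains`; the full `prr_call` objects are attached as
#'   attribute `"calls"`. Row order is by (species, protein), independent of
#'   input order.
#' @export
classify_proteins <- function(arches, rules = prr_rules()) {
  arches <- Filter(function(a) a$passed_search_gate, arches)
  calls <- lapply(arches, classify_protein, rules = rules)
  df <- data.frame(
    protein_id = vapply(calls, `[[`, character(1), "protein_id"),
    species_id = vapply(calls, function(c) c$species_id %||% NA_character_,
                        character(1)),
    category = vapply(calls, `[[`, character(1), "category"),
    flags = vapply(calls, function(c) paste(c$flags, collapse = ","),
                   character(1)),
    also_matches = vapply(calls, function(c)
      paste(c$also_matches, collapse = ","), character(1)),
    n_domains = vapply(arches, function(a) nrow(a$domains), integer(1)),
    stringsAsFactors = FALSE)
  o <- order(df$species_id, df$protein_id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "calls") <- calls[o]
  df
}

#' Per-species PRR count matrix
#'
#' Tallies classified proteins into the nine categories, the four receptor
#' type totals (TLR = prototypical + TLR-like; RLR = RIG-I/MDA5-like +
#' LGP2-like; NLR = prototypical + NLR-like; CTL = the three lectin groups)
#' and a grand total. Species listed in `manifest` but absent from the calls
#' are emitted as all-zero rows.
#'
#' @param calls `data.frame` from [classify_proteins()].
#' @param manifest optional character vector of species ids to guarantee rows
#'   for.
#' @return `data.frame` with one row per species: `species_id`, the nine
#'   category counts, `TLR`, `RLR`, `NLR`, `CTL`, `grand_total`.
#' @export
count_species <- function(calls, manifest = NULL) {
  species <- sort(unique(c(calls$species_id, manifest)))
  tab <- table(factor(calls$species_id, levels = species),
               factor(calls$category, levels = PRR_CATEGORIES))
  counts <- as.data.frame.matrix(tab)
  out <- data.frame(species_id = species, counts, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out$TLR <- out$PROTO_TLR + out$TLR_LIKE
  out$RLR <- out$RIG_MDA5_LIKE + out$LGP2_LIKE
  out$NLR <- out$PROTO_NLR + out$NLR_LIKE
  out$CTL <- out$CTL_TM + out$CTL_EXTRACELLULAR + out$CTL_UNKNOWN
  out$grand_total <- out$TLR + out$RLR + out$NLR + out$CTL
  rownames(out) <- NULL
  out
}

#' Census of domains found in combination with a focal domain
#'
#' Counts, over proteins whose retained architecture contains the focal
#' domain (NACHT or the C-type lectin domain), how many proteins carry each
#' co-occurring domain family. Counting is per protein, not per hit. Families
#' matching the focal vocabulary itself or any exclusion pattern (LRRs are
#' excluded for the NACHT census, following the survey convention) never
#' appear. Ties for the most common combination are reported in full.
#'
#' @param arches list of `prr_architecture`, each containing the focal
#'   domain (error otherwise).
#' @param focal `"NACHT"` or `"CTLD"`.
#' @param rules a [prr_rules()].
#' @param exclusions character vector of glob patterns to exclude
#'   (default: LRRs for the NACHT census, nothing for CTLD).
#' @return list with `census` (named integer vector, decreasing) and
#'   `most_common` (character vector; all ties).
#' @export
domain_combination_census <- function(arches, focal = c("NACHT", "CTLD"),
                                      rules = prr_rules(),
                                      exclusions = NULL) {
  focal <- match.arg(focal)
  focal_pats <- if (focal == "NACHT") rules$nacht_names else rules$ctld_names
  if (is.null(exclusions))
    exclusions <- if (focal == "NACHT") rules$lrr_names else character(0)
  per_protein <- lapply(arches, function(a) {
    dn <- a$domains$domain_name
    if (!any(match_domain(dn, focal_pats)))
      stopf("protein '%s' lacks the focal domain %s", a$protein_id, focal)
    fam <- unique(dn[!match_domain(dn, focal_pats) &
                       !match_domain(dn, exclusions)])
    fam
  })
  census <- table(unlist(per_protein))
  if (length(census) == 0L) {
    return(list(census = integer(0), most_common = character(0)))
  }
  census <- sort(census, decreasing = TRUE)
  v <- as.integer(census)
  names(v) <- names(census)
  list(census = v, most_common = sort(names(v)[v == max(v)]))
}
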