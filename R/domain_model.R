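# E-value inclusion thresholds and per-protein architecture assembly.
#
# Two independent stages mirror the survey's search procedure: a whole-protein
# homology gate on the alignment-query search (E < 10^-4.9, strict), then a
# per-domain filter on the profile-HMM annotation (non-repeat domains at the
# same strict 10^-4.9 threshold, repeat domains at 10^-3). A DExD/H-box
# helicase hit that failed clan confirmation is rescued only when the protein
# also carries a retained RIG-I repressor-domain hit.

#' Threshold configuration for candidate gating and domain filtering
#'
#' The defaults are the survey's published inclusion rules: whole-protein
#' search gate and non-repeat per-domain threshold both at `10^-4.9`
#' (~1.259e-5, applied strictly as `<`), repeat domains at `10^-3`.
#'
#' @param search_evalue_max whole-protein search-gate E-value bound.
#' @param nonrepeat_ievalue_max per-domain independent E-value bound for
#'   non-repeat families.
#' @param repeat_ievalue_max per-domain bound for repeat families (must be
#'   >= the non-repeat bound).
#' @param repeat_domain_patterns case-insensitive glob patterns naming the
#'   repeat families (leucine-rich repeats, ankyrin, WD40, sushi, TPR, EGF,
#'   collagen by default).
#' @param helicase_context_domains domain names whose retained presence
#'   licenses the clan-unconfirmed helicase exception (the RIG-I C-terminal
#'   repressor domain by default).
#' @param helicase_domain_patterns patterns identifying DExD/H-box
#'   helicase-class families, the only class the exception can rescue.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(search_evalue_max = 10^-4.9,
                             nonrepeat_ievalue_max = 10^-4.9,
                             repeat_ievalue_max = 1e-3,
                             repeat_domain_patterns = c("LRR*", "Ank*", "WD40",
                                                        "Sushi", "TPR*",
                                                        "EGF*", "Collagen*"),
                             helicase_context_domains = "RIG-I_C-RD",
                             helicase_domain_patterns = c("DEAD", "Helicase_C",
                                                          "ResIII", "DEXDc")) {
  stopifnot(search_evalue_max > 0, nonrepeat_ievalue_max > 0,
            repeat_ievalue_max > 0)
  if (repeat_ievalue_max < nonrepeat_ievalue_max)
    stopf("repeat threshold must be >= non-repeat threshold")
  structure(list(search_evalue_max = search_evalue_max,
                 nonrepeat_ievalue_max = nonrepeat_ievalue_max,
                 repeat_ievalue_max = repeat_ievalue_max,
                 repeat_domain_patterns = repeat_domain_patterns,
                 helicase_context_domains = helicase_context_domains,
                 helicase_domain_patterns = helicase_domain_patterns),
            class = "threshold_config")
}

#' Gate candidate proteins on the whole-protein search E-value
#'
#' A protein passes if at least one of its search hits has
#' `evalue < search_evalue_max` (strictly).
#'
#' @param search_hits `data.frame` with columns `query_id` (alignment query),
#'   `subject_id` (protein) and `evalue`, best-HSP collapsed.
#' @param cfg a [threshold_config()].
#' @return character vector of unique passing protein ids.
#' @export
gate_candidates <- function(search_hits, cfg = threshold_config()) {
  if (nrow(search_hits) == 0L) return(character(0))
  sort(unique(search_hits$subject_id[search_hits$evalue <
                                       cfg$search_evalue_max]))
}

#' Is a domain family a repeat family?
#'
#' @param domain_name character vector of family names.
#' @param cfg a [threshold_config()].
#' @return logical vector.
#' @export
is_repeat_domain <- function(domain_name, cfg = threshold_config()) {
  match_domain(domain_name, cfg$repeat_domain_patterns)
}

#' Filter a protein's domain hits into its retained architecture
#'
#' Applies the per-domain thresholds (strict `<`): repeat families against
#' `repeat_ievalue_max`, everything else against `nonrepeat_ievalue_max`.
#' Hits flagged `clan_confirmed = FALSE` are dropped, with one exception:
#' a helicase-class hit below threshold is retained when the protein also
#' carries a retained, clan-confirmed RIG-I repressor-domain hit. After
#' thresholding, retained hits of the same family that overlap each other by
#' more than 50% of both spans are merged, keeping the lower-E-value hit;
#' overlapping hits of different families are all kept. Retained domains are
#' returned sorted by start coordinate.
#'
#' @param hits domain-hit `data.frame` (one protein).
#' @param tm matching row of a TM table, or `NULL` for zero helices.
#' @param cfg a [threshold_config()].
#' @param passed_search_gate did the protein pass [gate_candidates()]?
#' @return an object of class `prr_architecture`: list with `protein_id`,
#'   `species_id`, `domains` (retained hits), `n_tm_helices`,
#'   `passed_search_gate`.
#' @export
filter_architecture <- function(hits, tm = NULL, cfg = threshold_config(),
                                passed_search_gate = TRUE) {
  pid <- unique(hits$protein_id)
  if (length(pid) > 1L)
    stopf("hits span multiple protein_ids: %s", paste(pid, collapse = ", "))
  if (length(pid) == 0L) stopf("no hits given; protein id unknown")
  sp <- unique(hits$species_id)[1]

  is_rep <- is_repeat_domain(hits$domain_name, cfg)
  below <- ifelse(is_rep, hits$i_evalue < cfg$repeat_ievalue_max,
                  hits$i_evalue < cfg$nonrepeat_ievalue_max)
  # clan-confirmed retained hits of the context (repressor) domain
  has_context <- any(below & hits$clan_confirmed &
                       match_domain(hits$domain_name,
                                    cfg$helicase_context_domains))
  is_helicase <- match_domain(hits$domain_name, cfg$helicase_domain_patterns)
  keep <- below & (hits$clan_confirmed | (is_helicase & has_context))
  kept <- hits[keep, , drop = FALSE]
  kept <- merge_same_family_overlaps(kept)
  kept <- kept[order(kept$env_start, kept$env_end, kept$domain_name), ,
               drop = FALSE]
  rownames(kept) <- NULL

  n_tm <- 0L
  if (!is.null(tm) && nrow(tm) > 0L) {
    row <- tm[tm$protein_id == pid, , drop = FALSE]
    if (nrow(row) > 0L) n_tm <- row$n_tm_helices[1]
  }
  structure(list(protein_id = pid, species_id = sp, domains = kept,
                 n_tm_helices = as.integer(n_tm),
                 passed_search_gate = isTRUE(passed_search_gate)),
            class = "prr_architecture")
}

# >50% mutual overlap within the same family -> keep the lower-i_evalue hit
merge_same_family_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  o <- order(hits$i_evalue, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  drop <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits) - 1L)) {
    if (drop[i]) next
    for (j in seq.int(i + 1L, nrow(hits))) {
      if (drop[j] || hits$domain_name[j] != hits$domain_name[i]) next
      ov <- min(hits$env_end[i], hits$env_end[j]) -
        max(hits$env_start[i], hits$env_start[j])
      li <- hits$env_end[i] - hits$env_start[i]
      lj <- hits$env_end[j] - hits$env_start[j]
      if (ov > 0.5 * li && ov > 0.5 * lj) drop[j] <- TRUE
    }
  }
  hits[!drop, , drop = FALSE]
}

#' Assemble filtered architectures for a whole annotation table
#'
#' Splits a domain-hit table by protein, applies [filter_architecture()] to
#' each, joins transmembrane-helix counts (proteins absent from the TM table
#' get zero helices, with a single summarizing warning), and marks which
#' proteins passed the search gate.
#'
#' @param domain_hits domain-hit `data.frame` (many proteins).
#' @param tm TM table from [read_tm_table()], or `NULL`.
#' @param cfg a [threshold_config()].
#' @param gated character vector of proteins that passed the search gate, or
#'   `NULL` to mark all proteins as gated.
#' @return named list of `prr_architecture` objects, one per protein.
#' @export
build_architectures <- function(domain_hits, tm = NULL,
                                cfg = threshold_config(), gated = NULL) {
  if (nrow(domain_hits) == 0L) return(list())
  by_prot <- split(domain_hits, domain_hits$protein_id)
  if (!is.null(tm)) {
    missing_tm <- setdiff(names(by_prot), tm$protein_id)
    if (length(missing_tm) > 0L)
      warnf("%d protein(s) absent from the TM table; assuming 0 helices",
            length(missing_tm))
  }
  out <- lapply(by_prot, function(h) {
    filter_architecture(h, tm, cfg,
                        passed_search_gate = is.null(gated) ||
                          h$protein_id[1] %in% gated)
  })
  out[order(names(out))]
}

#' @export
print.prr_architecture <- function(x, ...) {
  cat(sprintf("<prr_architecture> %s (%s): %d retained domain(s), %d TM helix(es)%s\n",
              x$protein_id, x$species_id %||% NA, nrow(x$domains),
              x$n_tm_helices,
              if (x$passed_search_gate) "" else " [failed search gate]"))
  if (nrow(x$domains) > 0L)
    cat(" ", paste(x$domains$domain_name, collapse = " - "), "\n")
  invisible(x)
}
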