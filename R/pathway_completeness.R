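# Downstream pathway survey: NF-kB / IkB-alpha architecture typing,
# reciprocal-best-hit presence calls for pathway members, complement-family
# assignment, and per-clade presence fractions.

NFKB_CLASSES <- c("NFKB_FULL", "NFKB_ANK", "NFKB_MINIMAL", "IKBA", "NONE")
COMPLEMENT_FAMILIES <- c("C3", "BF_C2", "MASP", "C6", "NONE")

#' Vocabulary for NF-kB / IkB-alpha architecture typing
#'
#' @param ... named overrides, as in [prr_rules()].
#' @return list of glob-pattern vocabularies.
#' @export
nfkb_rules <- function(...) {
  defaults <- list(
    rel_dna_names = c("RHD", "RHD_DNA_bind"),   # Rel homology DNA-binding
    rel_dimer_names = c("RHD_dimer", "TIG", "IPT*"),
    ankyrin_names = c("Ank*"),
    death_names = c("Death"))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L)
    stopf("unknown NF-kB vocabulary: %s", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  defaults
}

#' Classify a candidate protein's NF-kB / IkB-alpha architecture
#'
#' Classes are ordered by domain-set inclusion and the most complete
#' satisfied class wins: `NFKB_FULL` (Rel DNA-binding + Rel dimerization +
#' ankyrin repeats + death domain), `NFKB_ANK` (without the death domain),
#' `NFKB_MINIMAL` (Rel DNA-binding + dimerization only — the minimal
#' requirement, motivated by the known truncated cnidarian NF-kB), and
#' `IKBA` (at least two retained ankyrin repeats on a protein recovered by
#' the IkB-alpha query). "Multiple ankyrin repeats" is read as >= 2.
#'
#' @param arch a `prr_architecture` (candidate from the top-k query hits).
#' @param rules an [nfkb_rules()] vocabulary.
#' @param ikba_candidate was this protein retrieved by the IkB-alpha query?
#' @return list with `protein_id`, `class`, `n_ankyrin`.
#' @export
classify_nfkb <- function(arch, rules = nfkb_rules(), ikba_candidate = FALSE) {
  dn <- arch$domains$domain_name
  has_dna <- any(match_domain(dn, rules$rel_dna_names))
  has_dim <- any(match_domain(dn, rules$rel_dimer_names))
  n_ank <- sum(match_domain(dn, rules$ankyrin_names))
  has_death <- any(match_domain(dn, rules$death_names))
  cls <- if (has_dna && has_dim && n_ank >= 1L && has_death) "NFKB_FULL"
    else if (has_dna && has_dim && n_ank >= 1L) "NFKB_ANK"
    else if (has_dna && has_dim) "NFKB_MINIMAL"
    else if (ikba_candidate && n_ank >= 2L) "IKBA"
    else "NONE"
  list(protein_id = arch$protein_id, class = cls, n_ankyrin = n_ank)
}

#' Vocabulary and required multisets for the complement families
#'
#' @param ... named overrides.
#' @return list of glob-pattern vocabularies.
#' @export
complement_rules <- function(...) {
  defaults <- list(
    macroglobulin_names = c("A2M*", "MG1", "MG2", "MG3", "MG4",
                            "Macroglobulin*"),
    cub_names = c("CUB"),
    c345c_names = c("C345C"),
    sushi_names = c("Sushi"),
    vwf_names = c("VWA", "VWC", "VWD", "vWF*"),
    serine_protease_names = c("Trypsin", "Trypsin_2", "Peptidase_S1*"),
    tsp_names = c("TSP_1", "TSP_3", "TSP_C"),
    ldla_names = c("Ldl_recept_a"),
    macpf_names = c("MACPF"))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L)
    stopf("unknown complement vocabulary: %s", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  defaults
}

#' Assign a candidate protein to a complement family
#'
#' Required domain multisets ("multiple" read as >= 2):
#' * `C3`: >= 2 macroglobulin + >= 1 CUB + >= 1 C345c
#' * `MASP`: >= 2 CUB + >= 1 sushi + >= 1 serine protease
#' * `BF_C2` (Factor B / C2): >= 1 sushi + >= 1 von Willebrand factor +
#'   >= 1 serine protease
#' * `C6`: >= 1 each of thrombospondin, LDL-receptor class A, MACPF, sushi
#'
#' MASP is tested before Factor B/C2 because its rule is the more specific
#' of the two. Families missing exactly one required component are reported
#' as near-misses in `partial` (e.g. an architecture with all C3 domains but
#' no C345c).
#'
#' @param arch a `prr_architecture`.
#' @param rules a [complement_rules()] vocabulary.
#' @return list with `protein_id`, `family`, `partial` (families one
#'   component short), `evidence` (retained domain names).
#' @export
classify_complement <- function(arch, rules = complement_rules()) {
  dn <- arch$domains$domain_name
  n <- function(v) sum(match_domain(dn, rules[[v]]))
  comp <- list(
    C3 = c(n("macroglobulin_names") >= 2L, n("cub_names") >= 1L,
           n("c345c_names") >= 1L),
    MASP = c(n("cub_names") >= 2L, n("sushi_names") >= 1L,
             n("serine_protease_names") >= 1L),
    BF_C2 = c(n("sushi_names") >= 1L, n("vwf_names") >= 1L,
              n("serine_protease_names") >= 1L),
    C6 = c(n("tsp_names") >= 1L, n("ldla_names") >= 1L,
           n("macpf_names") >= 1L, n("sushi_names") >= 1L))
  sat <- vapply(comp, all, logical(1))
  family <- if (any(sat)) names(sat)[which(sat)[1]] else "NONE"
  partial <- names(comp)[vapply(comp, function(x) sum(!x) == 1L, logical(1))]
  if (family != "NONE") partial <- setdiff(partial, family)
  list(protein_id = arch$protein_id, family = family, partial = partial,
       evidence = unique(dn))
}

#' Reciprocal-best-hit presence call for one pathway member
#'
#' Forward direction: among hits of the member's human query (or queries)
#' against the species proteome, take the strongest hit (lowest E-value,
#' ties broken by higher bitscore). Backward direction: that protein's
#' strongest hit against the human proteome. The member is present iff the
#' backward best hit is unique and is one of the member's query ids. Any
#' remaining tie, or a missing hit in either direction, yields absent —
#' ambiguity is not evidence of presence.
#'
#' @param forward search table (human query -> species proteins), best-HSP
#'   collapsed, columns `query_id`, `subject_id`, `evalue`, `bitscore`.
#' @param backward search table (species protein -> human proteome).
#' @param member list with `member_name` and `query_ids` (character).
#' @param species_id species the tables belong to.
#' @return one-row `data.frame`: `species_id`, `member_name`, `present`,
#'   `cnidarian_protein`, `human_best_hit`.
#' @export
reciprocal_presence <- function(forward, backward, member,
                                species_id = NA_character_) {
  stopifnot(is.list(member), !is.null(member$member_name))
  qids <- member$query_ids
  present <- FALSE; prot <- NA_character_; back_hit <- NA_character_
  for (q in qids) {
    fwd <- forward[forward$query_id == q, , drop = FALSE]
    p <- best_subject(fwd)
    if (is.na(p)) next
    bwd <- backward[backward$query_id == p, , drop = FALSE]
    h <- best_subject(bwd)
    if (is.na(h)) next
    prot <- p; back_hit <- h
    if (h %in% qids) { present <- TRUE; break }
  }
  data.frame(species_id = species_id, member_name = member$member_name,
             present = present,
             cnidarian_protein = if (present) prot else NA_character_,
             human_best_hit = if (present) back_hit else NA_character_,
             stringsAsFactors = FALSE)
}

# unique best subject: lowest evalue, then highest bitscore; NA on a residual
# tie or empty table
best_subject <- function(hits) {
  if (nrow(hits) == 0L) return(NA_character_)
  best_e <- min(hits$evalue)
  cand <- hits[hits$evalue == best_e, , drop = FALSE]
  if (nrow(cand) > 1L) {
    best_b <- max(cand$bitscore)
    cand <- cand[cand$bitscore == best_b, , drop = FALSE]
  }
  if (length(unique(cand$subject_id)) != 1L) return(NA_character_)
  cand$subject_id[1]
}

#' Presence calls for every member of a pathway in one species
#'
#' @param forward,backward as in [reciprocal_presence()].
#' @param pathway list with `pathway_id` and `members` (list of
#'   `list(member_name, query_ids)`).
#' @param species_id species identifier.
#' @return `data.frame`, one row per member.
#' @export
pathway_presence <- function(forward, backward, pathway,
                             species_id = NA_character_) {
  nm <- vapply(pathway$members, `[[`, character(1), "member_name")
  if (anyDuplicated(nm))
    stopf("duplicate member name '%s' in pathway '%s'",
          nm[duplicated(nm)][1], pathway$pathway_id %||% "?")
  do.call(rbind, lapply(pathway$members, reciprocal_presence,
                        forward = forward, backward = backward,
                        species_id = species_id))
}

#' Built-in pathway member definitions
#'
#' Reads the packaged YAML describing the PRR-to-NF-kB signalling pathway
#' members and the lectin-complement pathway (member name and the human query
#' identifiers used for the reciprocal search). Editable: pass your own file.
#'
#' @param path YAML file; default is the copy shipped with the package.
#' @return named list of pathways, each `list(pathway_id, members)`.
#' @export
pathway_defs <- function(path = system.file("extdata", "pathways.yaml",
                                            package = "prrsurvey")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) {
    list(pathway_id = p$pathway_id,
         members = lapply(p$members, function(m)
           list(member_name = m$member_name,
                query_ids = as.character(m$query_ids))))
  })
}

#' Fraction of species in each group carrying each pathway member
#'
#' @param calls `data.frame` of presence calls (rows from
#'   [pathway_presence()] across species).
#' @param traits trait table ([read_trait_table()]); every species in
#'   `calls` must appear.
#' @param group_by name of the grouping column in `traits` (default
#'   `"clade"`).
#' @return `data.frame` `member_name` x group with columns `member_name`,
#'   `group`, `n_present`, `n_group`, `fraction` (in `[0, 1]`; `NA` and
#'   flagged when a group has zero species).
#' @export
presence_fractions <- function(calls, traits, group_by = "clade") {
  miss <- setdiff(unique(calls$species_id), traits$species_id)
  if (length(miss) > 0L)
    stopf("species missing from trait table: %s", paste(miss, collapse = ", "))
  grp <- traits[[group_by]][match(calls$species_id, traits$species_id)]
  groups <- sort(unique(as.character(traits[[group_by]])))
  members <- unique(calls$member_name)
  out <- expand.grid(member_name = members, group = groups,
                     stringsAsFactors = FALSE)
  out$n_present <- mapply(function(m, g) {
    sum(calls$present[calls$member_name == m & grp == g])
  }, out$member_name, out$group)
  out$n_group <- vapply(out$group, function(g) {
    length(unique(calls$species_id[grp == g]))
  }, integer(1))
  out$fraction <- ifelse(out$n_group > 0L, out$n_present / out$n_group, NA)
  out
}
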