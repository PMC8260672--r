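# Ground-truth fixture generator.
#
# Plants domain architectures that satisfy exactly one classification rule
# among near-miss decoys that satisfy none: architectures one domain short of
# a rule, hits with E-values just above the inclusion threshold (log-uniform
# in (threshold, 10x threshold), stressing the strict `<`), clan-unconfirmed
# helicases without the rescuing repressor-domain context, and proteins whose
# whole-protein search E-value misses the gate. Also simulates Brownian
# traits on trees, overdispersed trait-linked counts, and reciprocal-hit
# tables with planted orthologs.

# one planted architecture per category: list of (domain, log10 E window,
# clan) rows laid out left to right with 10-residue gaps (layout is cosmetic;
# the rules are order-insensitive, but a fixed layout keeps files
# reproducible)
PLANT_RECIPES <- list(
  PROTO_TLR = list(tm = 1L, domains = list(
    c("LRR_8", "strict"), c("LRR_8", "strict"), c("LRR_8", "repeat"),
    c("TIR", "strict"))),
  TLR_LIKE = list(tm = 1L, domains = list(c("TIR", "strict"))),
  RIG_MDA5_LIKE = list(tm = 0L, domains = list(
    c("CARD", "strict"), c("CARD", "strict"), c("DEAD", "strict"),
    c("Helicase_C", "strict"), c("RIG-I_C-RD", "strict"))),
  LGP2_LIKE = list(tm = 0L, domains = list(
    c("DEAD", "strict"), c("Helicase_C", "strict"),
    c("RIG-I_C-RD", "strict"))),
  PROTO_NLR = list(tm = 0L, domains = list(
    c("NACHT", "strict"), c("LRR_8", "strict"), c("LRR_8", "repeat"),
    c("LRR_8", "strict"))),
  NLR_LIKE = list(tm = 0L, domains = list(
    c("NACHT", "strict"), c("HEPN", "strict"))),
  CTL_TM = list(tm = 1L, domains = list(c("Lectin_C", "strict"))),
  CTL_EXTRACELLULAR = list(tm = 0L, domains = list(
    c("Lectin_C", "strict"), c("CUB", "strict"))),
  CTL_UNKNOWN = list(tm = 0L, domains = list(c("Lectin_C", "strict"))),
  # non-PRR architectures (classify NONE); usable as planted pathway members
  NFKB_FULL = list(tm = 0L, prr = "NONE", domains = list(
    c("RHD", "strict"), c("TIG", "strict"), c("Ank_2", "repeat"),
    c("Ank_2", "strict"), c("Death", "strict"))),
  NFKB_ANK = list(tm = 0L, prr = "NONE", domains = list(
    c("RHD", "strict"), c("TIG", "strict"), c("Ank_2", "strict"),
    c("Ank_2", "strict"))),
  NFKB_MINIMAL = list(tm = 0L, prr = "NONE", domains = list(
    c("RHD", "strict"), c("TIG", "strict"))),
  IKBA = list(tm = 0L, prr = "NONE", domains = list(
    c("Ank_2", "strict"), c("Ank_2", "strict"), c("Ank_2", "strict"))),
  C3 = list(tm = 0L, prr = "NONE", domains = list(
    c("A2M", "strict"), c("A2M", "strict"), c("CUB", "strict"),
    c("C345C", "strict"))),
  BF_C2 = list(tm = 0L, prr = "NONE", domains = list(
    c("Sushi", "strict"), c("VWA", "strict"), c("Trypsin", "strict"))),
  MASP = list(tm = 0L, prr = "NONE", domains = list(
    c("CUB", "strict"), c("CUB", "strict"), c("Sushi", "strict"),
    c("Trypsin", "strict"))),
  C6 = list(tm = 0L, prr = "NONE", domains = list(
    c("TSP_1", "strict"), c("Ldl_recept_a", "strict"),
    c("MACPF", "strict"), c("Sushi", "strict"))))

DECOY_RECIPES <- list(
  # TIR + LRR but no TM: enters the TLR branch, satisfies neither TLR rule
  tlr_no_tm = list(tm = 0L, gate = TRUE, domains = list(
    c("LRR_8", "strict"), c("TIR", "strict"))),
  # NACHT with i-Evalue just above the strict non-repeat threshold
  evalue_boundary = list(tm = 0L, gate = TRUE, domains = list(
    c("NACHT", "above"))),
  # clan-unconfirmed helicase without the repressor-domain context
  helicase_noclan = list(tm = 0L, gate = TRUE, domains = list(
    c("DEAD", "strict", "noclan"), c("Helicase_C", "strict", "noclan"))),
  # sound architecture, but the whole-protein search E-value misses the gate
  gate_fail = list(tm = 1L, gate = FALSE, domains = list(
    c("TIR", "strict"), c("LRR_8", "strict"))),
  # repeat-family hit above even the relaxed repeat threshold
  lrr_above = list(tm = 1L, gate = TRUE, domains = list(
    c("LRR_8", "repeat_above"), c("TIR", "above"))))

#' Specification of a planted synthetic proteome
#'
#' @param species_id species identifier.
#' @param counts named integer vector: how many proteins to plant per
#'   category (names from `names(plant_recipes())`, e.g. the nine PRR
#'   categories plus NF-kB classes and complement families).
#' @param decoys named integer vector over decoy kinds `tlr_no_tm`,
#'   `evalue_boundary`, `helicase_noclan`, `gate_fail`, `lrr_above`.
#' @param seed RNG seed for E-value draws.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(species_id, counts = integer(0), decoys = integer(0),
                       seed = 1L) {
  bad <- setdiff(names(counts), names(PLANT_RECIPES))
  if (length(bad) > 0L)
    stopf("unknown planted category: %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(decoys), names(DECOY_RECIPES))
  if (length(bad) > 0L)
    stopf("unknown decoy kind: %s", paste(bad, collapse = ", "))
  structure(list(species_id = species_id,
                 counts = counts[counts > 0],
                 decoys = decoys[decoys > 0],
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Names of the architectures the generator can plant
#' @return character vector of category names.
#' @export
plant_recipes <- function() names(PLANT_RECIPES)

# E-value draw per window, given the thresholds in force
draw_evalue <- function(kind, cfg) {
  thr_n <- cfg$nonrepeat_ievalue_max
  thr_r <- cfg$repeat_ievalue_max
  switch(kind,
    strict = 10^stats::runif(1, -12, log10(thr_n) - 0.2),
    # repeat-family hit between the strict and the relaxed threshold
    "repeat" = 10^stats::runif(1, log10(thr_n) + 0.05, log10(thr_r) - 0.05),
    above = 10^stats::runif(1, log10(thr_n), log10(thr_n) + 1),
    repeat_above = 10^stats::runif(1, log10(thr_r), log10(thr_r) + 1),
    stopf("unknown E-value window '%s'", kind))
}

#' Generate synthetic proteome tables from a plant specification
#'
#' Emits a whole-protein search-hit table, a per-domain annotation table, a
#' TM summary covering every protein, and a truth table. Running
#' [gate_candidates()], [build_architectures()] and [classify_proteins()]
#' over the output reproduces the truth exactly: planted architectures get
#' their category, decoys get `NONE` (or are excluded by the gate, truth
#' category `UNGATED`). Planted per-domain E-values are drawn strictly below
#' threshold; decoy E-values log-uniformly in (threshold, 10x threshold).
#' Every second planted LGP2-like protein carries clan-unconfirmed helicase
#' hits, exercising the repressor-domain context exception.
#'
#' @param spec a [plant_spec()].
#' @param cfg a [threshold_config()] (defines the thresholds the draws
#'   bracket).
#' @return list with `search_hits`, `domain_hits`, `tm`, `truth`
#'   (`protein_id`, `species_id`, `category`, `planted_as`).
#' @export
generate_proteome_tables <- function(spec, cfg = threshold_config()) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    sp <- spec$species_id
    gate <- cfg$search_evalue_max
    rows <- list(); search <- list(); tmrec <- list(); truth <- list()
    serial <- 0L

    emit <- function(recipe, planted_as, truth_cat, gate_ok,
                     noclan_helicase = FALSE) {
      serial <<- serial + 1L
      pid <- sprintf("%s_p%04d", sp, serial)
      pos <- 0L
      dr <- lapply(recipe$domains, function(d) {
        len <- 60L + (nchar(d[1]) * 7L) %% 80L   # fixed per-family length
        start <- pos; pos <<- pos + len + 10L
        clan <- !(length(d) >= 3L && d[3] == "noclan") &&
          !(noclan_helicase && d[1] %in% c("DEAD", "Helicase_C"))
        data.frame(protein_id = pid, species_id = sp, domain_name = d[1],
                   clan_confirmed = clan,
                   i_evalue = draw_evalue(d[2], cfg),
                   env_start = start, env_end = start + len,
                   bitscore = round(stats::runif(1, 20, 300), 1),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <<- do.call(rbind, dr)
      sev <- if (gate_ok) 10^stats::runif(1, -30, log10(gate) - 0.2)
             else 10^stats::runif(1, log10(gate), log10(gate) + 1)
      search[[length(search) + 1L]] <<- data.frame(
        query_id = "prr_alignment", subject_id = pid, evalue = sev,
        bitscore = round(stats::runif(1, 30, 800), 1),
        stringsAsFactors = FALSE)
      tmrec[[length(tmrec) + 1L]] <<- data.frame(
        protein_id = pid, n_tm_helices = recipe$tm,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        protein_id = pid, species_id = sp, category = truth_cat,
        planted_as = planted_as, stringsAsFactors = FALSE)
    }

    for (cat in names(spec$counts)) {
      recipe <- PLANT_RECIPES[[cat]]
      truth_cat <- recipe$prr %||% cat
      for (i in seq_len(spec$counts[[cat]])) {
        emit(recipe, cat, truth_cat, gate_ok = TRUE,
             noclan_helicase = (cat == "LGP2_LIKE" && i %% 2L == 0L))
      }
    }
    for (dk in names(spec$decoys)) {
      recipe <- DECOY_RECIPES[[dk]]
      for (i in seq_len(spec$decoys[[dk]])) {
        emit(recipe, dk, if (recipe$gate) "NONE" else "UNGATED",
             gate_ok = recipe$gate)
      }
    }

    bind <- function(l, proto) if (length(l) > 0L) do.call(rbind, l) else proto
    list(search_hits = bind(search,
                            data.frame(query_id = character(),
                                       subject_id = character(),
                                       evalue = numeric(),
                                       bitscore = numeric())),
         domain_hits = bind(rows, empty_domain_table()),
         tm = {
           t <- bind(tmrec, data.frame(protein_id = character(),
                                       n_tm_helices = integer()))
           t$helix_spans <- I(lapply(t$n_tm_helices, function(k)
             if (k > 0L) cbind(seq_len(k) * 100L - 100L,
                               seq_len(k) * 100L - 77L)
             else matrix(integer(0), ncol = 2)))
           t
         },
         truth = bind(truth, data.frame(protein_id = character(),
                                        species_id = character(),
                                        category = character(),
                                        planted_as = character())))
  })
}

#' Simulate Brownian motion along a tree
#'
#' Increments along each branch are independent normal with variance
#' `sigma2 * branch_length`; internal true states are recorded for
#' recovery tests. `sigma2 = 0` leaves every node at the root state.
#'
#' @param tree an [ape] `phylo` tree with branch lengths.
#' @param root root state.
#' @param sigma2 Brownian rate (>= 0).
#' @param seed RNG seed.
#' @return list with `tips` (named vector over tip labels) and
#'   `node_states` (named by node number, internal nodes).
#' @export
simulate_bm <- function(tree, root, sigma2, seed = 1L) {
  stopifnot(sigma2 >= 0)
  validate_tree(tree)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    tree <- ape::reorder.phylo(tree, "cladewise")
    states <- numeric(ntip + tree$Nnode)
    states[ntip + 1L] <- root
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      states[child] <- states[par] +
        stats::rnorm(1, 0, sqrt(sigma2 * tree$edge.length[e]))
    }
    tips <- stats::setNames(states[seq_len(ntip)], tree$tip.label)
    internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
    list(tips = tips,
         node_states = stats::setNames(states[internal],
                                       as.character(internal)))
  })
}

#' Simulate overdispersed trait-linked counts
#'
#' Counts are drawn from a gamma-Poisson mixture with mean
#' `exp(beta0 + beta1 * trait)` and variance `dispersion * mean`
#' (`dispersion = 1` reduces to pure Poisson noise).
#'
#' @param trait logical/0-1 vector (named or not).
#' @param beta0,beta1 log-scale intercept and trait effect.
#' @param dispersion variance inflation factor (>= 1; error below 1).
#' @param seed RNG seed.
#' @return integer vector of counts, names preserved.
#' @export
simulate_glm_counts <- function(trait, beta0, beta1, dispersion = 1,
                                seed = 1L) {
  if (dispersion < 1) stopf("dispersion must be >= 1")
  with_seed(seed, {
    mu <- exp(beta0 + beta1 * as.numeric(trait))
    lam <- if (dispersion == 1) mu else
      stats::rgamma(length(mu), shape = mu / (dispersion - 1),
                    scale = dispersion - 1)
    stats::setNames(stats::rpois(length(mu), lam), names(trait))
  })
}

#' Generate forward/backward search tables with planted orthologs
#'
#' Planted pairs are mutual best hits; one-way decoys have a forward best
#' whose backward best is a different human protein; tie decoys produce an
#' exact backward tie in both E-value and bitscore, which the reciprocal
#' rule must call absent. Background hits are weaker than every planted or
#' decoy hit.
#'
#' @param n_planted number of mutual-best-hit pairs.
#' @param n_oneway number of one-directional decoys.
#' @param n_tie number of exact-tie decoys.
#' @param n_background weak background hits per query.
#' @param seed RNG seed.
#' @return list with `forward`, `backward` (search tables), `members`
#'   (one per query, for [reciprocal_presence()]) and `truth`
#'   (`member_name`, `present`).
#' @export
generate_rbh_tables <- function(n_planted = 3L, n_oneway = 2L, n_tie = 1L,
                                n_background = 2L, seed = 1L) {
  with_seed(seed, {
    fw <- list(); bw <- list(); truth <- list()
    add <- function(l, q, s, e, b) {
      l[[length(l) + 1L]] <- data.frame(query_id = q, subject_id = s,
                                        evalue = e, bitscore = b,
                                        stringsAsFactors = FALSE)
      l
    }
    total <- n_planted + n_oneway + n_tie
    kind <- rep(c("planted", "oneway", "tie"),
                c(n_planted, n_oneway, n_tie))
    for (i in seq_len(total)) {
      q <- sprintf("HQ%02d", i); p <- sprintf("SP%02d", i)
      strong <- 10^stats::runif(1, -80, -40)
      fw <- add(fw, q, p, strong, 500)
      for (b in seq_len(n_background)) {
        fw <- add(fw, q, sprintf("SP%02d", total + b),
                  10^stats::runif(1, -20, -6), 80)
        bw <- add(bw, p, sprintf("HQ%02d", total + b),
                  10^stats::runif(1, -20, -6), 80)
      }
      if (kind[i] == "planted") {
        bw <- add(bw, p, q, strong, 500)
      } else if (kind[i] == "oneway") {
        bw <- add(bw, p, sprintf("HQ%02d", total + n_background + 1L),
                  strong, 500)
      } else {  # exact backward tie
        bw <- add(bw, p, q, 1e-30, 200)
        bw <- add(bw, p, sprintf("HQ%02d", total + n_background + 2L),
                  1e-30, 200)
      }
      truth[[i]] <- data.frame(member_name = q,
                               present = kind[i] == "planted",
                               stringsAsFactors = FALSE)
    }
    list(forward = collapse_best_hsp(do.call(rbind, fw)),
         backward = collapse_best_hsp(do.call(rbind, bw)),
         members = lapply(seq_len(total), function(i)
           list(member_name = sprintf("HQ%02d", i),
                query_ids = sprintf("HQ%02d", i))),
         truth = do.call(rbind, truth))
  })
}

# clade-typical planted-count ranges for the full synthetic survey;
# scaled to the magnitudes seen across cnidarian proteome surveys
# (anthozoans carry expanded NLR/CTL repertoires, medusozoans lack RLRs and
# prototypical NLRs, the outgroup is modest throughout)
CLADE_COUNT_RANGES <- list(
  anthozoa = list(PROTO_TLR = c(0, 10), TLR_LIKE = c(2, 20),
                  RIG_MDA5_LIKE = c(2, 15), LGP2_LIKE = c(0, 1),
                  PROTO_NLR = c(3, 30), NLR_LIKE = c(20, 90),
                  CTL_TM = c(5, 25), CTL_EXTRACELLULAR = c(15, 60),
                  CTL_UNKNOWN = c(10, 40)),
  medusozoa = list(PROTO_TLR = c(0, 0), TLR_LIKE = c(0, 6),
                   RIG_MDA5_LIKE = c(0, 0), LGP2_LIKE = c(0, 0),
                   PROTO_NLR = c(0, 0), NLR_LIKE = c(0, 15),
                   CTL_TM = c(2, 10), CTL_EXTRACELLULAR = c(5, 20),
                   CTL_UNKNOWN = c(3, 15)),
  outgroup = list(PROTO_TLR = c(0, 1), TLR_LIKE = c(1, 3),
                  RIG_MDA5_LIKE = c(0, 0), LGP2_LIKE = c(1, 1),
                  PROTO_NLR = c(1, 4), NLR_LIKE = c(5, 20),
                  CTL_TM = c(1, 5), CTL_EXTRACELLULAR = c(2, 8),
                  CTL_UNKNOWN = c(1, 5)))

#' Generate the full synthetic multi-species survey bundle
#'
#' Builds a 15-species study system: one sponge-like outgroup, six
#' medusozoan-like and eight anthozoan-like species, with per-species
#' planted PRR counts drawn uniformly from clade-typical ranges (anthozoans
#' with expanded NLR and lectin repertoires, medusozoans without RLRs or
#' prototypical NLRs), near-miss decoys in every species, a rooted
#' clade-structured coalescent tree, and a deterministic life-history trait
#' table (anthozoans sessile, mostly symbiotic and colonial).
#'
#' @param seed RNG seed controlling every random draw.
#' @param n_anthozoa,n_medusozoa species per clade.
#' @param outgroup include an outgroup species?
#' @param decoys named integer vector of decoys planted in every species.
#' @param outdir if non-`NULL`, the bundle is also written to disk
#'   (per-species headered domain/search/TM TSVs, `tree.nwk`, `traits.csv`,
#'   `truth.json`).
#' @return list with `species`, `domain_hits`, `search_hits`, `tm`, `truth`,
#'   `tree`, `traits` and `planted_counts` (species x category truth
#'   matrix).
#' @export
simulate_survey <- function(seed = 1L, n_anthozoa = 8L, n_medusozoa = 6L,
                            outgroup = TRUE,
                            decoys = c(tlr_no_tm = 3L, evalue_boundary = 3L,
                                       helicase_noclan = 2L, gate_fail = 2L,
                                       lrr_above = 1L),
                            outdir = NULL) {
  species <- data.frame(
    species_id = c(if (outgroup) "outgroup_01",
                   sprintf("medusozoa_%02d", seq_len(n_medusozoa)),
                   sprintf("anthozoa_%02d", seq_len(n_anthozoa))),
    clade = c(if (outgroup) "outgroup",
              rep("medusozoa", n_medusozoa), rep("anthozoa", n_anthozoa)),
    stringsAsFactors = FALSE)

  planted <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
      rng <- CLADE_COUNT_RANGES[[species$clade[i]]]
      vapply(rng, function(r) {
        as.integer(round(stats::runif(1, r[1], r[2])))
      }, integer(1))
    }))
  })
  rownames(planted) <- species$species_id

  bundles <- lapply(seq_len(nrow(species)), function(i) {
    generate_proteome_tables(
      plant_spec(species$species_id[i], counts = planted[i, ],
                 decoys = decoys, seed = seed + i))
  })
  cat_bind <- function(field) do.call(rbind, lapply(bundles, `[[`, field))

  tree <- with_seed(seed, {
    subtree <- function(labels, depth) {
      t <- if (length(labels) == 1L) NULL else ape::rcoal(length(labels),
                                                          tip.label = labels)
      if (is.null(t)) return(sprintf("%s:%g", labels, depth))
      t$edge.length <- t$edge.length / max(ape::node.depth.edgelength(t)) *
        depth
      sub(";$", "", ape::write.tree(t))
    }
    antho <- subtree(species$species_id[species$clade == "anthozoa"], 1)
    medu <- subtree(species$species_id[species$clade == "medusozoa"], 1)
    nwk <- if (outgroup) {
      sprintf("(outgroup_01:3,(%s:1,%s:1)cnidaria:1)root;", antho, medu)
    } else sprintf("(%s:1,%s:1)cnidaria;", antho, medu)
    ape::read.tree(text = nwk)
  })

  traits <- species
  n <- nrow(traits)
  is_a <- traits$clade == "anthozoa"
  is_m <- traits$clade == "medusozoa"
  # deterministic life-history pattern: anthozoans sessile, mostly symbiotic
  # and colonial; one symbiotic and one sessile medusozoan; sessile outgroup
  traits$symbiotic <- FALSE
  traits$symbiotic[is_a][seq_len(sum(is_a)) %% 4L != 0L] <- TRUE
  traits$symbiotic[which(is_m)[1]] <- TRUE
  traits$colonial <- FALSE
  traits$colonial[is_a][seq_len(sum(is_a)) %% 3L != 0L] <- TRUE
  if (sum(is_m) >= 2L) traits$colonial[which(is_m)[2L]] <- TRUE
  traits$sessile <- traits$clade != "medusozoa"
  traits$sessile[which(is_m)[1]] <- TRUE

  bundle <- list(species = species,
                 domain_hits = cat_bind("domain_hits"),
                 search_hits = cat_bind("search_hits"),
                 tm = cat_bind("tm"),
                 truth = cat_bind("truth"),
                 tree = tree, traits = traits, planted_counts = planted)
  if (!is.null(outdir)) write_survey_bundle(bundle, outdir)
  bundle
}

#' Write a synthetic survey bundle to disk
#'
#' Mirrors the layout of real survey inputs: per-species
#' `<sp>.domains.tsv`, `<sp>.search.tsv`, `<sp>.tm.tsv`, plus `tree.nwk`,
#' `traits.csv` and a machine-readable `truth.json`.
#'
#' @param bundle output of [simulate_survey()].
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_survey_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (sp in bundle$species$species_id) {
    dh <- bundle$domain_hits[bundle$domain_hits$species_id == sp, ]
    write_domain_table(dh, file.path(outdir, paste0(sp, ".domains.tsv")))
    sh <- bundle$search_hits[
      bundle$search_hits$subject_id %in% dh$protein_id, ]
    utils::write.table(sh, file.path(outdir, paste0(sp, ".search.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    tm <- bundle$tm[bundle$tm$protein_id %in% dh$protein_id,
                    c("protein_id", "n_tm_helices")]
    utils::write.table(tm, file.path(outdir, paste0(sp, ".tm.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  ape::write.tree(bundle$tree, file.path(outdir, "tree.nwk"))
  utils::write.csv(bundle$traits, file.path(outdir, "traits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(outdir, "truth.json"),
                       dataframe = "rows")
  invisible(outdir)
}
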