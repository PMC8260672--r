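# Readers and writers for the tabular inputs of the survey.
#
# All coordinates are stored 0-based half-open internally; the tabular inputs
# (HMMER/Pfam convention) are 1-based closed, so a source span [s, e] becomes
# [s - 1, e) on read and is written back as [s, e].

DOMAIN_COLS <- c("protein_id", "species_id", "domain_name", "clan_confirmed",
                 "i_evalue", "env_start", "env_end", "bitscore")

#' Read a per-domain annotation table
#'
#' Parses per-domain profile-HMM hits into the internal domain-hit
#' representation. Two dialects are supported:
#'
#' * `"hmmer_domtbl"`: HMMER3 `--domtblout` output as produced by `hmmscan`
#'   (whitespace-delimited, `#` comment lines; the query is the protein, the
#'   target the domain family; the per-domain independent E-value is taken
#'   from the `i-Evalue` column and coordinates from the envelope columns).
#' * `"generic_tsv"`: a plain TSV. Without a header the positional schema is
#'   `protein_id, domain_name, i_evalue, start, end[, clan_confirmed[,
#'   bitscore]]`; with a header line naming at least
#'   `protein_id, domain_name, i_evalue, env_start, env_end` any of the
#'   internal columns (including `species_id` and `clan_confirmed`) may be
#'   given. Start/end are 1-based closed.
#'
#' Hits whose source lacks a clan flag are marked `clan_confirmed = TRUE`
#' (i.e. assumed to have survived clan-level post-processing).
#'
#' @param path file path.
#' @param dialect `"generic_tsv"` or `"hmmer_domtbl"`.
#' @param species species identifier attached to every row when the file
#'   itself carries none.
#' @return a `data.frame` with columns `protein_id`, `species_id`,
#'   `domain_name`, `clan_confirmed`, `i_evalue`, `env_start`, `env_end`
#'   (0-based half-open), `bitscore`. An empty file yields a zero-row frame.
#' @export
read_domain_table <- function(path, dialect = c("generic_tsv", "hmmer_domtbl"),
                              species = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("domain table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "hmmer_domtbl") {
    return(parse_domtbl(lines, species))
  }
  parse_generic_domain_tsv(lines, species)
}

empty_domain_table <- function() {
  data.frame(protein_id = character(), species_id = character(),
             domain_name = character(), clan_confirmed = logical(),
             i_evalue = numeric(), env_start = integer(), env_end = integer(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

parse_evalue <- function(x, line_no, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad)) {
    stopf("line %d: unparsable %s value '%s'", line_no[bad][1], field,
          x[bad][1])
  }
  v
}

parse_generic_domain_tsv <- function(lines, species) {
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) return(empty_domain_table())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- grepl("^protein_id\\t", lines[1])
  if (has_header) {
    hdr <- trim_id(fields[[1]])
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0L) return(empty_domain_table())
    need <- c("protein_id", "domain_name", "i_evalue", "env_start", "env_end")
    miss <- setdiff(need, hdr)
    if (length(miss) > 0L)
      stopf("generic_tsv header missing column(s): %s",
            paste(miss, collapse = ", "))
    get_col <- function(nm, default = NULL) {
      if (nm %in% hdr) vapply(fields, function(f) {
        if (length(f) < match(nm, hdr)) NA_character_ else f[[match(nm, hdr)]]
      }, character(1)) else default
    }
    n <- length(fields)
    out <- data.frame(
      protein_id = trim_id(get_col("protein_id")),
      species_id = trim_id(get_col("species_id",
                                   rep(as.character(species), n))),
      domain_name = trim_id(get_col("domain_name")),
      clan_confirmed = parse_logical(get_col("clan_confirmed",
                                             rep("TRUE", n)), line_no),
      i_evalue = parse_evalue(get_col("i_evalue"), line_no, "i_evalue"),
      env_start = as.integer(get_col("env_start")) - 1L,
      env_end = as.integer(get_col("env_end")),
      bitscore = suppressWarnings(as.numeric(get_col("bitscore",
                                                     rep(NA, n)))),
      stringsAsFactors = FALSE)
  } else {
    nf <- lengths(fields)
    if (any(nf < 5L))
      stopf("line %d: expected at least 5 tab-separated fields, got %d",
            line_no[nf < 5L][1], nf[nf < 5L][1])
    col <- function(i, default = NA_character_) {
      vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
             character(1))
    }
    out <- data.frame(
      protein_id = trim_id(col(1)),
      species_id = rep(as.character(species), length(fields)),
      domain_name = trim_id(col(2)),
      clan_confirmed = parse_logical(ifelse(is.na(col(6)), "TRUE", col(6)),
                                     line_no),
      i_evalue = parse_evalue(col(3), line_no, "i_evalue"),
      env_start = as.integer(col(4)) - 1L,
      env_end = as.integer(col(5)),
      bitscore = suppressWarnings(as.numeric(col(7))),
      stringsAsFactors = FALSE)
  }
  validate_domain_rows(out, line_no)
  out
}

parse_logical <- function(x, line_no) {
  v <- toupper(trim_id(x))
  out <- v %in% c("TRUE", "T", "1", "YES")
  bad <- !v %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO")
  if (any(bad))
    stopf("line %d: unparsable logical value '%s'", line_no[bad][1], x[bad][1])
  out
}

validate_domain_rows <- function(df, line_no) {
  bad_ev <- !is.na(df$i_evalue) & df$i_evalue <= 0
  if (any(bad_ev))
    stopf("line %d: i_evalue must be > 0", line_no[bad_ev][1])
  bad_coord <- is.na(df$env_start) | is.na(df$env_end) |
    df$env_start >= df$env_end
  if (any(bad_coord))
    stopf("line %d: invalid coordinates (need start < end)",
          line_no[bad_coord][1])
  invisible(df)
}

# HMMER3 domtblout (hmmscan orientation): fixed whitespace-separated columns.
parse_domtbl <- function(lines, species) {
  lines <- lines[!grepl("^#", lines) & !grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(empty_domain_table())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22L))
    stopf("domtblout row with %d fields (need >= 22): '%s'",
          min(nf), lines[which.min(nf)])
  g <- function(i) vapply(fields, `[[`, character(1), i)
  ln <- seq_along(lines)
  out <- data.frame(
    protein_id = trim_id(g(4)),
    species_id = rep(as.character(species), length(lines)),
    domain_name = trim_id(g(1)),
    clan_confirmed = TRUE,
    i_evalue = parse_evalue(g(13), ln, "i-Evalue"),
    env_start = as.integer(g(20)) - 1L,
    env_end = as.integer(g(21)),
    bitscore = suppressWarnings(as.numeric(g(14))),
    stringsAsFactors = FALSE)
  validate_domain_rows(out, ln)
  out
}

#' Write a domain table in the headered generic TSV dialect
#'
#' Coordinates are written back in the source (1-based closed) convention, so
#' a written table re-read with [read_domain_table()] round-trips exactly.
#'
#' @param hits domain-hit `data.frame` as returned by [read_domain_table()].
#' @param path output path.
#' @export
write_domain_table <- function(hits, path) {
  out <- hits[, DOMAIN_COLS]
  out$env_start <- out$env_start + 1L   # back to 1-based closed
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-protein transmembrane-segment summary table
#'
#' TSV with columns `protein_id`, `n_tm_helices` and an optional third column
#' of comma-separated helix spans like `"20-42,60-82"` (1-based closed).
#' Proteins absent from the table are treated downstream as having zero
#' predicted helices.
#'
#' @param path file path.
#' @return `data.frame` with `protein_id`, `n_tm_helices` and a list column
#'   `helix_spans` of two-column matrices (0-based half-open).
#' @export
read_tm_table <- function(path) {
  if (!file.exists(path)) stopf("TM table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^protein_id\t", lines)]
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), n_tm_helices = integer(),
                      helix_spans = I(list()), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- trim_id(vapply(fields, `[[`, character(1), 1))
  n_tm <- as.integer(vapply(fields, `[[`, character(1), 2))
  if (any(is.na(n_tm) | n_tm < 0))
    stopf("invalid helix count for protein '%s'", ids[is.na(n_tm) | n_tm < 0][1])
  spans <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L || !nzchar(trimws(f[[3]])))
      return(matrix(integer(0), ncol = 2))
    parts <- strsplit(strsplit(trimws(f[[3]]), ",", fixed = TRUE)[[1]], "-")
    m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
    m[, 1] <- m[, 1] - 1L  # 0-based half-open
    m
  })
  ok_span <- vapply(seq_along(ids), function(i) {
    nrow(spans[[i]]) == 0L || nrow(spans[[i]]) == n_tm[i]
  }, logical(1))
  if (any(!ok_span))
    stopf("protein '%s': helix span count disagrees with n_tm_helices",
          ids[!ok_span][1])
  # duplicates: identical rows collapse, conflicting counts are an error
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      if (length(unique(n_tm[ids == id])) > 1L)
        stopf("duplicate protein_id '%s' with conflicting helix counts", id)
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; n_tm <- n_tm[keep]; spans <- spans[keep]
  }
  data.frame(protein_id = ids, n_tm_helices = n_tm,
             helix_spans = I(spans), stringsAsFactors = FALSE)
}

#' Read a tabular pairwise sequence-search table
#'
#' Accepts the standard 12-column tabular layout (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) or a
#' minimal 4-column `qseqid sseqid evalue bitscore` layout. Multiple HSPs per
#' (query, subject) pair are collapsed to the best one (lowest E-value, ties
#' by highest bitscore), so the result has one row per pair.
#'
#' @param path file path.
#' @return `data.frame` with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @export
read_search_table <- function(path) {
  if (!file.exists(path)) stopf("search table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(4L, 12L)))
    stopf("search table row with %d fields (expected 4 or 12)",
          nf[!nf %in% c(4L, 12L)][1])
  ev_col <- ifelse(nf == 12L, 11L, 3L)
  bs_col <- ifelse(nf == 12L, 12L, 4L)
  df <- data.frame(
    query_id = trim_id(vapply(fields, `[[`, character(1), 1)),
    subject_id = trim_id(vapply(fields, `[[`, character(1), 2)),
    evalue = parse_evalue(mapply(function(f, i) f[[i]], fields, ev_col),
                          seq_along(lines), "evalue"),
    bitscore = suppressWarnings(as.numeric(
      mapply(function(f, i) f[[i]], fields, bs_col))),
    stringsAsFactors = FALSE)
  if (any(df$evalue < 0)) stopf("negative E-value in search table")
  collapse_best_hsp(df)
}

# one row per (query, subject): lowest evalue, then highest bitscore
collapse_best_hsp <- function(df) {
  o <- order(df$query_id, df$subject_id, df$evalue, -df$bitscore)
  df <- df[o, , drop = FALSE]
  keep <- !duplicated(df[, c("query_id", "subject_id")])
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a species trait table
#'
#' CSV with a header; required columns `species_id` and `clade`
#' (`anthozoa`, `medusozoa` or `outgroup`); any further columns are parsed as
#' binary traits (logical or 0/1).
#'
#' @param path file path.
#' @return `data.frame` with `species_id`, `clade` (factor) and one logical
#'   column per trait.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stopf("trait table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "clade") %in% names(df)))
    stopf("trait table must have 'species_id' and 'clade' columns")
  df$species_id <- trim_id(df$species_id)
  if (anyDuplicated(df$species_id))
    stopf("duplicate species_id in trait table: '%s'",
          df$species_id[duplicated(df$species_id)][1])
  df$clade <- tolower(trim_id(df$clade))
  bad <- !df$clade %in% c("anthozoa", "medusozoa", "outgroup")
  if (any(bad)) stopf("unknown clade value '%s'", df$clade[bad][1])
  for (nm in setdiff(names(df), c("species_id", "clade"))) {
    v <- toupper(trim_id(df[[nm]]))
    df[[nm]] <- ifelse(v %in% c("TRUE", "T", "1", "YES"), TRUE,
                       ifelse(v %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
    if (anyNA(df[[nm]]))
      stopf("trait '%s' has missing/unparsable values", nm)
  }
  df
}

#' Read a rooted species tree from a Newick file
#'
#' Wraps [ape::read.tree()] and enforces the survey's requirements: exactly
#' one tree, uniquely labelled tips, and a branch length on every edge.
#' Multifurcations (including at the root) are accepted; the downstream
#' ancestral-state machinery handles arbitrary node degree.
#'
#' @param path file path.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("tree file not found: %s", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stopf("expected a single tree in %s", path)
  if (is.null(tr)) stopf("could not parse Newick in %s", path)
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate tip label '%s'", tr$tip.label[duplicated(tr$tip.label)][1])
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    bad <- if (is.null(tr$edge.length)) 1L else which(is.na(tr$edge.length))[1]
    stopf("missing branch length on edge %d (%d -> %d)", bad,
          tr$edge[bad, 1], tr$edge[bad, 2])
  }
  if (any(tr$edge.length < 0)) stopf("negative branch length in tree")
  invisible(tr)
}
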