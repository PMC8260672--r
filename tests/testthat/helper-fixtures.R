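# Fixture builders shared across the suite. All fixtures are built in code.

# Sequentially laid-out domain hits for one protein.
make_hits <- function(domains, protein = "P1", species = "sp1",
                      ievalue = 1e-8, clan = TRUE, len = 100L, gap = 10L) {
  n <- length(domains)
  ievalue <- rep_len(ievalue, n)
  clan <- rep_len(clan, n)
  start <- (seq_len(n) - 1L) * (len + gap)
  data.frame(protein_id = protein, species_id = species,
             domain_name = domains, clan_confirmed = clan,
             i_evalue = ievalue, env_start = start, env_end = start + len,
             bitscore = 50, stringsAsFactors = FALSE)
}

tm_row <- function(protein = "P1", n = 0L) {
  data.frame(protein_id = protein, n_tm_helices = as.integer(n),
             stringsAsFactors = FALSE)
}

# Filtered architecture straight from a domain-name vector.
toy_arch <- function(domains, tm = 0L, protein = "P1", species = "sp1",
                     ievalue = 1e-8, clan = TRUE, cfg = threshold_config()) {
  if (length(domains) == 0L) {
    # architecture with no retained domains: use one hopeless hit
    hits <- make_hits("ZZ_none", protein, species, ievalue = 1)
  } else {
    hits <- make_hits(domains, protein, species, ievalue, clan)
  }
  filter_architecture(hits, tm_row(protein, tm), cfg)
}

# Random rooted tree with positive branch lengths (ape coalescent).
random_tree <- function(ntip) {
  tr <- ape::rcoal(ntip)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Independent oracle: joint Brownian ML ancestral states by numerical
# minimization of the edge-wise weighted sum of squares.
numeric_asr_oracle <- function(tree, x) {
  ntip <- length(tree$tip.label)
  obj <- function(s) {
    st <- c(unname(x[tree$tip.label]), s)
    sum((st[tree$edge[, 2]] - st[tree$edge[, 1]])^2 / tree$edge.length)
  }
  fit <- stats::optim(rep(mean(x), tree$Nnode), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  stats::setNames(fit$par, as.character(seq.int(ntip + 1L,
                                                ntip + tree$Nnode)))
}

# Brute-force reciprocal-best-hit relation from a similarity matrix
# (rows = queries, cols = subjects; higher similarity = better hit).
brute_force_rbh <- function(sim) {
  pairs <- list()
  for (q in rownames(sim)) {
    s_best <- colnames(sim)[which(sim[q, ] == max(sim[q, ]))]
    if (length(s_best) != 1L) next
    q_best <- rownames(sim)[which(sim[, s_best] == max(sim[, s_best]))]
    if (length(q_best) == 1L && q_best == q)
      pairs[[length(pairs) + 1L]] <- c(q, s_best)
  }
  pairs
}
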