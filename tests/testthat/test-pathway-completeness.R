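test_that("NF-kB classes follow the minimal-domain rules", {
  expect_equal(classify_nfkb(toy_arch(c("RHD", "TIG")))$class, "NFKB_MINIMAL")
  expect_equal(classify_nfkb(
    toy_arch(c("RHD", "TIG", rep("Ank_2", 5), "Death")))$class, "NFKB_FULL")
  expect_equal(classify_nfkb(
    toy_arch(c("RHD", "TIG", "Ank_2", "Ank_2")))$class, "NFKB_ANK")
  expect_equal(classify_nfkb(toy_arch(rep("Ank_2", 4)),
                             ikba_candidate = TRUE)$class, "IKBA")
  # "multiple" ankyrin means >= 2
  expect_equal(classify_nfkb(toy_arch("Ank_2"),
                             ikba_candidate = TRUE)$class, "NONE")
  # ankyrin-only proteins not matched to the IkB query stay unclassified
  expect_equal(classify_nfkb(toy_arch(rep("Ank_2", 4)))$class, "NONE")
})

test_that("adding domains never demotes the NF-kB class", {
  base <- c("RHD", "TIG")
  chain <- list(character(0), "Ank_2", c("Ank_2", "Ank_2"),
                c("Ank_2", "Ank_2", "Death"))   # nested supersets
  rank <- c(NONE = 0, IKBA = 1, NFKB_MINIMAL = 2, NFKB_ANK = 3,
            NFKB_FULL = 4)
  prev <- 0
  for (e in chain) {
    cls <- classify_nfkb(toy_arch(c(base, e)))$class
    expect_gte(rank[[cls]], prev)
    prev <- rank[[cls]]
  }
})

test_that("complement family rules evaluate required domain multisets", {
  expect_equal(classify_complement(
    toy_arch(c("A2M", "A2M", "A2M", "CUB", "C345C")))$family, "C3")
  expect_equal(classify_complement(
    toy_arch(c("CUB", "CUB", "Sushi", "Sushi", "Trypsin")))$family, "MASP")
  expect_equal(classify_complement(
    toy_arch(c("Sushi", "VWA", "Trypsin")))$family, "BF_C2")
  expect_equal(classify_complement(
    toy_arch(c("TSP_1", "Ldl_recept_a", "MACPF", "Sushi")))$family, "C6")
  # "multiple" macroglobulin means >= 2
  expect_equal(classify_complement(
    toy_arch(c("A2M", "CUB", "C345C")))$family, "NONE")
  # MASP beats Factor B/C2 when both rules match
  expect_equal(classify_complement(
    toy_arch(c("CUB", "CUB", "Sushi", "VWA", "Trypsin")))$family, "MASP")
})

test_that("exhaustive C3 subset truth table classifies exactly", {
  req <- list(mg = c("A2M", "A2M"), cub = "CUB", c345c = "C345C")
  for (mask in 0:7) {
    parts <- req[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    doms <- unlist(parts, use.names = FALSE)
    res <- classify_complement(toy_arch(c(doms, "ZZ_pad")))
    expect_equal(res$family == "C3", mask == 7L, label = paste("mask", mask))
    if (mask %in% c(3L, 5L, 6L))   # exactly one component missing
      expect_true("C3" %in% res$partial)
  }
})

test_that("near-miss complement architectures are reported as partial", {
  res <- classify_complement(toy_arch(c("A2M", "A2M", "CUB")))  # no C345c
  expect_equal(res$family, "NONE")
  expect_true("C3" %in% res$partial)
})

test_that("reciprocal best hit requires a unique mutual best", {
  fwd <- data.frame(query_id = "HQ1", subject_id = c("P7", "P8"),
                    evalue = c(1e-40, 1e-10), bitscore = c(300, 80),
                    stringsAsFactors = FALSE)
  bwd_good <- data.frame(query_id = "P7", subject_id = c("HQ1", "HQ3"),
                         evalue = c(1e-38, 1e-12), bitscore = c(290, 70),
                         stringsAsFactors = FALSE)
  member <- list(member_name = "M1", query_ids = "HQ1")
  expect_true(reciprocal_presence(fwd, bwd_good, member, "s1")$present)

  bwd_bad <- transform(bwd_good, subject_id = c("HQ9", "HQ3"))
  expect_false(reciprocal_presence(fwd, bwd_bad, member, "s1")$present)

  none <- fwd[0, ]
  expect_false(reciprocal_presence(none, bwd_good, member, "s1")$present)

  # exact tie in E-value and bitscore: ambiguity is not evidence
  bwd_tie <- data.frame(query_id = "P7", subject_id = c("HQ1", "HQ9"),
                        evalue = 1e-30, bitscore = 200,
                        stringsAsFactors = FALSE)
  expect_false(reciprocal_presence(fwd, bwd_tie, member, "s1")$present)
})

test_that("reciprocal calls agree with brute-force RBH on symmetric scores", {
  set.seed(44)
  nq <- 6L; ns <- 6L
  for (rep in 1:5) {
    sim <- matrix(round(runif(nq * ns, 10, 500)), nq, ns,
                  dimnames = list(paste0("HQ", 1:nq), paste0("SP", 1:ns)))
    # symmetric similarity -> forward/backward built from the same matrix
    fwd <- data.frame(query_id = rep(rownames(sim), each = ns),
                      subject_id = rep(colnames(sim), nq),
                      evalue = as.vector(10^(-t(sim) / 50)),
                      bitscore = as.vector(t(sim)), stringsAsFactors = FALSE)
    bwd <- data.frame(query_id = rep(colnames(sim), each = nq),
                      subject_id = rep(rownames(sim), ns),
                      evalue = as.vector(10^(-sim / 50)),
                      bitscore = as.vector(sim), stringsAsFactors = FALSE)
    truth_pairs <- brute_force_rbh(sim)
    truth_q <- vapply(truth_pairs, `[[`, character(1), 1)
    for (q in rownames(sim)) {
      call <- reciprocal_presence(fwd, bwd,
                                  list(member_name = q, query_ids = q))
      expect_equal(call$present, q %in% truth_q, label = paste(rep, q))
    }
  }
})

test_that("presence fractions are per-group proportions in [0, 1]", {
  traits <- data.frame(species_id = paste0("s", 1:5),
                       clade = c("anthozoa", "anthozoa", "anthozoa",
                                 "medusozoa", "medusozoa"),
                       stringsAsFactors = FALSE)
  calls <- expand.grid(species_id = traits$species_id,
                       member_name = c("M1", "M2"),
                       stringsAsFactors = FALSE)
  calls$present <- c(TRUE, TRUE, TRUE, FALSE, FALSE,   # M1: 3/3 A, 0/2 M
                     FALSE, FALSE, FALSE, FALSE, FALSE)  # M2 absent
  fr <- presence_fractions(calls, traits)
  expect_equal(fr$fraction[fr$member_name == "M1" & fr$group == "anthozoa"], 1)
  expect_equal(fr$fraction[fr$member_name == "M1" & fr$group == "medusozoa"], 0)
  expect_true(all(fr$fraction[fr$member_name == "M2"] == 0))
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  # group-weighted sums equal overall presence counts
  expect_equal(sum(fr$n_present[fr$member_name == "M1"]),
               sum(calls$present[calls$member_name == "M1"]))
  expect_error(presence_fractions(
    transform(calls, species_id = "unknown"), traits), "missing")
})

test_that("built-in pathway definitions load with unique member names", {
  defs <- pathway_defs()
  expect_true(all(c("tlr_nfkb", "lectin_complement") %in% names(defs)))
  for (p in defs) {
    nms <- vapply(p$members, `[[`, character(1), "member_name")
    expect_equal(anyDuplicated(nms), 0L)
    expect_true(all(lengths(lapply(p$members, `[[`, "query_ids")) >= 1L))
  }
})
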