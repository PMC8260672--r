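rules <- prr_rules()

cases <- list(
  list(d = c("TIR", "LRR_8", "LRR_8"), tm = 1L, cat = "PROTO_TLR"),
  list(d = "TIR", tm = 1L, cat = "TLR_LIKE"),
  list(d = c("TIR", "LRR_8"), tm = 0L, cat = "NONE"),        # TLR needs TM
  list(d = c("DEAD", "CARD", "CARD", "RIG-I_C-RD"), tm = 0L,
       cat = "RIG_MDA5_LIKE"),
  list(d = c("DEAD", "RIG-I_C-RD"), tm = 0L, cat = "LGP2_LIKE"),
  list(d = "DEAD", tm = 0L, cat = "NONE"),
  list(d = c("NACHT", "LRR_8", "LRR_8"), tm = 0L, cat = "PROTO_NLR"),
  list(d = "NACHT", tm = 0L, cat = "NLR_LIKE"),
  list(d = "Lectin_C", tm = 1L, cat = "CTL_TM"),
  list(d = c("Lectin_C", "CUB"), tm = 0L, cat = "CTL_EXTRACELLULAR"),
  list(d = "Lectin_C", tm = 0L, cat = "CTL_UNKNOWN"),
  list(d = character(0), tm = 0L, cat = "NONE"))

test_that("the nine category rules classify canonical architectures", {
  for (cs in cases) {
    call <- classify_protein(toy_arch(cs$d, tm = cs$tm), rules)
    expect_equal(call$category, cs$cat,
                 label = paste(c(cs$d, "tm", cs$tm), collapse = "+"))
  }
})

test_that("branch gating keeps categories disjoint for fusion proteins", {
  # NACHT+TIR fusion enters the TLR branch, never counted as an NLR
  fusion <- classify_protein(toy_arch(c("TIR", "NACHT", "LRR_8"), tm = 0L))
  expect_equal(fusion$category, "NONE")
  expect_true("PROTO_NLR" %in% fusion$also_matches)
  # with a TM segment the same fusion is a prototypical TLR
  expect_equal(classify_protein(toy_arch(c("TIR", "NACHT", "LRR_8"),
                                         tm = 1L))$category, "PROTO_TLR")
  # helicase+CARD+CTD+repressor is RIG-I/MDA5-like, not LGP2 (CARD present)
  full <- classify_protein(toy_arch(c("DEAD", "CARD", "RIG-I_C-RD")))
  expect_equal(full$category, "RIG_MDA5_LIKE")
})

test_that("randomized fixtures respect the precedence cascade", {
  set.seed(33)
  pool <- c("TIR", "LRR_8", "NACHT", "CARD", "Lectin_C", "DEAD",
            "RIG-I_C-RD", "CUB", "HEPN")
  for (i in 1:40) {
    doms <- sample(pool, sample(1:5, 1), replace = TRUE)
    call <- classify_protein(toy_arch(doms, tm = sample(0:2, 1)))
    if ("TIR" %in% doms)
      expect_false(call$category %in% c("PROTO_NLR", "NLR_LIKE", "CTL_TM",
                                        "CTL_EXTRACELLULAR", "CTL_UNKNOWN",
                                        "RIG_MDA5_LIKE", "LGP2_LIKE"))
    if (any(c("DEAD") %in% doms) && !"TIR" %in% doms)
      expect_false(grepl("^(PROTO_NLR|NLR_LIKE|CTL)", call$category))
  }
})

test_that("CTL localization precedence: TM beats extracellular evidence", {
  both <- classify_protein(toy_arch(c("Lectin_C", "CUB"), tm = 1L))
  expect_equal(both$category, "CTL_TM")
})

test_that("special architecture flags are set where defined", {
  mbl <- classify_protein(toy_arch(c("Lectin_C", "Collagen")))
  expect_true("MBL_LIKE" %in% mbl$flags)
  expect_equal(mbl$category, "CTL_UNKNOWN")  # collagen not extracellular-ind.

  rdrp <- classify_protein(toy_arch(c("DEAD", "RIG-I_C-RD", "RdRP_1")))
  expect_equal(rdrp$category, "LGP2_LIKE")
  expect_true("RDRP_FUSION" %in% rdrp$flags)

  tn <- classify_protein(toy_arch(c("NACHT", "RVT_1")))
  expect_true("TRANSPOSON_DOMAIN" %in% tn$flags)
  tn2 <- classify_protein(toy_arch(c("Lectin_C", "Dimer_Tnp_hAT")))
  expect_true("TRANSPOSON_DOMAIN" %in% tn2$flags)
})

test_that("proteins failing the search gate must not be classified", {
  hits <- make_hits("TIR")
  arch <- filter_architecture(hits, tm_row("P1", 1L),
                              passed_search_gate = FALSE)
  expect_error(classify_protein(arch), "search gate")
})

test_that("classification is order-independent and evidence is retained", {
  a1 <- toy_arch(c("TIR", "LRR_8", "NACHT"), tm = 1L)
  hits_rev <- make_hits(c("NACHT", "LRR_8", "TIR"))
  a2 <- filter_architecture(hits_rev, tm_row("P1", 1L))
  c1 <- classify_protein(a1); c2 <- classify_protein(a2)
  expect_equal(c1$category, c2$category)
  expect_true(all(c1$evidence$domain_name %in% a1$domains$domain_name))
})

test_that("species counts obey the type-total invariants", {
  arches <- c(
    lapply(1:3, function(i) toy_arch(c("TIR", "LRR_8"), tm = 1L,
                                     protein = paste0("A", i),
                                     species = "s1")),
    lapply(1:2, function(i) toy_arch("TIR", tm = 1L,
                                     protein = paste0("B", i),
                                     species = "s1")),
    list(toy_arch("NACHT", protein = "C1", species = "s2"),
         toy_arch("ZZZ_unknown", protein = "D1", species = "s2")))
  calls <- classify_proteins(arches)
  counts <- count_species(calls, manifest = c("s1", "s2", "s3"))
  s1 <- counts[counts$species_id == "s1", ]
  expect_equal(s1$TLR, 5)                      # 3 proto + 2 TLR-like
  expect_equal(s1$grand_total, 5)
  expect_equal(counts[counts$species_id == "s3", "grand_total"], 0)
  # count conservation: totals equal non-NONE calls
  expect_equal(sum(counts$grand_total), sum(calls$category != "NONE"))
  expect_equal(counts$grand_total, counts$TLR + counts$RLR + counts$NLR +
                 counts$CTL)
})

test_that("domain-combination census counts proteins and honors exclusions", {
  arches <- list(toy_arch(c("NACHT", "HEPN"), protein = "P1"),
                 toy_arch(c("NACHT", "HEPN", "LRR_8"), protein = "P2"),
                 toy_arch(c("NACHT", "Death"), protein = "P3"))
  cen <- domain_combination_census(arches, "NACHT")
  expect_equal(cen$census, c(HEPN = 2L, Death = 1L))
  expect_equal(cen$most_common, "HEPN")
  expect_false("LRR_8" %in% names(cen$census))   # LRRs excluded by default

  single <- domain_combination_census(list(toy_arch("NACHT")), "NACHT")
  expect_equal(length(single$census), 0L)

  ctl <- domain_combination_census(
    list(toy_arch(c("Lectin_C", "EGF"), protein = "Q1"),
         toy_arch(c("Lectin_C", "EGF"), protein = "Q2"),
         toy_arch(c("Lectin_C", "ConA"), protein = "Q3")), "CTLD")
  expect_equal(ctl$most_common, "EGF")

  expect_error(domain_combination_census(list(toy_arch("TIR", tm = 1L)),
                                         "NACHT"), "focal")
})
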