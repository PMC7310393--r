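# shared toy: sires s1..s3 with phenotyped offspring in populations A/B/C
toy_connect <- function() {
  ped <- as_pedigree(tibble::tibble(
    animal = c("s1", "s2", "s3", "g", "dg", paste0("o", 1:14)),
    sire = c(NA, NA, NA, NA, "g",
             "s1", "s1", "s1", "s1", "s1",   # o1-o3 in A, o4-o5 in B
             "s2", "s2", "s2", "s2", "s2",   # o6-o10 in A
             "s3", "s3", "s3", "s3"),        # o11-o14 in B
    dam = c(NA, NA, NA, NA, NA,
            rep(NA, 5), rep("dg", 2), rep(NA, 3), rep("dg", 2), rep(NA, 2))
  ))
  population <- c(rep("A", 3), rep("B", 2), rep("A", 5), rep("B", 4))
  phen <- tibble::tibble(
    animal = paste0("o", 1:14),
    population = population,
    herd = ifelse(population == "A", "hA1", "hB1"),
    dam = ped$dam[match(paste0("o", 1:14), ped$animal)]
  )
  list(ped = ped, phen = phen)
}

test_that("sire offspring tallies follow the phenotype table", {
  tc <- toy_connect()
  tal <- tally_sire_offspring(tc$phen, tc$ped)
  pc <- tal %>% dplyr::count(sire, population, wt = n)
  expect_equal(pc$n[pc$sire == "s1" & pc$population == "A"], 3)
  expect_equal(pc$n[pc$sire == "s1" & pc$population == "B"], 2)
  expect_equal(sum(pc$sire == "s2" & pc$population == "B"), 0) # A only
  # phenotyped animal missing from pedigree is an error
  bad <- tc$phen
  bad$animal[1] <- "ghost"
  expect_error(tally_sire_offspring(bad, tc$ped), "absent")
})

test_that("maternal grand-sire tallies credit the dam's sire", {
  tc <- toy_connect()
  tal <- tally_mgs_grandoffspring(tc$phen, tc$ped)
  # dam dg has sire g; records o6,o7 (A) and o11,o12 (B) are dg's
  expect_setequal(unique(tal$sire), "g")
  expect_equal(sum(tal$n[tal$population == "A"]), 2)
  expect_equal(sum(tal$n[tal$population == "B"]), 2)
  # records with unknown dam contribute nothing
  expect_equal(sum(tal$n), 4)
})

test_that("genetic similarity matches hand evaluation and boundary cases", {
  counts <- tibble::tibble(
    sire = c("s1", "s1", "s2", "s3"),
    population = c("A", "B", "A", "B"),
    herd = "h", n = c(3, 2, 5, 4)
  )
  expect_equal(genetic_similarity(counts, "A", "B"), 5 / 14)
  expect_equal(genetic_similarity(counts, "A", "B"),
               genetic_similarity(counts, "B", "A"))  # symmetry
  no_common <- counts[counts$sire != "s1", ]
  expect_equal(genetic_similarity(no_common, "A", "B"), 0)
  all_common <- counts[counts$sire == "s1", ]
  expect_equal(genetic_similarity(all_common, "A", "B"), 1)
  # undefined (no offspring in either population) is missing, not zero
  expect_true(is.na(genetic_similarity(counts, "X", "Y")))
})

test_that("herd-level genetic similarity and harmonic means match hand sums", {
  # herd h of pop H: s1 has 4 in h and 6 in B; s2 has 2 in h only;
  # B also has s4 with 10 -> GS_hB = 10/22
  ped <- as_pedigree(tibble::tibble(
    animal = c("s1", "s2", "s4", paste0("x", 1:22)),
    sire = c(NA, NA, NA, rep("s1", 4), rep("s2", 2), rep("s1", 6),
             rep("s4", 10)),
    dam = NA
  ))
  phen <- tibble::tibble(
    animal = paste0("x", 1:22),
    population = c(rep("H", 6), rep("B", 16)),
    herd = c(rep("h", 6), rep("hb", 16))
  )
  g <- herd_gs(phen, ped, "H")
  expect_equal(g$gs[g$herd == "h" & g$population == "B"], 10 / 22)
  # herd harmonic mean: s1 contributes 2/(1/4 + 1/6) = 4.8
  hm <- herd_harmonic_means(phen, ped, "H")
  expect_equal(hm$hm[hm$herd == "h"], 4.8)

  # a herd whose sires serve nowhere else scores 0 against every population
  g0 <- herd_gs(
    tibble::tibble(animal = c("x5", "x6", "x7"),
                   population = c("H", "H", "B"),
                   herd = c("h", "h", "hb")),
    ped, "H"
  )
  expect_equal(g0$gs[g0$herd == "h"], 0)  # s2-sired h vs s1-sired B
})

test_that("GS_TOT is the arithmetic mean of the CB and CMGS coefficients", {
  expect_equal((0.4 + 0.2) / 2, 0.3)  # definition check via subset_by_gs below
  tc <- toy_connect()
  g_cb <- herd_gs(tc$phen, tc$ped, "A", "cb")
  g_cm <- herd_gs(tc$phen, tc$ped, "A", "cmgs")
  sel <- subset_by_gs(tc$phen, tc$ped, "A", top_fraction = 1, ancestor = "tot")
  manual <- mean((g_cb$gs + g_cm$gs) / 2, na.rm = TRUE)
  expect_equal(sel$score[sel$herd == "hA1"], manual)
})

test_that("BOD, AN_POP and harmonic means match the printed formulas", {
  expect_equal(bod(c(10, 10), 8), 0.25)
  expect_equal(an_pop(bod(c(10, 10), 8), 8), 2)
  expect_equal(bod(rep(7, 8), 8), 1)
  expect_equal(an_pop(1, 8), 8)
  expect_equal(bod(42, 8), 0.125)
  expect_equal(an_pop(0.125, 8), 1)
  expect_error(bod(c(0, 0), 8), "no offspring")
  # scale invariance
  for (k in c(2, 5, 10)) {
    expect_equal(bod(k * c(3, 1, 7), 8), bod(c(3, 1, 7), 8))
  }
  expect_equal(harmonic_mean_progeny(10, 10), 10)
  expect_equal(harmonic_mean_progeny(2, 6), 3)
  expect_equal(harmonic_mean_progeny(1, 1000), 2 / (1 + 1 / 1000))
  expect_error(harmonic_mean_progeny(0, 5), "positive")
})

test_that("the connectedness report assembles all coefficients", {
  tc <- toy_connect()
  rep <- connectedness_report(tc$phen, tc$ped, herd_population = "A")
  # s1 is the only common bull (A and B); s2, s3 are single-population
  expect_equal(rep$unique_cb, 1)
  pw <- rep$pairwise
  expect_equal(pw$cb[pw$pop_a == "A" & pw$pop_b == "B"], 1)
  # g is a CMGS (grand-offspring in A and B) but not a CB
  expect_equal(rep$unique_cmgs, 1)
  expect_false(rep$cmgs$also_cb[rep$cmgs$sire == "g"])
  # sire coefficients: s1 has 5 offspring in 2 of 2 populations
  s1 <- rep$sires[rep$sires$sire == "s1", ]
  expect_true(s1$is_cb)
  expect_equal(s1$total, 5)
  expect_equal(s1$an_pop, 2 * bod(c(3, 2), 2))
  # common bulls have AN_POP > 1
  expect_true(all(rep$sires$an_pop[rep$sires$is_cb] > 1))
  # herd table exists for the requested population
  expect_true(!is.null(rep$herd))
  expect_true("hA1" %in% rep$herd$herd)
  # tidy and autoplot
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("a dataset without sire exchange has no common bulls", {
  dat <- small_dataset(n_records = 120, populations = c("A", "B"),
                       f = 0, seed = 5)
  rep <- connectedness_report(dat$phenotypes, dat$pedigree)
  expect_equal(rep$unique_cb, 0)
  expect_true(all(rep$pairwise$gs == 0, na.rm = TRUE))
})

test_that("vectorized coefficients equal brute-force record enumeration", {
  dat <- small_dataset(n_records = 300, populations = c("A", "B", "C"),
                       f = 0.4, seed = 9)
  phen <- dat$phenotypes
  ped <- dat$pedigree
  sire_of <- setNames(ped$sire, ped$animal)
  phen$sire <- unname(sire_of[phen$animal])
  pairs <- utils::combn(c("A", "B", "C"), 2)
  fast <- gs_pairwise(tally_sire_offspring(phen, ped), c("A", "B", "C"))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    recs <- phen[!is.na(phen$sire) & phen$population %in% c(a, b), ]
    num <- 0; den <- 0
    for (s in unique(recs$sire)) {
      na <- sum(recs$sire == s & recs$population == a)
      nb <- sum(recs$sire == s & recs$population == b)
      den <- den + na + nb
      if (na > 0 && nb > 0) num <- num + na + nb
    }
    expect_equal(fast$gs[fast$pop_a == a & fast$pop_b == b], num / den)
  }
  # per-sire BOD by direct formula
  rep <- connectedness_report(phen, ped)
  for (s in utils::head(rep$sires$sire, 10)) {
    counts <- vapply(c("A", "B", "C"), function(p) {
      sum(phen$sire == s & phen$population == p, na.rm = TRUE)
    }, numeric(1))
    expect_equal(rep$sires$bod[rep$sires$sire == s], bod(counts, 3))
  }
})

test_that("the pairwise table formats with bulls, CB and GS in place", {
  tc <- toy_connect()
  rep <- connectedness_report(tc$phen, tc$ped)
  tab <- format_gs_table(rep)
  expect_equal(tab$population, rep$populations)
  expect_equal(tab$A[tab$population == "A"],
               rep$bulls_per_population$bulls[
                 rep$bulls_per_population$population == "A"])
  expect_equal(tab$B[tab$population == "A"], 1)        # CB count above
  expect_equal(tab$A[tab$population == "B"],
               rep$pairwise$gs[rep$pairwise$pop_a == "A" &
                                 rep$pairwise$pop_b == "B"])
})
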