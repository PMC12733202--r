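test_that("composition has the closed-form behaviour on simple sequences", {
  bg <- default_background()
  bg_p <- setNames(rep(0.05, 20L), names(bg))  # uniform 5% background
  attr(bg_p, "provenance") <- "uniform test background"

  p <- compose("PPPP", bg_p, "poly-P")
  expect_equal(unname(p$percentage[["P"]]), 100)
  expect_equal(unname(p$fold_change[["P"]]), 20)
  expect_equal(unname(p$log2_fc[["P"]]), log2(20), tolerance = 1e-12)
  expect_true(p$enriched[["P"]])
  expect_equal(p$length_counted, 4L)

  # absent residue: fold-change 0, log2 undefined, not enriched
  expect_equal(unname(p$fold_change[["W"]]), 0)
  expect_true(is.na(p$log2_fc[["W"]]))
  expect_false(p$enriched[["W"]])

  # X excluded from numerator and denominator
  px <- compose("PPXPP", bg_p, "with-X")
  expect_equal(px$length_counted, 4L)
  expect_equal(unname(px$percentage[["P"]]), 100)

  expect_error(compose("XXX", bg_p, "only-X"), "only X")
})

test_that("the enrichment threshold is inclusive at exactly 1.5-fold", {
  bg <- setNames(rep(0.05, 20L), pelpscope:::AA20)
  # 3 of 40 residues = 7.5% observed vs 5% expected = exactly 1.5x
  seqs <- paste0(strrep("P", 3L), strrep("A", 37L))
  prof <- compose(seqs, bg, "edge")
  expect_equal(unname(prof$fold_change[["P"]]), 1.5, tolerance = 1e-12)
  expect_true(prof$enriched[["P"]])
  # just below threshold is not enriched
  prof2 <- compose(paste0(strrep("P", 2L), strrep("A", 38L)), bg, "below")
  expect_false(prof2$enriched[["P"]])
})

test_that("profiles agree with an independent per-character tally", {
  set.seed(41)
  bg <- default_background()
  for (rep in 1:8) {
    s <- random_seq(sample(40:400, 1L), c(AA_ALL, "X"))
    prof <- compose(s, bg, "fixture")
    want <- tally_composition(s)
    expect_equal(as.integer(prof$counts), unname(as.integer(want)))
    expect_equal(prof$length_counted, sum(want))
    expect_equal(sum(prof$percentage), 100, tolerance = 1e-9)
    expect_equal(unname(prof$fold_change),
                 unname((want / sum(want)) / bg[AA_ALL]), tolerance = 1e-12)
  }
})

test_that("composition is invariant under sequence self-concatenation", {
  set.seed(43)
  s <- random_seq(120L)
  one <- compose(s, protein_id = "once")
  two <- compose(paste0(s, s), protein_id = "twice")
  expect_equal(one$percentage, two$percentage)
  expect_equal(one$fold_change, two$fold_change)
  expect_equal(one$enriched, two$enriched)
  expect_equal(one$ranks, two$ranks)
})

test_that("ranks order residues by contribution with mean-tie handling", {
  bg <- default_background()
  # 12 L, 10 E, and 3 copies of each of the 18 remaining residues
  s <- paste0(strrep("L", 12L), strrep("E", 10L),
              paste(rep(setdiff(AA_ALL, c("L", "E")), each = 3L),
                    collapse = ""))
  prof <- compose(s, bg, "ranked")
  expect_equal(unname(prof$ranks[["L"]]), 1)
  expect_equal(unname(prof$ranks[["E"]]), 2)
  # the 18 remaining residues tie for ranks 3..20 -> mean 11.5
  expect_true(all(prof$ranks[setdiff(AA_ALL, c("L", "E"))] == 11.5))

  # uniform composition: every residue at rank 10.5
  uni <- compose(paste(rep(AA_ALL, 2L), collapse = ""), bg, "uniform")
  expect_true(all(uni$ranks == 10.5))
})

test_that("rank aggregation orders tracked residues by summed contribution", {
  bg <- setNames(rep(0.05, 20L), pelpscope:::AA20)
  p1 <- compose(paste0(strrep("L", 5L), strrep("P", 3L), "ACDE"), bg, "p1")
  p2 <- compose(paste0(strrep("L", 6L), strrep("P", 4L), "ACD"), bg, "p2")
  agg <- aggregate_ranks(list(p1, p2), tracked = c("L", "P", "E"))
  expect_equal(agg$residue[agg$overall_rank == 1], "L")
  expect_lt(agg$rank_sum[agg$residue == "L"], agg$rank_sum[agg$residue == "P"])

  # single profile: overall order equals the profile's own order
  agg1 <- aggregate_ranks(list(p1), tracked = c("L", "P"))
  expect_equal(agg1$residue, c("L", "P"))

  expect_error(aggregate_ranks(list()), "empty cohort")
})

test_that("enrichment counts count proteins, not residues", {
  bg <- setNames(rep(0.05, 20L), pelpscope:::AA20)
  rich <- compose(strrep("P", 30L), bg, "r1")
  rich2 <- compose(paste0(strrep("P", 10L), strrep("A", 10L)), bg, "r2")
  plain <- compose(paste(rep(AA_ALL, 2L), collapse = ""), bg, "r3")
  counts <- enrichment_counts(list(rich, rich2, plain))
  expect_equal(unname(counts[["P"]]), 2L)
  expect_equal(unname(counts[["W"]]), 0L)
  # uniform 5% on a uniform background is fold-change 1.0 everywhere
  expect_equal(unname(enrichment_counts(list(plain))), rep(0L, 20L))
})

test_that("known compositionally biased fixtures validate correctly", {
  set.seed(47)
  bg <- default_background()
  base <- random_seq(300L)
  cohort <- data.frame(
    id = c("G_RICH_SYN", "PS_RICH_SYN"),
    species = "synthetic", clade = "", kingdom = "", phylum = "", class = "",
    sequence = c(paste0(base, strrep("G", 120L)),     # mimics a G-rich protein
                 paste0(base, strrep("PS", 90L))),    # mimics a P/S-rich one
    stringsAsFactors = FALSE)
  expected <- data.frame(id = c("G_RICH_SYN", "PS_RICH_SYN"),
                         residues = c("G", "P,S"),
                         stringsAsFactors = FALSE)
  verdict <- validate_against_known(cohort, expected, bg)
  expect_true(all(verdict$pass))
})

test_that("planted-multiplier recovery matches the exact binomial oracle", {
  # a 2.0x proline plant at length 500: planted frequency 2f/(1+f), a
  # protein is flagged when its count reaches 1.5 f L; the flagged fraction
  # must sit within 4 SD of the exact binomial detection probability
  bg <- default_background()
  f <- unname(bg[["P"]])
  fp <- 2 * f / (1 + f)
  L <- 500L
  n <- 200L
  p_detect <- pbinom(ceiling(1.5 * f * L) - 1L, L, fp, lower.tail = FALSE)
  spec <- cohort_spec(
    n_proteins = n, length_mean = L, length_sd = 0,
    enrichment_plan = data.frame(residue = "P", multiplier = 2, fraction = 1),
    architecture_plan = c(other = 1), seed = 37L)
  g <- generate_cohort(spec)
  frac <- mean(vapply(compose_cohort(g$cohort, bg),
                      function(p) p$enriched[["P"]], TRUE))
  expect_lt(abs(frac - p_detect), 4 * sqrt(p_detect * (1 - p_detect) / n))
})

test_that("fold-change is monotone in the residue count", {
  bg <- default_background()
  fcs <- vapply(1:8, function(k) {
    s <- paste0(strrep("C", k), strrep("A", 40L - k))
    unname(compose(s, bg, "m")$fold_change[["C"]])
  }, numeric(1L))
  expect_true(all(diff(fcs) > 0))
})
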