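test_that("global alignment matches the enumeration optimum on small pairs", {
  # exhaustive over every pair of length-1 and length-2 strings on {A,C,D,G}
  alpha <- c("A", "C", "D", "G")
  short <- c(alpha, as.vector(outer(alpha, alpha, paste0)))
  for (a in short) {
    for (b in short) {
      expect_equal(global_align(a, b)$score, bf_align_score(a, b),
                   info = paste(a, "vs", b))
    }
  }
  # randomised pairs up to length 6
  set.seed(53)
  for (rep in 1:60) {
    a <- random_seq(sample(3:6, 1L), alpha)
    b <- random_seq(sample(3:6, 1L), alpha)
    expect_equal(global_align(a, b)$score, bf_align_score(a, b),
                 info = paste(a, "vs", b))
  }
})

test_that("alignment identities behave at the extremes", {
  same <- global_align("MKLLAVE", "MKLLAVE")
  expect_equal(same$percent_identity, 100)
  expect_false(grepl("-", same$query_aln, fixed = TRUE))

  diff <- global_align("A", "R")
  expect_equal(diff$percent_identity, 0)

  gap <- global_align("ACDE", "ACE")
  expect_equal(gap$score, 7.5)  # 4 + 9 + 5 - (10 + 0.5)

  expect_error(global_align("", "ACD"), "empty sequence")
})

test_that("motif extraction on the reference against itself is the identity", {
  ref <- synthetic_reference()
  aln <- global_align(ref$sequence, ref$sequence)
  inst <- extract_motifs(aln, ref$annotation, "self")
  expect_equal(nrow(inst), 14L)
  expect_false(any(inst$length_deviant))
  expect_equal(inst$window,
               substring(ref$sequence, ref$annotation$start,
                         ref$annotation$end))
})

test_that("insertions widen and deletions shorten extracted windows", {
  ref <- synthetic_reference()
  ann <- ref$annotation
  pm1 <- ann[ann$motif_id == "PM1", ]
  # insert one residue strictly inside PM1's span
  q_ins <- paste0(substr(ref$sequence, 1L, pm1$start + 1L), "W",
                  substr(ref$sequence, pm1$start + 2L, nchar(ref$sequence)))
  inst <- extract_motifs(global_align(q_ins, ref$sequence), ann, "ins")
  got <- inst[inst$motif_id == "PM1", ]
  expect_equal(got$length, 5L)
  expect_true(got$length_deviant)

  # delete the middle residue of LM3
  lm3 <- ann[ann$motif_id == "LM3", ]
  mid <- lm3$start + 2L
  q_del <- paste0(substr(ref$sequence, 1L, mid - 1L),
                  substr(ref$sequence, mid + 1L, nchar(ref$sequence)))
  inst2 <- extract_motifs(global_align(q_del, ref$sequence), ann, "del")
  got2 <- inst2[inst2$motif_id == "LM3", ]
  expect_equal(got2$length, 4L)
  expect_true(got2$length_deviant)
  # motifs outside the edit are untouched
  expect_false(any(inst2$length_deviant[inst2$motif_id != "LM3"]))

  bad_ann <- data.frame(motif_id = "LM1", start = 1L,
                        end = nchar(ref$sequence) + 5L, canonical_length = 5L)
  expect_error(extract_motifs(global_align(ref$sequence, ref$sequence),
                              bad_ann, "x"), "outside reference")
})

test_that("position frequencies implement the strictly-greater-than-10 rule", {
  inst <- data.frame(
    motif_id = "LM1",
    protein_id = sprintf("p%d", 1:10),
    window = c(rep("LAALL", 6L), rep("AAALL", 3L), "VAALL"),
    length = 5L, length_deviant = FALSE, stringsAsFactors = FALSE)
  cs <- position_frequencies(inst, 5L)
  expect_equal(cs$n_counted, 10L)
  # position 1: 6 L + 3 A + 1 V; V sits at exactly 10% and is suppressed
  expect_equal(unname(cs$position_freq["pos1", c("L", "A", "V")]),
               c(60, 30, 10))
  expect_match(cs$consensus_pattern, "^L\\(60\\)/A\\(30\\)-")
  expect_false(grepl("V(", cs$consensus_pattern, fixed = TRUE))
  # fully conserved positions flagged and at 100%
  expect_equal(unname(cs$fully_conserved),
               c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_true(all(abs(rowSums(cs$position_freq) - 100) < 1e-6))

  # identical instances: all positions 100%, fully conserved
  same <- inst
  same$window <- "LAALL"
  cs2 <- position_frequencies(same, 5L)
  expect_equal(cs2$consensus_pattern,
               "L(100)-A(100)-A(100)-L(100)-L(100)")
  expect_true(all(cs2$fully_conserved))

  # mixed lengths: only canonical-length instances are counted
  mixed <- rbind(inst, data.frame(motif_id = "LM1", protein_id = "p11",
                                  window = "LALL", length = 4L,
                                  length_deviant = TRUE,
                                  stringsAsFactors = FALSE))
  expect_equal(position_frequencies(mixed, 5L)$n_counted, 10L)

  none <- mixed[mixed$length == 4L, ]
  expect_error(position_frequencies(none, 5L), "no canonical-length")
})

test_that("PFM export round-trips and regenerates the consensus exactly", {
  set.seed(59)
  inst <- generate_motif_instances("LM4", 200L, seed = 59)
  cs <- position_frequencies(inst, 5L)
  f <- tempfile(fileext = ".tsv")
  export_pfm(cs, f)
  mat <- read_pfm(f)
  expect_equal(dim(mat), c(5L, 20L))
  expect_equal(unname(rowSums(mat)), rep(100, 5L), tolerance = 1e-9)
  expect_equal(mat, cs$position_freq, tolerance = 1e-9)
  # consensus regenerated from the re-imported matrix is identical
  expect_equal(consensus_pattern(mat), cs$consensus_pattern)
  # and regeneration is idempotent
  expect_equal(consensus_pattern(cs$position_freq),
               consensus_pattern(cs$position_freq))

  fc <- tempfile(fileext = ".tsv")
  export_pfm(cs, fc, what = "counts")
  cmat <- read_pfm(fc)
  expect_equal(unname(rowSums(cmat)), rep(200, 5L))
})

test_that("de novo scanning agrees with a sliding-window oracle", {
  s <- scan_denovo("LAALL")
  expect_equal(s$LxxLL$starts, 1L)
  expect_equal(s$LxxLL$n_greedy, 1L)

  s2 <- scan_denovo("PAAPAAP")
  expect_equal(s2$PxxP$starts, c(1L, 4L))
  expect_equal(s2$PxxP$n_overlapping, 2L)
  expect_equal(s2$PxxP$n_greedy, 2L)  # windows 1-4 and 4-7 share one P only

  expect_equal(scan_denovo("AAAA")$LxxLL$n_overlapping, 0L)

  set.seed(61)
  for (rep in 1:10) {
    s <- random_seq(sample(30:120, 1L), c("L", "P", "A", "G"))
    got <- scan_denovo(s)
    expect_equal(got$LxxLL$starts, bf_scan(s, "L..LL"))
    expect_equal(got$PxxP$starts, bf_scan(s, "P..P"))
  }
})

test_that("synthetic position frequencies converge to the emissions", {
  em <- emission_for_table4("LM6")
  inst <- generate_motif_instances("LM6", 500L, em, seed = 67)
  cs <- position_frequencies(inst, 5L)
  dev <- abs(cs$position_freq / 100 - em) * 100
  expect_lt(max(dev), 5)  # multinomial bound at n = 500
})
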