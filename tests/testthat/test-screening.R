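hit_row <- function(protein_id, domain, start, end, evalue, score) {
  data.frame(protein_id = protein_id, domain_name = domain, pfam_acc = "",
             start = start, end = end, evalue = evalue, score = score,
             stringsAsFactors = FALSE)
}

test_that("TSV hit tables parse, filter by E-value and flag bad rows", {
  f <- write_lines_tmp(c(
    "protein_id\tdomain_name\tstart\tend\tevalue\tscore",
    "p1\tRIX1\t10\t200\t1e-30\t55.0",
    "p1\tNUC202\t300\t400\t0.5\t8.0"), ".tsv")
  expect_message(hits <- parse_domain_hits(f, "tsv"), "dropped 1 hit")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$domain_name, "RIX1")
  expect_equal(hits$start, 10L)

  # custom threshold keeps the weak hit
  hits2 <- parse_domain_hits(f, "tsv", evalue_threshold = 1)
  expect_equal(nrow(hits2), 2L)

  bad <- write_lines_tmp(c(
    "protein_id\tdomain_name\tstart\tend\tevalue\tscore",
    "p1\tRIX1\t200\t10\t1e-30\t55.0"), ".tsv")
  expect_error(parse_domain_hits(bad, "tsv"), "line 2")
})

test_that("domtblout tables parse envelope coordinates and skip comments", {
  pad <- function(...) paste(..., sep = " ")
  f <- write_lines_tmp(c(
    "# comment line",
    pad("RIX1", "PF08167.15", "180", "prot1", "-", "1130", "1e-40", "140",
        "0.1", "1", "1", "1e-41", "2e-40", "139", "0.1", "1", "178", "30",
        "208", "28", "210", "0.98", "description here"),
    pad("NUC202", "PF08166.15", "110", "prot1", "-", "1130", "1e-35", "120",
        "0.1", "1", "2", "1e-36", "3e-35", "119", "0.1", "1", "108", "292",
        "398", "290", "400", "0.97", "-"),
    "#"), ".tsv")
  hits <- parse_domain_hits(f, "domtblout")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$protein_id, c("prot1", "prot1"))
  expect_equal(hits$domain_name, c("RIX1", "NUC202"))
  expect_equal(hits$start, c(28L, 290L))   # envelope, not alignment, coords
  expect_equal(hits$end, c(210L, 400L))
  expect_equal(hits$evalue, c(2e-40, 3e-35))
  expect_equal(hits$pfam_acc, c("PF08167.15", "PF08166.15"))

  trunc <- write_lines_tmp("RIX1 PF08167.15 180 prot1", ".tsv")
  expect_error(parse_domain_hits(trunc, "domtblout"), "line 1")
})

test_that("overlap resolution keeps the best same-domain hit only", {
  # >50% overlap of the shorter hit, same domain: lower E-value survives
  hits <- rbind(hit_row("p1", "NUC202", 300, 400, 1e-20, 90),
                hit_row("p1", "NUC202", 310, 410, 1e-5, 40))
  out <- resolve_overlaps(hits)
  expect_equal(nrow(out), 1L)
  expect_equal(out$evalue, 1e-20)

  # different domains never suppress each other
  hits <- rbind(hit_row("p1", "RIX1", 30, 210, 1e-40, 150),
                hit_row("p1", "NUC202", 100, 250, 1e-35, 120))
  expect_equal(nrow(resolve_overlaps(hits)), 2L)

  # disjoint duplicate-domain hits both survive
  hits <- rbind(hit_row("p1", "NUC202", 290, 400, 1e-35, 120),
                hit_row("p1", "NUC202", 460, 570, 1e-30, 110))
  expect_equal(nrow(resolve_overlaps(hits)), 2L)

  # E-value tie broken by score, then by start
  hits <- rbind(hit_row("p1", "NUC202", 310, 410, 1e-20, 95),
                hit_row("p1", "NUC202", 300, 400, 1e-20, 90))
  out <- resolve_overlaps(hits)
  expect_equal(out$score, 95)
})

test_that("no surviving same-domain pair overlaps more than half the shorter", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:8, 1L)
    starts <- sample(1:500, n)
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      hit_row("p1", sample(c("RIX1", "NUC202"), 1L), starts[[i]],
              starts[[i]] + sample(50:150, 1L), 10^-sample(5:40, 1L),
              sample(30:150, 1L))
    }))
    out <- resolve_overlaps(hits)
    if (nrow(out) >= 2L) {
      for (i in seq_len(nrow(out) - 1L)) {
        for (j in seq.int(i + 1L, nrow(out))) {
          if (out$domain_name[[i]] != out$domain_name[[j]]) next
          ov <- min(out$end[[i]], out$end[[j]]) -
            max(out$start[[i]], out$start[[j]]) + 1L
          shorter <- min(out$end[[i]] - out$start[[i]],
                         out$end[[j]] - out$start[[j]]) + 1L
          expect_lte(ov, 0.5 * shorter)
        }
      }
    }
  }
})

test_that("architecture labels match the rule table exhaustively", {
  for (n_rix in 0:4) {
    for (n_nuc in 0:4) {
      hits <- rbind(
        if (n_rix > 0) do.call(rbind, lapply(seq_len(n_rix), function(i) {
          hit_row("p", "RIX1", 1 + 300 * (i - 1), 200 + 300 * (i - 1),
                  1e-30, 100)
        })),
        if (n_nuc > 0) do.call(rbind, lapply(seq_len(n_nuc), function(i) {
          hit_row("p", "NUC202", 1500 + 200 * (i - 1), 1600 + 200 * (i - 1),
                  1e-30, 100)
        })))
      if (is.null(hits)) hits <- pelpscope:::empty_hits()
      call <- classify_architecture(hits, "p")
      expect_equal(call$label, bf_architecture(n_rix, n_nuc))
      expect_equal(call$n_rix, n_rix)
      expect_equal(call$n_nuc, n_nuc)
    }
  }
})

test_that("taxonomy summary tallies groups and totals correctly", {
  calls <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    n_rix = c(1L, 1L, 0L, 1L, 0L, 0L),
    n_nuc = c(2L, 0L, 0L, 1L, 2L, 1L),
    label = c("PELP1_2NUC", "RIX_only", "other", "PELP1_1NUC", "NUC_only",
              "NUC_only"),
    stringsAsFactors = FALSE)
  taxonomy <- data.frame(
    id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    clade = "Opisthokonta",
    kingdom = c("Metazoa", "Metazoa", "Metazoa", "Fungi", "Fungi", "Fungi"),
    phylum = c("Chordata", "Chordata", "Chordata", "Mucoromycota",
               "Mucoromycota", "Mucoromycota"),
    class = c("Mammalia", "Mammalia", "Mammalia", "Glomeromycetes",
              "Glomeromycetes", "Glomeromycetes"),
    stringsAsFactors = FALSE)
  s <- taxonomy_summary(calls, taxonomy)
  expect_equal(nrow(s), 3L)  # two groups + totals
  fungi <- s[s$class == "Glomeromycetes", ]
  # hand tally: p4 PELP1_1NUC, p5 NUC_onlyx2, p6 NUC_onlyx1
  expect_equal(fungi$n_PELP1, 1L)
  expect_equal(fungi$n_RIX_only, 0L)
  expect_equal(fungi$n_2NUC_only, 1L)
  expect_equal(fungi$n_1NUC_only, 1L)
  mamm <- s[s$class == "Mammalia", ]
  expect_equal(unname(unlist(mamm[, 5:8])), c(1L, 1L, 0L, 0L))
  total <- s[s$clade == "Total", ]
  expect_equal(total$n_PELP1, sum(s$n_PELP1[s$clade != "Total"]))

  # a protein missing from the taxonomy lands in 'unassigned'
  expect_message(
    s2 <- taxonomy_summary(calls, taxonomy[-1L, ]),
    "unassigned")
  expect_true("unassigned" %in% s2$clade)

  # empty input: totals all zero
  s0 <- taxonomy_summary(calls[0L, ], taxonomy)
  expect_equal(s0$n_PELP1, 0L)
})
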