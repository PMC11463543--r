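test_that("SNX27 scanner applies the [S/T]-x-Phi C-terminal grammar", {
  hit <- scan_snx27("MKKAEDSGL", id = "p1")
  expect_equal(hit$matched, "SGL")
  expect_equal(hit$start, 7L)
  expect_true(hit$c_terminal)
  expect_gte(hit$acidic_context, 2L)  # E and D at -5/-4
  expect_null(scan_snx27("MKKAEDSGP"))  # P is not hydrophobic
  expect_null(scan_snx27("MKKAEDGGL"))  # no S/T at -3
  expect_null(scan_snx27("ML"))         # too short
  # acidic context is clipped at the sequence start
  short_hit <- scan_snx27("ESTAL")
  expect_equal(short_hit$acidic_context, 1L)
})

test_that("SNX17 scanner applies the Phi-x-N-x-x-[Y/F] grammar", {
  hits <- scan_snx17("KLANGGYQ", id = "p1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$matched, "LANGGY")
  expect_equal(c(hits$start, hits$end), c(2L, 7L))
  expect_equal(nrow(scan_snx17("KLANGGAQ")), 0L)  # A not in [Y/F]
  # overlapping starts are all reported
  hits2 <- scan_snx17("VANLLYINPPF")
  expect_equal(hits2$start, c(1L, 6L))
})

test_that("cytosolic-tail restriction uses the last TM span", {
  s <- paste0("LANGGY", strrep("G", 10), "LANGGY")
  hits_full <- scan_snx17(s, region = "full")
  expect_equal(hits_full$start, c(1L, 17L))
  topo <- data.frame(start = 8L, end = 12L)
  hits_tail <- scan_snx17(s, region = "cytosolic_tail", topology = topo)
  expect_equal(hits_tail$start, 17L)
  expect_equal(hits_tail$matched, "LANGGY")
  expect_warning(
    hits_fb <- scan_snx17(s, region = "cytosolic_tail"), "topology")
  expect_equal(hits_fb$region_flag, c("full_fallback", "full_fallback"))
})

test_that("scanners agree with the brute-force position checker", {
  withr::with_seed(55, {
    for (i in 1:250) {
      s <- random_aa_seq(sample(10:60, 1))
      expect_equal(!is.null(scan_snx27(s)), snx27_oracle(s), info = s)
      expect_equal(scan_snx17(s)$start, snx17_oracle_starts(s), info = s)
    }
  })
})

test_that("planted motifs are always recovered", {
  sim <- simulate_sequences(80, plant_snx27 = 1, plant_snx17 = 1, seed = 61)
  for (id in names(sim$sequences)) {
    expect_false(is.null(scan_snx27(sim$sequences[[id]], id = id)))
  }
  hits17 <- scan_motifs(sim$sequences, motifs = "SNX17")
  planted17 <- sim$motifs[sim$motifs$motif_type == "SNX17" &
                            sim$motifs$planted, ]
  key_hit <- paste(hits17$protein, hits17$start)
  expect_true(all(paste(planted17$protein, planted17$start) %in% key_hit))
})

test_that("peptide windows follow the stated window arithmetic", {
  seqs <- c(p30 = paste0(strrep("G", 27), "TAL"),
            p10 = paste0("GGGGGGG", "TAL"))
  h30 <- scan_snx27(seqs[["p30"]], id = "p30")
  pep <- extract_peptides(h30, seqs)
  expect_equal(pep$win_start, 16L)
  expect_equal(pep$win_end, 30L)
  expect_equal(nchar(pep$peptide), 15L)
  expect_false(pep$short)

  h10 <- scan_snx27(seqs[["p10"]], id = "p10")
  pep10 <- extract_peptides(h10, seqs)
  expect_equal(pep10$peptide, seqs[["p10"]], ignore_attr = TRUE)
  expect_true(pep10$short)

  # SNX17 window shifted inward at the N-terminus, motif contained
  s40 <- paste0("K", "LANGGY", strrep("Q", 33))
  h17 <- scan_snx17(s40, id = "p40")
  pep17 <- extract_peptides(h17, c(p40 = s40))
  expect_equal(c(pep17$win_start, pep17$win_end), c(1L, 15L))
  expect_true(grepl("LANGGY", pep17$peptide, fixed = TRUE))
  # and at the C-terminus
  s_end <- paste0(strrep("Q", 30), "LANGGY")
  h_end <- scan_snx17(s_end, id = "pe")
  pep_end <- extract_peptides(h_end, c(pe = s_end))
  expect_equal(c(pep_end$win_start, pep_end$win_end), c(22L, 36L))

  bad <- h30
  bad$end <- 99L
  expect_error(extract_peptides(bad, seqs), "out of bounds")
})

test_that("screen sets separate candidates from SNX17-only controls", {
  seqs <- c(both = paste0(strrep("A", 5), "LANGGY", strrep("G", 10), "TAL"),
            only17 = paste0(strrep("A", 5), "LANGGY", strrep("G", 10),
                            "GGP"),
            none = strrep("G", 24))
  h27 <- scan_motifs(seqs, motifs = "SNX27")
  h17 <- scan_motifs(seqs, motifs = "SNX17")
  sets <- build_screen_sets(h27, h17, seqs)
  s27 <- sets$snx27
  expect_equal(s27$protein[s27$role == "candidate"], "both")
  expect_equal(s27$protein[s27$role == "control"], "only17")
  expect_length(intersect(s27$protein[s27$role == "candidate"],
                          s27$protein[s27$role == "control"]), 0L)
  # controls are C-terminal 15-mer windows
  expect_equal(s27$peptide[s27$role == "control"],
               substr(seqs[["only17"]], 10, 24))
})

test_that("ipTM threshold is strict and pass counts are monotone", {
  q <- structure(data.frame(protein = c("a", "b", "c"),
                            motif_type = "SNX27",
                            peptide = c("AAA", "BBB", "CCC"),
                            win_start = 1L, win_end = 3L,
                            role = "candidate", short = TRUE),
                 class = c("peptide_query", "data.frame"))
  scr <- run_screen(q, c(0.6, 0.65, NA), run_config())
  expect_false(scr$results$passed[1])  # exactly 0.6 fails the strict >
  expect_true(scr$results$passed[2])
  expect_false(scr$results$passed[3])  # missing score never passes
  expect_equal(scr$summary$queries, 2L)  # NA excluded from counts

  cuts <- c(0.2, 0.4, 0.6, 0.8)
  passes <- vapply(cuts, function(ct)
    sum(run_screen(q, c(0.6, 0.65, 0.45),
                   run_config(iptm_cutoff = ct))$results$passed), 0L)
  expect_true(all(diff(passes) <= 0))
})

test_that("mock predictor is deterministic, clamped and discriminating", {
  sim <- simulate_sequences(120, plant_snx27 = 0.5, plant_snx17 = 0.5,
                            seed = 71)
  hits <- scan_motifs(sim$sequences)
  sets <- build_screen_sets(hits[hits$motif_type == "SNX27", ],
                            hits[hits$motif_type == "SNX17", ],
                            sim$sequences)
  sc1 <- mock_predictor(sets$snx27, sim$motifs, seed = 5)
  sc2 <- mock_predictor(sets$snx27, sim$motifs, seed = 5)
  expect_identical(sc1, sc2)
  expect_true(all(sc1 >= 0 & sc1 <= 1))

  # zero-noise scores sit exactly at the role means
  sc0 <- mock_predictor(sets$snx27, sim$motifs, seed = 5, sd = 1e-12)
  planted <- paste(sets$snx27$protein, "SNX27") %in%
    paste(sim$motifs$protein[sim$motifs$planted],
          sim$motifs$motif_type[sim$motifs$planted]) &
    sets$snx27$role == "candidate"
  expect_equal(unique(round(sc0[planted], 6)), 0.8)
  expect_equal(unique(round(sc0[!planted], 6)), 0.3)

  # candidate pass-rate beats control pass-rate
  scr <- run_screen(sets$snx27,
                    function(qq) mock_predictor(qq, sim$motifs, seed = 5))
  cand <- scr$results[scr$results$role == "candidate", ]
  ctrl <- scr$results[scr$results$role == "control", ]
  pt <- prop.test(c(sum(cand$passed), sum(ctrl$passed)),
                  c(nrow(cand), nrow(ctrl)), alternative = "greater")
  expect_lt(pt$p.value, 0.01)
})

test_that("per-protein pass uses the best window", {
  q <- structure(data.frame(protein = c("a", "a"), motif_type = "SNX17",
                            peptide = c("P1P", "P2P"), win_start = 1L,
                            win_end = 3L, role = "candidate",
                            short = TRUE),
                 class = c("peptide_query", "data.frame"))
  scr <- run_screen(q, c(0.3, 0.9), run_config())
  expect_equal(nrow(scr$per_protein), 1L)
  expect_true(scr$per_protein$passed)
  expect_equal(scr$per_protein$best_iptm, 0.9)
  expect_equal(scr$summary$queries_passed, 1L)
  expect_equal(scr$summary$proteins_passed, 1L)
})

test_that("logo probabilities and information content behave", {
  pfm1 <- build_logo("STAL", pseudocount = 0)
  expect_equal(pfm1$ic, rep(log2(20), 4), tolerance = 1e-9)
  expect_equal(colSums(pfm1$probs), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)

  peps <- withr::with_seed(3, replicate(1000, random_aa_seq(8)))
  pfm <- build_logo(peps)
  expect_true(all(pfm$ic < 0.2))
  expect_equal(colSums(pfm$probs), rep(1, 8), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_logo(c("AAA", "AAAA")), "equal length")

  # right-alignment pads short peptides with gaps excluded from counts
  aligned <- pad_right_align(c("STAL", "AL"))
  expect_equal(nchar(aligned), c(4L, 4L))
  pfm_gap <- build_logo(aligned, pseudocount = 0)
  expect_equal(unname(pfm_gap$probs["S", 1]), 1)  # gap ignored at pos 1
})

test_that("top-vs-bottom logos separate at motif-defining positions", {
  sim <- simulate_sequences(150, plant_snx27 = 0.5, plant_snx17 = 0,
                            seed = 81)
  hits <- scan_motifs(sim$sequences, motifs = "SNX27")
  h17 <- scan_motifs(sim$sequences, motifs = "SNX17")
  sets <- build_screen_sets(hits, h17, sim$sequences)
  scr <- run_screen(sets$snx27,
                    function(qq) mock_predictor(qq, sim$motifs, seed = 9))
  tb <- top_bottom_queries(scr, n_top = 10, n_bottom = 10,
                           motif_type = "SNX27")
  top_logo <- build_logo(pad_right_align(tb$top$peptide, 15))
  bot_logo <- build_logo(pad_right_align(tb$bottom$peptide, 15))
  # -3 ([S/T]) and -1 (Phi) positions of the 15-mer window
  expect_gt(top_logo$ic[13], bot_logo$ic[13])
  expect_gt(top_logo$ic[15], bot_logo$ic[15])
})
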