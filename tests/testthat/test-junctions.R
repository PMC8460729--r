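# junction detection, primer-remnant repair, cut-site profiles

test_that("junctions are detected at 8/9/10-base coordinate overlaps only", {
  fr <- frags(c(0, 16), c(25, 45))
  jn <- find_junctions(fr)
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$k, 9L)
  expect_equal(c(jn$overlap_start, jn$overlap_end), c(16L, 25L))
  expect_equal(find_junctions(frags(c(0, 15), c(25, 45)))$k, 10L)
  expect_equal(find_junctions(frags(c(0, 17), c(25, 45)))$k, 8L)
  # overlap of 7 is outside the duplication range: no junction
  expect_equal(nrow(find_junctions(frags(c(0, 18), c(25, 45)))), 0L)
  expect_error(find_junctions(fr, k_set = c(7, 9)), "subset of \\{8, 9, 10\\}")
})

test_that("strict mode enforces sequence identity across the overlap", {
  g <- random_genome(c(chr1 = 600), seed = 301)
  fr <- frags(c(0, 241), c(250, 500))
  fr$seq <- get_seq(g, fr$chrom, fr$start, fr$end)
  expect_equal(nrow(find_junctions(fr, reference = g)), 1L)
  # one mismatching base in the duplicated overlap voids the junction
  bad <- fr
  ov <- substring(bad$seq[2], 1, 9)
  flip <- chartr("ACGT", "TGCA", substring(ov, 5, 5))
  substring(bad$seq[2], 5, 5) <- flip
  expect_equal(nrow(find_junctions(bad, reference = g)), 0L)
  expect_equal(nrow(find_junctions(bad, reference = g, strict = FALSE)), 1L)
  # sequence-free fragments fall back to the coordinate test
  nos <- fr; nos$seq <- NA_character_
  expect_equal(nrow(find_junctions(nos, reference = g)), 1L)
})

test_that("primer remnants are trimmed only when all three conditions hold", {
  set.seed(302)
  chr <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  substring(chr, 289, 291) <- "TTT"   # reference at [288,291) must not be CAG
  g <- c(chr1 = chr)
  up <- list(chrom = "chr1", start = 100L, end = 300L)
  # downstream fragment truly [291,500) but observed with a CAG remnant:
  # 12 observed overlap bases of which only 9 truly overlap
  tailed_seq <- paste0("CAG", get_seq(g, "chr1", 291, 500))
  fr <- fragment_table(chrom = "chr1", start = c(100L, 288L), end = c(300L, 500L),
                       id = c("up", "down"),
                       seq = c(get_seq(g, "chr1", 100, 300), tailed_seq))
  expect_equal(nrow(find_junctions(fr, reference = g)), 0L)  # masked
  tp <- trim_primer_remnants(fr, g)
  down <- tp$fragments[tp$fragments$id == "down", ]
  expect_equal(down$start, 291L)
  expect_true(has_flag(down$flags, "primer_trimmed"))
  expect_identical(down$seq, get_seq(g, "chr1", 291, 500))
  expect_equal(sum(tp$repair_log$applied), 1L)
  expect_equal(nrow(find_junctions(tp$fragments, reference = g)), 1L)
  # a terminal CAG that matches the reference is left untouched
  chr2 <- chr
  substring(chr2, 292, 294) <- "CAG"    # [291,294) reads CAG in the reference
  g2 <- c(chr1 = chr2)
  fr2 <- fragment_table(chrom = "chr1", start = c(100L, 291L), end = c(300L, 500L),
                        id = c("up", "down"),
                        seq = get_seq(g2, c("chr1", "chr1"), c(100, 291), c(300, 500)))
  tp2 <- trim_primer_remnants(fr2, g2)
  expect_equal(tp2$fragments$start, c(100L, 291L))
  expect_false(any(tp2$repair_log$applied))
  # repair refused when it would drop the fragment below min_fragment_len
  short <- fragment_table(chrom = "chr1", start = c(100L, 288L), end = c(300L, 315L),
                          id = c("up", "shorty"),
                          seq = c(get_seq(g, "chr1", 100, 300),
                                  paste0("CAG", get_seq(g, "chr1", 291, 315))))
  tp3 <- trim_primer_remnants(short, g)
  expect_false(any(tp3$repair_log$applied))
  expect_true(any(tp3$repair_log$reason == "below min_fragment_len"))
})

test_that("simulated primer tails are repaired in full against truth", {
  g <- random_genome(c(chr1 = 150000), seed = 303)
  cfg <- quiet_config(primer_tail_prob = 0.3, seed = 8)
  lib <- sim_placed(g, mol_df(c(5000, 40000, 80000), c(15000, 50000, 90000)), cfg)
  dd <- deduplicate_fragments(lib$fragments)
  tp <- trim_primer_remnants(dd$fragments, g)
  truth <- lib$truth$fragments
  expect_gt(sum(truth$tail_side != "none"), 10)       # tails actually exercised
  expect_equal(sum(tp$repair_log$applied), sum(truth$tail_interior))
  # repair restores the truth junction census, except at junctions where
  # both facing ends were tailed (unrepairable by a single pass)
  jn <- find_junctions(tp$fragments, reference = g)
  bad5 <- truth[truth$tail_side == "five" & !truth$tail_interior, ]
  bad3 <- truth[truth$tail_side == "three" & !truth$tail_interior, ]
  cuts <- lib$truth$cut_events
  masked <- (cuts$overlap_start %in% (bad5$start + 3L)) |
            (cuts$pos %in% (bad3$end - 3L))
  expect_equal(nrow(jn), sum(!masked))
  expect_setequal(jn$overlap_start, cuts$overlap_start[!masked])
})

test_that("cut-site profiles extract the -2..Dup4 context per k class", {
  set.seed(304)
  chr <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  substring(chr, 99, 104) <- "TAGATC"  # -2,-1 = TA; Dup1..Dup4 = GATC
  g <- c(chr1 = chr)
  jn <- data.frame(up_id = "a", down_id = "b", chrom = "chr1",
                   overlap_start = 100L, overlap_end = 109L, k = 9L,
                   stringsAsFactors = FALSE)
  prof <- cut_site_profile(jn, g)
  expect_named(prof, c("8", "9", "10"))
  expect_equal(prof[["9"]]["G", "Dup1"], 1L)
  expect_equal(prof[["9"]]["A", "-1"], 1L)
  expect_equal(prof[["9"]]["T", "-2"], 1L)
  expect_equal(sum(prof[["9"]][, "Dup1"]), 1L)
  expect_true(all(prof[["8"]] == 0) && all(prof[["10"]] == 0))
  # zero junctions: all-zero profiles, not an error
  empty <- cut_site_profile(jn[0, ], g)
  expect_true(all(vapply(empty, function(m) all(m == 0), logical(1))))
})

test_that("a configured G/AT cut-site preference is recovered in the profile", {
  g <- random_genome(c(chr1 = 400000), seed = 305)
  cfg <- quiet_config(site_bias = 2, seed = 6)
  mols <- mol_df(starts = seq(0, 390000, by = 40000),
                 ends = seq(0, 390000, by = 40000) + 30000)
  ce <- do.call(rbind, lapply(seq_len(nrow(mols)), function(i)
    tagment_molecule(mols[i, ], cfg, g, seed = 600 + i)$cut_events))
  dup1 <- get_seq(g, ce$chrom, ce$overlap_start, ce$overlap_start + 1L)
  # weight 3:1 for G at Dup1 lifts its frequency from 0.25 towards 0.5
  expect_gt(length(dup1), 500)
  expect_gt(mean(dup1 == "G"), 0.35)
  m1 <- get_seq(g, ce$chrom, ce$overlap_start - 1L, ce$overlap_start)
  expect_gt(mean(m1 %in% c("A", "T")), 0.58)
})
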