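# tagmentation simulator: molecule sampling, cut/duplication arithmetic,
# defect geometries, library noise, perfect tiling, determinism

test_that("tagmentation duplication arithmetic and concatenation round-trip", {
  g <- random_genome(c(chr1 = 120000), seed = 201)
  cfg <- quiet_config(seed = 5)
  mols <- mol_df(starts = seq(0, 110000, by = 4000)[1:25],
                 ends = seq(0, 110000, by = 4000)[1:25] + 3000)
  for (i in seq_len(nrow(mols))) {
    tg <- tagment_molecule(mols[i, ], cfg, g, seed = 300 + i)
    frs <- tg$fragments
    # sum of fragment lengths = molecule length + sum of duplications
    expect_equal(sum(frs$end - frs$start),
                 (mols$end[i] - mols$start[i]) + sum(tg$cut_events$k))
    # trimming the k duplicated leading bases reconstitutes the molecule
    ks <- tg$cut_events$k
    pieces <- c(frs$seq[1],
                vapply(seq_len(nrow(frs) - 1), function(j)
                  substring(frs$seq[j + 1], ks[j] + 1), character(1)))
    expect_identical(paste(pieces, collapse = ""),
                     get_seq(g, mols$chrom[i], mols$start[i], mols$end[i]))
    # junction geometry: downstream starts k bases before upstream ends
    expect_equal(frs$start[-1], frs$end[-nrow(frs)] - ks)
  }
})

test_that("junction duplication lengths follow the configured proportions", {
  g <- random_genome(c(chr1 = 60000), seed = 202)
  cfg <- quiet_config(seed = 9)
  ks <- integer()
  i <- 0L
  while (length(ks) < 10000) {
    i <- i + 1L
    tg <- tagment_molecule(list(chrom = "chr1", start = 0L, end = 60000L,
                                molecule_id = sprintf("m%03d", i)),
                           cfg, genome = NULL, seed = 500 + i)
    ks <- c(ks, tg$cut_events$k)
  }
  p9 <- 1889 / 2125
  se <- sqrt(p9 * (1 - p9) / length(ks))
  expect_lt(abs(mean(ks == 9) - p9), 3 * se)
  expect_true(all(ks %in% 8:10))
})

test_that("molecule sampling hits the genome-fraction target", {
  g <- random_genome(c(chr1 = 100000), seed = 203)
  cfg <- sim_config(genome_fraction = 0.10, molecule_len_mean = 10000)
  counts <- vapply(1:200, function(s)
    nrow(sample_molecules(g, cfg, seed = s)), 1L)
  # expectation fraction*genome/mean = 1; mean over 200 seeds stays close
  expect_gt(mean(counts), 0.7)
  expect_lt(mean(counts), 1.3)
  # fraction 0 yields no molecules; fraction >= 1 is rejected
  expect_equal(nrow(sample_molecules(g, quiet_config(genome_fraction = 0))), 0L)
  expect_error(sim_config(genome_fraction = 1), "genome_fraction")
  # placements are independent: forcing two molecules can overlap one locus
  two <- sample_molecules(g, quiet_config(), n_molecules = 25, seed = 11)
  expect_equal(nrow(two), 25L)
  ov <- outer(two$start, two$end, "<") & outer(two$end, two$start, ">")
  expect_true(any(ov[upper.tri(ov)]))   # at 25 x 10 kb in 100 kb overlaps occur
})

test_that("defective-event scenarios reproduce the six artifact geometries", {
  # hand-traced toy coordinates; scale x10 so fragments pass length checks
  g <- random_genome(c(chr1 = 1000), seed = 204)
  cfg <- quiet_config()
  # 0/1: cut suppressed -> two indistinguishable long pieces + short sharing 5'
  frs <- sim_frags_manual(c(0, 241), c(250, 600), g)
  ce <- cuts_manual(pos = 250, k = 9, scenario = "0/1")
  out <- apply_defective_events(frs, ce, cfg, g, seed = 1)
  got <- out$fragments[order(out$fragments$start, out$fragments$end), ]
  expect_equal(got$start, c(0L, 0L, 0L))
  expect_equal(got$end, c(250L, 600L, 600L))
  expect_equal(got$artifact, c(TRUE, FALSE, FALSE))
  # the two long pieces are UFI-identical and collapse at dedup
  expect_equal(deduplicate_fragments(got)$total_unique, 2L)
  # 1/0 mirror: short shares the 3' end
  out <- apply_defective_events(frs, cuts_manual(250, 9, scenario = "1/0"),
                                cfg, g, seed = 1)
  got <- out$fragments[order(out$fragments$start, out$fragments$end), ]
  expect_equal(got$start, c(0L, 0L, 241L))
  expect_equal(got$end, c(600L, 600L, 600L))
  expect_true(got$artifact[got$start == 241][1])
  # 10/01: exactly two overlapping fragments, no shared ends
  frs3 <- sim_frags_manual(c(0, 241, 441), c(250, 450, 600), g)
  ce3 <- cuts_manual(c(250, 450), c(9, 9), scenario = c("10/01", NA))
  out <- apply_defective_events(frs3, ce3, cfg, g, seed = 1)
  got <- out$fragments[order(out$fragments$start), ]
  expect_equal(got$start, c(0L, 241L))
  expect_equal(got$end, c(450L, 600L))
  expect_false(any(got$artifact))
  # 00/11: four fragments, three unique lengths, shared 5' end
  out <- apply_defective_events(frs3, cuts_manual(c(250, 450), c(9, 9),
                                                  scenario = c("00/11", NA)),
                                cfg, g, seed = 1)
  got <- out$fragments
  expect_equal(nrow(got), 4L)
  expect_true(all(got$start == 0L))
  expect_equal(sort(unique(got$end)), c(250L, 450L, 600L))
  expect_equal(sum(got$artifact), 2L)   # the two shorter unique pieces
  # defect_rate 0 leaves tagmentation output untouched
  out <- apply_defective_events(frs3, cuts_manual(c(250, 450), c(9, 9)),
                                quiet_config(defect_rate = 0), g, seed = 1)
  expect_identical(out$fragments[, c("start", "end")], frs3[, c("start", "end")])
})

test_that("library noise stages compose as configured", {
  g <- random_genome(c(chr1 = 50000), seed = 205)
  mols <- mol_df(10000, 20000)
  lib <- sim_placed(g, mols, quiet_config(pcr_copy_mean = 1, seed = 3))
  # no noise: observed library equals the tagmented fragment set
  expect_equal(nrow(lib$fragments), nrow(lib$truth$fragments))
  expect_false(any(duplicated(paste(lib$fragments$start, lib$fragments$end))))
  # PCR only: observed count is the summed copy draw, coordinates unchanged
  lib2 <- sim_placed(g, mols, quiet_config(pcr_copy_mean = 4, seed = 3))
  expect_gt(nrow(lib2$fragments), nrow(lib2$truth$fragments) * 2)
  expect_setequal(unique(paste(lib2$fragments$start, lib2$fragments$end)),
                  paste(lib2$truth$fragments$start, lib2$truth$fragments$end))
  # contamination fragments are solo-labelled and under 200 bases
  lib3 <- sim_placed(g, mols, quiet_config(contamination_rate = 0.5, seed = 3))
  solo <- lib3$truth$fragments[lib3$truth$fragments$molecule == "solo", ]
  expect_gt(nrow(solo), 0)
  expect_true(all(solo$end - solo$start < 200))
  # dropout removes fragments without inventing new ones
  lib4 <- sim_placed(g, mols, quiet_config(dropout_rate = 0.3, seed = 3))
  expect_lt(nrow(lib4$truth$fragments), nrow(lib$truth$fragments))
})

test_that("perfect tiling covers the region with exact 9-base overlaps", {
  pt <- simulate_perfect_tiling("chr1", 2000, 52000, seed = 12)
  ov <- head(pt$end, -1) - tail(pt$start, -1)
  expect_true(all(ov == 9L))
  # union equals the region exactly: no gaps, exact boundaries
  expect_equal(pt$start[1], 2000L)
  expect_equal(pt$end[nrow(pt)], 52000L)
  expect_true(all(tail(pt$start, -1) < head(pt$end, -1)))
  expect_true(all(pt$end - pt$start >= 10))
  lens <- (pt$end - pt$start)[-nrow(pt)]
  expect_true(all(lens >= 35 & lens <= 150))
  # region of exactly one insert: a single fragment, no junctions
  one <- simulate_perfect_tiling("chr1", 0, 150, insert_range = c(150, 150))
  expect_equal(nrow(one), 1L)
})

test_that("simulation is deterministic and truth-consistent", {
  g <- random_genome(c(chr1 = 80000, chr2 = 40000), seed = 206)
  cfg <- sim_config(seed = 77, genome_fraction = 0.15)
  lib1 <- simulate_library(g, cfg)
  lib2 <- simulate_library(g, cfg)
  expect_identical(lib1, lib2)
  # every observed fragment id resolves in fragment_origins
  expect_true(all(lib1$fragments$id %in% names(lib1$truth$fragment_origins)))
  org <- unique(unname(lib1$truth$fragment_origins))
  expect_true(all(org %in% c(lib1$truth$molecules$molecule_id, "solo")))
  # simulator calls leave the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_library(g, cfg)); after <- runif(1)
  expect_identical(before, after)
})
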