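test_that("pairwise overlap is exact-match, directed and asymmetric", {
  ov <- pairwise_overlap(list(A = c("s1", "s2", "s3", "s4"),
                              B = c("s1", "s5")))
  expect_identical(ov["A", "B"], 0.25)
  expect_identical(ov["B", "A"], 0.5)
  expect_identical(ov["A", "A"], 1)
  expect_identical(pairwise_overlap(list(X = "a", Y = "b"))["X", "Y"], 0)
  expect_warning(ov2 <- pairwise_overlap(list(A = "a", E = character(0))),
                 "empty")
  expect_true(is.na(ov2["A", "E"]))
  expect_error(pairwise_overlap(list(A = "a")), "2 samples")
})

test_that("independent synthetic repertoires barely overlap; replicates do", {
  # junction entropy makes the clone space >> 1e8: cross overlap < 1e-3
  r1 <- synthetic_repertoire(ref_fixture, 5000, "naive-like", seed = 1)
  r2 <- synthetic_repertoire(ref_fixture, 5000, "naive-like", seed = 2)
  w1 <- repwell:::clone_read_window(r1$clones)
  w2 <- repwell:::clone_read_window(r2$clones)
  ov <- pairwise_overlap(list(a = w1, b = w2))
  expect_lt(ov["a", "b"], 1e-3)
  # two multinomial samples of the SAME repertoire overlap more than
  # samples from different repertoires, over >= 9/10 seeds
  hits <- 0L
  for (s in 1:10) {
    seed <- HOUSE_SEED + s
    rA <- synthetic_repertoire(ref_fixture, 2000, "memory-like",
                               seed = seed)
    rB <- synthetic_repertoire(ref_fixture, 2000, "memory-like",
                               seed = seed + 5000)
    wA <- repwell:::clone_read_window(rA$clones)
    wB <- repwell:::clone_read_window(rB$clones)
    samp <- function(w, freq, n, sd) with_seed(sd, {
      unique(w[stats::rmultinom(1, n, freq)[, 1] > 0])
    })
    a1 <- samp(wA, rA$clones$frequency, 800, seed + 1)
    a2 <- samp(wA, rA$clones$frequency, 800, seed + 2)
    b1 <- samp(wB, rB$clones$frequency, 800, seed + 3)
    ov <- pairwise_overlap(list(a1 = a1, a2 = a2, b1 = b1))
    if (ov["a1", "a2"] > ov["a1", "b1"]) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("V usage splits tied calls and conserves percentages", {
  ref <- ref_fixture
  ann <- data.frame(v_call = c("IGHV1-2*01", "IGHV1-2*01", "IGHV3-23*01"),
                    occupancy = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  u <- v_usage(ann, ref, weighting = "occupancy")
  expect_equal(u$gene$percent[u$gene$gene == "IGHV1-2"], 50)
  expect_equal(u$gene$percent[u$gene$gene == "IGHV3-23"], 50)
  u2 <- v_usage(ann, ref, weighting = "unique")
  expect_equal(u2$gene$percent[u2$gene$gene == "IGHV1-2"], 200 / 3,
               tolerance = 1e-9)
  expect_lt(abs(sum(u$gene$percent) - 100), 1e-9)
  expect_lt(abs(sum(u$family$percent) - 100), 1e-9)
  # a within-family tie leaves the family percentage unchanged
  ann3 <- data.frame(v_call = c("IGHV4-59*01,IGHV4-59*02", "IGHV1-2*01"),
                     occupancy = c(1L, 1L), stringsAsFactors = FALSE)
  u3 <- v_usage(ann3, ref)
  expect_equal(u3$family$percent[u3$family$family == "IGHV4"], 50)
})

test_that("CDR3 length distributions report histogram, cumulative and mean", {
  ann <- data.frame(cdr3_length = c(45L, 45L, 48L), occupancy = c(1L, 1L, 1L))
  d <- cdr3_length_distribution(ann, weighting = "unique")
  expect_equal(d$mean_length, 46)
  expect_equal(d$histogram$percent, c(200 / 3, 100 / 3))
  expect_equal(d$histogram$cumulative_percent[2], 100)
  expect_true(all(diff(d$histogram$cumulative_percent) >= 0))
  # single clone: a step to 100
  d1 <- cdr3_length_distribution(data.frame(cdr3_length = 48L,
                                            occupancy = 3L))
  expect_identical(nrow(d1$histogram), 1L)
  expect_equal(d1$histogram$cumulative_percent, 100)
  # generator round trip: naive mean ~48 nt, memory ~45 nt
  cln <- build_clone_sequences(ref_fixture, 3000, 0, n_insert_max = 8,
                               seed = HOUSE_SEED)
  clm <- build_clone_sequences(ref_fixture, 3000, 0, n_insert_max = 5,
                               seed = HOUSE_SEED + 1)
  mn <- mean(cln$cdr3_end - cln$cdr3_start)
  mm <- mean(clm$cdr3_end - clm$cdr3_start)
  expect_equal(mn, 48, tolerance = 0.5 / 48)
  expect_equal(mm, 45, tolerance = 0.5 / 45)
})

test_that("substitution-by-occupancy tables conserve their margins", {
  ann <- data.frame(v_mutation_count = c(0L, 0L, 2L, 5L),
                    occupancy = c(1L, 2L, 1L, 1L))
  tab <- shm_by_occupancy(ann)
  expect_identical(sum(tab), 4L)
  expect_identical(as.integer(margin.table(tab, 2)),
                   as.integer(table(ann$occupancy)))
  # all-zero input: a single row
  tab0 <- shm_by_occupancy(data.frame(v_mutation_count = c(0L, 0L),
                                      occupancy = c(1L, 3L)))
  expect_identical(nrow(tab0), 1L)
})

test_that("position profiles weight, split classes and ignore order", {
  # one mutated and one clean clone assigned to the same gene
  cl <- build_clone_sequences(ref_fixture, 2, shm_rate = 0, seed = 8)
  reads <- repwell:::clone_read_window(cl)
  a0 <- assign_germline(reads, ref_fixture)
  # force both onto the same gene for the constructed case
  g <- a0$v_best[1]
  reads <- reads[c(1, 1)]
  r2 <- reads[2]
  gp <- a0$v_gene_start[1] + 50L
  base <- substr(r2, 51, 51)
  r2 <- mutate_at(r2, 51, c(A = "G", G = "A", C = "T", T = "C")[[base]])
  ann <- annotate_clones(c(reads[1], r2), ref_fixture)
  ann$clones$occupancy <- c(1L, 1L)
  prof <- shm_position_profile(ann, g)
  row <- prof[prof$gene_pos == gp, ]
  expect_equal(row$rate, 0.5)
  expect_equal(row$transition_rate, 0.5)
  expect_equal(row$transversion_rate, 0)
  expect_true(all(prof$rate[prof$gene_pos != gp] == 0))
  # order invariance
  ann_rev <- annotate_clones(c(r2, reads[1]), ref_fixture)
  ann_rev$clones$occupancy <- c(1L, 1L)
  expect_equal(shm_position_profile(ann_rev, g), prof)
  # absent gene: empty profile
  expect_identical(nrow(shm_position_profile(ann, "IGHV1-18*01")), 0L)
})

test_that("planted hotspot positions surface in the top rate decile", {
  # single-V reference so every clone profiles onto one gene
  ref1 <- ref_fixture[ref_fixture$segment_class != "V" |
                        ref_fixture$segment_id == "IGHV3-23*01", ]
  v_seq <- ref1$sequence[ref1$segment_id == "IGHV3-23*01"]
  mot <- annotate_motifs(v_seq)
  hot <- which(mot$labels == "hotspot") - 1L          # 0-based gene pos
  planted <- hot[hot >= 40][1:6]                      # always read-covered
  cl <- build_clone_sequences(ref1, 1000, shm_rate = 0.035,
                              n_insert_max = 5,
                              hotspot_positions = planted,
                              hotspot_weight = 60, seed = HOUSE_SEED)
  ann <- annotate_clones(repwell:::clone_read_window(cl), ref1)
  ann$clones$occupancy <- 1L
  prof <- shm_position_profile(ann, "IGHV3-23*01")
  top <- prof$gene_pos[order(-prof$rate)][1:ceiling(nrow(prof) / 10)]
  expect_true(all(planted %in% top))
})

test_that("motif annotation flags GYW/WRC hotspots and SYC/GRS coldspots", {
  m <- annotate_motifs("GCT")
  expect_identical(m$labels[1], "hotspot")           # GYW targets the G
  expect_identical(m$matches$targeted_pos, 0L)
  expect_identical(annotate_motifs("GGA")$matches$name, character(0))
  m2 <- annotate_motifs("AGC")                       # WRC targets the C
  expect_identical(m2$labels[3], "hotspot")
  m3 <- annotate_motifs("CTC")                       # SYC coldspot
  expect_identical(m3$labels[3], "coldspot")
  # hotspot precedence over coldspot on the same base
  m4 <- annotate_motifs("AGCTT")   # WRC targets C at 2; GYW? G C T = yes at 1
  expect_identical(m4$labels[3], "hotspot")
  # non-ACGT stays none
  expect_identical(annotate_motifs("GNT")$labels[2], "none")
  # table round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_table(default_motif_table(), path)
  expect_identical(read_motif_table(path), default_motif_table())
})

test_that("capture fractions reproduce the published percentage bounds", {
  expect_identical(round(capture_fraction(2e7, 6.5e8), 1), 3.1)
  expect_identical(round(capture_fraction(2e7, 3.0e8), 1), 6.7)
  expect_identical(round(capture_fraction(1.5e7, 3.0e8), 1), 5)
  expect_error(capture_fraction(1, 0), "positive")
})
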