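test_that("compile_motif parses bracket notation and wildcards", {
  m <- compile_motif("[DSNTV]L[IL]D[ILMFW]")
  expect_length(m$classes, 5L)
  expect_equal(vapply(m$classes, length, 1L), c(5L, 1L, 2L, 1L, 5L))

  w <- compile_motif("WxxW")
  expect_equal(vapply(w$classes, length, 1L), c(1L, 20L, 20L, 1L))

  expect_error(compile_motif("[L"), "unbalanced")
  expect_error(compile_motif("[LJ]AA"), "invalid residue")
  expect_error(compile_motif("A1A"), "invalid token")
  expect_error(compile_motif("AL"), "at least 3")
})

test_that("scan_sequence finds the known adaptor peptide hits", {
  lib <- cbm_motifs()
  h <- scan_sequence("GVSLIDL", lib$CBM_core, protein_id = "Ent2")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)
  expect_equal(h$matched, "SLIDL")

  expect_equal(nrow(scan_sequence("", lib$CBM)), 0L)

  # Apl2.1: the Asp-extended variant matches, the narrower one does not
  h_wide <- scan_sequence("SQDLLDLF", lib$CBM)
  h_core <- scan_sequence("SQDLLDLF", lib$CBM_core)
  expect_equal(h_wide$matched, "DLLDL")
  expect_equal(h_wide$start, 3L)
  expect_equal(nrow(h_core), 0L)

  h_yap <- scan_sequence("NLNLIDM", lib$CBM)
  expect_equal(h_yap$matched, "NLIDM")
  expect_equal(h_yap$start, 3L)
})

test_that("scanning agrees with the exhaustive window oracle", {
  set.seed(42)
  lib <- cbm_motifs()
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    seq <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
                        n, replace = TRUE), collapse = "")
    for (m in lib) {
      expect_equal(scan_sequence(seq, m)$start, brute_scan(seq, m$classes),
                   info = paste(m$name, seq))
    }
  }
})

test_that("hits round-trip and overlapping matches are all reported", {
  seq <- "TLILDLILDL"   # overlapping CBM-like windows
  h <- scan_sequence(seq, cbm_motifs()$CBM_core)
  expect_equal(h$start, brute_scan(seq, cbm_motifs()$CBM_core$classes))
  for (i in seq_len(nrow(h)))
    expect_equal(substr(seq, h$start[i], h$end[i]), h$matched[i])
})

test_that("disorder filtering honours cutoff, kind and boundaries", {
  seq <- "AAGVSLIDLAA"
  h <- scan_sequence(seq, cbm_motifs()$CBM)
  expect_equal(nrow(h), 1L)
  n <- nchar(seq)

  kept <- filter_by_disorder(h, rep(1, n), cutoff = 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$disorder_mean, 1)
  expect_equal(nrow(filter_by_disorder(h, rep(0, n), cutoff = 0.5)), 0L)

  # pLDDT: strict < at the threshold
  expect_equal(nrow(filter_by_disorder(h, rep(49.9, n), kind = "plddt")), 1L)
  expect_equal(nrow(filter_by_disorder(h, rep(50, n), kind = "plddt")), 0L)

  expect_error(filter_by_disorder(h, rep(1, 3), seq_length = n),
               "does not match")
})

test_that("raising the disorder cutoff never adds hits", {
  set.seed(7)
  seq <- paste(sample(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      400, replace = TRUE), collapse = "")
  h <- scan_sequence(seq, compile_motif("[LI]xx[LI]"))
  scores <- runif(400)
  counts <- vapply(seq(0, 1, by = 0.1), function(cut)
    nrow(filter_by_disorder(h, scores, cutoff = cut)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("scan_proteome aggregates, filters and validates ids", {
  seqs <- c(Ent1 = "GYTLIDL", Ent2 = "GVSLIDL", Ent5.1 = "IPDLIDLDD",
            Yap1801 = "NLNLIDM", Yap1802 = "NPNLIDI", Apl2.1 = "SQDLLDLF")
  res <- scan_proteome(seqs, cbm_motifs()$CBM)
  expect_equal(attr(res, "n_hits"), 6L)
  expect_equal(attr(res, "n_proteins"), 6L)

  expect_equal(attr(scan_proteome(c(a = "GGGGGG"), cbm_motifs()$CBM),
                    "n_hits"), 0L)
  expect_error(scan_proteome(setNames(c("AAA", "AAA"), c("a", "a")),
                             cbm_motifs()$CBM), "duplicate")
})

test_that("proteome scan recovers exactly the disorder-planted motifs", {
  plants <- data.frame(
    protein = 1:3, position = c(10L, 40L, 20L),
    instance = c("DLIDL", "SLIDF", "NLIDM"),
    disordered = c(TRUE, TRUE, FALSE))
  g <- gen_toy_proteome(3L, plants = plants, seed = 11L)
  res <- scan_proteome(g$sequences, cbm_motifs()$CBM, tracks = g$tracks,
                       cutoff = 0.5)
  # background collisions are known from the manifest's exhaustive self-scan
  bg <- g$manifest$all_hits
  planted_keys <- paste(sprintf("prot%03d", plants$protein), plants$position)
  bg_keys <- setdiff(paste(bg$protein_id, bg$start), planted_keys)
  extra <- sum(paste(res$protein_id, res$start) %in% bg_keys)
  expect_equal(nrow(res) - extra, 2L)  # the two disordered plants
  expect_true(all(planted_keys[1:2] %in% paste(res$protein_id, res$start)))
  expect_false(planted_keys[3] %in% paste(res$protein_id, res$start))
})

test_that("FASTA and disorder TSV round-trip through files", {
  tmp <- withr::local_tempdir()
  seqs <- c(p1 = "GVSLIDLKKK", p2 = "MMMMDLIDLMM")
  fa <- file.path(tmp, "x.fa")
  write_fasta(seqs, fa)
  expect_equal(read_fasta(fa), seqs)

  tsv <- file.path(tmp, "d.tsv")
  df <- rbind(data.frame(protein_id = "p1", position = 1:10, score = 0.9),
              data.frame(protein_id = "p2", position = 1:11, score = 0.1))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tracks <- read_disorder_tsv(tsv)
  expect_equal(tracks$p1, rep(0.9, 10))
  res <- scan_proteome(fa, cbm_motifs()$CBM, tracks = tsv, cutoff = 0.5)
  expect_equal(res$protein_id, "p1")
})
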