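test_that("motif location finds first occurrence and handles absence", {
  ref <- make_reference(seed = 1, length = 600, motif = "RWGKPV",
                        motif_position = 300)
  expect_equal(unname(locate_motif(ref$sequence, "RWGKPV")), c(300L, 305L))
  expect_equal(unname(locate_motif("RWGKPV", "RWGKPV")), c(1L, 6L))
  two <- paste0("AAAACCCCC", "RWGKPV", "DDDDD", "RWGKPV", "EEEE")
  expect_warning(span <- locate_motif(two, "RWGKPV"), "first occurrence")
  expect_equal(unname(span), c(10L, 15L))
  # exhaustive-scan oracle for the first occurrence
  starts <- which(vapply(1:(nchar(two) - 5), function(i) {
    substr(two, i, i + 5) == "RWGKPV"
  }, logical(1)))
  expect_equal(span[["start"]], starts[1])
  expect_error(locate_motif("AAAAAAAAAA", "RWGKPV"), "not found")
  fz <- locate_motif("AAARWGKPAAAA", "RWGKPV", fuzzy = TRUE)
  expect_equal(unname(fz), c(4L, 9L))
})

test_that("alignment of identical and substituted sequences is gapless", {
  s <- "ARNDCQEGHILKMFPSTWYV"
  a <- align_pair(s, s)
  expect_false(grepl("-", a$aligned_query))
  expect_false(grepl("-", a$aligned_ref))
  expect_equal(identity_percent(a$aligned_ref, a$aligned_query), 100)
  s2 <- sub("I", "W", s)
  a2 <- align_pair(s2, s)
  expect_false(grepl("-", a2$aligned_query))
  expect_equal(identity_percent(a2$aligned_ref, a2$aligned_query), 95)
})

test_that("a query that is an exact substring aligns gaplessly in place", {
  ref <- "ACDEFGHRWGKPVACDEFGH"
  a <- align_pair("RWGKPV", ref)
  expect_equal(a$aligned_ref, ref)
  expect_equal(a$aligned_query, "-------RWGKPV-------")
  # oracle: plain substring search
  expect_equal(regexpr("RWGKPV", ref, fixed = TRUE)[1], 8L)
})

test_that("degapping aligned strings reproduces the inputs", {
  withr::with_seed(7, {
    for (i in 1:20) {
      q <- random_peptide(sample(3:15, 1))
      r <- random_peptide(sample(3:15, 1))
      a <- align_pair(q, r)
      expect_equal(nchar(a$aligned_query), nchar(a$aligned_ref))
      expect_equal(gsub("-", "", a$aligned_query), q)
      expect_equal(gsub("-", "", a$aligned_ref), r)
    }
  })
})

test_that("alignment score matches the exhaustive DP oracle on short pairs", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  withr::with_seed(11, {
    sub <- e$BLOSUM62
    for (i in 1:60) {
      q <- random_peptide(sample(1:12, 1))
      r <- random_peptide(sample(1:12, 1))
      a <- align_pair(q, r)
      expect_equal(a$score, oracle_overlap_score(q, r, sub),
                   info = paste(q, r))
    }
  })
})

test_that("identity respects the reference-column denominator and gap rule", {
  expect_equal(identity_percent("RWGKPV", "RWGKPV"), 100)
  expect_equal(identity_percent("RWGKPV", "RWGKPA"), 100 * 5 / 6)
  # gap in the query counts as mismatch
  expect_equal(identity_percent("RWGKPV", "RW-KPV", columns = 1:6),
               100 * 5 / 6)
  # columns where the reference is gapped are excluded from the denominator
  expect_equal(identity_percent("RW-KPV", "RWGKPV"), 100)
  expect_error(identity_percent("RWG", "RWGK"), "length")
  # symmetry when neither sequence has gaps
  withr::with_seed(3, {
    for (i in 1:10) {
      x <- random_peptide(8); y <- random_peptide(8)
      expect_equal(identity_percent(x, y), identity_percent(y, x))
    }
  })
})

test_that("epitope window trims to motif +/- flank and clips at ends", {
  ref <- make_reference(seed = 2, length = 600, motif_position = 300)
  win_ref <- substr(ref$sequence, 270, 335)
  a <- align_pair(win_ref, win_ref)
  w <- epitope_window(a, motif_span = c(31L, 36L), flank = 30L)
  expect_equal(nchar(w$trimmed_ref), 66)  # 6 + 2 * 30 reference positions
  expect_equal(w$motif_cols, 31:36)
  # flank clipped at the left end of the reference
  near_start <- make_reference(seed = 3, length = 200, motif_position = 10)
  full <- align_pair(near_start$sequence, near_start$sequence)
  w2 <- epitope_window(full, motif_span = c(10L, 15L), flank = 30L)
  expect_equal(nchar(w2$trimmed_ref), 45)  # positions 1..45
  # a query aligned wholly left of the motif does not cover the epitope
  off <- list(aligned_query = paste0("RWGKPV", strrep("-", 10)),
              aligned_ref = random_peptide(16))
  expect_null(epitope_window(off, motif_span = c(11L, 16L), flank = 2L))
})

test_that("screening recovers planted per-family identities", {
  tp <- make_test_population()
  hits <- screen_orfs(tp$pop$orfs, tp$pop$taxonomy, tp$ref, flank = 30)
  expect_equal(nrow(hits), 13)
  byfam <- split(hits, hits$family)
  expect_true(all(abs(byfam$fam_a$motif_identity - 100) < 1e-9))
  expect_true(all(abs(byfam$fam_b$motif_identity - 100 * 5 / 6) < 1e-9))
  expect_true(all(abs(byfam$fam_c$motif_identity - 100 * 4 / 6) < 1e-9))
  expect_true(all(abs(byfam$fam_a$window_identity - 100) < 1e-9))
  # monotonicity: more motif mismatches never increase motif identity
  expect_true(mean(byfam$fam_a$motif_identity) >=
                mean(byfam$fam_b$motif_identity))
  expect_true(mean(byfam$fam_b$motif_identity) >=
                mean(byfam$fam_c$motif_identity))
  # unknown taxonomy becomes "unassigned"
  h2 <- screen_orfs(tp$pop$orfs[1], character(0), tp$ref)
  expect_equal(h2$family, "unassigned")
  expect_error(screen_orfs(character(0), character(0), tp$ref), "empty")
})

test_that("family summaries aggregate counts and mean identities", {
  hits <- data.frame(
    orf_id = paste0("o", 1:5),
    family = c("fa", "fa", "fa", "fb", "fb"),
    covers_epitope = TRUE,
    motif_identity = c(100, 100, 50, 100, 100),
    window_identity = c(90, 80, 70, 95, 85),
    trimmed_ref = "X", trimmed_query = "X"
  )
  class(hits) <- c("mimicry_hits", "data.frame")
  s <- summarize_families(hits)
  expect_equal(s$family, c("fa", "fb"))  # sorted by n_sequences desc
  expect_equal(s$n_sequences, c(3L, 2L))
  expect_equal(s$n_full_motif, c(2L, 2L))
  expect_equal(s$mean_window_identity, c(80, 90))
  expect_true(all(s$n_full_motif <= s$n_sequences))
  empty <- summarize_families(hits[0, ])
  expect_equal(nrow(empty), 0)
  # generator truth reproduced exactly per family
  tp <- make_test_population()
  sh <- summarize_families(
    screen_orfs(tp$pop$orfs, tp$pop$taxonomy, tp$ref))
  truth <- tp$pop$truth$full_motif
  expect_equal(setNames(sh$n_full_motif, sh$family)[names(truth)], truth)
})

test_that("homology distribution bins hits and conserves totals", {
  hits <- data.frame(
    orf_id = paste0("o", 1:4), family = c("fa", "fa", "fb", "fb"),
    covers_epitope = TRUE, motif_identity = 100,
    window_identity = c(10, 60, 100, 100),
    trimmed_ref = "X", trimmed_query = "X"
  )
  class(hits) <- c("mimicry_hits", "data.frame")
  d <- homology_distribution(hits, bin_edges = c(0, 50, 100))
  expect_equal(unname(d["fa", ]), c(1L, 1L))
  expect_equal(unname(d["fb", ]), c(0L, 2L))  # identity 100 in closed last bin
  expect_equal(unname(rowSums(d)), c(2L, 2L))
  expect_error(homology_distribution(hits, bin_edges = c(0, 50, 40, 100)))
})
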