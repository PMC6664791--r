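test_that("baseline engine satisfies the fold contract", {
  eng <- baseline_engine()
  f <- fold(rna_sequence("a", "AAAA"), eng)
  expect_equal(f$structure, "....")
  expect_equal(f$pmfe, 0)

  f2 <- fold(rna_sequence("h", "GGGAAACCC"), eng)
  expect_equal(nchar(f2$structure), 9)
  expect_gte(sum(strsplit(f2$structure, "")[[1]] == "("), 3)
  expect_lt(f2$pmfe, 0)
  # determinism
  expect_identical(fold(rna_sequence("h", "GGGAAACCC"), eng), f2)
  expect_error(fold(rna_sequence("n", "ACGN"), eng), "non-ACGU")
})

test_that("baseline engine matches brute-force enumeration of nested pairings", {
  eng <- baseline_engine()
  set.seed(11)
  seqs <- c("GGGAAACCC", "GCGCAAAAGCGC", "AUAUAUAUAU",
            replicate(8, random_rna(sample(6:11, 1))))
  for (s in seqs) {
    f <- fold(rna_sequence("s", s), eng)
    expect_equal(-f$pmfe, max_pairing_weight_bruteforce(s), info = s)
    # structure is properly nested with min hairpin loop 3 and admissible pairs
    for (p in dotbracket_pairs(f$structure)) {
      expect_gte(p[2] - p[1], 4)
      bases <- paste0(substr(s, p[1], p[1]), substr(s, p[2], p[2]))
      expect_true(bases %in% c("GC", "CG", "AU", "UA", "GU", "UG"), info = s)
    }
  }
})

test_that("stub engine returns preloaded results; fold_result validates", {
  eng <- stub_engine(list(GGGAAACCC = list("(((...)))", -1.0)))
  f <- fold(rna_sequence("x", "GGGAAACCC"), eng)
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$pmfe, -1.0)
  expect_error(fold(rna_sequence("y", "ACGU"), eng), "no entry")

  expect_error(fold_result("((..", 0), "unbalanced")
  expect_error(fold_result("(x)", 0), "outside")
  expect_error(fold_result("(...)", 1.5), "pmfe")
  expect_equal(fold_result("....", -3)$pmfe, 0)  # no pairs -> energy 0
})

test_that("external engine parses RNAfold-style output and reports failures", {
  fake <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo '>x'", "echo 'GGGAAACCC'",
               "echo '(((...))) ( -1.20)'"), fake)
  Sys.chmod(fake, "0755")
  eng <- external_engine(fake, args = character(0))
  f <- fold(rna_sequence("x", "GGGAAACCC"), eng)
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$pmfe, -1.2)
  expect_match(f$engine, "^external:")

  bad <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo 'garbage'"), bad)
  Sys.chmod(bad, "0755")
  expect_error(fold(rna_sequence("x", "GGGAAACCC"), external_engine(bad, character(0))),
               "engine error")
})

test_that("triplet features follow the worked examples", {
  tf <- triplet_features(rna_sequence("x", "ACGU"),
                         fold_result("....", 0))
  expect_length(tf, 32)
  expect_equal(unname(tf["C..."]), 0.5)
  expect_equal(unname(tf["G..."]), 0.5)
  expect_equal(sum(tf), 1)

  tf2 <- triplet_features(rna_sequence("h", "GGGAAACCC"),
                          fold_result("(((...)))", -1))
  expected <- c("G(((" = 1, "G((." = 1, "A(.." = 1, "A..." = 1,
                "A..(" = 1, "C.((" = 1, "C(((" = 1) / 7
  expect_equal(tf2[names(expected)], expected)
  expect_equal(sum(tf2), 1)
  expect_equal(sum(tf2 > 0), 7)

  expect_error(triplet_features(rna_sequence("s", "AC"),
                                fold_result("..", 0)), "degenerate")
})

test_that("triplet vectors are simplex points for random folded sequences", {
  set.seed(21)
  eng <- baseline_engine()
  for (i in 1:25) {
    s <- random_rna_seq(paste0("t", i), sample(3:60, 1))
    tf <- triplet_features(s, fold(s, eng))
    expect_length(tf, 32)
    expect_true(all(tf >= 0))
    expect_equal(sum(tf), 1)
  }
})

test_that("dinucleotide shuffle preserves composition and terminals", {
  expect_equal(dinucleotide_shuffle(rna_sequence("a", "AAAA"), 1)$residues,
               "AAAA")
  expect_equal(dinucleotide_shuffle(rna_sequence("a", "ACAC"), 1)$residues,
               "ACAC")  # admissible set is a singleton
  expect_error(dinucleotide_shuffle(rna_sequence("a", "A")), "degenerate")
  expect_error(dinucleotide_shuffle(rna_sequence("a", "ACGN")), "non-ACGU")

  s <- random_rna_seq("r", 200)
  out <- dinucleotide_shuffle(s, rng_seed = 9)
  expect_equal(dinuc_counts(out$residues), dinuc_counts(s$residues))
  expect_equal(substr(out$residues, 1, 1), substr(s$residues, 1, 1))
  expect_equal(substr(out$residues, 200, 200), substr(s$residues, 200, 200))
  # seeded reproducibility; different seeds explore the admissible set
  expect_equal(dinucleotide_shuffle(s, rng_seed = 9)$residues, out$residues)
})

test_that("qmfe follows the n/(N+1) formula and tie rule", {
  # homopolymer: every shuffle identical, pmfe ties count toward n
  q <- qmfe(rna_sequence("a", strrep("A", 50)), N = 10,
            engine = baseline_engine(), rng_seed = 1)
  expect_equal(q$n, 10L)
  expect_equal(q$qmfe, 10 / 11)

  # stub engine: original -10; exactly 3 of 9 shuffles at -11.
  # AAAACCCCGGGGUUUU's shuffles are enumerable by seed: use a counting stub.
  orig <- strrep("AU", 10)
  calls <- new.env(); calls$i <- 0L
  # first call folds the original (-10); shuffle calls 2..4 are more stable
  eng <- structure(list(name = "count-stub", fold_fun = function(seq) {
    calls$i <- calls$i + 1L
    pm <- if (calls$i == 1L) -10 else if (calls$i <= 4L) -11 else -9
    db <- paste0("(", strrep(".", seq$length - 2L), ")")
    fold_result(db, pm, "count-stub")
  }), class = "folding_engine")
  q2 <- qmfe(rna_sequence("x", orig), N = 9, engine = eng, rng_seed = 2)
  expect_equal(q2$n, 3L)
  expect_equal(q2$qmfe, 3 / 10)
  expect_equal(q2$pmfe_original, -10)

  expect_error(qmfe(rna_sequence("x", orig), N = 0), "N must be")
})

test_that("qmfe bounds and monotonicity hold", {
  s <- random_rna_seq("m", 40)
  set.seed(3)
  for (N in c(1, 5, 9)) {
    q <- qmfe(s, N = N, engine = baseline_engine(), rng_seed = 4)
    expect_gte(q$qmfe, 0)
    expect_lte(q$qmfe, N / (N + 1))
    if (N == 1) expect_true(q$qmfe %in% c(0, 0.5))
  }
  # with a fixed null, a more stable original never raises qmfe
  null_pmfe <- c(-5, -8, -2, -7)
  qm <- function(orig) sum(null_pmfe <= orig) / (length(null_pmfe) + 1)
  origs <- seq(-10, 0, by = 0.5)
  expect_true(all(diff(vapply(origs, qm, 0)) >= 0))
})

test_that("structural feature vector is the 33-entry concatenation", {
  s <- rna_sequence("h", "GGGAAACCCGGGAAACCC")
  sv <- structural_feature_vector(s, engine = baseline_engine(), N = 5,
                                  rng_seed = 6)
  expect_length(sv, 33)
  expect_equal(names(sv)[33], "QMFE")
  f <- fold(s, baseline_engine())
  expect_equal(sv[1:32], triplet_features(s, f))
  q <- qmfe(s, N = 5, engine = baseline_engine(), rng_seed = 6)
  expect_equal(unname(sv["QMFE"]), q$qmfe)
})
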