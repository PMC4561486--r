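test_that("hexamer scan is an exact string match in the +1..+9 window", {
  cds <- "ATGCCCTGAGGGTGCAAACCC"
  hits <- scan_hexamer(cds, 7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 1)
  expect_equal(hits$variant, "GGGTGC")
  expect_equal(hits$adjacency, "adjacent")

  # offset 4: proximal
  cds2 <- "ATGCCCTGAAAAGGGTGTCCCAAA"
  hits2 <- scan_hexamer(cds2, 7)
  expect_equal(hits2$offset, 4)
  expect_equal(hits2$adjacency, "proximal")

  # motif-free control
  expect_equal(nrow(scan_hexamer("ATGCCCTGAAAACCCAAACCC", 7)), 0)
  expect_error(scan_hexamer("ATGCCC", 1), class = "spsevo_position_error")
})

test_that("folding matches brute-force enumeration on short sequences", {
  expect_equal(fold_window("AAAAAAAAAA")$score, 0)
  expect_equal(fold_window("GGGGAAACCCC")$score, 12)
  withr::with_seed(51, {
    for (rep in 1:100) {
      n <- sample(8:14, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      expect_equal(fold_window(seq)$score, oracle_fold_max(seq),
                   info = seq)
    }
  })
})

test_that("pair lists are always nested and respect the minimum loop", {
  withr::with_seed(52, {
    for (rep in 1:25) {
      seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      f <- fold_window(seq)
      expect_true(is_nested_dotbracket(f$dotbracket))
      if (nrow(f$pairs)) {
        expect_true(all(f$pairs$j - f$pairs$i >= 4))
        expect_true(all(f$pairs$i < f$pairs$j))
      }
    }
  })
})

test_that("planted recoding elements are recovered and classified", {
  for (s in 1:25) {
    sre <- generate_recoding_window("SRE", seed = s)
    f <- fold_window(sre$window, sre$uga_pos)
    expect_gte(f$n_stems, 1)
    expect_equal(classify_recoding_element(f), "SRE")

    hre <- generate_recoding_window("HRE", seed = s)
    fh <- fold_window(hre$window, hre$uga_pos)
    expect_gte(fh$n_stems, 3)
    expect_equal(classify_recoding_element(fh), "HRE")

    none <- generate_recoding_window("none", seed = s)
    fn <- fold_window(none$window, none$uga_pos)
    expect_equal(classify_recoding_element(fn), "none")
  }
})

test_that("a hairpin planted around a gene's UGA is found by folding", {
  pr <- seed_profile()
  g <- generate_sps_gene(pr, site_residue = "U", hairpin = TRUE, seed = 5)
  u <- g$truth$uga_nt_pos
  lo <- max(1, u - 60)
  win <- substr(g$cds, lo, min(nchar(g$cds), u + 62))
  f <- fold_window(win, u - lo + 1)
  expect_gte(f$n_stems, 1)
  expect_false(f$uga_context == "unpaired_outside")
})

test_that("prokaryotic-mode scan calls a lone downstream stem bSECIS-like", {
  # single GC hairpin strictly 3' of the UGA
  win <- paste0(strrep("A", 40), "TGA", strrep("A", 6), "GGGGGGGG", "AAA",
                "CCCCCCCC", strrep("A", 20))
  f <- fold_window(win, 41)
  expect_equal(f$n_stems, 1)
  expect_equal(classify_recoding_element(f, mode = "prokaryotic"),
               "bSECIS-like")
  expect_equal(classify_recoding_element(f, mode = "eukaryotic"), "SRE")
})

test_that("consensus folding finds shared structure and covariation", {
  base <- generate_recoding_window("SRE", seed = 3)
  # identical rows: consensus equals the single-sequence fold, covariation 0
  rows <- setNames(rep(base$window, 4), paste0("s", 1:4))
  cons <- consensus_fold(rows, uga_pos = base$uga_pos)
  single <- fold_window(base$window, base$uga_pos)
  expect_equal(cons$pairs$i, single$pairs$i)
  expect_equal(cons$pairs$j, single$pairs$j)
  expect_equal(cons$covariation, 0)

  # one compensatory G:C -> A:T double substitution at a planted pair
  p <- single$pairs[ceiling(nrow(single$pairs) / 2), ]
  mut <- base$window
  substr(mut, p$i, p$i) <- "A"
  substr(mut, p$j, p$j) <- "T"
  rows2 <- setNames(c(rep(base$window, 3), mut), paste0("s", 1:4))
  cons2 <- consensus_fold(rows2, uga_pos = base$uga_pos)
  expect_gte(cons2$covariation, 1)

  # shuffling residues within each row destroys the pairability consensus
  # (a shared permutation would merely relocate complementary column pairs)
  withr::with_seed(53, {
    wide <- vapply(1:6, function(i) {
      w <- generate_recoding_window("SRE", seed = i)
      substr(w$window, 30, 95)
    }, character(1))
    names(wide) <- paste0("r", 1:6)
    empty <- 0
    for (rep in 1:100) {
      shuf <- vapply(wide, function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, character(1))
      cf <- consensus_fold(shuf)
      if (nrow(cf$pairs) == 0) empty <- empty + 1
    }
    expect_gte(empty, 95)
  })
})
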