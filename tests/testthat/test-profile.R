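test_that("profile frequencies use add-one pseudocounts over 21 symbols", {
  aligned <- c(a = "MU", b = "M-")
  pr <- build_profile(aligned, sec_column = 2)
  # column 2 has a single non-gap symbol (U): frequency (1+1)/(1+21)
  expect_equal(unname(pr$freq["U", 2]), 2 / 22)
  expect_equal(sum(pr$freq[, 2]), 1)
  # modal symbol scores highest in every column
  aligned2 <- c(a = "MAUW", b = "MAUW", c = "MAUW")
  pr2 <- build_profile(aligned2, sec_column = 3)
  for (j in 1:4) {
    expect_equal(names(which.max(pr2$score[rownames(pr2$freq), j])),
                 strsplit("MAUW", "")[[1]][j])
  }
  expect_error(build_profile(c(a = "MA", b = "MAA"), 1),
               class = "spsevo_ragged_error")
  expect_error(build_profile(c(a = "M-", b = "M-"), 2),
               class = "spsevo_profile_error")
})

test_that("the packaged profile carries both U and C at the Sec column", {
  pr <- seed_profile()
  col <- vapply(pr$alignment, function(s) substr(s, pr$sec_column,
                                                 pr$sec_column), character(1))
  expect_true(all(c("U", "C") %in% col))
  expect_gt(pr$freq["U", pr$sec_column], 1 / 22)
})

test_that("profile members self-map and report their own site residue", {
  pr <- seed_profile()
  for (id in names(pr$alignment)) {
    gapped <- strsplit(pr$alignment[[id]], "")[[1]]
    member <- paste(gapped[gapped != "-"], collapse = "")
    aln <- align_to_profile(member, pr)
    call <- call_site_residue(aln, pr, gene_id = id)
    expect_equal(call$residue, gapped[pr$sec_column], info = id)
    expect_true(call$confident, info = id)
    # identity mapping after gap removal
    non_gap_cols <- which(gapped != "-")
    expect_equal(aln$mapping[non_gap_cols], seq_along(non_gap_cols))
  }
})

test_that("overlap alignment matches exhaustive mapping search on toy profiles", {
  # oracle: enumerate every monotone injective column -> position mapping,
  # score = column log-odds + affine gap costs, free terminal overhangs
  # Free-end-gap semantics: at each terminus the overhang is free in one
  # sequence only; a simultaneous overhang in both is bridged by a penalized
  # gap (the cheaper of the two runs).
  oracle_align <- function(protein, profile, go = 11, ge = 1) {
    p <- strsplit(protein, "")[[1]]
    L <- profile$n_columns
    n <- length(p)
    best <- 0
    gap_cost <- function(len) if (len <= 0) 0 else go + (len - 1) * ge
    enum <- function(col, last_col, last_pos, acc) {
      if (!is.na(last_pos)) {
        end_pen <- min(gap_cost(L - last_col), gap_cost(n - last_pos))
        best <<- max(best, acc - end_pen)
      }
      if (col > L) return()
      enum(col + 1, last_col, last_pos, acc)
      for (pos in seq_len(n)) {
        if (!is.na(last_pos) && pos <= last_pos) next
        sc <- profile$score[p[pos], col]
        pen <- if (is.na(last_pos)) {
          min(gap_cost(col - 1), gap_cost(pos - 1))
        } else {
          gap_cost(col - last_col - 1) + gap_cost(pos - last_pos - 1)
        }
        enum(col + 1, col, pos, acc + sc - pen)
      }
    }
    enum(1, NA, NA, 0)
    best
  }
  withr::with_seed(61, {
    aa20 <- setdiff(spsevo:::AA_ALPHABET_21, "U")
    for (rep in 1:8) {
      L <- sample(4:6, 1)
      base <- paste(c(sample(aa20, L - 1, TRUE), "U"), collapse = "")
      aligned <- setNames(rep(base, 3), c("a", "b", "c"))
      pr <- build_profile(aligned, sec_column = L)
      prot <- paste(sample(c(aa20, "U"), sample(4:7, 1), TRUE),
                    collapse = "")
      got <- align_to_profile(prot, pr)$score
      expect_equal(got, oracle_align(prot, pr), tolerance = 1e-9,
                   info = prot)
    }
  })
})

test_that("unrelated terminal prefixes dangle without shifting the core", {
  pr <- seed_profile()
  member <- gsub("-", "", pr$alignment[[2]])
  withr::with_seed(62, {
    prefix <- paste(sample(setdiff(spsevo:::AA_ALPHABET_21, "U"), 10, TRUE),
                    collapse = "")
  })
  aln0 <- align_to_profile(member, pr)
  aln1 <- align_to_profile(paste0(prefix, member), pr)
  shift <- aln1$mapping - aln0$mapping
  core <- !is.na(aln0$mapping) & !is.na(aln1$mapping)
  expect_true(all(shift[core] == 10))
})

test_that("non-homologous input is rejected by the confidence threshold", {
  pr <- seed_profile()
  member <- gsub("-", "", pr$alignment[[1]])
  reversed <- paste(rev(strsplit(member, "")[[1]]), collapse = "")
  call <- call_site_residue(align_to_profile(reversed, pr), pr)
  expect_false(call$confident)
  expect_lt(call$flank_identity, 0.4)
  # empirical null: shuffled members score below genuine members
  withr::with_seed(63, {
    real_score <- align_to_profile(member, pr)$score
    shuf_scores <- vapply(1:50, function(i) {
      s <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
      align_to_profile(s, pr)$score
    }, numeric(1))
    expect_gt(real_score, max(shuf_scores))
  })
})
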