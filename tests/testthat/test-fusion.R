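test_that("ORF extension stops at the flanking stops, both strands", {
  pr <- seed_profile()
  # no fusion: planted stops bound the gene immediately
  g <- generate_sps_gene(pr, site_residue = "C", seed = 71)
  ext <- extend_orf(g$genome, g$annotation)
  expect_equal(ext$up_codons, 0L)
  expect_equal(ext$down_codons, 0L)
  expect_equal(ext$cds, g$cds)

  # planted 150-aa N-terminal fusion: >= 450 nt gained upstream
  gf <- generate_sps_gene(pr, site_residue = "C", fusion_side = "N",
                          fusion_len = 150, seed = 72)
  extf <- extend_orf(gf$genome, gf$annotation)
  expect_gte(3 * extf$up_codons, 450)
  expect_equal(extf$down_codons, 0L)

  # strand symmetry: the minus-strand twin extends identically
  gm <- generate_sps_gene(pr, site_residue = "C", fusion_side = "N",
                          fusion_len = 150, strand = "-", seed = 72)
  extm <- extend_orf(gm$genome, gm$annotation)
  expect_equal(extm$up_codons, extf$up_codons)
  expect_equal(extm$cds, extf$cds)

  bad <- g$annotation
  bad$end <- nchar(g$genome[[1]]) + 9
  expect_error(extend_orf(g$genome, bad), class = "spsevo_coord_error")
})

test_that("extensions are reported against the profile with the threshold", {
  pr <- seed_profile()
  gf <- generate_sps_gene(pr, site_residue = "C", fusion_side = "N",
                          fusion_len = 150, seed = 73)
  ext <- extend_orf(gf$genome, gf$annotation)
  prot <- translate_cds(ext$cds)
  rep150 <- detect_extension(prot, pr, gene_id = "gf")
  expect_equal(nrow(rep150), 1)
  expect_equal(rep150$side, "N")
  expect_lte(abs(rep150$extension_len - 150), 10)

  # short extension below the default threshold is not reported
  g20 <- generate_sps_gene(pr, site_residue = "C", fusion_side = "N",
                           fusion_len = 20, seed = 74)
  e20 <- extend_orf(g20$genome, g20$annotation)
  expect_equal(nrow(detect_extension(translate_cds(e20$cds), pr)), 0)

  # no fusion planted: empty report
  g0 <- generate_sps_gene(pr, site_residue = "U", seed = 75)
  e0 <- extend_orf(g0$genome, g0$annotation)
  expect_equal(nrow(detect_extension(translate_cds(e0$cds), pr)), 0)

  # C-terminal fusion is reported on the C side
  gc <- generate_sps_gene(pr, site_residue = "C", fusion_side = "C",
                          fusion_len = 120, seed = 76)
  ec <- extend_orf(gc$genome, gc$annotation)
  repc <- detect_extension(translate_cds(ec$cds), pr, gene_id = "gc")
  expect_equal(repc$side, "C")
  expect_lte(abs(repc$extension_len - 120), 10)
})

test_that("extension detection never alters the core site call", {
  pr <- seed_profile()
  gf <- generate_sps_gene(pr, site_residue = "U", fusion_side = "N",
                          fusion_len = 150, seed = 77)
  ext <- extend_orf(gf$genome, gf$annotation)
  prot <- translate_cds(ext$cds)
  call <- call_site_residue(align_to_profile(prot, pr), pr)
  expect_equal(call$residue, "U")
  expect_true(call$confident)
})

test_that("recurrent planted domains cluster into their families", {
  pr <- seed_profile()
  withr::with_seed(81, {
    aa20 <- setdiff(spsevo:::AA_ALPHABET_21, c("U", "M"))
    domA <- paste(sample(aa20, 150, TRUE), collapse = "")
    domB <- paste(sample(aa20, 150, TRUE), collapse = "")
    mutate_dom <- function(d, k = 8) {
      x <- strsplit(d, "")[[1]]
      pos <- sample(length(x), k)
      x[pos] <- sample(aa20, k, TRUE)
      paste(x, collapse = "")
    }
    reports <- dplyr::bind_rows(
      lapply(1:5, function(i) tibble::tibble(
        gene_id = paste0("a", i), side = "N", extension_len = 150L,
        extension_sequence = mutate_dom(domA)
      )),
      lapply(1:3, function(i) tibble::tibble(
        gene_id = paste0("b", i), side = "N", extension_len = 150L,
        extension_sequence = mutate_dom(domB)
      ))
    )
  })
  cl <- cluster_extensions(reports)
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(as.integer(table(cl$cluster_id)[c("1", "2")]), c(5L, 3L))
  expect_true(all(cl$confidence == "high"))
  # clustering is invariant to input order
  cl2 <- cluster_extensions(reports[sample(nrow(reports)), ])
  expect_equal(dplyr::arrange(cl, gene_id)$cluster_id,
               dplyr::arrange(cl2, gene_id)$cluster_id)

  single <- cluster_extensions(reports[1, ])
  expect_equal(single$cluster_id, 1L)
  expect_equal(single$confidence, "low")
})

test_that("unrelated random extensions stay below the linkage threshold", {
  withr::with_seed(82, {
    aa20 <- setdiff(spsevo:::AA_ALPHABET_21, c("U", "M"))
    n_linked <- 0
    for (rep in 1:200) {
      a <- paste(sample(aa20, 150, TRUE), collapse = "")
      b <- paste(sample(aa20, 150, TRUE), collapse = "")
      if (spsevo:::identity_global(a, b) >= 0.30) n_linked <- n_linked + 1
    }
    expect_equal(n_linked, 0)
  })
})
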