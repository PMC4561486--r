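test_that("species overlap labels duplications after parallel paralogy", {
  tr <- ape::read.tree(text = "((Hsap_1,Mmus_1),(Hsap_2,Mmus_2));")
  sp <- c(Hsap_1 = "Hsap", Mmus_1 = "Mmus", Hsap_2 = "Hsap",
          Mmus_2 = "Mmus")
  lab <- label_duplications(tr, sp)
  root <- length(tr$tip.label) + 1L
  expect_equal(lab$label[lab$node == root], "duplication")
  expect_true(all(lab$label[lab$node != root] == "speciation"))

  tr2 <- ape::read.tree(text = "((Hsap,Mmus),Drer);")
  sp2 <- setNames(c("Hsap", "Mmus", "Drer"), tr2$tip.label)
  expect_true(all(label_duplications(tr2, sp2)$label == "speciation"))

  expect_error(label_duplications(tr2, sp2[-1]),
               class = "spsevo_leaf_error")
})

test_that("random trees agree with a naive set-intersection oracle", {
  withr::with_seed(91, {
    for (rep in 1:10) {
      tr <- ape::rtree(20, rooted = TRUE, br = NULL)
      tr$tip.label <- paste0("g", 1:20)
      sp <- setNames(paste0("sp", sample(1:8, 20, TRUE)), tr$tip.label)
      lab <- label_duplications(tr, sp)
      # naive oracle: for each internal node collect tip sets per child by
      # brute-force descent
      tips_under <- function(node) {
        if (node <= 20) return(tr$tip.label[node])
        kids <- tr$edge[tr$edge[, 1] == node, 2]
        unlist(lapply(kids, tips_under))
      }
      for (nd in lab$node) {
        kids <- tr$edge[tr$edge[, 1] == nd, 2]
        sets <- lapply(kids, function(k) unique(sp[tips_under(k)]))
        expect_equal(lab$label[lab$node == nd] == "duplication",
                     length(intersect(sets[[1]], sets[[2]])) > 0)
      }
      # consistent species renaming leaves labels unchanged
      sp_renamed <- setNames(paste0("X_", sp), names(sp))
      expect_equal(label_duplications(tr, sp_renamed)$label, lab$label)
    }
  })
})

test_that("site-residue history emits SC and SO per the event rules", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  h <- reconstruct_site_history(tr, c(A = "U", B = "U", C = "C", D = "U"))
  root <- length(tr$tip.label) + 1L
  expect_equal(unname(h$ancestral_states[paste0("node", root)]), "U")
  expect_equal(h$score, 1)
  expect_equal(nrow(h$events), 1)
  expect_equal(h$events$event, "SC")
  expect_equal(h$events$branch, "C")

  h0 <- reconstruct_site_history(tr, c(A = "U", B = "U", C = "U", D = "U"))
  expect_equal(nrow(h0$events), 0)

  # two independent U -> R substitutions
  h2 <- reconstruct_site_history(tr, c(A = "R", B = "U", C = "R", D = "U"))
  expect_equal(unname(h2$ancestral_states[paste0("node", root)]), "U")
  expect_equal(sum(h2$events$event == "SO"), 2)
  expect_true(all(h2$events$from_state == "U"))
  expect_true(all(h2$events$to_state == "R"))

  expect_error(reconstruct_site_history(tr, c(A = "x", B = "x", C = "x",
                                              D = "x")),
               class = "spsevo_input_error")
})

test_that("event counts equal the parsimony score on random small trees", {
  withr::with_seed(92, {
    for (rep in 1:60) {
      ntips <- sample(4:6, 1)
      tr <- ape::rtree(ntips, rooted = TRUE, br = NULL)
      tr$tip.label <- paste0("t", seq_len(ntips))
      states <- setNames(sample(c("U", "C", "T", "R"), ntips, TRUE),
                         tr$tip.label)
      h <- reconstruct_site_history(tr, states)
      expect_equal(nrow(h$events), h$score)
      expect_equal(h$score, oracle_parsimony_min(tr, states))
    }
  })
})

test_that("duplication labels are merged as GD events and x leaves pruned", {
  tr <- ape::read.tree(text = "((Hsap_1,Mmus_1),(Hsap_2,Mmus_2));")
  sp <- c(Hsap_1 = "Hsap", Mmus_1 = "Mmus", Hsap_2 = "Hsap",
          Mmus_2 = "Mmus")
  lab <- label_duplications(tr, sp)
  h <- reconstruct_site_history(
    tr, c(Hsap_1 = "U", Mmus_1 = "U", Hsap_2 = "T", Mmus_2 = "T"),
    duplication_labels = lab
  )
  expect_equal(sum(h$events$event == "GD"), 1)
  expect_equal(sum(h$events$event == "SO"), 1) # single U -> T change

  hx <- reconstruct_site_history(
    tr, c(Hsap_1 = "U", Mmus_1 = "x", Hsap_2 = "C", Mmus_2 = "C")
  )
  expect_equal(length(hx$tree$tip.label), 3)
  expect_equal(sum(hx$events$event == "SC"), 1)
})
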