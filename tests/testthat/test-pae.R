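balanced4 <- function() ape::read.tree(text = "((A,B),(C,D));")

char_matrix <- function(states, faunas = c("A", "B", "C", "D")) {
  # states: character vector, one string of 0/1 per taxon (rows = taxa)
  inc <- do.call(rbind, lapply(states, function(s)
    as.integer(strsplit(s, "")[[1]])))
  rownames(inc) <- paste0("t", seq_along(states))
  colnames(inc) <- faunas
  occurrence_matrix(inc)
}

test_that("Fitch lengths match hand counts on the 4-leaf balanced tree", {
  tr <- balanced4()
  expect_equal(fitch_length(tr, char_matrix("1100")), 1)
  expect_equal(fitch_length(tr, char_matrix("1010")), 2)
  expect_equal(fitch_length(tr, char_matrix("1111")), 0) # constant
  expect_error(fitch_length(tr, char_matrix("110", faunas = c("A", "B", "C"))),
               "do not match")
})

test_that("Fitch equals the exhaustive assignment oracle on small trees", {
  set.seed(21)
  for (rep_ in 1:6) {
    nf <- sample(4:6, 1)
    faunas <- LETTERS[seq_len(nf)]
    tr <- ape::rtree(nf, tip.label = sample(faunas))
    tr$edge.length <- NULL
    m <- random_matrix(8, nf, seed = 100 + rep_)
    colnames(m) <- faunas
    m <- occurrence_matrix(unclass(m))
    expect_equal(fitch_length(tr, m), brute_parsimony(tr, m),
                 info = paste("replicate", rep_))
  }
})

test_that("irreversible parsimony forbids losses and charges the origin", {
  tr <- balanced4() # rooted between the (A,B) and (C,D) pairs
  expect_equal(irreversible_length(tr, char_matrix("1100")), 1)
  expect_equal(irreversible_length(tr, char_matrix("1111")), 1) # single origin
  # 0111 needs one origin; standard parsimony also says 1; but 1011
  # (paraphyletic presence) forces two origins with losses banned
  expect_equal(irreversible_length(tr, char_matrix("1011")), 2)
  expect_gt(irreversible_length(tr, char_matrix("1011")),
            fitch_length(tr, char_matrix("1011")))
  expect_error(irreversible_length(ape::unroot(balanced4()),
                                   char_matrix("1100")), "rooted")
})

test_that("irreversible matches its brute-force oracle and bounds Fitch", {
  set.seed(33)
  for (rep_ in 1:6) {
    nf <- sample(4:6, 1)
    faunas <- LETTERS[seq_len(nf)]
    tr <- ape::rtree(nf, tip.label = sample(faunas))
    tr$edge.length <- NULL
    m <- random_matrix(8, nf, seed = 200 + rep_)
    colnames(m) <- faunas
    m <- occurrence_matrix(unclass(m))
    irr <- irreversible_length(tr, m)
    expect_equal(irr, brute_parsimony(tr, m, irreversible = TRUE))
    expect_gte(irr, fitch_length(tr, m))
  }
})

test_that("Fitch agrees with phangorn on larger random instances", {
  set.seed(5)
  m <- random_matrix(30, 8, seed = 44)
  X <- t(unclass(m))
  pd <- phangorn::phyDat(X, type = "USER", levels = c(0, 1))
  for (k in 1:4) {
    tr <- ape::rtree(8, tip.label = sample(colnames(m)))
    tr$edge.length <- NULL
    expect_equal(fitch_length(tr, m),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("heuristic search finds the exhaustive optimum on 5 faunas", {
  m <- random_matrix(15, 5, seed = 7)
  res <- parsimony_search(m, n_additions = 5, seed = 2)
  allt <- phangorn::allTrees(5, tip.label = colnames(m))
  lens <- vapply(allt, function(t) fitch_length(t, m), 0)
  expect_equal(res$length, min(lens))
  expect_equal(res$n_found, sum(lens == min(lens)))
})

test_that("a clean nested matrix yields its single caterpillar topology", {
  # fauna k holds taxa 1..k: all informative characters are suffix sets,
  # jointly compatible only with the accumulation-order caterpillar
  m <- nested_subset_matrix(6)
  res <- parsimony_search(m, root = "F01", n_additions = 5, seed = 4)
  cat_tree <- ape::read.tree(
    text = "(F01,(F02,(F03,(F04,(F05,F06)))));")
  expect_equal(res$n_found, 1L)
  expect_true(same_topology(ape::unroot(res$trees[[1]]),
                            ape::unroot(cat_tree)))
})

test_that("search needs 4 faunas and an outgroup for irreversibility", {
  m <- random_matrix(8, 3, seed = 1)
  expect_error(parsimony_search(m), "at least 4")
  m4 <- random_matrix(8, 4, seed = 1)
  expect_error(parsimony_search(m4, criterion = "irreversible"),
               "requires a root")
})

test_that("strict consensus collapses exactly the conflicting clades", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  same <- strict_consensus(list(t1, t1))
  expect_true(same_topology(same, t1))
  cons <- strict_consensus(list(t1, t2))
  # the (D,E)/(C,E) conflict collapses; (A,B) survives
  pp <- ape::prop.part(cons)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(i) sort(labs[i]))
  expect_true(list(c("A", "B")) %in% clades)
  expect_false(list(c("D", "E")) %in% clades)
  pruned <- strict_consensus(list(t1, t2), prune = c("D", "E"))
  expect_setequal(pruned$tip.label, c("A", "B", "C"))
  t3 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(strict_consensus(list(t1, t3)), "different leaf sets")
})

test_that("newick serialisation round-trips search results", {
  m <- random_matrix(12, 5, seed = 10)
  res <- parsimony_search(m, root = "F01", n_additions = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(res$trees[[1]], path)
  back <- ape::read.tree(path)
  expect_true(same_topology(back, res$trees[[1]]))
})

test_that("symmetric resampling rewards clean signal and stays in range", {
  # two cleanly supported blocks
  inc <- rbind(matrix(c(1L, 1L, 0L, 0L, 0L), 6, 5, byrow = TRUE),
               matrix(c(0L, 0L, 0L, 1L, 1L), 6, 5, byrow = TRUE))
  dimnames(inc) <- list(paste0("t", 1:12), c("A", "B", "O", "D", "E"))
  m <- occurrence_matrix(inc)
  sup <- symmetric_resampling(m, root = "O", reps = 20, seed = 2,
                              n_additions = 2, swap = "spr")
  expect_true(all(sup$frequency >= 0 & sup$frequency <= 100))
  expect_true(all(sup$gc <= sup$frequency))
  ab <- sup[sup$clade %in% c("A,B", "D,E"), ]
  expect_true(all(ab$frequency == 100))
  expect_true(all(ab$gc == 100))
  expect_error(symmetric_resampling(m, root = "O", reps = 0), "positive")
})

test_that("identity perturbation with one replicate gives all-or-nothing", {
  m <- random_matrix(14, 5, seed = 13)
  sup <- symmetric_resampling(m, root = "F01", reps = 1, change_prob = 0,
                              seed = 1, n_additions = 2, swap = "spr")
  expect_true(all(sup$frequency %in% c(0, 100)))
})
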