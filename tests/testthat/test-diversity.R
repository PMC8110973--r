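test_that("boundary-crosser classes follow the range definitions", {
  m <- occurrence_matrix(rbind(spans = c(1L, 1L, 1L, 0L),
                               confined = c(0L, 1L, 0L, 0L),
                               laz = c(1L, 0L, 1L, 1L)),
                         faunas = paste0("F", 1:4))
  bc <- bin_crossings(m)
  expect_equal(bc$Nbt[2], 2L)  # 'spans' and 'laz' pass through bin 2
  expect_equal(bc$NFL[2], 1L)  # 'confined' enters and exits in bin 2
  expect_equal(bc$NbL[3], 1L)  # 'spans' last appears in bin 3
  expect_equal(bc$Nb, bc$Nbt + bc$NbL)
  expect_equal(bc$Nt, bc$Nbt + bc$NFt)
})

test_that("crosser classes match an independent re-scan on random data", {
  m <- random_matrix(50, 8, seed = 31)
  bc <- bin_crossings(m)
  A <- unclass(m)
  for (k in seq_len(ncol(A))) {
    nbt <- nbl <- nft <- nfl <- 0
    for (i in seq_len(nrow(A))) {
      occ <- which(A[i, ] == 1L)
      f <- min(occ); l <- max(occ)
      if (f < k && l > k) nbt <- nbt + 1
      if (f < k && l == k) nbl <- nbl + 1
      if (f == k && l > k) nft <- nft + 1
      if (f == k && l == k) nfl <- nfl + 1
    }
    expect_equal(unlist(bc[k, c("Nbt", "NbL", "NFt", "NFL")]),
                 c(Nbt = nbt, NbL = nbl, NFt = nft, NFL = nfl))
  }
  # conservation: range-through richness equals the class total
  bc2 <- bin_crossings(m, approach = "range_through")
  expect_equal(bc2$richness, bc2$Nbt + bc2$NbL + bc2$NFt + bc2$NFL)
  # Lazarus filling can only add richness
  expect_true(all(bc2$richness >= bc$richness))
})

test_that("Foote rates evaluate their closed forms and flag gaps", {
  bc <- data.frame(fauna = c("X", "Y"), Nbt = c(50L, 0L), NbL = c(50L, 2L),
                   NFt = c(50L, 1L), NFL = c(0L, 1L), richness = c(150L, 4L),
                   composite = FALSE)
  bc$Nb <- bc$Nbt + bc$NbL
  bc$Nt <- bc$Nbt + bc$NFt
  tt <- foote_rates(bc)
  expect_equal(tt$q[1], log(2))
  expect_equal(tt$p[1], log(2))
  expect_equal(tt$net[1], 0)
  expect_equal(tt$turnover[1], 2 * log(2))
  # zero crossers: undefined, not infinite
  expect_true(is.na(tt$q[2]) && is.na(tt$p[2]))
  expect_false(tt$defined[2])
  # complete survival
  bc$Nbt[2] <- bc$Nb[2] <- 10L; bc$Nt[2] <- 10L
  expect_equal(foote_rates(bc)$q[2], 0)
})

test_that("complete sampling recovers the generating rates (small run)", {
  sim <- simulate_succession(succession_spec(n_taxa = 150, n_faunas = 10,
                                             r = 1, seed = 8))
  bc <- bin_crossings(sim$matrix)
  tt <- foote_rates(bc)
  mid <- 2:9
  expect_lt(abs(mean(tt$q[mid], na.rm = TRUE) - 0.35), 0.15)
  expect_lt(abs(mean(tt$p[mid], na.rm = TRUE) - 0.35), 0.15)
})

test_that("rarefaction at fraction 1 is the identity and is seeded", {
  m <- random_matrix(30, 5, seed = 17)
  full <- suppressWarnings(rarefy_metrics(m, fraction = 1, iters = 5,
                                          seed = 1))
  bc <- foote_rates(bin_crossings(m))
  expect_equal(full$richness_mean, as.numeric(bc$richness))
  expect_equal(full$p_mean, bc$p)
  a <- rarefy_metrics(m, fraction = 0.5, iters = 20, seed = 42)
  b <- rarefy_metrics(m, fraction = 0.5, iters = 20, seed = 42)
  expect_identical(a, b)
})

test_that("per-fauna subsampled richness equals the draw quota exactly", {
  m <- random_matrix(40, 5, seed = 23)
  res <- rarefy_metrics(m, fraction = 0.4, iters = 10, seed = 3)
  expect_equal(res$richness_mean, as.numeric(res$quota))
})

test_that("faunas below the record quota are excluded with a warning", {
  inc <- cbind(F1 = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
               F2 = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  rownames(inc) <- paste0("t", 1:8)
  m <- occurrence_matrix(inc)
  expect_warning(res <- rarefy_metrics(m, fraction = 0.4, iters = 5,
                                       seed = 1), "excluded")
  expect_false("F2" %in% res$fauna)
})

test_that("closed-form rarefaction matches Monte-Carlo draws", {
  counts <- c(5L, 3L, 2L, 1L, 1L) # per-taxon record counts
  n <- 6L
  set.seed(99)
  pool <- rep(seq_along(counts), counts)
  mc <- mean(replicate(4000, length(unique(sample(pool, n)))))
  expect_lt(abs(rarefy_richness(counts, n) - mc), 0.05)
  expect_equal(rarefy_richness(counts, sum(counts)), length(counts))
  expect_equal(rarefy_richness(counts, 0), 0)
})

test_that("category counts respect labels and log exclusions", {
  m <- occurrence_matrix(rbind(b1 = c(1L, 1L), b2 = c(1L, 0L),
                               b3 = c(1L, 1L), g1 = c(1L, 1L),
                               nolab = c(1L, 1L)),
                         faunas = c("X", "Y"))
  traits <- taxon_traits(data.frame(
    taxon = c("b1", "b2", "b3", "g1"),
    diet = c("browser", "browser", "browser", "grazer"),
    group = NA, size = NA))
  expect_warning(expect_message(
    cc <- category_counts(m, traits, "diet"), "unlabeled"), "coverage")
  expect_equal(unname(cc["browser", "X"]), 3L)
  expect_equal(unname(cc["grazer", "X"]), 1L)
  props <- cc[, "X"] / sum(cc[, "X"])
  expect_equal(unname(props[c("browser", "grazer")]), c(0.75, 0.25))
  expect_equal(sum(cc[, "X"]) + attr(cc, "unlabeled")[["X"]],
               sum(unclass(m)[, "X"]))
})

test_that("the multinomial change statistic matches its closed form", {
  expect_equal(multinomial_change(c(10, 10), c(10, 10),
                                  smoothing = 0)$delta_ll, 0)
  expect_false(multinomial_change(c(10, 10), c(10, 10))$significant)
  res <- multinomial_change(c(10, 10), c(20, 0), smoothing = 0)
  expect_equal(res$delta_ll, 20 * log(2))
  expect_true(res$significant)
  expect_error(multinomial_change(numeric(0), numeric(0)), "empty")
})

test_that("delta-LL is nonnegative, relabel-invariant and count-linear", {
  set.seed(12)
  for (rep_ in 1:20) {
    prev <- rpois(5, 4) + 1
    nxt <- rpois(5, 4)
    if (sum(nxt) == 0) nxt[1] <- 1
    d <- multinomial_change(prev, nxt)$delta_ll
    expect_gte(d, -1e-12)
    perm <- sample(5)
    expect_equal(multinomial_change(prev[perm], nxt[perm])$delta_ll, d)
    expect_equal(multinomial_change(2 * prev, 2 * nxt,
                                    smoothing = 0)$delta_ll,
                 2 * multinomial_change(prev, nxt, smoothing = 0)$delta_ll)
  }
})

test_that("community change runs along a succession in both approaches", {
  sim <- simulate_succession(succession_spec(seed = 4))
  res1 <- suppressWarnings(suppressMessages(
    community_change(sim$matrix, sim$traits, "diet")))
  res2 <- suppressWarnings(suppressMessages(
    community_change(sim$matrix, sim$traits, "diet",
                     approach = "range_through")))
  expect_equal(nrow(res1), ncol(sim$matrix) - 1L)
  expect_true(all(res1$delta_ll >= 0))
  expect_true(all(res2$delta_ll >= 0))
})
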