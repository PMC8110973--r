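# Parsimony analysis of endemicity: faunas as terminals, taxa as binary
# characters. Tree length is a two-state Sankoff dynamic programme,
# vectorised over characters, with either the standard (symmetric) cost or
# the irreversible cost (losses 1->0 forbidden; state 0 ancestral).

PAE_INF <- 1e7

# Generic DP over an adjacency list. `adj` is a list of integer neighbour
# vectors; nodes 1..ntip are tips (tip i = fauna i = row i of X). Returns
# the per-character minimal cost vector.
sankoff_adj <- function(adj, ntip, X, weights = NULL, irreversible = FALSE,
                        root_tip = NULL, root_node = NULL) {
  nchar_ <- ncol(X)
  tipcost <- function(v) {
    rbind(ifelse(X[v, ] == 0L, 0, PAE_INF),
          ifelse(X[v, ] == 1L, 0, PAE_INF))
  }
  # min over child states of trans(parent_state, child_state) + childcost
  minin <- if (irreversible) {
    function(C) rbind(pmin(C[1, ], C[2, ] + 1),  # parent 0: keep or gain
                      C[2, ])                    # parent 1: child must be 1
  } else {
    function(C) rbind(pmin(C[1, ], C[2, ] + 1),
                      pmin(C[1, ] + 1, C[2, ]))
  }
  rec <- function(v, parent) {
    if (v <= ntip) return(tipcost(v))
    C <- matrix(0, 2, nchar_)
    for (nb in adj[[v]]) {
      if (nb == parent) next
      C <- C + minin(rec(nb, v))
    }
    C
  }
  if (!is.null(root_tip)) {
    # virtual root on the edge subtending the designated outgroup tip
    v <- setdiff(adj[[root_tip]], 0L)[1]
    C <- minin(tipcost(root_tip)) + minin(rec(v, root_tip))
  } else {
    start <- root_node %||% (ntip + 1L)
    C <- rec(start, 0L)
  }
  per <- if (irreversible) pmin(C[1, ], C[2, ] + 1) else pmin(C[1, ], C[2, ])
  if (!is.null(weights)) per <- per * weights
  per
}

phylo_adj <- function(phy) {
  nn <- ape::Ntip(phy) + phy$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

pae_characters <- function(m, tree) {
  if (!setequal(tree$tip.label, faunas_of(m)))
    stop("tree leaves do not match the matrix faunas")
  X <- t(unclass(m))[tree$tip.label, , drop = FALSE]
  storage.mode(X) <- "integer"
  X
}

#' Fitch (standard parsimony) length of a fauna tree
#'
#' Minimal number of character-state changes over all internal-state
#' assignments, summed across taxa (characters), with equal costs for gains
#' and losses. Handles multifurcating trees.
#'
#' @param tree an [ape::phylo] tree whose tip labels are the matrix faunas.
#' @param m an [occurrence_matrix()].
#' @param weights optional per-character (per-taxon) weights.
#' @return total length in steps.
#' @export
fitch_length <- function(tree, m, weights = NULL) {
  X <- pae_characters(m, tree)
  per <- sankoff_adj(phylo_adj(tree), ape::Ntip(tree), X, weights,
                     irreversible = FALSE, root_node = ape::Ntip(tree) + 1L)
  sum(per)
}

#' Irreversible (gains-only) parsimony length
#'
#' Minimal changes when losses (1 to 0) are forbidden, so only shared
#' presences can support groupings; state 0 is ancestral, and a character
#' present everywhere still costs its single origin on the root edge. The
#' tree must be rooted (root the matrix's outgroup fauna first).
#'
#' @inheritParams fitch_length
#' @return total length in steps; always `>=` the Fitch length.
#' @export
irreversible_length <- function(tree, m, weights = NULL) {
  if (!ape::is.rooted(tree))
    stop("irreversible parsimony requires a rooted tree")
  X <- pae_characters(m, tree)
  per <- sankoff_adj(phylo_adj(tree), ape::Ntip(tree), X, weights,
                     irreversible = TRUE, root_node = ape::Ntip(tree) + 1L)
  sum(per)
}

## ---- lightweight unrooted trees for the search -------------------------

ut_new <- function(ntip, tips3) {
  adj <- vector("list", ntip + 1L)
  adj[[ntip + 1L]] <- tips3
  for (t in tips3) adj[[t]] <- ntip + 1L
  list(adj = adj, ntip = ntip)
}

ut_add_node <- function(tr) {
  tr$adj[[length(tr$adj) + 1L]] <- integer(0)
  list(tr = tr, id = length(tr$adj))
}

ut_add_edge <- function(tr, u, v) {
  tr$adj[[u]] <- c(tr$adj[[u]], v)
  tr$adj[[v]] <- c(tr$adj[[v]], u)
  tr
}

ut_del_edge <- function(tr, u, v) {
  tr$adj[[u]] <- setdiff(tr$adj[[u]], v)
  tr$adj[[v]] <- setdiff(tr$adj[[v]], u)
  tr
}

ut_edges <- function(tr) {
  out <- list()
  for (u in seq_along(tr$adj)) {
    nb <- tr$adj[[u]]
    for (v in nb[nb > u]) out[[length(out) + 1L]] <- c(u, v)
  }
  out
}

ut_subdivide <- function(tr, u, v) {
  nn <- ut_add_node(tr)
  tr <- nn$tr; w <- nn$id
  tr <- ut_del_edge(tr, u, v)
  tr <- ut_add_edge(tr, u, w)
  tr <- ut_add_edge(tr, w, v)
  list(tr = tr, node = w)
}

ut_suppress <- function(tr, w) {
  nb <- tr$adj[[w]]
  if (length(nb) != 2L) return(tr)
  tr <- ut_del_edge(tr, w, nb[1])
  tr <- ut_del_edge(tr, w, nb[2])
  ut_add_edge(tr, nb[1], nb[2])
}

ut_insert_tip <- function(tr, tip, u, v) {
  sd <- ut_subdivide(tr, u, v)
  tr <- sd$tr
  while (length(tr$adj) < tip) tr$adj[[length(tr$adj) + 1L]] <- integer(0)
  ut_add_edge(tr, sd$node, tip)
}

ut_component <- function(tr, start) {
  seen <- start
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    new <- setdiff(tr$adj[[v]], seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  seen
}

ut_length <- function(tr, X, weights = NULL, criterion = "standard",
                      root_tip = NULL) {
  irrev <- criterion == "irreversible"
  start <- if (irrev) NULL else which(lengths(tr$adj) > 1L)[1]
  per <- sankoff_adj(tr$adj, tr$ntip, X, weights, irreversible = irrev,
                     root_tip = if (irrev) root_tip else NULL,
                     root_node = start)
  sum(per)
}

# canonical topology hash: splits encoded by the tip side not holding tip 1
ut_hash <- function(tr) {
  tips <- seq_len(tr$ntip)
  splits <- character(0)
  for (e in ut_edges(tr)) {
    if (e[1] <= tr$ntip || e[2] <= tr$ntip) next # trivial split
    tr2 <- ut_del_edge(tr, e[1], e[2])
    side <- intersect(ut_component(tr2, e[1]), tips)
    if (1L %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > tr$ntip - 2L) next
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  paste(sort(splits), collapse = ";")
}

ut_to_phylo <- function(tr, labels) {
  ntip <- tr$ntip
  alive <- which(lengths(tr$adj) > 0L)
  internals <- alive[alive > ntip]
  if (!length(internals)) stop("degenerate tree")
  newid <- integer(length(tr$adj))
  newid[seq_len(ntip)] <- seq_len(ntip)
  # preorder DFS from an internal node adjacent to the lowest tip
  root <- tr$adj[[1]][1]
  if (root <= ntip) root <- internals[1]
  nextid <- ntip + 1L
  edges <- matrix(0L, 0, 2)
  stack <- list(c(root, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1]; parent <- top[2]
    if (v > ntip) { newid[v] <- nextid; nextid <- nextid + 1L }
    if (parent) edges <- rbind(edges, c(newid[parent], v))
    for (nb in rev(tr$adj[[v]])) if (nb != parent)
      stack[[length(stack) + 1L]] <- c(nb, v)
  }
  # children recorded before their new ids are known for internals: fix up
  for (k in seq_len(nrow(edges)))
    if (edges[k, 2] > ntip) edges[k, 2] <- newid[edges[k, 2]]
  phy <- list(edge = edges, tip.label = labels, Nnode = nextid - ntip - 1L)
  class(phy) <- "phylo"
  phy
}

# TBR/SPR neighbourhood. For each edge, bisect the tree; degree-2
# junctions are spliced out; the two components are rejoined by a new edge
# between a subdivision of any edge of one side and any edge of the other
# ("tbr"), or with the pruned side's original junction kept intact ("spr").
ut_neighbors <- function(tr, mode = c("tbr", "spr")) {
  mode <- match.arg(mode)
  out <- list()
  attach_all <- function(bis, a_opts, b_opts) {
    for (ap in a_opts) for (bp in b_opts) {
      t2 <- bis
      if (!is.null(ap$edge)) {
        sd <- ut_subdivide(t2, ap$edge[1], ap$edge[2])
        t2 <- sd$tr; anode <- sd$node
      } else anode <- ap$node
      if (!is.null(bp$edge)) {
        sd <- ut_subdivide(t2, bp$edge[1], bp$edge[2])
        t2 <- sd$tr; bnode <- sd$node
      } else bnode <- bp$node
      out[[length(out) + 1L]] <<- ut_add_edge(t2, anode, bnode)
    }
  }
  side_opts <- function(bis, junction, suppressed_rep, allow_edges) {
    comp <- ut_component(bis, suppressed_rep)
    eds <- Filter(function(ed) ed[1] %in% comp, ut_edges(bis))
    if (allow_edges && length(eds)) lapply(eds, function(ed) list(edge = ed))
    else list(list(node = junction))
  }
  for (e in ut_edges(tr)) {
    u <- e[1]; v <- e[2]
    base <- ut_del_edge(tr, u, v)
    if (mode == "tbr") {
      bis <- base
      rep_u <- if (length(bis$adj[[u]]) == 2L) bis$adj[[u]][1] else u
      if (length(bis$adj[[u]]) == 2L) bis <- ut_suppress(bis, u)
      rep_v <- if (length(bis$adj[[v]]) == 2L) bis$adj[[v]][1] else v
      if (length(bis$adj[[v]]) == 2L) bis <- ut_suppress(bis, v)
      a_opts <- side_opts(bis, u, rep_u, allow_edges = TRUE)
      b_opts <- side_opts(bis, v, rep_v, allow_edges = TRUE)
      attach_all(bis, a_opts, b_opts)
    } else {
      # spr: prune each side in turn, keeping its junction as attach point
      for (sw in list(c(u, v), c(v, u))) {
        a <- sw[1]; b <- sw[2]
        bis <- base
        rep_b <- if (length(bis$adj[[b]]) == 2L) bis$adj[[b]][1] else b
        if (length(bis$adj[[b]]) == 2L) bis <- ut_suppress(bis, b)
        b_opts <- side_opts(bis, b, rep_b, allow_edges = TRUE)
        attach_all(bis, list(list(node = a)), b_opts)
      }
    }
  }
  out
}

## ---- search ------------------------------------------------------------

#' Heuristic parsimony tree search over faunas
#'
#' Random stepwise-addition starting trees followed by branch swapping
#' (tree bisection-reconnection by default), keeping every distinct
#' topology at the best length found; equal-length neighbours of the best
#' trees are swept so that tied optima are collected. Seed-reproducible.
#'
#' @param m an [occurrence_matrix()] (faunas are terminals, taxa binary
#'   characters); at least 4 faunas.
#' @param root outgroup fauna used to root result trees, and required for
#'   the irreversible criterion.
#' @param n_additions number of random addition sequences.
#' @param swap `"tbr"`, `"spr"` or `"none"`.
#' @param criterion `"standard"` (Fitch) or `"irreversible"` (gains only).
#' @param seed integer seed.
#' @param weights optional per-character weights (used by
#'   [symmetric_resampling()]).
#' @param max_trees cap on stored equally-parsimonious trees.
#' @return object of class `pae_search`: `trees` (a `multiPhylo`; rooted at
#'   `root` when given), `length` (best steps), `criterion`, `n_found`.
#' @export
parsimony_search <- function(m, root = NULL, n_additions = 10,
                             swap = c("tbr", "spr", "none"),
                             criterion = c("standard", "irreversible"),
                             seed = NULL, weights = NULL, max_trees = 100) {
  swap <- match.arg(swap)
  criterion <- match.arg(criterion)
  faunas <- faunas_of(m)
  ntip <- length(faunas)
  if (ntip < 4) stop("parsimony search needs at least 4 faunas")
  if (criterion == "irreversible" && is.null(root))
    stop("the irreversible criterion requires a root (outgroup) fauna")
  if (!is.null(root) && !root %in% faunas)
    stop("unknown root fauna: ", root)
  if (!is.null(seed)) set.seed(seed)
  X <- t(unclass(m))[faunas, , drop = FALSE]
  storage.mode(X) <- "integer"
  root_tip <- if (!is.null(root)) match(root, faunas) else NULL
  score <- function(tr) ut_length(tr, X, weights, criterion, root_tip)

  best_len <- Inf
  best <- list(); best_hash <- character(0)
  add_best <- function(tr, len) {
    if (len < best_len - 1e-9) {
      best_len <<- len; best <<- list(); best_hash <<- character(0)
    }
    if (len <= best_len + 1e-9 && length(best) < max_trees) {
      h <- ut_hash(tr)
      if (!h %in% best_hash) {
        best[[length(best) + 1L]] <<- tr
        best_hash <<- c(best_hash, h)
      }
    }
  }

  for (rep_ in seq_len(n_additions)) {
    ord <- sample.int(ntip)
    tr <- ut_new(ntip, ord[1:3])
    for (tip in ord[-(1:3)]) {
      cand_best <- NULL; cand_len <- Inf
      for (e in ut_edges(tr)) {
        t2 <- ut_insert_tip(tr, tip, e[1], e[2])
        l2 <- score(t2)
        if (l2 < cand_len) { cand_len <- l2; cand_best <- t2 }
      }
      tr <- cand_best
    }
    len <- score(tr)
    if (swap != "none") {
      repeat {
        moved <- FALSE
        for (nb in ut_neighbors(tr, swap)) {
          l2 <- score(nb)
          if (l2 < len - 1e-9) { tr <- nb; len <- l2; moved <- TRUE; break }
        }
        if (!moved) break
      }
    }
    add_best(tr, len)
  }

  # plateau sweep: collect equal-length neighbours of the best trees
  if (swap != "none") {
    queue <- best
    qi <- 1L
    while (qi <= length(queue) && length(best) < max_trees) {
      for (nb in ut_neighbors(queue[[qi]], swap)) {
        if (length(best) >= max_trees) break
        if (abs(score(nb) - best_len) < 1e-9) {
          n_before <- length(best)
          add_best(nb, best_len)
          if (length(best) > n_before) queue[[length(queue) + 1L]] <- nb
        }
      }
      qi <- qi + 1L
    }
  }

  trees <- lapply(best, ut_to_phylo, labels = faunas)
  if (!is.null(root))
    trees <- lapply(trees, function(t)
      ape::root(t, outgroup = root, resolve.root = TRUE))
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, length = best_len, criterion = criterion,
                 root = root, n_found = length(trees), seed = seed),
            class = "pae_search")
}

#' @export
print.pae_search <- function(x, ...) {
  cat(sprintf("PAE %s parsimony: %d tree(s) of %g steps\n",
              x$criterion, x$n_found, x$length))
  invisible(x)
}

#' Strict consensus of equally parsimonious trees
#'
#' Optionally prunes a leaf set from every tree first ("reduced" strict
#' consensus, used when rogue faunas collapse resolution).
#'
#' @param trees a `multiPhylo` (or list of [ape::phylo]) with identical leaf
#'   sets.
#' @param prune character vector of leaves to drop before consensus.
#' @return an [ape::phylo] consensus tree.
#' @export
strict_consensus <- function(trees, prune = NULL) {
  trees <- unclass(trees)
  if (!length(trees)) stop("no trees supplied")
  leaf0 <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!identical(sort(t$tip.label), leaf0))
    stop("trees have different leaf sets")
  if (!is.null(prune))
    trees <- lapply(trees, ape::drop.tip, tip = prune)
  if (length(trees) == 1L) return(trees[[1]])
  rooted <- all(vapply(trees, ape::is.rooted, TRUE))
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = rooted)
}

## ---- resampling support ------------------------------------------------

rooted_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(i) sort(labs[i]))
  sets[lengths(sets) < length(labs)] # drop the root clade
}

clades_incompatible <- function(s, t) {
  i <- length(intersect(s, t))
  i > 0 && i < length(s) && i < length(t)
}

#' Symmetric resampling support for PAE clades
#'
#' Each character is independently perturbed with probability
#' `change_prob`: upweighted (weight 2) or downweighted (weight 0) with
#' equal chance, so expected weights are unchanged. The search is re-run on
#' each perturbed matrix and, for every clade of the reference consensus,
#' the recovery frequency and the frequency difference GC (frequency minus
#' the best contradicting clade's frequency) are reported.
#'
#' @param m an [occurrence_matrix()].
#' @param root outgroup fauna (trees are rooted here; clades are rooted
#'   groups).
#' @param reps number of resampling replicates.
#' @param change_prob per-character perturbation probability (default 0.33).
#' @param seed integer seed.
#' @param reference optional `pae_search` result to annotate; computed with
#'   the same settings when omitted.
#' @param ... further arguments to [parsimony_search()] (e.g. `n_additions`,
#'   `swap`, `criterion`).
#' @return data.frame with columns `clade` (comma-joined fauna set),
#'   `frequency` and `gc`, both in percent.
#' @export
symmetric_resampling <- function(m, root, reps = 1000, change_prob = 0.33,
                                 seed = NULL, reference = NULL, ...) {
  if (reps <= 0) stop("reps must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference))
    reference <- parsimony_search(m, root = root, ...)
  ref_clades <- unique(unlist(lapply(reference$trees, function(t)
    vapply(rooted_clades(t), paste, "", collapse = ",")), use.names = FALSE))
  ntaxa <- nrow(m)
  tally <- new.env(parent = emptyenv())
  bump <- function(key) assign(key, (tally[[key]] %||% 0) + 1L, envir = tally)
  for (r in seq_len(reps)) {
    u <- stats::runif(ntaxa)
    w <- ifelse(u < change_prob / 2, 2, ifelse(u < change_prob, 0, 1))
    res <- parsimony_search(m, root = root, weights = w, ...)
    cons <- strict_consensus(res$trees)
    for (cl in rooted_clades(cons)) bump(paste(cl, collapse = ","))
  }
  seen <- ls(tally)
  freq_of <- function(key) 100 * (tally[[key]] %||% 0) / reps
  out <- lapply(ref_clades, function(key) {
    s <- strsplit(key, ",")[[1]]
    contra <- seen[vapply(seen, function(k)
      clades_incompatible(s, strsplit(k, ",")[[1]]), TRUE)]
    best_contra <- if (length(contra)) max(vapply(contra, freq_of, 0)) else 0
    data.frame(clade = key, frequency = freq_of(key),
               gc = freq_of(key) - best_contra)
  })
  do.call(rbind, out)
}
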