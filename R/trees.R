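SEP <- "\x1f"  # clade-key separator; never occurs in sane language ids

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering producing a rooted ultrametric
#' tree; each internal node sits at half the merge distance.  Ties are broken
#' deterministically: among all minimal-distance pairs, the lowest (i, j)
#' pair in the current cluster ordering wins, so repeated runs on equal
#' input give identical trees.
#'
#' @param D symmetric nonnegative distance matrix, zero diagonal (L >= 2).
#' @param labels tip labels; default rownames of `D`.
#' @return an [ape::read.tree()] `"phylo"` tree with branch lengths.
#' @export
upgma <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")
  if (anyNA(D) || any(!is.finite(D))) stop("NaN/Inf in distance matrix")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("negative distances")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # build with placeholder ids; arbitrary labels (spaces etc) are assigned
  # to the parsed tree afterwards
  nwk <- sprintf("x%d", seq_len(n))
  heights <- rep(0, n)
  sizes <- rep(1L, n)
  d <- D
  while (length(nwk) > 1L) {
    k <- length(nwk)
    dd <- d
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    dmin <- min(dd)
    hit <- which(dd == dmin, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    h <- dmin / 2
    s <- sprintf("(%s:%.17g,%s:%.17g)",
                 nwk[i], h - heights[i], nwk[j], h - heights[j])
    # average-linkage update weighted by cluster sizes (true UPGMA)
    keep <- setdiff(seq_len(k), c(i, j))
    newd <- (sizes[i] * d[i, keep] + sizes[j] * d[j, keep]) /
      (sizes[i] + sizes[j])
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    nwk <- c(nwk[keep], s)
    heights <- c(heights[keep], h)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  tr$tip.label <- labels[as.integer(sub("^x", "", tr$tip.label))]
  tr
}

# descendant-tip label sets for every internal node (recursive, rooted)
clade_label_sets <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- vector("list", n + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  sets <- vector("list", n + nnode)
  rec <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    out <- unlist(lapply(kids[[v]], rec))
    sets[[v]] <<- out
    out
  }
  rec(n + 1L)
  lapply(which(!vapply(sets, is.null, logical(1))), function(v) sets[[v]])
}

# canonical string keys of the clades of a rooted tree
# trivial = FALSE drops the root (full leaf set); singletons never appear
clade_keys <- function(tree, trivial = TRUE) {
  sets <- clade_label_sets(tree)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = SEP), character(1))
  if (!trivial) {
    full <- paste(sort(tree$tip.label), collapse = SEP)
    keys <- keys[keys != full]
  }
  unique(keys)
}

check_same_leaves <- function(trees) {
  ref <- sort(trees[[1]]$tip.label)
  for (t in trees[-1]) {
    if (!identical(sort(t$tip.label), ref)) {
      stop("trees have mismatched leaf sets")
    }
  }
  ref
}

#' Robinson-Foulds distance between rooted trees
#'
#' Size of the symmetric difference between the two trees' sets of
#' nontrivial clades (rooted convention).  0 means identical topologies.
#'
#' @param t1,t2 `"phylo"` trees on the same leaf set.
#' @return nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(list(t1, t2))
  k1 <- clade_keys(t1, trivial = FALSE)
  k2 <- clade_keys(t2, trivial = FALSE)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Clade support table from a sample of trees
#'
#' For every clade appearing in any input tree (internal nodes, including
#' the root), the fraction of trees that contain it.  Singleton clades are
#' trivially supported by every tree and are not listed.
#'
#' @param trees list of `"phylo"` trees with identical leaf sets.
#' @return data.frame with columns `clade` (comma-joined constituents),
#'   `size`, `count`, `support`, sorted by decreasing support; attribute
#'   `n_trees`.
#' @export
clade_supports <- function(trees) {
  if (length(trees) < 1) stop("need at least one tree")
  check_same_leaves(trees)
  tab <- table(unlist(lapply(trees, clade_keys, trivial = TRUE)))
  keys <- names(tab)
  counts <- as.integer(tab)
  out <- data.frame(
    clade = vapply(strsplit(keys, SEP, fixed = TRUE),
                   paste, character(1), collapse = ", "),
    size = lengths(strsplit(keys, SEP, fixed = TRUE)),
    count = counts,
    support = counts / length(trees),
    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$size, out$clade), ]
  rownames(out) <- NULL
  attr(out, "n_trees") <- length(trees)
  out
}

# internal: clade counts keyed by canonical key
clade_counts <- function(trees) {
  tab <- table(unlist(lapply(trees, clade_keys, trivial = TRUE)))
  setNames(as.integer(tab), names(tab))
}

#' Majority-rule consensus tree
#'
#' Contains exactly the clades whose support is strictly greater than
#' `threshold` (default 0.5); with the strict inequality, two conflicting
#' clades at exactly 0.5 are both excluded, and all retained clades are
#' mutually compatible, so the consensus is always a valid (possibly
#' multifurcating) rooted tree.  Supports are attached as internal node
#' labels.
#'
#' @param trees list of `"phylo"` trees with identical leaf sets.
#' @param threshold minimum (exclusive) support for inclusion; values below
#'   0.5 are rejected since majority compatibility is then not guaranteed.
#' @return a `"phylo"` tree with `node.label` = clade support.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (length(trees) < 1) stop("need at least one tree")
  if (threshold < 0.5) stop("threshold below 0.5 may yield incompatible clades")
  leaves <- check_same_leaves(trees)
  counts <- clade_counts(trees)
  supp <- counts / length(trees)
  full_key <- paste(leaves, collapse = SEP)
  keep <- names(supp)[supp > threshold | names(supp) == full_key]
  sets <- strsplit(keep, SEP, fixed = TRUE)
  names(sets) <- keep
  if (!full_key %in% keep) {
    sets[[full_key]] <- leaves
    supp[full_key] <- 1
  }
  # nest clades: recursively attach maximal proper sub-clades
  build <- function(key) {
    s <- sets[[key]]
    inner <- keep[vapply(keep, function(k2) {
      s2 <- sets[[k2]]
      length(s2) < length(s) && all(s2 %in% s)
    }, logical(1))]
    # maximal among inner
    maximal <- inner[vapply(inner, function(k2) {
      s2 <- sets[[k2]]
      !any(vapply(inner, function(k3) {
        s3 <- sets[[k3]]
        length(s3) > length(s2) && all(s2 %in% s3)
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(sets[maximal])
    if (anyDuplicated(covered)) stop("incompatible clades in consensus")
    singles <- setdiff(s, covered)
    parts <- c(vapply(maximal, build, character(1)),
               sprintf("x%d", match(singles, leaves)))
    sprintf("(%s)%.10g", paste(parts, collapse = ","), supp[key])
  }
  tr <- ape::read.tree(text = paste0(build(full_key), ";"))
  tr$tip.label <- leaves[as.integer(sub("^x", "", tr$tip.label))]
  tr
}

#' Maximum clade credibility tree
#'
#' Scores every input tree by the sum over its nontrivial clades of the log
#' clade support (estimated from the whole sample) and returns the
#' highest-scoring member; ties go to the first occurrence.
#'
#' @param trees nonempty list of `"phylo"` trees on one leaf set.
#' @return the winning `"phylo"` tree (with `node.label` supports attached
#'   via attribute `"mcc_score"` on the tree).
#' @export
mcc_tree <- function(trees) {
  if (length(trees) < 1) stop("need at least one tree")
  check_same_leaves(trees)
  counts <- clade_counts(trees)
  supp <- counts / length(trees)
  scores <- vapply(trees, function(t) {
    sum(log(supp[clade_keys(t, trivial = FALSE)]))
  }, numeric(1))
  best <- trees[[which.max(scores)]]
  attr(best, "mcc_score") <- max(scores)
  best
}

#' Write / read Newick trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] with a
#' malformedness check that reports the character position of unbalanced
#' parentheses.  Spaces in labels (e.g. "Inari Sami") are stored as
#' underscores -- the classic Newick convention -- and restored on read.
#'
#' @param tree a `"phylo"`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  tree$tip.label <- gsub(" ", "_", tree$tip.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @return `read_newick`: a `"phylo"`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  in_q <- FALSE
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "'") in_q <- !in_q
    if (!in_q) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("malformed Newick: ", depth, " unclosed '(' at end")
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr)) stop("malformed Newick: parser failed")
  tr$tip.label <- gsub("_", " ", tr$tip.label)
  tr
}

#' UPGMA trees from posterior latent-distance draws
#'
#' One tree per (possibly subsampled) posterior draw.
#'
#' @param fit a `"ggp_fit"`.
#' @param chain chain index, or `NULL` to pool chains.
#' @param max_trees cap on the number of trees (draws are thinned evenly).
#' @return list of `"phylo"` trees.
#' @export
posterior_trees <- function(fit, chain = NULL, max_trees = 400L) {
  d <- fit$draws$delta
  iter <- dim(d)[1]
  chs <- if (is.null(chain)) seq_len(dim(d)[2]) else chain
  per <- max(1L, min(iter, ceiling(max_trees / length(chs))))
  idx <- unique(round(seq(1, iter, length.out = per)))
  langs <- fit$language_ids
  out <- list()
  for (ch in chs) {
    for (it in idx) {
      out[[length(out) + 1L]] <-
        upgma(expand_distances(d[it, ch, ], labels = langs))
    }
  }
  out
}

#' Convergence summary with topology-level verdict
#'
#' Reports conventional split R-hat per parameter -- which is *expected* to
#' be large for the latent distances, since the distance scale is not
#' identified across chains -- together with a topology-level check: a
#' majority consensus tree per chain and pairwise Robinson-Foulds distances
#' between those per-chain consensus trees.  The run is flagged
#' "topology-converged" when all pairwise RF distances are at most
#' `rf_threshold`.
#'
#' @param fit a `"ggp_fit"` (or anything with `draws$delta` and
#'   `language_ids`).
#' @param rf_threshold maximum admissible pairwise RF distance (default 2).
#' @param max_trees_per_chain trees per chain used for the per-chain
#'   consensus (draws thinned evenly).
#' @return list of class `"ggp_convergence"`: `rhat`, `chain_consensus`,
#'   `rf` (matrix or NULL), `topology_converged` (logical or NA for a single
#'   chain).
#' @export
convergence_summary <- function(fit, rf_threshold = 2,
                                max_trees_per_chain = 100L) {
  d <- fit$draws$delta
  chains <- dim(d)[2]
  cons <- lapply(seq_len(chains), function(ch) {
    majority_consensus(posterior_trees(fit, chain = ch,
                                       max_trees = max_trees_per_chain))
  })
  rf <- NULL
  verdict <- NA
  if (chains >= 2) {
    rf <- matrix(0L, chains, chains)
    for (a in seq_len(chains - 1)) {
      for (b in seq.int(a + 1, chains)) {
        rf[a, b] <- rf[b, a] <- rf_distance(cons[[a]], cons[[b]])
      }
    }
    verdict <- all(rf[upper.tri(rf)] <= rf_threshold)
  }
  structure(list(rhat = fit$diagnostics$rhat,
                 ess = fit$diagnostics$ess,
                 divergences = fit$diagnostics$divergences,
                 chain_consensus = cons, rf = rf,
                 rf_threshold = rf_threshold,
                 topology_converged = verdict),
            class = "ggp_convergence")
}

#' @export
print.ggp_convergence <- function(x, ...) {
  cat("<convergence summary>\n")
  rh <- x$rhat[!is.na(x$rhat)]
  if (length(rh)) {
    cat(sprintf("  split R-hat: max %.3f (%s), median %.3f\n",
                max(rh), names(rh)[which.max(rh)], median(rh)))
  }
  if (!is.null(x$rf)) {
    cat("  pairwise RF between per-chain consensus trees:",
        paste(x$rf[upper.tri(x$rf)], collapse = ", "), "\n")
    cat(sprintf("  topology-converged (all RF <= %g): %s\n",
                x$rf_threshold, x$topology_converged))
    cat("  note: large R-hat on latent distances with RF ~ 0 indicates the\n",
        " benign scale non-identifiability, not a sampling failure\n")
  } else {
    cat("  single chain: no cross-chain verdict\n")
  }
  invisible(x)
}
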