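# Independent oracles used to check the package's computations.

# Betweenness by exhaustive enumeration of all simple paths between every
# node pair (feasible for tiny graphs): for each unordered pair (s, t) the
# shortest length is found, the shortest paths counted, and each
# intermediate node credited with its fraction of them.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  score <- stats::setNames(numeric(n), rownames(adj))
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      cur <- path[length(path)]
      if (cur == to) {
        out[[length(out) + 1L]] <<- path
        return(invisible())
      }
      for (nb in which(adj[cur, ] > 0)) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(from)
    out
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1L)))
        score[v] <- score[v] + through / length(shortest)
      }
    }
  }
  score
}

random_connected_graph <- function(n_nodes, p_edge = 0.5) {
  repeat {
    adj <- matrix(0L, n_nodes, n_nodes)
    adj[upper.tri(adj)] <- as.integer(stats::runif(n_nodes * (n_nodes - 1) / 2) < p_edge)
    adj <- adj + t(adj)
    dimnames(adj) <- list(sprintf("n%02d", 1:n_nodes), sprintf("n%02d", 1:n_nodes))
    # connectivity via reachability
    reach <- (diag(n_nodes) + adj) %*% (diag(n_nodes) + adj)
    for (i in seq_len(n_nodes)) reach <- reach %*% (diag(n_nodes) + adj)
    if (all(reach > 0) && sum(adj) > 0) return(adj)
  }
}

# Plug-in discrete mutual information (nats) from the joint count table.
discrete_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  keep <- tab > 0
  sum(tab[keep] * log(tab[keep] / outer(px, py)[keep]))
}

# Direct evaluation of Newman modularity Q for a partition of an igraph.
modularity_direct <- function(net, membership) {
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  q <- 0
  for (cl in unique(membership)) {
    nodes <- names(membership)[membership == cl]
    sub <- igraph::induced_subgraph(net, nodes)
    e_c <- igraph::ecount(sub)
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# All set partitions of 1..n via restricted growth strings, preallocated
# using the Bell-number recurrence.
set_partitions <- function(n) {
  bell <- function(k) {
    b <- 1
    row <- 1
    for (i in seq_len(k - 1)) {
      new_row <- cumsum(c(row[length(row)], row))
      row <- new_row
      b <- row[1]
    }
    row[length(row)]
  }
  out <- vector("list", bell(n))
  idx <- 0L
  rgs <- integer(n)
  rec <- function(i, maxv) {
    if (i > n) {
      idx <<- idx + 1L
      out[[idx]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      rec(i + 1L, max(maxv, v))
    }
  }
  rec(1L, 0L)
  out[seq_len(idx)]
}

# Exact P(|S1 n S2 n S3| >= observed) for uniform random subsets of given
# size from a shared universe, by enumeration over all subset triples
# encoded as bit masks.
exact_overlap_prob <- function(universe_size, subset_size, observed) {
  combos <- utils::combn(universe_size, subset_size)
  masks <- apply(combos, 2L, function(ix) sum(bitwShiftL(1L, ix - 1L)))
  n_sets <- length(masks)
  hits <- 0
  popcount <- function(v) {
    c <- 0L
    while (any(v > 0L)) {
      c <- c + (v %% 2L)
      v <- v %/% 2L
    }
    c
  }
  for (i in seq_len(n_sets)) {
    m12 <- bitwAnd(masks[i], masks)
    for (j in seq_len(n_sets)) {
      m123 <- bitwAnd(m12[j], masks)
      hits <- hits + sum(popcount(m123) >= observed)
    }
  }
  hits / n_sets^3
}

# Bottleneck ranking check helper: dominant planted module of a cluster.
dominant_module <- function(members, annot, truth) {
  mods <- truth$gene_module[probe_genes(annot, members)]
  mods <- mods[grepl("^M\\d+$", mods)]
  if (length(mods) == 0L) return(NA_character_)
  names(sort(table(mods), decreasing = TRUE))[1L]
}

# Adjusted Rand index between two labelings (Hubert & Arabie).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab)
  si <- s(rowSums(tab))
  sj <- s(colSums(tab))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
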