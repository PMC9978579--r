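# Hierarchical density-based clustering (HDBSCAN, excess-of-mass cluster
# selection).  Self-contained: core distances -> mutual-reachability
# graph -> minimum spanning tree -> single-linkage dendrogram ->
# condensed tree -> stability-based selection.  Dense O(n^2) throughout,
# which is ample for the sample counts this package embeds.

#' Density-based clustering with noise
#'
#' @param x numeric matrix (points x dims) or a `dist` object.
#' @param min_cluster_size smallest cluster size considered real (>= 2).
#' @param min_samples neighbourhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @return Integer vector of cluster labels, `0` marking noise points.
#' @export
hdbscan_cluster <- function(x, min_cluster_size = 5,
                            min_samples = min_cluster_size) {
  stopifnot(min_cluster_size >= 2, min_samples >= 1)
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(dist(x))
  n <- nrow(d)
  if (n <= min_cluster_size) return(integer(n))

  ms <- min(min_samples, n - 1)
  # core distance: distance to the ms-th nearest neighbour, the point
  # itself counted at distance zero (reference-implementation convention)
  core <- vapply(seq_len(n), function(i) sort(d[i, ])[ms], numeric(1))
  mreach <- pmax(outer(core, core, pmax), d)
  diag(mreach) <- 0

  mst <- prim_mst_cpp(mreach)
  sl <- .single_linkage(mst, n)
  cond <- .condense_tree(sl, n, min_cluster_size)
  .eom_labels(cond, n)
}

# single-linkage dendrogram from MST edges: merge table with columns
# left, right (cluster ids; 1..n are points, n+1.. are merges), height, size
.single_linkage <- function(mst, n) {
  ord <- order(mst[, 3])
  parent <- seq_len(2 * n - 1)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cluster_of <- seq_len(n)           # current dendrogram node per root
  sizes <- rep(1L, 2 * n - 1)
  merges <- matrix(0, n - 1, 4)
  colnames(merges) <- c("left", "right", "height", "size")
  for (t in seq_len(n - 1)) {
    e <- ord[t]
    ra <- find(mst[e, 1]); rb <- find(mst[e, 2])
    ca <- cluster_of[ra]; cb <- cluster_of[rb]
    new_id <- n + t
    merges[t, ] <- c(ca, cb, mst[e, 3], sizes[ca] + sizes[cb])
    sizes[new_id] <- sizes[ca] + sizes[cb]
    parent[ra] <- rb
    cluster_of[find(rb)] <- new_id
  }
  merges
}

# walk the dendrogram top-down, creating condensed clusters only at
# splits where both sides hold >= min_cluster_size points; smaller sides
# "fall out" of their cluster at lambda = 1/height
.condense_tree <- function(merges, n, mcs) {
  node_size <- function(id) if (id <= n) 1L else merges[id - n, "size"]
  leaves_under <- function(id) {
    out <- integer(0); stack <- id
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, merges[v - n, "left"], merges[v - n, "right"])
    }
    out
  }
  clusters <- list()
  new_cluster <- function(parent, birth) {
    clusters[[length(clusters) + 1]] <<- list(
      parent = parent, birth = birth, death = NA_real_,
      children = integer(0), points = integer(0), lambdas = numeric(0))
    length(clusters)
  }
  fall_out <- function(cid, pts, lambda) {
    cl <- clusters[[cid]]
    cl$points <- c(cl$points, pts)
    cl$lambdas <- c(cl$lambdas, rep(lambda, length(pts)))
    clusters[[cid]] <<- cl
  }
  root <- new_cluster(0L, 0)
  stack <- list(list(node = 2L * n - 1L, cid = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr$node; cid <- fr$cid
    if (node <= n) { fall_out(cid, node, Inf); next }
    h <- max(merges[node - n, "height"], 1e-12)
    lambda <- 1 / h
    l <- merges[node - n, "left"]; r <- merges[node - n, "right"]
    sl <- node_size(l); sr <- node_size(r)
    if (sl >= mcs && sr >= mcs) {
      clusters[[cid]]$death <- lambda
      cl_l <- new_cluster(cid, lambda)
      cl_r <- new_cluster(cid, lambda)
      clusters[[cid]]$children <- c(cl_l, cl_r)
      stack[[length(stack) + 1]] <- list(node = l, cid = cl_l)
      stack[[length(stack) + 1]] <- list(node = r, cid = cl_r)
    } else if (sl >= mcs) {
      fall_out(cid, leaves_under(r), lambda)
      stack[[length(stack) + 1]] <- list(node = l, cid = cid)
    } else if (sr >= mcs) {
      fall_out(cid, leaves_under(l), lambda)
      stack[[length(stack) + 1]] <- list(node = r, cid = cid)
    } else {
      fall_out(cid, c(leaves_under(l), leaves_under(r)), lambda)
    }
  }
  clusters
}

.eom_labels <- function(clusters, n) {
  nc <- length(clusters)
  if (nc == 0) return(integer(n))
  # points under the full condensed subtree of each cluster
  subtree_points <- function(cid) {
    out <- integer(0); stack <- cid
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      out <- c(out, clusters[[v]]$points)
      stack <- c(stack, clusters[[v]]$children)
    }
    out
  }
  stability <- numeric(nc)
  for (i in seq_len(nc)) {
    cl <- clusters[[i]]
    lam <- pmin(cl$lambdas, 1e12)       # leaves fall out at +Inf
    s <- sum(lam - cl$birth)
    if (length(cl$children)) {
      passed <- sum(vapply(cl$children, function(ch)
        length(subtree_points(ch)), integer(1)))
      s <- s + passed * (cl$death - cl$birth)
    }
    stability[i] <- s
  }
  selected <- logical(nc)
  score <- numeric(nc)
  for (i in rev(seq_len(nc))) {         # children are created after parents
    cl <- clusters[[i]]
    if (!length(cl$children)) {
      selected[i] <- TRUE
      score[i] <- stability[i]
    } else {
      child_sum <- sum(score[cl$children])
      if (i > 1 && stability[i] > child_sum) {
        selected[i] <- TRUE
        score[i] <- stability[i]
        # deselect the whole subtree below
        stack <- cl$children
        while (length(stack)) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[v] <- FALSE
          stack <- c(stack, clusters[[v]]$children)
        }
      } else {
        score[i] <- child_sum
      }
    }
  }
  selected[1] <- FALSE                  # never collapse to one root cluster
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(nc)) {
    if (!selected[i]) next
    lab <- lab + 1L
    labels[subtree_points(i)] <- lab
  }
  labels
}
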