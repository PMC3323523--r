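#' Restrict a signature to the pre-scission clustering window
#'
#' Mean values on the grid restricted to `window` (inclusive of on-grid
#' endpoints), by default -82 s to 0 s: clustering compares the shape of the
#' recruitment curve leading up to scission.
#'
#' @param sig a `recruitment_signature` (or list with `t_rel` and `mean`).
#' @param window `c(t_a, t_b)` seconds.
#' @return Named numeric vector (names = times).
#' @export
prescission_window <- function(sig, window = c(-82, 0)) {
  sel <- sig$t_rel >= window[1] & sig$t_rel <= window[2]
  if (min(sig$t_rel) > window[1] || max(sig$t_rel) < window[2])
    stop("signature does not cover the requested window", call. = FALSE)
  v <- sig$mean[sel]
  if (anyNA(v))
    stop("signature has missing values inside the clustering window",
         call. = FALSE)
  stats::setNames(v, sig$t_rel[sel])
}

#' Assemble a signature set for clustering
#'
#' @param curves named list of equal-length numeric vectors (one windowed
#'   curve per condition label), or a matrix with labelled rows.
#' @return Class `signature_set`: list with `labels` and `curves` matrix.
#' @export
signature_set <- function(curves) {
  if (is.list(curves)) {
    len <- unique(lengths(curves))
    if (length(len) != 1L)
      stop("curves must share one time grid", call. = FALSE)
    curves <- do.call(rbind, curves)
  }
  if (is.null(rownames(curves)))
    stop("curves must be labelled", call. = FALSE)
  structure(list(labels = rownames(curves), curves = curves),
            class = "signature_set")
}

#' Pairwise cosine distance matrix of recruitment curves
#'
#' `d(i, j) = 1 - u_i . u_j / (||u_i|| ||u_j||)` on the windowed curves. By
#' default the raw (un-centred) cosine is used; `centered = TRUE` subtracts
#' each curve's mean first, making the similarity a Pearson correlation.
#'
#' @param set a [signature_set()] (or a labelled matrix of curves).
#' @param centered subtract curve means before the cosine?
#' @return Symmetric matrix with zero diagonal, labels as dimnames.
#' @export
cosine_distance_matrix <- function(set, centered = FALSE) {
  m <- if (inherits(set, "signature_set")) set$curves else set
  if (nrow(m) < 2L) stop("need at least 2 curves", call. = FALSE)
  if (centered) m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  if (any(zero))
    stop("zero-norm curve(s): ", paste(rownames(m)[zero], collapse = ", "),
         call. = FALSE)
  sim <- (m %*% t(m)) / outer(nrm, nrm)
  d <- 1 - sim
  diag(d) <- 0
  d[d < 0] <- 0  # guard tiny negative round-off
  d
}

#' Average-linkage (UPGMA) agglomeration
#'
#' Repeatedly merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the unweighted mean of the original
#' pairwise distances over all member pairs (UPGMA). `weighted = TRUE`
#' averages the two merged clusters' distances instead (WPGMA). Ties are
#' broken deterministically by lexicographic order of each cluster's
#' smallest member label.
#'
#' @param d symmetric distance matrix with labelled dimnames, or a `dist`.
#' @param weighted use WPGMA instead of UPGMA?
#' @return An `hclust`-compatible object (merge, height, order, labels),
#'   usable with [stats::cutree()], [stats::cophenetic()] and `plot()`.
#' @export
average_linkage <- function(d, weighted = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  stopifnot(n >= 2L, isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  members <- as.list(seq_len(n))       # original leaf indices per cluster
  ids <- -(seq_len(n))                 # hclust coding: negative = leaf
  key <- labels                        # tie-break key: smallest member label
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL; bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- cur[i, j]
      better <- dij < bestd - 1e-12 ||
        (abs(dij - bestd) <= 1e-12 && !is.null(best) &&
         order_pair(key[i], key[j], key[best[1L]], key[best[2L]]))
      if (is.null(best) || better) { best <- c(i, j); bestd <- dij }
    }
    i <- best[1L]; j <- best[2L]
    merge[s, ] <- sort(c(ids[i], ids[j]))
    height[s] <- bestd
    new_members <- c(members[[i]], members[[j]])
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- vapply(seq_len(k), function(q) {
      if (q == i || q == j) return(NA_real_)
      if (weighted) (cur[i, q] + cur[j, q]) / 2
      else (ni * cur[i, q] + nj * cur[j, q]) / (ni + nj)
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    members <- c(members[keep], list(new_members))
    ids <- c(ids[keep], s)
    key <- c(key[keep], min(key[c(i, j)]))
  }
  out <- list(merge = merge, height = height,
              order = tree_order(merge, n), labels = labels,
              method = if (weighted) "wpgma" else "average",
              call = match.call(), dist.method = "cosine")
  class(out) <- "hclust"
  out
}

# TRUE when pair (a1, a2) precedes pair (b1, b2) lexicographically
order_pair <- function(a1, a2, b1, b2) {
  a <- sort(c(a1, a2)); b <- sort(c(b1, b2))
  if (a[1L] != b[1L]) return(a[1L] < b[1L])
  a[2L] < b[2L]
}

# leaf order for plotting: recursive left-to-right traversal of the merges
tree_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

# cophenetic distance matrix from an hclust-style tree: the height of the
# first merge joining each pair (explicit lowest-common-cluster computation)
cophenetic_matrix <- function(tree) {
  n <- length(tree$labels)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  clusters <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get <- function(id) if (id < 0) -id else clusters[[id]]
    a <- get(tree$merge[s, 1L]); b <- get(tree$merge[s, 2L])
    coph[a, b] <- tree$height[s]
    coph[b, a] <- tree$height[s]
    clusters[[s]] <- c(a, b)
  }
  coph
}

#' Cophenetic correlation of a dendrogram with its input distances
#'
#' Pearson correlation between the upper triangle of the original distance
#' matrix and the cophenetic distances induced by the tree (the merge height
#' of the lowest cluster containing each pair). A value near 1 means the
#' dendrogram faithfully represents the pairwise distances.
#'
#' @param tree result of [average_linkage()].
#' @param d the distance matrix the tree was built from.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("cophenetic correlation needs >= 3 leaves", call. = FALSE)
  if (!is.null(rownames(d))) d <- d[tree$labels, tree$labels]
  coph <- cophenetic_matrix(tree)
  ut <- upper.tri(d)
  stats::cor(d[ut], coph[ut])
}

#' Export a dendrogram as Newick
#'
#' @param tree result of [average_linkage()].
#' @param path output file.
#' @return Invisibly, the Newick string.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/factor vectors of cluster labels, same length.
#' @return ARI (1 = identical partitions up to relabelling).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
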