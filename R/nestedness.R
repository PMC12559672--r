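# NODF over a binary incidence matrix: for each ordered node pair within a
# class with strictly decreasing degree, paired nestedness is
# 100 * |shared partners| / degree of the poorer node; equal degrees score 0
# (the "decreasing fill" rule). NODF averages over all row pairs and all
# column pairs. Order-free: depends only on degrees and overlaps.
nodf_matrix <- function(inc) {
  score_class <- function(x) {
    n <- nrow(x)
    if (n < 2L) return(numeric(0L))
    deg <- rowSums(x)
    shared <- x %*% t(x)
    out <- numeric(n * (n - 1L) / 2L)
    k <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        k <- k + 1L
        hi <- max(deg[i], deg[j]); lo <- min(deg[i], deg[j])
        out[k] <- if (hi > lo && lo > 0) 100 * shared[i, j] / lo else 0
      }
    }
    out
  }
  pairs <- c(score_class(inc), score_class(t(inc)))
  if (length(pairs) == 0L) {
    stop("NODF needs at least 2 nodes in each class", call. = FALSE)
  }
  mean(pairs)
}

#' NODF nestedness of a bipartite network
#'
#' Overlap-and-decreasing-fill nestedness on the 0-100 scale: 100 for a
#' perfectly nested matrix with distinct degrees, 0 when no poorer node's
#' partners are contained in a richer node's.
#'
#' @param n a [build_network()] result with at least 2 species and 2 patches.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(n) {
  stopifnot(inherits(n, "bipartite_network"))
  if (length(n$species_nodes) < 2L || length(n$patch_nodes) < 2L) {
    stop("NODF needs at least 2 nodes in each class", call. = FALSE)
  }
  nodf_matrix(n$incidence)
}

#' Nestedness contribution (cnodf) of one node
#'
#' z-score of the observed NODF against a null in which only the focal
#' node's links are replaced by a uniformly random partner set of the same
#' degree (the other class's full node roster is the partner pool). A zero
#' null standard deviation yields 0.
#'
#' @param n a [build_network()] result.
#' @param node node identifier (species or patch name).
#' @param n_random number of randomizations (default 100, minimum 2).
#' @param seed RNG seed for reproducibility (default 0).
#' @return z-score (NODF_obs - mean NODF_null) / sd NODF_null.
#' @export
cnodf <- function(n, node, n_random = 100L, seed = 0L) {
  stopifnot(inherits(n, "bipartite_network"))
  if (n_random < 2L) stop("n_random must be >= 2", call. = FALSE)
  inc <- n$incidence
  is_species <- node %in% rownames(inc)
  is_patch <- node %in% colnames(inc)
  if (!is_species && !is_patch) {
    stop("node not found in network: ", node, call. = FALSE)
  }
  if (!is_species) inc <- t(inc)  # focal node always a row below
  obs <- nodf_matrix(inc)
  row <- which(rownames(inc) == node)
  degree <- sum(inc[row, ])
  npart <- ncol(inc)
  null <- numeric(n_random)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_random)) {
    partners <- sample.int(npart, degree)
    inc[row, ] <- 0L
    inc[row, partners] <- 1L
    null[r] <- nodf_matrix(inc)
  }
  s <- stats::sd(null)
  if (s == 0) return(0)
  (obs - mean(null)) / s
}
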