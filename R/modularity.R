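# Barber bipartite modularity of a given module assignment.
# Q = (1/E) * sum over species i, patch j in the same module of
#     (A_ij - k_i * d_j / E)
barber_q <- function(inc, mod_rows, mod_cols) {
  E <- sum(inc)
  k <- rowSums(inc); d <- colSums(inc)
  q <- 0
  for (m in unique(c(mod_rows, mod_cols))) {
    ri <- which(mod_rows == m); cj <- which(mod_cols == m)
    if (length(ri) == 0L || length(cj) == 0L) next
    q <- q + sum(inc[ri, cj, drop = FALSE]) -
      sum(k[ri]) * sum(d[cj]) / E
  }
  q / E
}

#' Barber bipartite modularity
#'
#' Maximizes Barber's Q_B for a bipartite network by seeded label
#' propagation: species and patch labels are swept alternately, each node
#' adopting the module that maximizes its modularity gain, with multiple
#' random restarts. Deterministic for a fixed seed. A best partition that
#' does not beat the trivial single module (Q = 0) collapses to it.
#'
#' @param n a [build_network()] result with at least one link.
#' @param seed RNG seed (default 0).
#' @param restarts number of random restarts (default 20).
#' @return list with `q` (modularity) and `partition` (named integer vector
#'   of module ids over species then patch nodes).
#' @export
modularity <- function(n, seed = 0L, restarts = 20L) {
  stopifnot(inherits(n, "bipartite_network"))
  inc <- n$incidence
  E <- sum(inc)
  if (E == 0) stop("modularity undefined for a network with no links", call. = FALSE)
  ns <- nrow(inc); np <- ncol(inc)
  k <- rowSums(inc); d <- colSums(inc)

  sweep_once <- function(mr, mc) {
    repeat {
      changed <- FALSE
      mods <- sort(unique(c(mr, mc)))
      # species adopt the patch-side module with the best gain
      for (i in seq_len(ns)) {
        gains <- vapply(mods, function(m) {
          cj <- which(mc == m)
          if (length(cj) == 0L) return(-Inf)
          sum(inc[i, cj]) - k[i] * sum(d[cj]) / E
        }, numeric(1L))
        best <- mods[which.max(gains)]
        if (best != mr[i] && max(gains) > -Inf) { mr[i] <- best; changed <- TRUE }
      }
      mods <- sort(unique(c(mr, mc)))
      for (j in seq_len(np)) {
        gains <- vapply(mods, function(m) {
          ri <- which(mr == m)
          if (length(ri) == 0L) return(-Inf)
          sum(inc[ri, j]) - d[j] * sum(k[ri]) / E
        }, numeric(1L))
        best <- mods[which.max(gains)]
        if (best != mc[j] && max(gains) > -Inf) { mc[j] <- best; changed <- TRUE }
      }
      if (!changed) break
    }
    list(mr = mr, mc = mc)
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  best_q <- -Inf; best <- NULL
  for (r in seq_len(restarts)) {
    if (r == 1L) {
      mc <- seq_len(np)           # each patch its own module
    } else {
      mc <- sample.int(sample.int(np, 1L), np, replace = TRUE)
    }
    mr <- rep(1L, ns)
    res <- sweep_once(mr, mc)
    q <- barber_q(inc, res$mr, res$mc)
    if (q > best_q + 1e-12) { best_q <- q; best <- res }
  }
  if (best_q <= 1e-12) {            # single module never scores below 0
    best_q <- 0
    best <- list(mr = rep(1L, ns), mc = rep(1L, np))
  }
  # canonical relabelling by first appearance (species then patches)
  labels <- c(best$mr, best$mc)
  relab <- match(labels, unique(labels))
  partition <- stats::setNames(relab, c(rownames(inc), colnames(inc)))
  list(q = best_q, partition = partition)
}
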