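#' Node metric series across periods
#'
#' For every node appearing in any of the per-period networks: degree and
#' nestedness contribution (cnodf) per period, and the coefficient of
#' variation of each across the periods where the node is present
#' (sample standard deviation / mean; a zero mean yields `NA`).
#'
#' @param nets named or ordered list of [build_network()] results, one per
#'   period (period labels taken from the networks).
#' @param n_random randomizations per cnodf call (default 100).
#' @param seed base RNG seed; each (node, period) cnodf uses a derived seed.
#' @param with_cnodf set FALSE to skip the (slower) cnodf columns.
#' @return data frame with one row per node: node_id, node_class, then
#'   degree_<period> and cnodf_<period> columns, cv_degree, cv_cnodf.
#' @export
node_metric_series <- function(nets, n_random = 100L, seed = 0L,
                               with_cnodf = TRUE) {
  if (length(nets) < 2L) stop("need at least 2 networks", call. = FALSE)
  periods <- vapply(seq_along(nets), function(i) {
    p <- nets[[i]]$period
    if (is.null(p)) paste0("t", i) else p
  }, character(1L))
  all_species <- sort(unique(unlist(lapply(nets, `[[`, "species_nodes"))))
  all_patches <- sort(unique(unlist(lapply(nets, `[[`, "patch_nodes"))))
  nodes <- data.frame(
    node_id = c(all_species, all_patches),
    node_class = rep(c("species", "patch"),
                     c(length(all_species), length(all_patches))),
    stringsAsFactors = FALSE
  )
  np <- length(nets)
  deg <- matrix(NA_real_, nrow(nodes), np,
                dimnames = list(nodes$node_id, periods))
  cno <- deg
  for (t in seq_len(np)) {
    net <- nets[[t]]
    ds <- rowSums(net$incidence); dp <- colSums(net$incidence)
    deg[names(ds), t] <- ds
    deg[names(dp), t] <- dp
    if (with_cnodf) {
      present <- c(names(ds), names(dp))
      for (id in present) {
        cno[id, t] <- cnodf(net, id, n_random = n_random,
                            seed = derive_seed(seed, t * 1000L + match(id, rownames(deg))))
      }
    }
  }
  cv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    m <- mean(x)
    if (m == 0) return(NA_real_)
    stats::sd(x) / m
  }
  out <- nodes
  for (t in seq_len(np)) out[[paste0("degree_", periods[t])]] <- deg[, t]
  if (with_cnodf) {
    for (t in seq_len(np)) out[[paste0("cnodf_", periods[t])]] <- cno[, t]
  }
  out$cv_degree <- apply(deg, 1L, cv)
  if (with_cnodf) {
    # CV of a signed z-score uses the mean magnitude to stay interpretable
    out$cv_cnodf <- apply(cno, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) return(NA_real_)
      m <- mean(abs(x))
      if (m == 0) return(NA_real_)
      stats::sd(x) / m
    })
  }
  rownames(out) <- NULL
  out
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney U with the tie-corrected normal approximation.
#' U is reported for the first group (number of pairs where a > b, ties
#' counted half).
#'
#' @param a,b numeric vectors (each length >= 1).
#' @return list with `u`, `z`, `p`.
#' @export
rank_sum_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups need at least one value", call. = FALSE)
  }
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    stop("degenerate comparison: all values identical", call. = FALSE)
  }
  rk <- rank(pooled)
  Ra <- sum(rk[seq_len(na)])
  u <- Ra - na * (na + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_u <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (var_u > 0) (u - na * nb / 2) / sqrt(var_u) else 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u, z = z, p = p)
}

# deterministic 32-bit-safe derived seeds
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}
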