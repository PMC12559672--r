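# Shared link-set tally for one ordered pair of networks:
# a = links present at both times, b = only at t1, c = only at t2.
link_tally <- function(n1, n2) {
  l1 <- link_keys(n1); l2 <- link_keys(n2)
  if (length(l1) == 0L && length(l2) == 0L) {
    stop("temporal beta undefined: both networks empty", call. = FALSE)
  }
  list(
    shared = intersect(l1, l2),
    lost = setdiff(l1, l2),
    gained = setdiff(l2, l1)
  )
}

#' Temporal beta diversity of species-patch links
#'
#' Jaccard dissimilarity (b + c) / (a + b + c) between the link sets of the
#' same metacommunity network at two time points, where a is the number of
#' shared links, b links present only at the first time and c links present
#' only at the second.
#'
#' @param n1,n2 [build_network()] results for the two periods.
#' @return dissimilarity in \[0, 1\].
#' @export
beta_temporal <- function(n1, n2) {
  t <- link_tally(n1, n2)
  (length(t$lost) + length(t$gained)) /
    (length(t$shared) + length(t$lost) + length(t$gained))
}

#' Extinction and colonization components of temporal beta diversity
#'
#' beta_extinction = b / (a + b + c): links present only at the earlier
#' time (lost). beta_colonization = c / (a + b + c): links present only at
#' the later time (gained). They sum to the temporal beta diversity.
#'
#' @inheritParams beta_temporal
#' @return list with `beta_extinction` and `beta_colonization`.
#' @export
partition_extinction_colonization <- function(n1, n2) {
  t <- link_tally(n1, n2)
  tot <- length(t$shared) + length(t$lost) + length(t$gained)
  list(beta_extinction = length(t$lost) / tot,
       beta_colonization = length(t$gained) / tot)
}

#' Local/regional/landscape/RL components of temporal beta diversity
#'
#' Every changed link (present at exactly one of the two times) is assigned
#' to one component by node persistence. A node persists when it has at
#' least one link at both times (or is named in the roster overrides, for
#' surveyed-but-empty nodes):
#' species and patch persistent = local; species turnover only = regional;
#' patch turnover only = landscape; both turn over = regional-landscape (RL).
#' Component values are link counts over (a + b + c) and sum to the
#' temporal beta diversity.
#'
#' @inheritParams beta_temporal
#' @param persistent_species,persistent_patches optional rosters of node ids
#'   to treat as persistent regardless of link incidence.
#' @return list with `beta_local`, `beta_regional`, `beta_landscape`,
#'   `beta_rl`.
#' @export
partition_components <- function(n1, n2, persistent_species = NULL,
                                 persistent_patches = NULL) {
  t <- link_tally(n1, n2)
  tot <- length(t$shared) + length(t$lost) + length(t$gained)
  sp_persist <- union(intersect(n1$species_nodes, n2$species_nodes),
                      persistent_species)
  pa_persist <- union(intersect(n1$patch_nodes, n2$patch_nodes),
                      persistent_patches)
  changed <- c(t$lost, t$gained)
  counts <- c(local = 0L, regional = 0L, landscape = 0L, rl = 0L)
  if (length(changed) > 0L) {
    parts <- strsplit(changed, "\r", fixed = TRUE)
    for (pr in parts) {
      sp <- pr[1L] %in% sp_persist
      pa <- pr[2L] %in% pa_persist
      comp <- if (sp && pa) "local" else if (!sp && pa) "regional"
              else if (sp && !pa) "landscape" else "rl"
      counts[comp] <- counts[comp] + 1L
    }
  }
  list(beta_local = counts[["local"]] / tot,
       beta_regional = counts[["regional"]] / tot,
       beta_landscape = counts[["landscape"]] / tot,
       beta_rl = counts[["rl"]] / tot)
}

#' Full beta partition for one ordered pair of networks
#'
#' Computes the link tally once and derives the temporal beta diversity,
#' both partitions, and the raw link counts from it, guaranteeing that the
#' components are mutually consistent.
#'
#' @inheritParams partition_components
#' @return one-row data frame: pair, beta_temporal, beta_extinction,
#'   beta_colonization, beta_local, beta_regional, beta_landscape, beta_rl,
#'   a_shared, b_lost, c_gained.
#' @export
beta_pair <- function(n1, n2, persistent_species = NULL,
                      persistent_patches = NULL) {
  t <- link_tally(n1, n2)
  a <- length(t$shared); b <- length(t$lost); cc <- length(t$gained)
  ec <- partition_extinction_colonization(n1, n2)
  comp <- partition_components(n1, n2, persistent_species, persistent_patches)
  p1 <- if (is.null(n1$period)) "t1" else n1$period
  p2 <- if (is.null(n2$period)) "t2" else n2$period
  data.frame(
    pair = paste0(p1, "->", p2),
    beta_temporal = (b + cc) / (a + b + cc),
    beta_extinction = ec$beta_extinction,
    beta_colonization = ec$beta_colonization,
    beta_local = comp$beta_local,
    beta_regional = comp$beta_regional,
    beta_landscape = comp$beta_landscape,
    beta_rl = comp$beta_rl,
    a_shared = a, b_lost = b, c_gained = cc,
    stringsAsFactors = FALSE
  )
}

#' Beta partition table over all ordered period pairs
#'
#' One [beta_pair()] row per ordered pair (t_i, t_j), i < j, in the order
#' the networks are given (chronological period order by convention).
#'
#' @param nets ordered list of at least two [build_network()] results.
#' @inheritParams partition_components
#' @return data frame with one row per pair, in deterministic pair order.
#' @export
beta_matrix <- function(nets, persistent_species = NULL,
                        persistent_patches = NULL) {
  if (length(nets) < 2L) stop("need at least 2 networks", call. = FALSE)
  rows <- list()
  for (i in seq_len(length(nets) - 1L)) {
    for (j in (i + 1L):length(nets)) {
      rows[[length(rows) + 1L]] <-
        beta_pair(nets[[i]], nets[[j]], persistent_species, persistent_patches)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
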