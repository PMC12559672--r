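#' Build a bipartite species-patch occurrence network
#'
#' Links a species to a patch when its count reaches `presence_threshold`
#' individuals. Nodes without any link are dropped unless `keep_isolated`.
#'
#' @param m an [to_abundance_matrix()] result (species x patch counts).
#' @param presence_threshold minimum count for a link (default 1).
#' @param keep_isolated keep zero-degree nodes (default FALSE).
#' @return Object of class `bipartite_network`: list with `period`,
#'   `species_nodes`, `patch_nodes`, `links` (data frame species/patch) and
#'   `incidence` (binary species x patch matrix).
#' @export
build_network <- function(m, presence_threshold = 1L, keep_isolated = FALSE) {
  stopifnot(is.matrix(m))
  if (presence_threshold < 1) stop("presence_threshold must be >= 1", call. = FALSE)
  inc <- (unclass(m) >= presence_threshold) * 1L
  if (!keep_isolated) {
    inc <- inc[rowSums(inc) > 0, colSums(inc) > 0, drop = FALSE]
  }
  idx <- which(inc == 1L, arr.ind = TRUE)
  links <- data.frame(
    species = if (nrow(idx) > 0L) rownames(inc)[idx[, 1L]] else character(0L),
    patch = if (nrow(idx) > 0L) colnames(inc)[idx[, 2L]] else character(0L),
    stringsAsFactors = FALSE
  )
  links <- links[order(links$species, links$patch), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(
    period = attr(m, "period"),
    species_nodes = rownames(inc),
    patch_nodes = colnames(inc),
    links = links,
    incidence = inc
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite_network",
      if (!is.null(x$period)) paste0("[", x$period, "]") else "",
      ": ", length(x$species_nodes), " species x ", length(x$patch_nodes),
      " patches, ", nrow(x$links), " links\n", sep = "")
  invisible(x)
}

# link set as canonical "species||patch" keys
link_keys <- function(n) {
  if (nrow(n$links) == 0L) character(0L)
  else paste(n$links$species, n$links$patch, sep = "\r")
}

#' Connectance of a bipartite network
#'
#' Realized links divided by all possible species x patch links.
#'
#' @param n a [build_network()] result.
#' @return value in \[0, 1\].
#' @export
connectance <- function(n) {
  stopifnot(inherits(n, "bipartite_network"))
  ns <- length(n$species_nodes); np <- length(n$patch_nodes)
  if (ns == 0L || np == 0L) {
    stop("connectance undefined for an empty node class", call. = FALSE)
  }
  nrow(n$links) / (ns * np)
}
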