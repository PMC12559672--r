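#' Diversity profile of a community
#'
#' Abundance, species richness, Shannon-Wiener diversity (natural log) and
#' Pielou evenness for one vector of species counts. Zero counts are
#' excluded from the proportions. Pielou evenness H/ln(S) is undefined for
#' fewer than two species and returned as `NA`.
#'
#' @param counts non-negative numeric vector of per-species counts.
#' @return list with `abundance`, `richness`, `shdi`, `pielou`.
#' @examples
#' diversity_profile(c(5, 5, 5, 5))  # shdi = log(4), pielou = 1
#' @export
diversity_profile <- function(counts) {
  if (length(counts) == 0L) stop("empty count vector", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  pos <- counts[counts > 0]
  abundance <- sum(counts)
  richness <- length(pos)
  if (richness == 0L) {
    return(list(abundance = 0, richness = 0L, shdi = 0, pielou = NA_real_))
  }
  p <- pos / sum(pos)
  shdi <- -sum(p * log(p))
  pielou <- if (richness >= 2L) shdi / log(richness) else NA_real_
  list(abundance = abundance, richness = richness, shdi = shdi,
       pielou = pielou)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' sum(|x - y|) / sum(x + y); 0 for identical communities, 1 for fully
#' disjoint ones.
#'
#' @param x,y equal-length non-negative count vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  denom <- sum(x) + sum(y)
  if (denom == 0) {
    stop("Bray-Curtis undefined: both communities empty", call. = FALSE)
  }
  sum(abs(x - y)) / denom
}

#' Diversity table for a survey set
#'
#' One diversity profile per (period, patch) and, when `by = "subregion"`,
#' per (period, subregion) with patches pooled.
#'
#' @param s a [survey_set()].
#' @param by `"patch"` or `"subregion"`.
#' @return data frame with columns period, unit, abundance, richness,
#'   shdi, pielou.
#' @export
diversity_table <- function(s, by = c("patch", "subregion")) {
  by <- match.arg(by)
  stopifnot(inherits(s, "survey_set"))
  rec <- s$records
  unit <- if (by == "patch") rec$patch_id else rec$subregion
  key <- interaction(rec$period, unit, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(rec)), key), function(idx) {
    sub <- rec[idx, , drop = FALSE]
    counts <- tapply(sub$count, sub$species, sum)
    prof <- diversity_profile(as.numeric(counts))
    data.frame(period = sub$period[1L], unit = unit[idx][1L],
               abundance = prof$abundance, richness = prof$richness,
               shdi = prof$shdi, pielou = prof$pielou,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(period = character(), unit = character(),
                      abundance = numeric(), richness = integer(),
                      shdi = numeric(), pielou = numeric())
  }
  rownames(out) <- NULL
  out[order(out$period, out$unit), , drop = FALSE]
}
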