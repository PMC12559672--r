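# Independent brute-force oracles. These are deliberately written as
# straight-line re-derivations from first principles (loops, set algebra,
# exhaustive enumeration) and share no code with the package internals.

# Shannon diversity by direct summation
oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts[counts > 0])
  -sum(p * log(p))
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# NODF by exhaustive pair enumeration on a binary matrix
oracle_nodf <- function(inc) {
  vals <- c()
  for (dir in 1:2) {
    m <- if (dir == 1) inc else t(inc)
    if (nrow(m) >= 2) {
      for (i in 1:(nrow(m) - 1)) {
        for (j in (i + 1):nrow(m)) {
          di <- sum(m[i, ]); dj <- sum(m[j, ])
          if (di == dj || min(di, dj) == 0) {
            vals <- c(vals, 0)
          } else {
            poor <- if (di < dj) i else j
            rich <- if (di < dj) j else i
            shared <- sum(m[poor, ] == 1 & m[rich, ] == 1)
            vals <- c(vals, 100 * shared / sum(m[poor, ]))
          }
        }
      }
    }
  }
  mean(vals)
}

oracle_connectance <- function(inc) sum(inc) / (nrow(inc) * ncol(inc))

# Mann-Whitney U for group a by exhaustive pair counting
oracle_mwu_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    if (ai > bj) u <- u + 1 else if (ai == bj) u <- u + 0.5
  }
  u
}

# beta partition by independent set algebra over "sp|pa" strings
oracle_beta <- function(links1, links2) {
  k1 <- paste(links1$species, links1$patch, sep = "|")
  k2 <- paste(links2$species, links2$patch, sep = "|")
  a <- sum(k1 %in% k2)
  b <- sum(!k1 %in% k2)
  cc <- sum(!k2 %in% k1)
  tot <- a + b + cc
  sp1 <- unique(links1$species); sp2 <- unique(links2$species)
  pa1 <- unique(links1$patch); pa2 <- unique(links2$patch)
  comp <- c(local = 0, regional = 0, landscape = 0, rl = 0)
  for (k in c(setdiff(k1, k2), setdiff(k2, k1))) {
    bits <- strsplit(k, "|", fixed = TRUE)[[1]]
    sp_per <- bits[1] %in% sp1 && bits[1] %in% sp2
    pa_per <- bits[2] %in% pa1 && bits[2] %in% pa2
    lab <- if (sp_per && pa_per) "local" else if (pa_per) "regional"
           else if (sp_per) "landscape" else "rl"
    comp[lab] <- comp[lab] + 1
  }
  list(beta_temporal = (b + cc) / tot,
       beta_extinction = b / tot, beta_colonization = cc / tot,
       beta_local = comp[["local"]] / tot,
       beta_regional = comp[["regional"]] / tot,
       beta_landscape = comp[["landscape"]] / tot,
       beta_rl = comp[["rl"]] / tot)
}

# Barber Q of one labelled partition, coded independently
oracle_barber_q <- function(inc, rmod, cmod) {
  E <- sum(inc)
  q <- 0
  for (i in seq_len(nrow(inc))) {
    for (j in seq_len(ncol(inc))) {
      if (rmod[i] == cmod[j]) {
        q <- q + inc[i, j] - sum(inc[i, ]) * sum(inc[, j]) / E
      }
    }
  }
  q / E
}

# exhaustive maximum of Barber Q over every partition of all nodes
# (restricted-growth-string enumeration; feasible for <= 10 nodes)
oracle_barber_best <- function(inc) {
  n <- nrow(inc) + ncol(inc)
  best <- -Inf
  rgs <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      rmod <- prefix[seq_len(nrow(inc))]
      cmod <- prefix[nrow(inc) + seq_len(ncol(inc))]
      q <- oracle_barber_q(inc, rmod, cmod)
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      rgs(c(prefix, lab), max(maxlab, lab))
    }
  }
  rgs(integer(0), 0L)
  best
}

# exhaustive cnodf null: every possible partner set of the focal degree
oracle_cnodf_exhaustive <- function(net, node) {
  inc <- net$incidence
  if (node %in% colnames(inc)) inc <- t(inc)
  obs <- oracle_nodf(inc)
  row <- which(rownames(inc) == node)
  deg <- sum(inc[row, ])
  sets <- utils::combn(ncol(inc), deg)
  null <- apply(sets, 2, function(cols) {
    m <- inc
    m[row, ] <- 0
    m[row, cols] <- 1
    oracle_nodf(m)
  })
  s <- sqrt(mean((null - mean(null))^2))   # population SD of the full null
  if (s == 0) 0 else (obs - mean(null)) / s
}

# random bipartite occurrence network helpers
random_incidence <- function(ns, np, fill = 0.4) {
  m <- matrix(rbinom(ns * np, 1, fill), ns, np,
              dimnames = list(paste0("s", seq_len(ns)),
                              paste0("p", seq_len(np))))
  m
}

random_network <- function(ns, np, fill = 0.4, period = NULL) {
  m <- random_incidence(ns, np, fill)
  attr(m, "period") <- period
  build_network(m)
}

# network straight from an explicit link list (node sets = incident nodes)
network_from_links <- function(species, patch, period = NULL) {
  sp <- sort(unique(species)); pa <- sort(unique(patch))
  m <- matrix(0L, length(sp), length(pa), dimnames = list(sp, pa))
  m[cbind(match(species, sp), match(patch, pa))] <- 1L
  attr(m, "period") <- period
  build_network(m)
}
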