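# Brute-force zero-recombination enumeration, independent of the GF(2)
# solver: founders take every canonical phase assignment (first heterozygous
# locus fixed, remaining het loci both ways), children take every
# transmission choice, and assignments are kept when every member's derived
# unordered genotype matches the input.  Configurations are unique at the
# haplotype-string level.

oracle_enumerate <- function(ped) {
  n <- n_members(ped); L <- n_markers(ped)
  g1 <- ped$geno[, seq(1, 2 * L, 2), drop = FALSE]
  g2 <- ped$geno[, seq(2, 2 * L, 2), drop = FALSE]
  small <- pmin(g1, g2); large <- pmax(g1, g2)
  het <- small != large
  fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
  founders <- which(is.na(fi)); kids <- which(!is.na(fi))
  # parents-before-children order (independent re-derivation)
  ord <- integer(0); placed <- logical(n)
  while (length(ord) < n) {
    for (j in seq_len(n)) {
      if (placed[j]) next
      if ((is.na(fi[j]) || placed[fi[j]]) && (is.na(mi[j]) || placed[mi[j]])) {
        ord <- c(ord, j); placed[j] <- TRUE
      }
    }
  }
  # founder options: list of 2 x L allele matrices
  founder_opts <- lapply(founders, function(j) {
    hm <- which(het[j, ])
    free <- if (length(hm) > 1) hm[-1] else integer(0)
    combos <- if (length(free)) expand.grid(rep(list(0:1), length(free)))
              else data.frame(row.names = 1)
    lapply(seq_len(nrow(combos)), function(r) {
      h1 <- small[j, ]; h2 <- large[j, ]
      fl <- free[combos[r, ] == 1]
      h1[fl] <- large[j, fl]; h2[fl] <- small[j, fl]
      rbind(h1, h2)
    })
  })
  kid_opts <- rep(list(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))), length(kids))
  counts <- c(vapply(founder_opts, length, 0L), lengths(kid_opts))
  keys <- character(0)
  idx <- rep(1L, length(counts))
  repeat {
    haps <- vector("list", n)
    for (t in seq_along(founders))
      haps[[founders[t]]] <- founder_opts[[t]][[idx[t]]]
    ok <- TRUE
    for (j in ord) {
      if (is.na(fi[j])) next
      tr <- kid_opts[[match(j, kids)]][[idx[length(founders) + match(j, kids)]]]
      hp <- haps[[fi[j]]][tr[1], ]; hm <- haps[[mi[j]]][tr[2], ]
      if (any(pmin(hp, hm) != small[j, ]) || any(pmax(hp, hm) != large[j, ])) {
        ok <- FALSE; break
      }
      haps[[j]] <- rbind(hp, hm)
    }
    if (ok)
      keys <- c(keys, paste(vapply(seq_len(n), function(j)
        paste(paste(haps[[j]][1, ], collapse = ""),
              paste(haps[[j]][2, ], collapse = ""), sep = "|"), ""),
        collapse = ";"))
    # advance mixed-radix counter
    pos <- 1L
    while (pos <= length(counts)) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= counts[pos]) break
      idx[pos] <- 1L; pos <- pos + 1L
    }
    if (pos > length(counts)) break
  }
  sort(unique(keys))
}
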