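## Single-locus transmission disequilibrium test.
##
## For every SNP, each heterozygous parent of each affected child contributes
## one transmission tally: b counts transmissions of the designated allele,
## c non-transmissions.  The transmitted allele is deduced from the child's
## and the other parent's genotypes; fully ambiguous triples (parents and
## child all heterozygous for the same two alleles) contribute 1/2 to each
## side.  The test statistic is McNemar's (b - c)^2 / (b + c) on 1 df.

#' Transmission counts at one SNP
#'
#' @param peds list of \code{fhm_pedigree} objects (or one pedigree).
#' @param snp 1-based SNP index.
#' @param designated allele whose transmissions are counted as \code{b};
#'   default 1.
#' @return List with \code{b}, \code{c} and \code{informative} (number of
#'   heterozygous-parent/affected-child pairs tallied).
#' @export
count_transmissions <- function(peds, snp, designated = 1L) {
  if (inherits(peds, "fhm_pedigree")) peds <- list(peds)
  b <- 0; cc <- 0
  for (ped in peds) {
    g1 <- unname(ped$geno[, 2 * snp - 1]); g2 <- unname(ped$geno[, 2 * snp])
    fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
    aff <- which(!is.na(ped$phenotype) & ped$phenotype == 1 & !is.na(fi))
    for (j in aff) {
      child <- sort(c(g1[j], g2[j]))
      for (side in 1:2) {
        p <- if (side == 1) fi[j] else mi[j]
        o <- if (side == 1) mi[j] else fi[j]
        pa <- c(g1[p], g2[p]); oa <- c(g1[o], g2[o])
        if (pa[1] == pa[2]) next                    # homozygous: uninformative
        # transmitted alleles t (from this parent) consistent with the trio
        cand <- unique(unlist(lapply(unique(pa), function(t) {
          lapply(unique(oa), function(t2)
            if (identical(sort(c(t, t2)), child)) t else NULL)
        })))
        if (!length(cand)) next                     # Mendelian inconsistency
        wt <- 1 / length(cand)
        for (t in cand) {
          if (t == designated) b <- b + wt else cc <- cc + wt
        }
      }
    }
  }
  list(b = b, c = cc, informative = b + cc)
}

#' TDT chi-square test from transmission counts
#'
#' @param counts list with \code{b} and \code{c} (see
#'   \code{\link{count_transmissions}}).
#' @return List with \code{chi2}, \code{p} and \code{informative} flag;
#'   \code{b + c = 0} gives chi2 = 0, p = 1, uninformative.
#' @export
tdt_test <- function(counts) {
  b <- counts$b; cc <- counts$c
  if (b + cc == 0) return(list(chi2 = 0, p = 1, informative = FALSE))
  chi2 <- (b - cc)^2 / (b + cc)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       informative = TRUE)
}

#' Single-locus TDT scan over all SNPs
#'
#' Runs the transmission disequilibrium test at every SNP across a set of
#' pedigrees, counting every (heterozygous parent, affected child) pair at
#' any generation, and applies a Bonferroni correction over SNPs.
#'
#' @param peds list of \code{fhm_pedigree} objects.
#' @param map optional marker map data frame (adds a \code{name} column).
#' @param alpha overall significance level after Bonferroni (default 0.05).
#' @return A data frame of class \code{tdt_scan}: one row per SNP with
#'   \code{b}, \code{c}, \code{chi2}, \code{p}, \code{p_adjusted},
#'   \code{significant}.
#' @export
tdt <- function(peds, map = NULL, alpha = 0.05) {
  if (inherits(peds, "fhm_pedigree")) peds <- list(peds)
  L <- n_markers(peds[[1]])
  rows <- lapply(seq_len(L), function(m) {
    ct <- count_transmissions(peds, m)
    tt <- tdt_test(ct)
    data.frame(marker = m, b = ct$b, c = ct$c, chi2 = tt$chi2, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * L)
  out$significant <- out$p_adjusted <= alpha
  if (!is.null(map)) out <- cbind(name = map$name[seq_len(L)], out)
  attr(out, "alpha") <- alpha
  class(out) <- c("tdt_scan", "data.frame")
  out
}
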