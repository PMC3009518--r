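## End-to-end simulation studies: type-I error, power on the single-locus
## and rare-haplotype disease models, and mapping precision.  Power is the
## fraction of replicates in which a method reports any marker significant
## after multiple-testing correction at the overall alpha.

replicate_hit <- function(peds, method, window, alpha, seed) {
  if (method == "fhapminer") {
    fit <- suppressWarnings(fhapminer(peds, window = window, alpha = alpha,
                                      seed = seed))
    any(fit$scan$significant, na.rm = TRUE)
  } else {
    any(tdt(peds, alpha = alpha)$significant)
  }
}

#' Empirical family-wise type-I error under the null model
#'
#' Simulates replicates in which phenotypes are Bernoulli draws independent
#' of genotype (at rate \code{K}), with ascertainment on one affected member
#' still applied, and reports the fraction of replicates in which each
#' method declares any marker significant after Bonferroni correction.
#'
#' @param table founder haplotype frequency table.
#' @param n_replicates number of replicates (default 100).
#' @param n_families ascertained families per replicate (default 50).
#' @param K null affection probability; defaults to the prevalence of
#'   penetrance set C at risk-allele frequency 0.1 (about 0.1).
#' @param alpha overall significance level (default 0.05).
#' @param window scan window (default 1).
#' @param methods any of \code{"fhapminer"}, \code{"tdt"}.
#' @param seed root seed.
#' @return List with \code{rate} (named per method), \code{hits} (logical
#'   matrix replicates x methods) and the configuration.
#' @export
run_type1 <- function(table, n_replicates = 100, n_families = 50,
                      K = prevalence(penetrance_sets()$C, 0.1),
                      alpha = 0.05, window = 1,
                      methods = c("fhapminer", "tdt"), seed = NULL) {
  model <- penetrance_model(K, K, K, mode = "null")
  hits <- matrix(NA, n_replicates, length(methods),
                 dimnames = list(NULL, methods))
  for (r in seq_len(n_replicates)) {
    rseed <- if (is.null(seed)) NULL else derive_seed(seed, "rep", r)
    sim <- simulate_families(n_families, table, model, seed = rseed)
    for (meth in methods)
      hits[r, meth] <- replicate_hit(sim$peds, meth, window, alpha,
                                     seed = if (is.null(rseed)) NULL
                                            else derive_seed(rseed, meth))
  }
  list(rate = colMeans(hits), hits = hits, n_replicates = n_replicates,
       n_families = n_families, K = K, alpha = alpha)
}

power_one_setting <- function(table, model, n_families, n_replicates,
                              window, alpha, methods, seed, map = NULL,
                              true_cm = NULL) {
  hits <- matrix(NA, n_replicates, length(methods),
                 dimnames = list(NULL, methods))
  prec <- matrix(NA_real_, n_replicates, length(methods),
                 dimnames = list(NULL, methods))
  for (r in seq_len(n_replicates)) {
    rseed <- if (is.null(seed)) NULL else derive_seed(seed, "rep", r)
    sim <- simulate_families(n_families, table, model, seed = rseed)
    for (meth in methods) {
      mseed <- if (is.null(rseed)) NULL else derive_seed(rseed, meth)
      if (meth == "fhapminer") {
        fit <- suppressWarnings(fhapminer(sim$peds, window = window,
                                          alpha = alpha, seed = mseed))
        hits[r, meth] <- any(fit$scan$significant, na.rm = TRUE)
        pvals <- fit$scan$p_raw
      } else {
        tt <- tdt(sim$peds, alpha = alpha)
        hits[r, meth] <- any(tt$significant)
        pvals <- tt$p
      }
      if (!is.null(map) && !is.null(true_cm))
        prec[r, meth] <- mapping_precision(pvals, map, true_cm)$distance
    }
  }
  list(power = colMeans(hits), precision = colMeans(prec))
}

#' Power study under the single-locus disease model
#'
#' For each requested SNP in turn: simulate ascertained families with that
#' SNP as the risk locus (risk allele = its minor allele in the table),
#' delete the risk SNP before analysis, and estimate each method's power as
#' the fraction of replicates with any Bonferroni-significant marker.  SNPs
#' are labelled Low/Medium/High by minor allele frequency.
#'
#' @param table founder haplotype frequency table.
#' @param penetrance penetrance triple (or \code{penetrance_model} whose
#'   triple is used).
#' @param snps SNP indices to scan (default: all polymorphic SNPs).
#' @param n_families,n_replicates sampling effort per SNP (defaults 50/100).
#' @param alpha,window,methods,seed as in \code{\link{run_type1}}.
#' @param maf_cuts Low/Medium and Medium/High MAF boundaries
#'   (default 0.13, 0.30).
#' @param precision also compute average mapping precision per SNP.
#' @param spacing_bp physical marker spacing of the synthetic map used for
#'   precision.
#' @return A data frame (one row per SNP x method) with \code{snp},
#'   \code{maf}, \code{maf_group}, \code{method}, \code{power} and
#'   \code{precision_cM} (NA unless requested).
#' @export
run_power_single_locus <- function(table, penetrance, snps = NULL,
                                   n_families = 50, n_replicates = 100,
                                   alpha = 0.05, window = 1,
                                   methods = c("fhapminer", "tdt"),
                                   maf_cuts = c(0.13, 0.30),
                                   precision = FALSE, spacing_bp = 10000,
                                   seed = NULL) {
  f <- penetrance_triple(penetrance)
  maf <- table_maf(table)
  if (is.null(snps)) snps <- maf$snp[maf$maf > 0]
  L <- attr(table, "L")
  full_map <- make_map(L, spacing_bp = spacing_bp)
  rows <- list()
  for (snp in snps) {
    if (maf$maf[maf$snp == snp] == 0) {
      warning("SNP ", snp, " is monomorphic in the table; skipped")
      next
    }
    model <- penetrance_model(f[1], f[2], f[3], mode = "single-locus",
                              risk_snp = snp,
                              risk_allele = maf$minor[maf$snp == snp])
    res <- power_one_setting(
      table, model, n_families, n_replicates, window, alpha, methods,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "snp", snp),
      map = if (precision) full_map[-snp, , drop = FALSE] else NULL,
      true_cm = if (precision) full_map$cM[snp] else NULL)
    m <- maf$maf[maf$snp == snp]
    grp <- if (m < maf_cuts[1]) "Low" else if (m < maf_cuts[2]) "Medium"
           else "High"
    rows[[length(rows) + 1L]] <-
      data.frame(snp = snp, maf = m, maf_group = grp, method = methods,
                 power = res$power,
                 precision_cM = if (precision) res$precision else NA_real_,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power study under the rare-haplotype disease model
#'
#' For each number k of risk haplotypes: draws \code{n_selections} random
#' risk sets from the haplotypes rarer than \code{threshold}, estimates
#' power for each selection over \code{n_replicates}, and averages over
#' selections.
#'
#' @param table founder haplotype frequency table.
#' @param penetrance penetrance triple applied to risk-haplotype copies.
#' @param k_range numbers of risk haplotypes (default 2:6).
#' @param n_selections random risk-set draws per k (default 10).
#' @param n_families,n_replicates sampling effort (defaults 100/100).
#' @param threshold rarity threshold (default 0.02).
#' @param window scan window (default 10 for haplotype studies).
#' @param alpha,methods,seed as in \code{\link{run_type1}}.
#' @return A data frame with \code{k}, \code{method}, \code{power} (mean over
#'   selections).
#' @export
run_power_rare_hap <- function(table, penetrance, k_range = 2:6,
                               n_selections = 10, n_families = 100,
                               n_replicates = 100, threshold = 0.02,
                               window = 10, alpha = 0.05,
                               methods = c("fhapminer", "tdt"), seed = NULL) {
  f <- penetrance_triple(penetrance)
  rows <- list()
  for (k in k_range) {
    pw <- matrix(NA_real_, n_selections, length(methods),
                 dimnames = list(NULL, methods))
    for (s in seq_len(n_selections)) {
      sseed <- if (is.null(seed)) NULL else derive_seed(seed, "k", k, "sel", s)
      risk <- pick_rare_haplotypes(table, k, threshold,
                                   seed = if (is.null(sseed)) NULL
                                          else derive_seed(sseed, "riskset"))
      model <- penetrance_model(f[1], f[2], f[3], mode = "rare-haplotype",
                                risk_haplotypes = risk)
      pw[s, ] <- power_one_setting(table, model, n_families, n_replicates,
                                   window, alpha, methods, seed = sseed)$power
    }
    rows[[length(rows) + 1L]] <-
      data.frame(k = k, method = methods, power = colMeans(pw),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mapping precision of a scan
#'
#' Genetic distance (cM) between the marker with the lowest p-value and the
#' true risk locus, based on the original map.  Ties are broken by the
#' lowest marker index; a scan in which every p-value is identical is
#' flagged uninformative (the tie-broken pick is still reported).
#'
#' @param pvalues per-marker p-values of the analysed (risk-SNP-free) panel.
#' @param map map data frame for those markers (same order).
#' @param true_cm genetic position (cM) of the true risk SNP on the original
#'   map.
#' @return List with \code{distance} (cM), \code{marker} (index of the pick)
#'   and \code{uninformative}.
#' @export
mapping_precision <- function(pvalues, map, true_cm) {
  if (length(pvalues) != nrow(map))
    stop("p-value / map length mismatch")
  idx <- which.min(pvalues)  # ties resolve to the lowest index
  list(distance = abs(map$cM[idx] - true_cm), marker = idx,
       uninformative = length(unique(pvalues[!is.na(pvalues)])) <= 1)
}
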