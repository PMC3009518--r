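## Pedigree simulator: CEPH-like family structures, founder haplotype
## dropping from a population frequency table, penetrance-model phenotypes
## and ascertainment on at least one affected member.

#' Penetrance model
#'
#' The probability of being affected given 0, 1 or 2 copies of the risk
#' allele (single-locus mode) or of a risk haplotype (rare-haplotype mode).
#' \code{mode = "null"} makes affection an i.i.d. Bernoulli(\code{f[1]}) draw
#' independent of genotype, the null model of the type-I error studies.
#'
#' @param f0,f1,f2 penetrances in [0, 1] for 0/1/2 risk copies.
#' @param mode one of \code{"single-locus"}, \code{"rare-haplotype"},
#'   \code{"null"}.
#' @param risk_snp 1-based risk SNP index (single-locus mode).
#' @param risk_allele risk allele code at that SNP (default: the minor allele
#'   of the simulation frequency table).
#' @param risk_haplotypes character vector of risk haplotype strings
#'   (rare-haplotype mode).
#' @return An object of class \code{penetrance_model}.
#' @export
penetrance_model <- function(f0, f1, f2 = f1,
                             mode = c("single-locus", "rare-haplotype", "null"),
                             risk_snp = NULL, risk_allele = NULL,
                             risk_haplotypes = NULL) {
  mode <- match.arg(mode)
  f <- c(f0, f1, f2)
  if (any(f < 0 | f > 1)) stop("penetrances must lie in [0, 1]")
  structure(list(f = f, mode = mode, risk_snp = risk_snp,
                 risk_allele = risk_allele,
                 risk_haplotypes = risk_haplotypes),
            class = "penetrance_model")
}

#' The three standard penetrance sets
#'
#' Set A = (0.05, 0.15, 0.25), set B = (0.01, 0.1, 0.15),
#' set C = (0.05, 0.3, 0.5).
#'
#' @return Named list of penetrance triples.
#' @export
penetrance_sets <- function() {
  list(A = c(0.05, 0.15, 0.25), B = c(0.01, 0.10, 0.15),
       C = c(0.05, 0.30, 0.50))
}

penetrance_triple <- function(model) {
  if (inherits(model, "penetrance_model")) model$f else as.numeric(model)
}

hwe_freqs <- function(p_D) c((1 - p_D)^2, 2 * p_D * (1 - p_D), p_D^2)

#' Population prevalence under Hardy-Weinberg equilibrium
#'
#' \deqn{K = (1-p_D)^2 f_0 + 2 p_D (1-p_D) f_1 + p_D^2 f_2.}
#'
#' @param model a \code{penetrance_model} or a penetrance triple.
#' @param p_D risk allele (or total risk haplotype) frequency.
#' @return numeric prevalence.
#' @export
prevalence <- function(model, p_D) {
  sum(hwe_freqs(p_D) * penetrance_triple(model))
}

#' Genotype distribution among affected individuals
#'
#' Bayes inversion of the HWE genotype priors through the penetrances:
#' \eqn{\Pr(G = g \mid A) = \Pr(G = g) f_g / K}.
#'
#' @inheritParams prevalence
#' @return Numeric triple \code{(Pr(dd|A), Pr(dD|A), Pr(DD|A))}, summing to 1.
#' @export
genotype_given_affected <- function(model, p_D) {
  f <- penetrance_triple(model)
  K <- prevalence(f, p_D)
  if (K == 0) stop("prevalence is zero; conditional distribution undefined")
  hwe_freqs(p_D) * f / K
}

#' Genotype relative risks
#'
#' \eqn{\lambda_1 = f_1/f_0}, \eqn{\lambda_2 = f_2/f_0}; with \eqn{f_0 = 0}
#' the risks are reported as \code{Inf} rather than raising an error.
#'
#' @inheritParams prevalence
#' @return Numeric pair \code{c(lambda1, lambda2)}.
#' @export
relative_risks <- function(model) {
  f <- penetrance_triple(model)
  if (f[1] == 0) return(c(lambda1 = Inf, lambda2 = Inf))
  c(lambda1 = f[2] / f[1], lambda2 = f[3] / f[1])
}

## --- family structures -----------------------------------------------------

# child-count distribution: negative binomial (dispersion 8, mu 8.4744)
# truncated to keep total sizes in 4-20; with P(three generations) = 52/65
# the long-run mean family size is 13, matching CEPH-study summaries.
STRUCT_NB_SIZE <- 8
STRUCT_NB_MU <- 8.4744

sample_nchildren <- function(lo, hi) {
  k <- lo:hi
  w <- stats::dnbinom(k, size = STRUCT_NB_SIZE, mu = STRUCT_NB_MU)
  sample(k, 1, prob = w)
}

#' Sample a CEPH-like pedigree skeleton
#'
#' Three-generation families (probability \code{p_three_gen}, default 52/65)
#' have four grandparents and a parental couple in which the father descends
#' from one grandparental couple and the mother from the other, plus a
#' sibship; two-generation families are a couple plus a sibship.  Sibship
#' sizes follow a truncated negative binomial so that total sizes span 4-20
#' with long-run mean 13.
#'
#' @param family_id identifier for the new family.
#' @param p_three_gen probability of a three-generation family.
#' @param seed optional seed.
#' @return An \code{fhm_pedigree} skeleton (no genotypes, phenotypes NA).
#' @export
sample_structure <- function(family_id = "F1", p_three_gen = 52 / 65,
                             seed = NULL) {
  with_seed(seed, {
    three <- stats::runif(1) < p_three_gen
    if (three) {
      k <- sample_nchildren(1L, 14L)
      id <- c("gf1", "gm1", "gf2", "gm2", "fa", "mo", paste0("c", seq_len(k)))
      father <- c(NA, NA, NA, NA, "gf1", "gf2", rep("fa", k))
      mother <- c(NA, NA, NA, NA, "gm1", "gm2", rep("mo", k))
      sex <- c(1, 2, 1, 2, 1, 2, rep_len(1:2, k))
    } else {
      k <- sample_nchildren(2L, 18L)
      id <- c("fa", "mo", paste0("c", seq_len(k)))
      father <- c(NA, NA, rep("fa", k))
      mother <- c(NA, NA, rep("mo", k))
      sex <- c(1, 2, rep_len(1:2, k))
    }
    fhm_pedigree(family_id, id, father, mother, sex,
                 rep(NA_real_, length(id)),
                 matrix(integer(0), length(id), 0))
  })
}

#' Drop founder haplotypes through a pedigree
#'
#' Each founder receives two haplotypes drawn i.i.d. from the population
#' frequency table; each child receives one whole haplotype from each parent
#' chosen by a fair coin (zero recombination).  Genotypes are derived from
#' the haplotypes and the true configuration is returned as ground truth.
#'
#' @param skeleton an \code{fhm_pedigree} (genotypes ignored).
#' @param table a \code{hap_freq_table}.
#' @param seed optional seed.
#' @return List with \code{ped} (pedigree with genotypes) and \code{truth}
#'   (the planted \code{hap_config}).
#' @export
drop_genes <- function(skeleton, table, seed = NULL) {
  with_seed(seed, {
    n <- n_members(skeleton)
    hapmat <- do.call(rbind, lapply(table$haplotype, hap_chars))
    L <- ncol(hapmat)
    hap <- array(0L, c(n, L, 2))
    origin <- matrix(0L, n, 2)
    ord <- peel_order(skeleton)
    fi <- match(skeleton$father, skeleton$id)
    mi <- match(skeleton$mother, skeleton$id)
    for (j in ord) {
      if (is.na(fi[j])) {
        draw <- sample.int(nrow(hapmat), 2, replace = TRUE, prob = table$freq)
        hap[j, , 1] <- hapmat[draw[1], ]
        hap[j, , 2] <- hapmat[draw[2], ]
        origin[j, ] <- c(2L * (j - 1L) + 1L, 2L * (j - 1L) + 2L)
      } else {
        hp <- sample(1:2, 1); hm <- sample(1:2, 1)
        hap[j, , 1] <- hap[fi[j], , hp]
        hap[j, , 2] <- hap[mi[j], , hm]
        origin[j, 1] <- origin[fi[j], hp]
        origin[j, 2] <- origin[mi[j], hm]
      }
    }
    geno <- matrix(0L, n, 2 * L)
    if (L) {
      geno[, seq(1, 2 * L, 2)] <- pmin(hap[, , 1], hap[, , 2])
      geno[, seq(2, 2 * L, 2)] <- pmax(hap[, , 1], hap[, , 2])
    }
    ped <- skeleton
    ped$geno <- geno
    truth <- structure(list(family_id = ped$family_id, id = ped$id,
                            phenotype = ped$phenotype,
                            founder = is_founder(ped),
                            hap = hap, origin = origin),
                       class = "hap_config")
    list(ped = ped, truth = truth)
  })
}

# risk-copy count per member under a penetrance model
risk_copies <- function(ped, truth, model) {
  n <- n_members(ped)
  switch(model$mode,
    "null" = integer(n),
    "single-locus" = {
      m <- model$risk_snp
      if (is.null(m) || m < 1 || m > n_markers(ped))
        stop("risk SNP index out of range")
      (ped$geno[, 2 * m - 1] == model$risk_allele) +
        (ped$geno[, 2 * m] == model$risk_allele)
    },
    "rare-haplotype" = {
      s <- hap_strings(truth)
      (s[, 1] %in% model$risk_haplotypes) + (s[, 2] %in% model$risk_haplotypes)
    })
}

#' Assign phenotypes under a penetrance model
#'
#' Each member is independently affected with probability \eqn{f_g}, where g
#' is its risk-allele or risk-haplotype copy count (0 under the null model).
#'
#' @param ped pedigree with genotypes.
#' @param truth the planted \code{hap_config} (needed in rare-haplotype mode).
#' @param model a \code{penetrance_model}.
#' @param seed optional seed.
#' @return The pedigree with phenotypes 1/0 filled in.
#' @export
assign_phenotypes <- function(ped, truth, model, seed = NULL) {
  with_seed(seed, {
    g <- risk_copies(ped, truth, model)
    ped$phenotype <- as.numeric(stats::runif(n_members(ped)) < model$f[g + 1])
    ped
  })
}

#' Remove one SNP column from a pedigree (and optionally its map row)
#'
#' In single-locus studies the risk SNP is deleted before analysis so that
#' power reflects linkage disequilibrium with the remaining markers.
#'
#' @param ped pedigree.
#' @param snp 1-based SNP index to remove.
#' @return Pedigree with \code{n_markers - 1} SNPs.
#' @export
strip_snp <- function(ped, snp) {
  ped$geno <- ped$geno[, -c(2 * snp - 1, 2 * snp), drop = FALSE]
  ped
}

#' Simulate an ascertained family dataset
#'
#' Repeats structure sampling, gene dropping and phenotype assignment,
#' keeping only families with at least one affected member, until
#' \code{n_families} are collected.  In single-locus mode the risk SNP column
#' is removed from the analysed genotypes (the truth record keeps its
#' identity and original position).
#'
#' @param n_families number of ascertained families to return.
#' @param table founder haplotype frequency table.
#' @param model a \code{penetrance_model}.
#' @param p_three_gen probability of a three-generation structure.
#' @param strip remove the risk SNP column (single-locus mode only).
#' @param seed root seed; per-family substream seeds are derived from it.
#' @param max_tries safety cap on total families attempted.
#' @return List with \code{peds}, \code{truths} (lists of length
#'   \code{n_families}), \code{risk_snp}, \code{attempted} (families drawn
#'   before ascertainment).
#' @export
simulate_families <- function(n_families, table, model,
                              p_three_gen = 52 / 65, strip = TRUE,
                              seed = NULL, max_tries = 1e6) {
  peds <- vector("list", n_families)
  truths <- vector("list", n_families)
  got <- 0L
  tries <- 0L
  while (got < n_families) {
    tries <- tries + 1L
    if (tries > max_tries) stop("ascertainment failed after ", max_tries,
                                " attempts; is the affection rate zero?")
    fseed <- if (is.null(seed)) NULL else derive_seed(seed, "family", tries)
    sk <- sample_structure(paste0("F", got + 1L), p_three_gen,
                           seed = if (is.null(fseed)) NULL
                                  else derive_seed(fseed, "structure"))
    gd <- drop_genes(sk, table,
                     seed = if (is.null(fseed)) NULL
                            else derive_seed(fseed, "genedrop"))
    ped <- assign_phenotypes(gd$ped, gd$truth, model,
                             seed = if (is.null(fseed)) NULL
                                    else derive_seed(fseed, "phenotype"))
    if (!any(ped$phenotype == 1, na.rm = TRUE)) next
    got <- got + 1L
    gd$truth$phenotype <- ped$phenotype
    peds[[got]] <- ped
    truths[[got]] <- gd$truth
  }
  risk_snp <- if (model$mode == "single-locus") model$risk_snp else NULL
  if (strip && !is.null(risk_snp))
    peds <- lapply(peds, strip_snp, snp = risk_snp)
  list(peds = peds, truths = truths, risk_snp = risk_snp, attempted = tries)
}

#' Select rare haplotypes as a risk set
#'
#' @param table frequency table.
#' @param k number of risk haplotypes to draw.
#' @param threshold rarity threshold on population frequency (default 0.02).
#' @param seed optional seed.
#' @return Character vector of k distinct haplotype strings.
#' @export
pick_rare_haplotypes <- function(table, k, threshold = 0.02, seed = NULL) {
  eligible <- table$haplotype[table$freq < threshold]
  if (length(eligible) < k)
    stop("only ", length(eligible), " haplotypes below frequency ",
         threshold, "; cannot select ", k)
  with_seed(seed, sample(eligible, k))
}

#' Uniform synthetic marker map
#'
#' Evenly spaced markers, 1 cM per Mb (0.01 cM per 10 kb by default).  The
#' map plays no role in zero-recombination inference; it is used for
#' mapping-precision reporting.
#'
#' @param L marker count.
#' @param spacing_bp physical spacing (default 10 kb).
#' @param cm_per_mb genetic map density.
#' @param chr chromosome label.
#' @return Map data frame (\code{name}, \code{chr}, \code{cM}, \code{bp}).
#' @export
make_map <- function(L, spacing_bp = 10000, cm_per_mb = 1, chr = "1") {
  bp <- 1 + (seq_len(L) - 1) * spacing_bp
  data.frame(name = paste0("snp", seq_len(L)), chr = chr,
             cM = (bp - 1) / 1e6 * cm_per_mb, bp = bp,
             stringsAsFactors = FALSE)
}

#' Synthetic 19-SNP, 29-haplotype frequency panel
#'
#' A deterministic stand-in for a cystic-fibrosis-region-like haplotype
#' panel: 29 haplotypes over 19 biallelic SNPs arranged in three haplotype
#' blocks, of which 22 are rare variants sharing the frequency 0.01786 and 7
#' are common block combinations.  This panel is synthetic - it reproduces
#' only the summary structure of such data (haplotype count, rare-haplotype
#' count and frequency, block-wise LD, a spread of MAFs), not any real
#' haplotypes.
#'
#' @return A \code{hap_freq_table}.
#' @export
synthetic_cf_panel <- function() {
  # three blocks (SNPs 1-7, 8-13, 14-19); SNPs 8 and 16 are monomorphic in
  # the common haplotypes so their minor alleles ride only on rare variants,
  # giving the panel a spread of MAFs from ~0.02 upward
  common <- c("1111111111111111111",
              "2221111111111221222",
              "1111111122222111111",
              "2221111122222221222",
              "1112222111111221222",
              "2222222122222111111",
              "1112222122222111111")
  cfreq <- c(0.20, 0.12, 0.10, 0.08, 0.05, 0.03, 0.02708)
  haps <- common
  rare <- character(0)
  i <- 0L
  while (length(rare) < 22L) {
    i <- i + 1L
    base <- hap_chars(common[(i - 1L) %% 7L + 1L])
    pos <- (i * 5L) %% 19L + 1L
    repeat {
      v <- base
      v[pos] <- 3L - v[pos]
      s <- paste(v, collapse = "")
      if (!(s %in% haps)) break
      pos <- pos %% 19L + 1L
    }
    rare <- c(rare, s)
    haps <- c(haps, s)
  }
  hap_freq_table(c(common, rare), c(cfreq, rep(0.01786, 22)))
}
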