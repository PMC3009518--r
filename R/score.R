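## Phenotype scores for founder haplotypes.
##
## Within a family, each founder haplotype copy accumulates evidence from the
## members that carry it by descent.  The default (deviation) score sums the
## carriers' trait deviations from the family mean weighted by copy number,
## so that haplotypes over-represented in affected / high-trait members score
## high and the scores of one family always sum to zero.  An alternative
## relative-risk style score forms a pseudocounted ratio of carriage in
## high-trait versus low-trait members; its exact published form is not fully
## specified, so the ratio implemented here is this package's declared
## reconstruction and is not the default.

score_frame <- function(config, s) {
  fh <- founder_haplotypes(config)
  fh$score <- s
  fh
}

#' Deviation phenotype score for founder haplotypes (default measure)
#'
#' For founder haplotype k of family i with member copy counts
#' \eqn{c_{ij} \in \{0,1,2\}}, the score is
#' \deqn{s_{ik} = \sum_j c_{ij} (Y_{ij} - \bar Y_i)}
#' where \eqn{\bar Y_i} is the family mean phenotype.  Members with missing
#' phenotype are excluded from both the mean and the sum.  Binary traits use
#' their 1/0 coding directly.
#'
#' @param config a \code{hap_config} for one family.
#' @param phenotype optional numeric vector overriding the phenotypes stored
#'   in the configuration.
#' @return The \code{\link{founder_haplotypes}} data frame with an added
#'   \code{score} column.
#' @export
score_deviation <- function(config, phenotype = NULL) {
  y <- phenotype %||% config$phenotype
  keep <- !is.na(y)
  if (!any(keep))
    stop("family '", config$family_id, "': no phenotyped members to score")
  cmat <- carrier_multiplicity(config)
  dev <- y[keep] - mean(y[keep])
  s <- as.vector(cmat[, keep, drop = FALSE] %*% dev)
  score_frame(config, s)
}

#' Relative-risk style phenotype score for founder haplotypes
#'
#' Carrier-weighted high-versus-low trait ratio with a 1/2 pseudocount:
#' \deqn{s_{ik} = \frac{\sum_j c_{ij} I(Y_{ij} \ge t) + 1/2}
#'                     {\sum_j c_{ij} I(Y_{ij} < t) + 1/2}}
#' with \eqn{I} the indicator and \eqn{t} a user threshold (for binary traits
#' any \eqn{t \in (0, 1]} splits affected from normal).  A haplotype carried
#' by nobody scores 1.
#'
#' @inheritParams score_deviation
#' @param t threshold splitting high from low phenotypes (default 0.5).
#' @return As \code{\link{score_deviation}}.
#' @export
score_relative_risk <- function(config, phenotype = NULL, t = 0.5) {
  y <- phenotype %||% config$phenotype
  keep <- !is.na(y)
  if (!any(keep))
    stop("family '", config$family_id, "': no phenotyped members to score")
  cmat <- carrier_multiplicity(config)[, keep, drop = FALSE]
  hi <- as.numeric(y[keep] >= t)
  s <- (as.vector(cmat %*% hi) + 0.5) /
       (as.vector(cmat %*% (1 - hi)) + 0.5)
  score_frame(config, s)
}

#' Score one family's founder haplotypes
#'
#' @param config a \code{hap_config}.
#' @param measure \code{"deviation"} (default) or \code{"relative-risk"}.
#' @param t threshold for the relative-risk measure.
#' @param phenotype optional phenotype override.
#' @return Scored founder haplotype data frame.
#' @export
score_founders <- function(config, measure = c("deviation", "relative-risk"),
                           t = 0.5, phenotype = NULL) {
  measure <- match.arg(measure)
  if (measure == "deviation") score_deviation(config, phenotype)
  else score_relative_risk(config, phenotype, t)
}

#' Pool scored founder haplotypes across families
#'
#' Founder haplotypes from different families are treated as independent
#' draws from the population; identical allele strings from different
#' families stay separate records, each keeping its own family's score.
#'
#' @param families list of scored founder haplotype data frames.
#' @return One concatenated data frame.
#' @export
pool_scores <- function(families) {
  if (!length(families))
    return(data.frame(family = character(), founder = character(),
                      copy = integer(), label = character(),
                      haplotype = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, families)
  rownames(out) <- NULL
  out
}
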