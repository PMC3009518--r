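#' Family-based haplotype association mining
#'
#' The central fitting function: for each family it infers the
#' zero-recombination haplotype solution space, draws one configuration
#' uniformly at random as the working solution, scores every founder
#' haplotype by its carriers' phenotype deviations, pools founder haplotypes
#' across families, and runs the marker-by-marker similarity-clustering
#' association scan.
#'
#' @param peds list of \code{\link{fhm_pedigree}} objects (complete
#'   genotypes, no loops).
#' @param map optional marker map data frame; adds marker names/positions to
#'   the scan table.
#' @param window sliding-window length in markers (1 for single-SNP studies,
#'   10 for haplotype studies).
#' @param w_L,w_N similarity weights for shared-segment length and matching
#'   allele count.
#' @param measure founder score: \code{"deviation"} (default) or
#'   \code{"relative-risk"}.
#' @param threshold high/low trait threshold for the relative-risk measure.
#' @param qtype Q statistic flavour (\code{"welch"} or \code{"one-sample"}).
#' @param minpts,eps_frac density-clustering parameters
#'   (see \code{\link{hap_cluster}}).
#' @param alpha overall significance level.
#' @param correction \code{"bonferroni"} or \code{"permutation"}.
#' @param B permutation count when \code{correction = "permutation"}.
#' @param seed root seed for configuration picking (and permutation).
#' @param on_conflict what to do with a family whose genotypes admit no
#'   zero-recombination configuration: \code{"drop"} (exclude with a warning,
#'   continue with the rest) or \code{"error"}.
#' @return An object of class \code{fhapminer}: list with \code{scan} (the
#'   per-marker \code{\link{hap_scan}} table), \code{pooled} (scored founder
#'   haplotypes), \code{dof} (phasing degrees of freedom per family),
#'   \code{excluded} (families dropped for phase conflicts), \code{alpha} and
#'   the call.
#' @examples
#' tab <- synthetic_cf_panel()
#' model <- penetrance_model(0.05, 0.3, 0.5, mode = "single-locus",
#'                           risk_snp = 4, risk_allele = 2)
#' sim <- simulate_families(12, tab, model, seed = 1)
#' fit <- fhapminer(sim$peds, seed = 1)
#' summary(fit)
#' @export
fhapminer <- function(peds, map = NULL, window = 1, w_L = 1, w_N = 1,
                      measure = c("deviation", "relative-risk"),
                      threshold = 0.5, qtype = c("welch", "one-sample"),
                      minpts = NULL, eps_frac = 0.8, alpha = 0.05,
                      correction = c("bonferroni", "permutation"), B = 200,
                      seed = NULL, on_conflict = c("drop", "error")) {
  measure <- match.arg(measure)
  qtype <- match.arg(qtype)
  correction <- match.arg(correction)
  on_conflict <- match.arg(on_conflict)
  if (inherits(peds, "fhm_pedigree")) peds <- list(peds)

  scored <- list()
  dof <- integer(0)
  excluded <- character(0)
  for (i in seq_along(peds)) {
    ped <- peds[[i]]
    space <- tryCatch(phase_solve(ped), error = function(e) e)
    if (inherits(space, "error")) {
      if (on_conflict == "error") stop(space)
      warning("family '", ped$family_id, "' excluded: ",
              conditionMessage(space))
      excluded <- c(excluded, ped$family_id)
      next
    }
    cfg <- pick_config(space, seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, "pick", i))
    scored[[length(scored) + 1L]] <-
      score_founders(cfg, measure = measure, t = threshold)
    dof[ped$family_id] <- space$dof
  }
  if (!length(scored)) stop("no family could be phased")
  pooled <- pool_scores(scored)
  scan <- hap_scan(pooled, W = window, w_L = w_L, w_N = w_N,
                   minpts = minpts, eps_frac = eps_frac, alpha = alpha,
                   correction = correction, B = B, qtype = qtype,
                   seed = if (is.null(seed)) NULL
                          else derive_seed(seed, "scan"))
  if (!is.null(map)) {
    scan$name <- map$name[scan$marker]
    scan$cM <- map$cM[scan$marker]
  }
  structure(list(scan = scan, pooled = pooled, dof = dof,
                 excluded = excluded, alpha = alpha, window = window,
                 measure = measure, correction = correction,
                 call = match.call()),
            class = "fhapminer")
}

#' @export
print.fhapminer <- function(x, ...) {
  cat("Family-based haplotype association scan\n")
  cat(sprintf("  families analysed: %d (%d excluded); pooled founder haplotypes: %d\n",
              length(x$dof), length(x$excluded), nrow(x$pooled)))
  cat(sprintf("  window: %d marker(s); score: %s; correction: %s; alpha: %g\n",
              x$window, x$measure, x$correction, x$alpha))
  sig <- sum(x$scan$significant, na.rm = TRUE)
  cat(sprintf("  markers: %d; significant after correction: %d\n",
              nrow(x$scan), sig))
  if (sig) {
    top <- x$scan[which.min(x$scan$p_adjusted), ]
    cat(sprintf("  top marker: %d (Q = %.3f, adjusted p = %.3g)\n",
                top$marker, top$Q, top$p_adjusted))
  }
  invisible(x)
}

#' @export
summary.fhapminer <- function(object, ...) {
  print(object)
  cat("\nPer-marker results:\n")
  print.data.frame(object$scan, digits = 4, row.names = FALSE)
  invisible(object$scan)
}

#' @export
coef.fhapminer <- function(object, ...) {
  stats::setNames(object$scan$Q, paste0("marker", object$scan$marker))
}

#' Manhattan-style plot of a haplotype association scan
#'
#' @param x an \code{fhapminer} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.fhapminer <- function(x, ...) {
  p <- x$scan$p_adjusted
  xs <- if (!is.null(x$scan$cM)) x$scan$cM else x$scan$marker
  xl <- if (!is.null(x$scan$cM)) "position (cM)" else "marker index"
  graphics::plot(xs, -log10(pmax(p, 1e-16)), type = "h", lwd = 2,
                 xlab = xl, ylab = expression(-log[10](p[adj])), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "grey40")
  invisible(x)
}
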