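## Haplotype similarity clustering and association scan.
##
## Around each marker, pooled founder haplotypes are compared with a
## position-weighted similarity combining (i) the length of the contiguous
## shared segment containing the focal marker and (ii) the number of matching
## alleles inside a fixed window.  Haplotypes are grouped with a density-based
## (DBSCAN-style) clustering on the induced distance, each cluster's
## phenotype-score mean is contrasted with the rest of the sample by a t-type
## Q score, and the best cluster per marker is tested genome-wide with
## Bonferroni or permutation control.

#' Window bounds around a focal marker
#' @keywords internal
window_bounds <- function(focal, L, W) {
  half <- (W - 1L) %/% 2L
  c(max(1L, focal - half), min(L, focal + half))
}

#' Position-weighted haplotype similarity
#'
#' Within the \code{W}-marker window centered on \code{focal} (clipped at
#' chromosome ends), computes \eqn{S = w_L L + w_N N} where N is the number of
#' positions with identical alleles and L the length of the longest run of
#' consecutive matches containing the focal position (0 when the focal
#' alleles differ).  Symmetric; maximal for identical strings.
#'
#' @param h1,h2 allele strings (or integer vectors) of equal length.
#' @param focal focal marker (1-based).
#' @param W odd window length in markers.
#' @param w_L,w_N non-negative weights for segment length and match count.
#' @return numeric similarity.
#' @export
similarity <- function(h1, h2, focal, W = 1, w_L = 1, w_N = 1) {
  if (is.character(h1)) h1 <- hap_chars(h1)
  if (is.character(h2)) h2 <- hap_chars(h2)
  if (length(h1) != length(h2)) stop("haplotype length mismatch")
  if (focal < 1 || focal > length(h1)) stop("focal marker out of bounds")
  b <- window_bounds(focal, length(h1), W)
  eq <- h1[b[1]:b[2]] == h2[b[1]:b[2]]
  f <- focal - b[1] + 1L
  N <- sum(eq)
  if (!eq[f]) return(w_N * N)
  lo <- f; while (lo > 1 && eq[lo - 1]) lo <- lo - 1
  hi <- f; while (hi < length(eq) && eq[hi + 1]) hi <- hi + 1
  w_L * (hi - lo + 1L) + w_N * N
}

# pairwise similarity matrix for rows of integer allele matrix `hmat`
# around `focal`; vectorized over pairs
similarity_matrix <- function(hmat, focal, W = 1, w_L = 1, w_N = 1) {
  n <- nrow(hmat)
  b <- window_bounds(focal, ncol(hmat), W)
  idx <- b[1]:b[2]
  f <- focal - b[1] + 1L
  eqs <- lapply(idx, function(m) outer(hmat[, m], hmat[, m], "=="))
  N <- Reduce(`+`, eqs)
  run <- eqs[[f]] * 1
  L <- run
  P <- eqs[[f]]
  if (f > 1) for (d in seq(f - 1, 1)) {          # extend left
    P <- P & eqs[[d]]
    if (!any(P)) break
    L <- L + P
  }
  P <- eqs[[f]]
  if (f < length(idx)) for (d in seq(f + 1, length(idx))) {  # extend right
    P <- P & eqs[[d]]
    if (!any(P)) break
    L <- L + P
  }
  w_L * L + w_N * N
}

#' Density-based clustering of haplotypes around a marker
#'
#' DBSCAN on the distance \eqn{d = S_{max} - S}, where \eqn{S_{max}} is the
#' self-similarity of an identical pair in the (clipped) window.  A haplotype
#' is a core point when at least \code{minpts} haplotypes (itself included)
#' have similarity at least \code{eps_frac * S_max} with it; clusters are the
#' connected components of core points plus their reachable border points;
#' noise belongs to no cluster.  Deterministic given input order.
#'
#' @param haplotypes character vector of allele strings (or integer matrix,
#'   one row per haplotype).
#' @param focal focal marker (1-based).
#' @param W,w_L,w_N similarity parameters (see \code{\link{similarity}}).
#' @param minpts core-point threshold; default \code{max(2, ceiling(0.05 n))}.
#' @param eps_frac minimum similarity as a fraction of \eqn{S_{max}}
#'   (default 0.8).
#' @return List of integer index vectors, one per cluster (possibly empty).
#' @export
hap_cluster <- function(haplotypes, focal, W = 1, w_L = 1, w_N = 1,
                        minpts = NULL, eps_frac = 0.8) {
  hmat <- if (is.matrix(haplotypes)) haplotypes
          else do.call(rbind, lapply(haplotypes, hap_chars))
  n <- nrow(hmat)
  if (n < 2) return(list())
  minpts <- minpts %||% max(2L, ceiling(0.05 * n))
  S <- similarity_matrix(hmat, focal, W, w_L, w_N)
  b <- window_bounds(focal, ncol(hmat), W)
  smax <- (w_L + w_N) * (b[2] - b[1] + 1L)
  nbr <- S >= eps_frac * smax - 1e-9
  core <- rowSums(nbr) >= minpts
  if (!any(core)) return(list())
  cl <- integer(n)            # 0 = unassigned/noise
  ncl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cl[i] != 0L) next
    ncl <- ncl + 1L
    queue <- i
    cl[i] <- ncl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      reach <- which(nbr[q, ] & cl == 0L)
      if (length(reach)) {
        cl[reach] <- ncl
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  lapply(seq_len(ncl), function(k) which(cl == k))
}

#' Q score of a haplotype cluster
#'
#' Measures the deviation of the cluster's phenotype-score mean from the rest
#' of the sample.  The default is a Welch two-sample t statistic between
#' in-cluster and out-of-cluster scores (two-sided p from the t distribution
#' with Welch-Satterthwaite degrees of freedom); \code{type = "one-sample"}
#' instead contrasts the cluster mean with the overall mean using the
#' cluster's own standard error.  The sign of Q is kept; ranking uses |Q|.
#'
#' @param cluster_scores numeric scores of cluster members (>= 2).
#' @param all_scores numeric scores of the full pooled sample (>= 3); the
#'   cluster must be a strict subset.
#' @param type \code{"welch"} (default) or \code{"one-sample"}.
#' @return List with elements \code{Q} and \code{p}.
#' @export
q_score <- function(cluster_scores, all_scores,
                    type = c("welch", "one-sample")) {
  type <- match.arg(type)
  n1 <- length(cluster_scores); n <- length(all_scores)
  if (n1 < 2 || n < 3 || n1 >= n)
    stop("cluster must be a strict subset with >= 2 members of >= 3 scores")
  if (type == "welch") {
    # complement = all minus one instance of each cluster score
    rest <- all_scores
    for (v in cluster_scores) rest <- rest[-match(v, rest)]
    m1 <- mean(cluster_scores); m2 <- mean(rest)
    v1 <- stats::var(cluster_scores); v2 <- stats::var(rest)
    se2 <- v1 / n1 + v2 / length(rest)
    if (se2 <= 0) {
      if (m1 == m2) return(list(Q = 0, p = 1))
      return(list(Q = sign(m1 - m2) * Inf, p = 0))
    }
    Q <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) +
                   v2^2 / (length(rest)^2 * (length(rest) - 1)))
  } else {
    m1 <- mean(cluster_scores); v1 <- stats::var(cluster_scores)
    if (v1 <= 0) {
      if (m1 == mean(all_scores)) return(list(Q = 0, p = 1))
      return(list(Q = sign(m1 - mean(all_scores)) * Inf, p = 0))
    }
    Q <- (m1 - mean(all_scores)) / sqrt(v1 / n1)
    df <- n1 - 1
  }
  list(Q = Q, p = 2 * stats::pt(-abs(Q), df))
}

# best (max |Q|) cluster at one marker; ties: smaller p, larger cluster,
# lexicographically smallest member set
best_cluster <- function(clusters, scores, qtype) {
  best <- NULL
  for (idx in clusters) {
    # both the cluster and its complement need >= 2 scores for a t contrast
    if (length(idx) < 2 || length(idx) > length(scores) - 2) next
    qs <- q_score(scores[idx], scores, type = qtype)
    cand <- list(members = idx, Q = qs$Q, p = qs$p)
    if (is.null(best)) { best <- cand; next }
    d <- abs(cand$Q) - abs(best$Q)
    take <- if (abs(d) > 1e-12) d > 0
      else if (cand$p != best$p) cand$p < best$p
      else if (length(cand$members) != length(best$members))
        length(cand$members) > length(best$members)
      else paste(cand$members, collapse = ",") <
           paste(best$members, collapse = ",")
    if (take) best <- cand
  }
  best
}

#' Marker-by-marker haplotype association scan
#'
#' For each marker: windowed segments of all pooled founder haplotypes are
#' clustered by position-weighted similarity, every cluster receives a Q
#' score, and the cluster with the highest |Q| is taken as the marker's
#' statistic.  Multiplicity over markers is controlled by Bonferroni
#' (p multiplied by the marker count) or by a permutation null of the
#' genome-wide maximum |Q| obtained by shuffling scores against haplotypes.
#'
#' @param pooled data frame of pooled scored founder haplotypes
#'   (\code{\link{pool_scores}}): columns \code{haplotype} and \code{score}.
#' @param W window length in markers (odd; clipped at the ends).
#' @param w_L,w_N similarity weights.
#' @param minpts,eps_frac clustering parameters (see \code{\link{hap_cluster}}).
#' @param alpha overall significance level (default 0.05).
#' @param correction \code{"bonferroni"} (default) or \code{"permutation"}.
#' @param B permutation count (default 200).
#' @param qtype Q statistic flavour, see \code{\link{q_score}}.
#' @param seed optional seed for the permutation null.
#' @return A data frame of class \code{hap_scan} with one row per marker:
#'   \code{marker} (1-based), \code{n_cluster}, \code{cluster_size}, \code{Q},
#'   \code{p_raw}, \code{p_adjusted}, \code{significant}; the best cluster
#'   memberships are in \code{attr(, "clusters")}.
#' @export
hap_scan <- function(pooled, W = 1, w_L = 1, w_N = 1,
                     minpts = NULL, eps_frac = 0.8, alpha = 0.05,
                     correction = c("bonferroni", "permutation"), B = 200,
                     qtype = c("welch", "one-sample"), seed = NULL) {
  correction <- match.arg(correction)
  qtype <- match.arg(qtype)
  hmat <- do.call(rbind, lapply(pooled$haplotype, hap_chars))
  L <- ncol(hmat)
  n <- nrow(hmat)
  if (W > L) {
    warning("window of ", W, " markers clipped to chromosome length ", L)
    W <- L
  }
  scores <- pooled$score
  clusters_at <- function(m) hap_cluster(hmat, m, W, w_L, w_N, minpts, eps_frac)
  marker_clusters <- lapply(seq_len(L), clusters_at)

  eval_scores <- function(sc) {
    vapply(seq_len(L), function(m) {
      b <- best_cluster(marker_clusters[[m]], sc, qtype)
      if (is.null(b)) NA_real_ else abs(b$Q)
    }, 0)
  }

  best <- lapply(seq_len(L), function(m)
    best_cluster(marker_clusters[[m]], scores, qtype))
  Q <- vapply(best, function(b) if (is.null(b)) NA_real_ else b$Q, 0)
  p_raw <- vapply(best, function(b) if (is.null(b)) NA_real_ else b$p, 0)
  size <- vapply(best, function(b) if (is.null(b)) NA_integer_
                 else length(b$members), 0L)

  if (correction == "bonferroni") {
    p_adj <- pmin(1, p_raw * L)
  } else {
    null_max <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        mx <- suppressWarnings(max(eval_scores(sample(scores)), na.rm = TRUE))
        if (is.finite(mx)) mx else 0
      }, 0)
    })
    p_adj <- vapply(abs(Q), function(q) {
      if (is.na(q)) NA_real_ else (1 + sum(null_max >= q)) / (B + 1)
    }, 0)
    p_adj <- pmax(p_adj, p_raw, na.rm = FALSE)
  }
  out <- data.frame(marker = seq_len(L),
                    n_cluster = lengths(marker_clusters),
                    cluster_size = size, Q = Q, p_raw = p_raw,
                    p_adjusted = p_adj,
                    significant = !is.na(p_adj) & p_adj <= alpha)
  attr(out, "clusters") <- lapply(best, function(b) b$members)
  attr(out, "alpha") <- alpha
  class(out) <- c("hap_scan", "data.frame")
  out
}
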