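## Zero-recombination haplotype inference.
##
## Under the zero-recombination assumption each child receives one entire
## haplotype from each parent, so one binary inheritance variable (h) per
## parent-child edge describes transmission across all SNPs, and one binary
## phase variable (w) per heterozygous (member, locus) cell describes which
## allele sits on the member's first haplotype (w = 0: the smaller allele).
## Genotype consistency at every child locus translates into XOR constraints
## among these variables; the full solution space is the affine solution set
## of a linear system over GF(2), obtained here by Gaussian elimination.

# Assemble the GF(2) system for one pedigree.  Returns variable maps and the
# constraint rows; assumes complete genotypes, no loops, members validated.
build_phase_system <- function(ped) {
  n <- n_members(ped)
  L <- n_markers(ped)
  g1 <- ped$geno[, seq(1, 2 * L, by = 2), drop = FALSE]
  g2 <- ped$geno[, seq(2, 2 * L, by = 2), drop = FALSE]
  if (any(g1 == 0L | g2 == 0L))
    stop("pedigree '", ped$family_id,
         "': missing genotypes are not supported by the phaser")
  if (has_loops(ped))
    stop("pedigree '", ped$family_id,
         "': looped pedigrees are not supported by the phaser")
  small <- pmin(g1, g2)
  large <- pmax(g1, g2)
  het <- small != large

  widx <- matrix(0L, n, L)
  widx[het] <- seq_len(sum(het))
  n_w <- sum(het)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  kids <- which(!is.na(fi))
  hpat <- hmat <- rep(NA_integer_, n)
  hpat[kids] <- n_w + seq_along(kids)
  hmat[kids] <- n_w + length(kids) + seq_along(kids)
  V <- n_w + 2L * length(kids)

  rows <- list()
  add <- function(vars, rhs) rows[[length(rows) + 1L]] <<- c(vars, -(rhs %% 2L))
  conflict <- FALSE

  # canonicalization: first heterozygous locus of each founder fixed to put
  # the smaller allele on the designated-first haplotype
  for (j in which(is_founder(ped))) {
    hm <- which(het[j, ])
    if (length(hm)) add(widx[j, hm[1]], 0L)
  }

  # transmission constraints, father (side = 1) and mother (side = 2)
  for (j in kids) {
    for (side in 1:2) {
      p <- if (side == 1) fi[j] else mi[j]
      e <- if (side == 1) hpat[j] else hmat[j]
      for (m in seq_len(L)) {
        ch <- het[j, m]; ph <- het[p, m]
        if (!ch && !ph) {
          if (small[j, m] != small[p, m] && large[j, m] != small[p, m])
            conflict <- TRUE
        } else if (!ch && ph) {
          a <- small[j, m]
          if (a != small[p, m] && a != large[p, m]) { conflict <- TRUE; next }
          add(c(widx[p, m], e), as.integer(a == large[p, m]))
        } else if (ch && !ph) {
          x <- small[p, m]
          if (x != small[j, m] && x != large[j, m]) { conflict <- TRUE; next }
          # slot receiving from this parent: paternal slot carries the smaller
          # child allele iff w_c = 0; maternal slot iff w_c = 1
          tgt <- if (side == 1) as.integer(x == large[j, m])
                 else           as.integer(x == small[j, m])
          add(widx[j, m], tgt)
        } else {
          ca <- c(small[j, m], large[j, m]); pa <- c(small[p, m], large[p, m])
          shared <- intersect(ca, pa)
          if (!length(shared)) { conflict <- TRUE; next }
          if (length(shared) == 2L) {
            # t = small_p iff (w_p xor e) = 0; receiving slot holds small_c
            # iff w_c = [side == 2]
            add(c(widx[j, m], widx[p, m], e), as.integer(side == 2))
          } else {
            s <- shared[1]
            tgt <- if (side == 1) as.integer(s == large[j, m])
                   else           as.integer(s == small[j, m])
            add(widx[j, m], tgt)
            add(c(widx[p, m], e), as.integer(s == large[p, m]))
          }
        }
      }
    }
  }
  list(ped = ped, n = n, L = L, small = small, large = large, het = het,
       widx = widx, n_w = n_w, fi = fi, mi = mi, kids = kids,
       hpat = hpat, hmat = hmat, V = V, rows = rows,
       mendel_conflict = conflict)
}

# Reduced row echelon form over GF(2).  M holds variable columns plus a final
# right-hand-side column.  Returns pivot columns, their rows, and whether the
# system is consistent.
gf2_rref <- function(M) {
  nr <- nrow(M); nc <- ncol(M); nv <- nc - 1L
  r <- 1L
  pivcol <- integer(0)
  for (cc in seq_len(nv)) {
    if (r > nr) break
    hit <- which(M[r:nr, cc] == 1L)
    if (!length(hit)) next
    p <- r + hit[1L] - 1L
    if (p != r) { tmp <- M[r, ]; M[r, ] <- M[p, ]; M[p, ] <- tmp }
    others <- which(M[, cc] == 1L)
    others <- others[others != r]
    if (length(others))
      M[others, ] <- (M[others, , drop = FALSE] +
                        matrix(M[r, ], length(others), nc, byrow = TRUE)) %% 2L
    pivcol <- c(pivcol, cc)
    r <- r + 1L
  }
  consistent <- !(r <= nr && any(M[r:nr, nc] == 1L))
  list(M = M, pivcol = pivcol, pivrow = seq_along(pivcol),
       consistent = consistent)
}

#' Solve the zero-recombination phasing problem for one pedigree
#'
#' Computes the complete solution space of haplotype configurations
#' consistent with the genotypes under zero recombination, as a particular
#' solution plus free binary variables over GF(2).  Configurations are
#' canonicalized by fixing the first heterozygous locus of every founder
#' (smaller allele on the designated-first haplotype), so the reported number
#' of solutions is modulo founder phase swaps.
#'
#' @param ped an \code{fhm_pedigree} with complete genotypes and no loops.
#' @return An object of class \code{phase_space} with elements including
#'   \code{dof} (degrees of freedom: the number of configurations is
#'   \code{2^dof}) and \code{consistent}.  Mendelian violations raise an
#'   error naming the individual and SNP; a consistent-genotype pedigree with
#'   no zero-recombinant solution raises a conflict error (use
#'   \code{\link{enumerate_configs}} for an empty-list return instead).
#' @seealso \code{\link{enumerate_configs}}, \code{\link{pick_config}},
#'   \code{\link{founder_haplotypes}}
#' @export
phase_solve <- function(ped) {
  viol <- validate_mendelian(ped)
  if (nrow(viol))
    stop("pedigree '", ped$family_id, "': Mendelian violation at SNP ",
         viol$snp[1], ", individual '", viol$individual[1], "'")
  sp <- phase_solve_raw(ped)
  if (!sp$consistent)
    stop("pedigree '", ped$family_id,
         "': constraint system inconsistent; no zero-recombination solution")
  sp
}

# as phase_solve but returns an (possibly inconsistent) space without error
phase_solve_raw <- function(ped) {
  sys <- build_phase_system(ped)
  V <- sys$V
  nr <- length(sys$rows)
  M <- matrix(0L, nr, V + 1L)
  for (i in seq_len(nr)) {
    row <- sys$rows[[i]]
    rhs <- row[length(row)]
    vars <- row[-length(row)]
    M[i, vars] <- (M[i, vars] + 1L) %% 2L  # duplicated vars cancel over GF(2)
    M[i, V + 1L] <- -rhs
  }
  rr <- gf2_rref(M)
  consistent <- rr$consistent && !sys$mendel_conflict
  free <- setdiff(seq_len(V), rr$pivcol)

  # affine map from free variables to the w (phase) variables, whose values
  # determine the haplotype strings: A x_free + c0 over GF(2)
  A <- matrix(0L, sys$n_w, length(free))
  c0 <- integer(sys$n_w)
  if (sys$n_w > 0 && consistent) {
    for (k in seq_len(sys$n_w)) {
      pi <- match(k, rr$pivcol)
      if (is.na(pi)) {
        A[k, match(k, free)] <- 1L
      } else {
        if (length(free)) A[k, ] <- rr$M[pi, free]
        c0[k] <- rr$M[pi, V + 1L]
      }
    }
  }
  # basis: free variables whose A-columns are linearly independent; distinct
  # assignments of the basis give all string-distinct configurations
  basis <- integer(0)
  if (length(free) && sys$n_w > 0 && consistent) {
    Ab <- rbind(A, 0L)  # guard for single-row edge cases
    piv <- gf2_rref(cbind(Ab, 0L))$pivcol
    basis <- free[piv[piv <= length(free)]]
  }
  structure(c(sys, list(rref = rr, free = free, A = A, c0 = c0,
                        basis = basis, dof = length(basis),
                        consistent = consistent)),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf(paste0("Zero-recombination phase space for pedigree '%s':\n",
                     "  %d members, %d SNPs, %d heterozygous cells\n",
                     "  consistent: %s; degrees of freedom: %d (%s distinct ",
                     "configurations)\n"),
              x$ped$family_id, x$n, x$L, x$n_w, x$consistent, x$dof,
              format(2^x$dof)))
  invisible(x)
}

# full variable assignment from values of the free variables
full_assignment <- function(space, xfree) {
  x <- integer(space$V)
  if (length(space$free)) x[space$free] <- xfree
  rr <- space$rref
  for (i in seq_along(rr$pivcol)) {
    v <- rr$pivcol[i]
    val <- rr$M[i, space$V + 1L]
    if (length(space$free))
      val <- (val + sum(rr$M[i, space$free] * xfree)) %% 2L
    x[v] <- val
  }
  x
}

# Build a haplotype configuration from a full variable assignment.
config_from_assignment <- function(space, x) {
  n <- space$n; L <- space$L
  hap <- array(0L, c(n, L, 2))
  hap[, , 1] <- space$small
  hap[, , 2] <- space$large
  if (space$n_w) {
    flip <- space$het & matrix(FALSE, n, L)
    wvals <- x[seq_len(space$n_w)]
    flip[space$het] <- wvals[space$widx[space$het]] == 1L
    tmp <- hap[, , 1][flip]
    hap[, , 1][flip] <- hap[, , 2][flip]
    hap[, , 2][flip] <- tmp
  }
  origin <- matrix(0L, n, 2)  # slot id: 2*(member-1) + which-of-two
  ord <- peel_order(space$ped)
  for (j in ord) {
    if (is.na(space$fi[j])) {
      origin[j, ] <- c(2L * (j - 1L) + 1L, 2L * (j - 1L) + 2L)
    } else {
      hp <- x[space$hpat[j]]
      hm <- x[space$hmat[j]]
      origin[j, 1] <- origin[space$fi[j], 1L + hp]
      origin[j, 2] <- origin[space$mi[j], 1L + hm]
    }
  }
  structure(list(family_id = space$ped$family_id, id = space$ped$id,
                 phenotype = space$ped$phenotype,
                 founder = is_founder(space$ped),
                 hap = hap, origin = origin),
            class = "hap_config")
}

#' @export
print.hap_config <- function(x, ...) {
  s <- hap_strings(x)
  cat(sprintf("Haplotype configuration, pedigree '%s' (%d members):\n",
              x$family_id, length(x$id)))
  for (j in seq_along(x$id))
    cat(sprintf("  %s: %s | %s\n", x$id[j], s[j, 1], s[j, 2]))
  invisible(x)
}

#' Haplotype strings of a configuration
#' @param config a \code{hap_config}.
#' @return character matrix, one row per member, columns = the two haplotypes
#'   (paternal first for non-founders).
#' @export
hap_strings <- function(config) {
  n <- dim(config$hap)[1]
  out <- matrix("", n, 2)
  for (s in 1:2)
    out[, s] <- apply(config$hap[, , s, drop = FALSE], 1, paste, collapse = "")
  out
}

#' Enumerate all zero-recombination haplotype configurations
#'
#' Materializes the complete canonical solution set of
#' \code{\link{phase_solve}}.  Returns an empty list when the genotypes are
#' Mendelian-consistent locus by locus but no zero-recombinant configuration
#' exists.
#'
#' @param ped an \code{fhm_pedigree}, or a \code{phase_space}.
#' @param limit refuse to materialize more than this many configurations
#'   (default \code{2^20}).
#' @return List of \code{hap_config} objects, length \code{2^dof}.
#' @export
enumerate_configs <- function(ped, limit = 2^20) {
  space <- if (inherits(ped, "phase_space")) ped else {
    viol <- validate_mendelian(ped)
    if (nrow(viol))
      stop("pedigree '", ped$family_id, "': Mendelian violation at SNP ",
           viol$snp[1], ", individual '", viol$individual[1], "'")
    phase_solve_raw(ped)
  }
  if (!space$consistent) return(list())
  if (2^space$dof > limit)
    stop("solution space has 2^", space$dof,
         " configurations, above the materialization limit")
  ib <- match(space$basis, space$free)
  lapply(seq_len(2^space$dof) - 1L, function(code) {
    xfree <- integer(length(space$free))
    if (space$dof)
      xfree[ib] <- as.integer(intToBits(code)[seq_len(space$dof)])
    config_from_assignment(space, full_assignment(space, xfree))
  })
}

#' Draw one configuration uniformly from the solution space
#'
#' When several zero-recombination configurations are consistent with a
#' family's genotypes, the analysis pipeline selects one uniformly at random
#' as the working solution.
#'
#' @param space a \code{phase_space} from \code{\link{phase_solve}}.
#' @param seed optional integer; fixed seed gives a reproducible draw.
#' @return A \code{hap_config}.
#' @export
pick_config <- function(space, seed = NULL) {
  if (!space$consistent)
    stop("pedigree '", space$ped$family_id, "': empty solution space")
  with_seed(seed, {
    xfree <- if (length(space$free))
      sample(0:1, length(space$free), replace = TRUE) else integer(0)
    config_from_assignment(space, full_assignment(space, xfree))
  })
}

#' Founder haplotypes of a configuration
#'
#' Every configuration resolves each member's two haplotypes to one of the
#' \code{2 x n_founders} founder haplotype copies; this extracts those copies
#' with their descent labels.
#'
#' @param config a \code{hap_config}.
#' @return A data frame with one row per founder haplotype copy: \code{family},
#'   \code{founder} (member id), \code{copy} (1 or 2), \code{label}
#'   (\code{family:founder:copy}) and \code{haplotype} (allele string).
#' @export
founder_haplotypes <- function(config) {
  fidx <- which(config$founder)
  s <- hap_strings(config)
  out <- data.frame(
    family = config$family_id,
    founder = rep(config$id[fidx], each = 2),
    copy = rep(1:2, length(fidx)),
    haplotype = as.vector(t(s[fidx, , drop = FALSE])),
    stringsAsFactors = FALSE)
  out$label <- paste(out$family, out$founder, out$copy, sep = ":")
  out[, c("family", "founder", "copy", "label", "haplotype")]
}

# slot id (2*(member-1)+copy) for each founder haplotype copy, aligned with
# founder_haplotypes() row order
founder_slot_ids <- function(config) {
  fidx <- which(config$founder)
  as.vector(t(cbind(2L * (fidx - 1L) + 1L, 2L * (fidx - 1L) + 2L)))
}

#' Carrier multiplicities of founder haplotypes
#'
#' @param config a \code{hap_config}.
#' @return Integer matrix (founder haplotype copies x members); entry (k, j)
#'   is the number of copies (0, 1 or 2) of founder haplotype k that member j
#'   carries by descent.  Columns sum to 2.
#' @export
carrier_multiplicity <- function(config) {
  slots <- founder_slot_ids(config)
  t(vapply(slots, function(s) rowSums(config$origin == s), numeric(length(config$id))))
}
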