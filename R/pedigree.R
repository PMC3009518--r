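#' Construct a pedigree object
#'
#' The central container for one family: identifiers, parental links, sex,
#' phenotype and per-member SNP genotypes.  Binary traits are coded 1/0 for
#' affected/normal; missing phenotypes are \code{NA}.  Genotypes are unordered
#' allele pairs, alleles coded as positive integers (SNPs use 1/2), allele 0
#' meaning missing (accepted here, rejected by the phaser).
#'
#' @param family_id character scalar.
#' @param id character vector of member identifiers (unique within family).
#' @param father,mother character vectors of parental ids; \code{NA} for both
#'   marks a founder.  Partial parenthood (one \code{NA}) is rejected.
#' @param sex integer vector: 1 male, 2 female, 0 unknown.
#' @param phenotype numeric vector; \code{NA} allowed.
#' @param geno integer matrix with one row per member and two columns per SNP
#'   (the two alleles of each unordered genotype).
#' @param check logical; validate structural invariants.
#' @return An object of class \code{fhm_pedigree}.
#' @export
fhm_pedigree <- function(family_id, id, father, mother, sex, phenotype, geno,
                         check = TRUE) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  father[father %in% c("0", "")] <- NA
  mother[mother %in% c("0", "")] <- NA
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ped <- structure(list(
    family_id = as.character(family_id)[1],
    id = id, father = father, mother = mother,
    sex = as.integer(sex), phenotype = as.numeric(phenotype),
    geno = geno
  ), class = "fhm_pedigree")
  if (check) validate_pedigree(ped)
  ped
}

#' @export
print.fhm_pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d members (%d founders), %d SNPs\n",
              x$family_id, n_members(x), sum(is_founder(x)), n_markers(x)))
  invisible(x)
}

#' Number of members / markers of a pedigree
#' @param ped an \code{fhm_pedigree}.
#' @return integer count.
#' @export
n_members <- function(ped) length(ped$id)

#' @rdname n_members
#' @export
n_markers <- function(ped) ncol(ped$geno) %/% 2L

#' Founder indicator
#' @param ped an \code{fhm_pedigree}.
#' @return logical vector, TRUE for members with no parents in the pedigree.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

validate_pedigree <- function(ped) {
  n <- n_members(ped)
  if (n < 1) stop("pedigree '", ped$family_id, "': no members")
  if (anyDuplicated(ped$id))
    stop("pedigree '", ped$family_id, "': duplicated member ids")
  if (ncol(ped$geno) %% 2L != 0L)
    stop("pedigree '", ped$family_id, "': odd genotype column count")
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("pedigree '", ped$family_id, "': member '", ped$id[which(half)[1]],
         "' has exactly one parent; both or neither required")
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad))
      stop("pedigree '", ped$family_id, "': member '", ped$id[which(bad)[1]],
           "' references unknown ", col, " '", ref[which(bad)[1]], "'")
  }
  if (any(!is.na(ped$father) & ped$father == ped$id) ||
      any(!is.na(ped$mother) & ped$mother == ped$id))
    stop("pedigree '", ped$family_id, "': member is its own parent")
  peel_order(ped)  # errors on parental cycles
  invisible(ped)
}

# Topological (parents-before-children) member order; errors on cycles.
peel_order <- function(ped) {
  n <- n_members(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fi) | placed[pmax(fi, 1L)] & !is.na(fi)) &
      (is.na(mi) | placed[pmax(mi, 1L)] & !is.na(mi))
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n)
    stop("pedigree '", ped$family_id, "': cyclic parental references")
  ord
}

#' Detect marriage/inbreeding loops
#'
#' A pedigree is loop-free when its marriage graph (members plus one node per
#' mating, edges spouse-mating and mating-child) is a forest.  Loop-free,
#' complete-genotype pedigrees are the domain of the exact phaser.
#'
#' @param ped an \code{fhm_pedigree}.
#' @return logical scalar.
#' @export
has_loops <- function(ped) {
  kids <- which(!is.na(ped$father))
  if (!length(kids)) return(FALSE)
  mate <- paste(ped$father[kids], ped$mother[kids], sep = "\r")
  mates <- unique(mate)
  # nodes: members + matings; edges: 2 spouse edges per mating + 1 per child
  n_nodes <- n_members(ped) + length(mates)
  edges <- rbind(
    cbind(match(ped$father[kids][match(mates, mate)], ped$id),
          n_members(ped) + seq_along(mates)),
    cbind(match(ped$mother[kids][match(mates, mate)], ped$id),
          n_members(ped) + seq_along(mates)),
    cbind(kids, n_members(ped) + match(mate, mates))
  )
  # forest check per connected component via union-find
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a == b) return(TRUE)
    parent[a] <- b
  }
  FALSE
}

#' Mendelian-consistency check
#'
#' For every non-founder and every SNP, tests whether the child's unordered
#' allele pair can be formed by drawing one allele from each parent.
#' Violations are returned as data, not raised as errors: they are the
#' natural screening output before phasing.  Loci where any of the three
#' genotypes is missing (allele 0) are skipped.
#'
#' @param ped an \code{fhm_pedigree}.
#' @return A data frame with columns \code{family}, \code{individual},
#'   \code{snp} (1-based), one row per violation; zero rows if consistent.
#' @export
validate_mendelian <- function(ped) {
  L <- n_markers(ped)
  out <- list()
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  for (j in which(!is.na(fi))) {
    g <- ped$geno
    for (m in seq_len(L)) {
      c1 <- g[j, 2 * m - 1]; c2 <- g[j, 2 * m]
      f1 <- g[fi[j], 2 * m - 1]; f2 <- g[fi[j], 2 * m]
      m1 <- g[mi[j], 2 * m - 1]; m2 <- g[mi[j], 2 * m]
      if (any(c(c1, c2, f1, f2, m1, m2) == 0L)) next
      ok <- (c1 %in% c(f1, f2) && c2 %in% c(m1, m2)) ||
            (c2 %in% c(f1, f2) && c1 %in% c(m1, m2))
      if (!ok)
        out[[length(out) + 1L]] <-
          data.frame(family = ped$family_id, individual = ped$id[j], snp = m,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family = character(), individual = character(),
                      snp = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
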