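#' Read a LINKAGE-style PED file
#'
#' Whitespace-delimited, pre-makeped dialect: six leading columns (family,
#' individual, father, mother, sex, phenotype) followed by two allele columns
#' per SNP.  Parent id 0 means no parent; allele 0 means missing; lines
#' starting with \code{#} are comments.  The phenotype column holds 1/0 for
#' affected/normal in binary traits, or a quantitative value; the
#' \code{pheno_missing} sentinel becomes \code{NA}.
#'
#' @param path file path.
#' @param pheno_missing phenotype sentinel mapped to \code{NA} (default -9).
#' @return A list of \code{\link{fhm_pedigree}} objects, one per family id,
#'   member order preserved.
#' @export
read_ped <- function(path, pheno_missing = -9) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty PED file: ", path)
  toks <- strsplit(lines, "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < 8) || any(nf != nf[1]) || nf[1] %% 2L != 0L) {
    bad <- which(nf != nf[1] | nf < 8 | nf %% 2L != 0L)[1]
    stop("PED format error at line ", bad, ": expected ", nf[1],
         " whitespace-delimited fields (6 + 2 per SNP), found ", nf[bad])
  }
  tab <- do.call(rbind, toks)
  fam <- tab[, 1]
  peds <- lapply(unique(fam), function(f) {
    rows <- which(fam == f)
    ph <- suppressWarnings(as.numeric(tab[rows, 6]))
    ph[!is.na(ph) & ph == pheno_missing] <- NA
    g <- matrix(suppressWarnings(as.integer(tab[rows, -(1:6), drop = FALSE])),
                nrow = length(rows))
    if (anyNA(g)) stop("PED file '", path, "', family '", f,
                       "': non-integer allele code")
    fhm_pedigree(f, tab[rows, 2], tab[rows, 3], tab[rows, 4],
                 suppressWarnings(as.integer(tab[rows, 5])), ph, g)
  })
  names(peds) <- unique(fam)
  peds
}

#' Write pedigrees to a LINKAGE-style PED file
#'
#' Inverse of \code{\link{read_ped}}; round-trips canonical files byte for
#' byte (single-space delimited, families and members in input order).
#'
#' @param peds list of \code{fhm_pedigree} objects (or a single one).
#' @param path output path.
#' @param pheno_missing sentinel written for \code{NA} phenotypes.
#' @export
write_ped <- function(peds, path, pheno_missing = -9) {
  if (inherits(peds, "fhm_pedigree")) peds <- list(peds)
  lines <- unlist(lapply(peds, function(p) {
    ph <- p$phenotype
    ph_str <- ifelse(is.na(ph), format(pheno_missing),
                     sub("\\.0+$", "", format(ph, trim = TRUE)))
    paste(p$family_id, p$id,
          ifelse(is.na(p$father), "0", p$father),
          ifelse(is.na(p$mother), "0", p$mother),
          p$sex, ph_str,
          apply(p$geno, 1, paste, collapse = " "))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-column marker map
#'
#' Columns: marker name, chromosome label, genetic position (cM), physical
#' position (bp).  Comment lines start with \code{#}.  Positions must be
#' non-decreasing within a chromosome.
#'
#' @param path file path.
#' @return A data frame with columns \code{name}, \code{chr}, \code{cM},
#'   \code{bp}.
#' @export
read_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("name", "chr", "cM", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  for (ch in unique(tab$chr)) {
    p <- tab$cM[tab$chr == ch]
    if (is.unsorted(p)) stop("map '", path, "': genetic positions decrease ",
                             "within chromosome ", ch)
  }
  tab
}

#' @rdname read_map
#' @param map a map data frame as returned by \code{read_map}.
#' @export
write_map <- function(map, path) {
  writeLines(paste(map$name, map$chr, format(map$cM, trim = TRUE),
                   format(map$bp, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Construct / read a population haplotype frequency table
#'
#' A frequency table lists distinct haplotypes (allele strings over L markers,
#' one character per allele) with population frequencies summing to 1.
#' Founder haplotypes in the simulator are drawn i.i.d. from such a table.
#'
#' @param haplotype character vector of equal-length allele strings.
#' @param freq numeric frequencies.
#' @param renormalize if TRUE, rescale frequencies to sum to 1; otherwise a
#'   sum deviating from 1 by more than \code{1e-6} is an error.
#' @return A data frame of class \code{hap_freq_table} with columns
#'   \code{haplotype} and \code{freq}; \code{attr(,"L")} holds marker count.
#' @export
hap_freq_table <- function(haplotype, freq, renormalize = FALSE) {
  haplotype <- as.character(haplotype)
  freq <- as.numeric(freq)
  if (length(haplotype) != length(freq)) stop("haplotype/freq length mismatch")
  if (anyDuplicated(haplotype))
    stop("duplicate haplotype strings in frequency table")
  L <- unique(nchar(haplotype))
  if (length(L) != 1) stop("haplotype strings of unequal length")
  if (any(freq < 0 | freq > 1)) stop("frequencies outside [0, 1]")
  s <- sum(freq)
  if (abs(s - 1) > 1e-6) {
    if (!renormalize)
      stop(sprintf(paste0("frequencies sum to %.8f, not 1; pass ",
                          "renormalize = TRUE to rescale"), s))
    freq <- freq / s
  } else if (s != 1) freq <- freq / s
  structure(data.frame(haplotype = haplotype, freq = freq,
                       stringsAsFactors = FALSE),
            L = L, class = c("hap_freq_table", "data.frame"))
}

#' @rdname hap_freq_table
#' @param path TSV file of haplotype string and frequency (comments with
#'   \code{#}).
#' @export
read_frequency_table <- function(path, renormalize = FALSE) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = c("character", "numeric"),
                           col.names = c("haplotype", "freq"))
  hap_freq_table(tab$haplotype, tab$freq, renormalize = renormalize)
}

#' @rdname hap_freq_table
#' @param table a \code{hap_freq_table}.
#' @export
write_frequency_table <- function(table, path) {
  writeLines(paste(table$haplotype,
                   format(table$freq, trim = TRUE, digits = 12), sep = "\t"),
             path)
  invisible(path)
}

# split a frequency-table string into an integer allele vector
hap_chars <- function(s) as.integer(strsplit(s, "")[[1]])

#' Per-SNP allele frequencies and MAF from a haplotype frequency table
#'
#' @param table a \code{hap_freq_table}.
#' @return A data frame with one row per SNP: \code{snp}, \code{maf} and the
#'   \code{minor} allele code.
#' @export
table_maf <- function(table) {
  mat <- do.call(rbind, lapply(table$haplotype, hap_chars))
  L <- ncol(mat)
  out <- lapply(seq_len(L), function(m) {
    al <- sort(unique(mat[, m]))
    fr <- vapply(al, function(a) sum(table$freq[mat[, m] == a]), 0)
    k <- which.min(fr)
    data.frame(snp = m, maf = if (length(al) == 1) 0 else fr[k],
               minor = al[k])
  })
  do.call(rbind, out)
}
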