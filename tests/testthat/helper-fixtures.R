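# Fixture builders shared across the test files.

make_trio <- function(fg, mg, cg, pheno = c(0, 0, 1), fam = "T") {
  fhm_pedigree(fam, c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
               c(1, 2, 1), pheno, rbind(fg, mg, cg))
}

# an 8-member two-couple family: two founder couples, one child each,
# married with a grandchild sibship of two
make_two_couple_family <- function(geno, fam = "F8", pheno = rep(NA, 8)) {
  fhm_pedigree(fam,
               id     = c("1", "2", "3", "7", "4", "5", "6", "8"),
               father = c(NA, NA, NA, NA, "1", "3", "4", "4"),
               mother = c(NA, NA, NA, NA, "2", "7", "5", "5"),
               sex = c(1, 2, 1, 2, 1, 2, 1, 2), phenotype = pheno,
               geno = geno)
}

# random small pedigree with gene-dropped genotypes from a random frequency
# table; <= 6 members, <= L_max SNPs (uses the caller's RNG stream)
random_dropped_pedigree <- function(L_max = 4) {
  L <- sample(seq_len(L_max), 1)
  n_hap <- sample(2:5, 1)
  haps <- unique(replicate(n_hap, paste(sample(1:2, L, replace = TRUE),
                                        collapse = "")))
  freq <- stats::runif(length(haps))
  tab <- hap_freq_table(haps, freq / sum(freq))
  shape <- sample(1:4, 1)
  sk <- switch(shape,
    fhm_pedigree("R", c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                 c(1, 2, 1), rep(NA, 3), matrix(integer(0), 3, 0)),
    fhm_pedigree("R", c("f", "m", "c1", "c2"), c(NA, NA, "f", "f"),
                 c(NA, NA, "m", "m"), c(1, 2, 1, 2), rep(NA, 4),
                 matrix(integer(0), 4, 0)),
    fhm_pedigree("R", c("gf", "gm", "fa", "mo", "c1"),
                 c(NA, NA, "gf", NA, "fa"), c(NA, NA, "gm", NA, "mo"),
                 c(1, 2, 1, 2, 1), rep(NA, 5), matrix(integer(0), 5, 0)),
    fhm_pedigree("R", c("gf", "gm", "fa", "mo", "c1", "c2"),
                 c(NA, NA, "gf", NA, "fa", "fa"),
                 c(NA, NA, "gm", NA, "mo", "mo"),
                 c(1, 2, 1, 2, 1, 2), rep(NA, 6), matrix(integer(0), 6, 0)))
  drop_genes(sk, tab)
}

config_keys <- function(configs) {
  sort(vapply(configs, function(cf) {
    paste(apply(hap_strings(cf), 1, paste, collapse = "|"), collapse = ";")
  }, ""))
}
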