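# Standard genetic code tables shared across the package. All codons are DNA
# (T, not U); alternative codes are out of scope.

GENETIC_CODE_DNA <- Biostrings::GENETIC_CODE

STOP_CODONS <- sort(names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == "*"])

SENSE_CODONS <- sort(names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"])

# codon -> one-letter amino acid, sense codons only
CODON_AA <- GENETIC_CODE_DNA[SENSE_CODONS]

AA_LETTERS <- sort(unique(unname(CODON_AA)))

# amino acid -> character vector of its synonymous codons (sorted)
AA_FAMILIES <- split(SENSE_CODONS, CODON_AA)

# amino acid -> degeneracy (1, 2, 3, 4 or 6 in the standard code)
AA_DEGENERACY <- vapply(AA_FAMILIES, length, integer(1))

# ENC degeneracy classes (standard code): 9 two-fold, 1 three-fold (Ile),
# 5 four-fold, 3 six-fold (Leu, Ser, Arg); Met and Trp contribute the
# constant 2 in Wright's formula.
ENC_CLASSES <- list(
  `2` = names(AA_DEGENERACY)[AA_DEGENERACY == 2L],
  `3` = names(AA_DEGENERACY)[AA_DEGENERACY == 3L],
  `4` = names(AA_DEGENERACY)[AA_DEGENERACY == 4L],
  `6` = names(AA_DEGENERACY)[AA_DEGENERACY == 6L]
)

.is_gc <- function(base) base == "G" | base == "C"

# per-codon logical: G or C at position i
CODON_GC1 <- .is_gc(substr(SENSE_CODONS, 1L, 1L))
CODON_GC2 <- .is_gc(substr(SENSE_CODONS, 2L, 2L))
CODON_GC3 <- .is_gc(substr(SENSE_CODONS, 3L, 3L))
names(CODON_GC1) <- names(CODON_GC2) <- names(CODON_GC3) <- SENSE_CODONS

# mean GC fraction of the first two codon positions, per amino acid, averaged
# uniformly over the family's codons (used by the simulator's GC12 tilt)
AA_GC12 <- vapply(AA_FAMILIES, function(cods) {
  mean((CODON_GC1[cods] + CODON_GC2[cods]) / 2)
}, numeric(1))
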