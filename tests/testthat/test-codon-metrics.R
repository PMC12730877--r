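test_that("codon counting separates sense and stop codons", {
  cc <- count_codons("ATGTAA")
  expect_equal(cc$n_codons, 1)
  expect_equal(unname(cc$counts["ATG"]), 1)
  expect_equal(unname(cc$stop_counts["TAA"]), 1)

  cc2 <- count_codons("ATGGCTGCTTAA")
  expect_equal(cc2$n_codons, 3)
  expect_equal(unname(cc2$counts[c("ATG", "GCT")]), c(1, 2))

  expect_error(count_codons("ATGGC"), "divisible by 3")
  expect_warning(count_codons("ATGTAAGCTTAA"), "internal stop")
})

test_that("amino-acid composition is a percentage over translated codons", {
  # equal totals per amino acid -> every frequency 5%
  fams <- cubtools:::AA_FAMILIES
  counts <- unlist(lapply(fams, function(f) {
    setNames(rep(60 / length(f), length(f)), f)
  }))
  names(counts) <- sub("^[A-Z]\\.", "", names(counts))
  aa <- aa_composition(codon_counts(counts))
  expect_equal(unname(aa), rep(5, 20), tolerance = 1e-12)
  expect_equal(sum(aa), 100, tolerance = 1e-9)

  expect_equal(unname(aa_composition(codon_counts(c(GCT = 10)))["A"]), 100)
  mix <- aa_composition(codon_counts(c(GCT = 3, AAA = 1)))
  expect_equal(unname(mix[c("A", "K")]), c(75, 25))
  expect_error(aa_composition(codon_counts(c(GCT = 0))), "no sense codons")
})

test_that("RSCU reproduces the defining ratios and flags thresholds", {
  # equal usage in every family -> all RSCU 1
  even <- codon_counts(setNames(rep(4, 61), cubtools:::SENSE_CODONS))
  r <- rscu(even)
  expect_equal(unname(r$values), rep(1, 61))
  expect_true(all(r$flags == "neutral"))

  # two-fold family (3,1) -> (1.5, 0.5)
  r2 <- rscu(codon_counts(c(AAT = 3, AAC = 1)))
  expect_equal(unname(r2$values[c("AAT", "AAC")]), c(1.5, 0.5))
  expect_equal(unname(r2$flags[c("AAT", "AAC")]),
               c("neutral", "underrepresented"))

  # four-fold family fully concentrated -> degeneracy at the used codon
  r4 <- rscu(codon_counts(c(GCT = 4)))
  expect_equal(unname(r4$values[c("GCT", "GCC", "GCA", "GCG")]),
               c(4, 0, 0, 0))
  expect_equal(unname(r4$flags["GCT"]), "overrepresented")

  # zero-count families are undefined, not zero; Met/Trp report 1
  expect_true(is.na(r4$values["TTT"]))
  rM <- rscu(codon_counts(c(ATG = 5)))
  expect_equal(unname(rM$values["ATG"]), 1)
  expect_true(is.na(rM$values["TGG"]))
})

test_that("RSCU family sums equal degeneracy on random inputs", {
  set.seed(42)
  fams <- cubtools:::AA_FAMILIES
  for (i in 1:20) {
    cc <- counts_list_to_obj(random_counts())
    r <- rscu(cc)
    for (aa in names(fams)) {
      fam <- fams[[aa]]
      if (sum(cc$counts[fam]) == 0) {
        expect_true(all(is.na(r$values[fam])))
      } else {
        expect_equal(sum(r$values[fam]), length(fam), tolerance = 1e-9)
      }
    }
  }
})

test_that("positional GC matches hand tallies and excludes the stop", {
  g <- positional_gc("ATGTAA")
  expect_equal(unlist(g), c(gc1 = 0, gc2 = 0, gc3 = 1, gc12 = 0))
  g2 <- positional_gc(paste0("GCG", "TCA"))
  expect_equal(unlist(g2), c(gc1 = 0.5, gc2 = 1, gc3 = 0.5, gc12 = 0.75))
  g3 <- positional_gc("GGGGGGGGG")
  expect_equal(unlist(g3), c(gc1 = 1, gc2 = 1, gc3 = 1, gc12 = 1))
  expect_equal(g2$gc12, (g2$gc1 + g2$gc2) / 2)
})

test_that("codon homozygosity follows Wright's corrected estimator", {
  expect_equal(codon_homozygosity(c(2, 0)), 1)
  expect_equal(codon_homozygosity(c(3, 1)), 0.5)
  expect_true(is.na(codon_homozygosity(c(1, 0))))
  expect_true(is.na(codon_homozygosity(c(0, 0))))
  expect_error(codon_homozygosity(c(-1, 2)), "negative")
})

test_that("ENC hits its theoretical boundaries", {
  # one codon per amino acid -> 20 exactly
  first <- vapply(cubtools:::AA_FAMILIES, `[[`, character(1), 1)
  one_codon <- codon_counts(setNames(rep(100, 20), first))
  expect_identical(enc(one_codon), 20)

  # equal synonymous usage at >= 6000 codons per amino acid -> rounds to 61
  even <- codon_counts(setNames(rep(6000, 61), cubtools:::SENSE_CODONS))
  expect_equal(round(enc(even)), 61)

  # two-fold families at F = 0.5, all other classes at F = 1 -> 29
  counts <- setNames(rep(0, 0), character(0))
  for (aa in names(cubtools:::AA_FAMILIES)) {
    fam <- cubtools:::AA_FAMILIES[[aa]]
    k <- length(fam)
    counts <- c(counts, if (k == 2) setNames(c(3, 1), fam)
                else setNames(c(10, rep(0, k - 1)), fam))
  }
  expect_equal(enc(codon_counts(counts)), 29)
})

test_that("ENC is permutation-invariant within families and monotone in bias", {
  base <- counts_list_to_obj(random_counts())
  permuted <- base
  fam <- cubtools:::AA_FAMILIES[["A"]]
  permuted$counts[fam] <- permuted$counts[rev(fam)]
  permuted <- codon_counts(c(permuted$counts, permuted$stop_counts))
  expect_equal(enc(base), enc(permuted))

  # concentrate a 2-fold family stepwise: ENC must strictly decrease
  # (large counts keep the estimate off the 61 cap once bias appears)
  make <- function(split) {
    counts <- setNames(rep(1000, 61), cubtools:::SENSE_CODONS)
    counts[c("AAT", "AAC")] <- split
    codon_counts(counts)
  }
  encs <- vapply(list(c(1000, 1000), c(1400, 600), c(1800, 200), c(2000, 0)),
                 function(s) enc(make(s)), numeric(1))
  expect_true(all(diff(encs) < 0))
})

test_that("uniform random codon usage drives ENC to 61 and RSCU to 1", {
  set.seed(7)
  cods <- sample(cubtools:::SENSE_CODONS, 60000, replace = TRUE)
  cc <- count_codons(paste(c(cods, "TAA"), collapse = ""))
  expect_gt(enc(cc), 60.5)
  r <- rscu(cc)
  expect_lt(max(abs(r$values - 1)), 0.15)
})

test_that("genome profile pools counts rather than averaging genes", {
  g1 <- make_cds(rep("GCT", 40))
  g2 <- make_cds(rep("GCC", 40))
  genes <- data.frame(gene_id = c("a", "b"), genome_id = "gx",
                      sequence = c(g1, g2), source = "cds_fasta",
                      stringsAsFactors = FALSE)
  prof <- genome_profile(genes)
  # pooled Ala counts (40, 40, 0, 0) -> RSCU 2, 2, 0, 0
  expect_equal(unname(prof$rscu$values[c("GCT", "GCC", "GCA", "GCG")]),
               c(2, 2, 0, 0))
  # single gene equals per-gene metrics; duplication leaves profile unchanged
  one <- genome_profile(genes[1, ])
  dup <- genome_profile(rbind(genes[1, ], genes[1, ]))
  expect_equal(one$gc, dup$gc)
  expect_equal(one$enc, dup$enc)
  expect_equal(one$gc$gc3, positional_gc(g1)$gc3)
  expect_error(genome_profile(genes[0, ]), "empty")
})

test_that("pooled genome ENC matches per-gene ENC for a shared distribution", {
  set.seed(3)
  seqs <- replicate(5, paste(
    c(sample(cubtools:::SENSE_CODONS, 4000, replace = TRUE), "TAA"),
    collapse = ""))
  genes <- data.frame(gene_id = paste0("g", 1:5), genome_id = "gx",
                      sequence = seqs, source = "cds_fasta",
                      stringsAsFactors = FALSE)
  prof <- genome_profile(genes)
  per_gene <- gene_metrics(genes)$enc
  expect_equal(prof$enc, mean(per_gene), tolerance = 0.01)
})
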