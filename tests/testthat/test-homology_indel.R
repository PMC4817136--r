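test_that("Karlin-Altschul bit score and E-value follow the closed form", {
  bit <- karlin_bit_score(1000)
  expect_equal(bit, (1.28 * 1000 - log(0.46)) / log(2), tolerance = 1e-12)
  expect_gt(bit, 500)  # a perfect 1 kb match passes the genome-scale gate
  expect_equal(karlin_evalue(bit, 1000, 4e8), 1000 * 4e8 * 2^(-bit))
  # a perfect match needs a raw score of ~270 before it can reach bit 500
  expect_lt(karlin_bit_score(260), 500)
  expect_gt(karlin_bit_score(280), 500)
})

test_that("k-mer index stores L-k+1 positions, skips N and is self-consistent", {
  set.seed(41)
  s <- random_dna(1000)
  idx <- build_query_index(c(c1 = s), k = 13)
  n_pos <- sum(lengths(as.list(idx$env)))
  expect_equal(n_pos, 1000 - 13 + 1)
  # every stored position reproduces its k-mer
  kmers <- ls(idx$env)
  for (km in sample(kmers, 50)) {
    for (p in idx$env[[km]]) expect_identical(substr(s, p + 1, p + 13), km)
  }
  sN <- paste0(substr(s, 1, 100), "N", substr(s, 102, 1000))
  idxN <- build_query_index(c(c1 = sN), k = 13)
  expect_equal(sum(lengths(as.list(idxN$env))), (1000 - 13 + 1) - 13)
  expect_error(build_query_index(c(c1 = s), k = 7), "k must be")
})

test_that("identical sequences yield no indel calls", {
  set.seed(43)
  s <- random_dna(200)
  res <- align_and_call_indels(s, s)
  expect_equal(nrow(res$indels), 0L)
  expect_equal(res$alignment$score, 200)
})

test_that("a single deletion is called at its left-normalized position", {
  res <- align_and_call_indels("ACGTACGT", "ACGACGT")
  expect_equal(nrow(res$indels), 1L)
  expect_identical(res$indels$kind, "deletion")
  expect_equal(res$indels$length, 1L)
  expect_equal(res$indels$ref_pos, 3L)
  expect_identical(res$indels$allele_ref, "T")

  # deletion inside a homopolymer shifts to the leftmost equivalent position
  hom <- align_and_call_indels("CCAAAAGG", "CCAAAGG")
  expect_equal(hom$indels$ref_pos, 2L)
  expect_identical(hom$indels$allele_ref, "A")

  # insertion inside a homopolymer likewise
  ins <- align_and_call_indels("CCAAAGG", "CCAAAAGG")
  expect_identical(ins$indels$kind, "insertion")
  expect_equal(ins$indels$ref_pos, 2L)
  expect_identical(ins$indels$allele_query, "A")
})

test_that("signed indel lengths conserve the length difference and reconstruct the query", {
  set.seed(47)
  for (i in 1:120) {
    ref <- random_dna(sample(40:200, 1))
    query <- ref
    deletions_only <- i %% 2 == 0
    if (deletions_only) {
      # plan well-separated deletion segments on the reference; with a
      # 1-base anchor between gaps the affine model rightly prefers one
      # merged gap plus a substitution, so keep anchors >= 3 bases
      slots <- seq(5, nchar(ref) - 20, by = 18)
      n_del <- min(sample(1:3, 1), length(slots))
      pos <- sort(slots[sample.int(length(slots), n_del)])
      lens <- sample(1:12, n_del, replace = TRUE)
      for (v in rev(seq_len(n_del)))
        query <- paste0(substr(query, 1, pos[v]),
                        substr(query, pos[v] + lens[v] + 1, nchar(query)))
    } else {
      for (v in seq_len(sample(1:3, 1))) {
        L <- sample(1:12, 1)
        if (runif(1) < 0.5 && nchar(query) > L + 10) {
          p <- sample(5:(nchar(query) - L - 5), 1)
          query <- paste0(substr(query, 1, p), substr(query, p + L + 1, nchar(query)))
        } else {
          p <- sample(5:(nchar(query) - 5), 1)
          query <- paste0(substr(query, 1, p), random_dna(L),
                          substr(query, p + 1, nchar(query)))
        }
      }
    }
    calls <- align_and_call_indels(ref, query)$indels
    signed <- sum(ifelse(calls$kind == "insertion", calls$length, -calls$length))
    expect_equal(signed, nchar(query) - nchar(ref))
    rebuilt <- apply_indels(ref, calls)
    expect_equal(nchar(rebuilt), nchar(query))
    if (deletions_only) {
      # with deletions only, every optimal alignment column is a match, so
      # the calls reconstruct the query byte-identically; random inserted
      # bases admit equal-scoring alternative placements, so mixed cases are
      # checked by length and signed sum above
      expect_identical(rebuilt, query)
    }
    if (nrow(calls) > 1) {
      ends <- calls$ref_pos + ifelse(calls$kind == "deletion", calls$length, 0L)
      expect_true(all(calls$ref_pos[-1] >= ends[-nrow(calls)]))  # non-overlapping
    }
  }
})

test_that("the enumeration oracle and the DP agree (oracle validated by full enumeration)", {
  set.seed(53)
  # validate the memoized oracle itself against brute-force enumeration
  for (i in 1:6) {
    a <- random_dna(sample(2:5, 1)); b <- random_dna(sample(2:5, 1))
    expect_equal(oracle_align_score(a, b), oracle_align_enumerate(a, b))
  }
  # then the production DP against the oracle on short pairs
  for (i in 1:60) {
    a <- random_dna(sample(1:12, 1)); b <- random_dna(sample(1:12, 1))
    expect_equal(align_global(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("homology mapping recovers the exact simulated homolog and gates correctly", {
  sim <- simulate_genome_pair(sim_config(n_chromosomes = 1, n_genes = 8,
                                         intron_len = c(60, 500),
                                         intron_snp_rate = 0, seed = 59))
  idx <- build_query_index(sim$query, 13)
  introns <- extract_all_introns(sim$models, sim$ref)
  truth <- sim$truth_introns
  n_checked <- 0
  for (i in seq_len(nrow(introns))) {
    mt <- map_intron_to_query(introns$sequence[i], idx, min_bit = 50, max_evalue = 1e-6)
    expect_false(is.null(mt), info = paste("intron", i))
    tw <- truth[truth$gene_id == introns$gene_id[i] &
                truth$intron_ordinal == introns$ordinal[i], ]
    expect_identical(mt$query_seq, tw$query_seq, info = paste("intron", i))
    expect_false(mt$ambiguous)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
  # a random sequence absent from the query maps nowhere
  set.seed(61)
  expect_null(map_intron_to_query(random_dna(300), idx, min_bit = 50, max_evalue = 1e-6))
  # the production bit gate rejects a short perfect match
  short <- introns$sequence[which.min(introns$intron_len)]
  if (nchar(short) < 300)
    expect_null(map_intron_to_query(short, idx, min_bit = 500, max_evalue = 1e-50))
})

# hand-built one-gene genomes with planted variants of chosen sizes
plant_pair <- function(ops, intron_len = 300, seed = 67) {
  set.seed(seed)
  exL <- random_dna(150); exR <- random_dna(150)
  intron <- random_dna(intron_len)
  q_intron <- intron
  for (op in rev(ops)) {  # apply right-to-left
    if (op$kind == "del") {
      q_intron <- paste0(substr(q_intron, 1, op$pos),
                         substr(q_intron, op$pos + op$len + 1, nchar(q_intron)))
    } else {
      q_intron <- paste0(substr(q_intron, 1, op$pos), random_dna(op$len),
                         substr(q_intron, op$pos + 1, nchar(q_intron)))
    }
  }
  sp1 <- random_dna(300); sp2 <- random_dna(300)
  list(ref = c(chr = paste0(sp1, exL, intron, exR, sp2)),
       query = c(chr = paste0(sp1, exL, q_intron, exR, sp2)),
       models = list(G1 = gene_model("G1", "chr", "+",
                                     rbind(c(300L, 450L),
                                           c(450L + intron_len, 600L + intron_len)))))
}

test_that("ILP conversion reports net and gross FLP and the assay tier", {
  cn <- design_constraints(genomic_product = c(100, 3000))
  run <- function(pp) run_marker_pipeline(pp$ref, pp$models, pp$query,
                                          constraints = cn, per_gene = Inf,
                                          min_bit = 50, max_evalue = 1e-3)
  # +5 insertion and -2 deletion in one intron: net 3, gross 7, sequencing tier
  res <- run(plant_pair(list(list(kind = "ins", pos = 60, len = 5),
                             list(kind = "del", pos = 200, len = 2))))
  expect_equal(nrow(res$ilp), 1L)
  expect_equal(res$ilp$flp_net, 3L)
  expect_equal(res$ilp$flp_gross, 7L)
  expect_identical(res$ilp$assay_tier, "sequencing")
  expect_equal(res$ilp$n_indels, 2L)
  expect_match(res$ilp$marker_id, "^OsILP\\d{5}$")

  # single 3-base deletion: net = gross = 3
  res3 <- run(plant_pair(list(list(kind = "del", pos = 100, len = 3)), seed = 71))
  expect_equal(res3$ilp$flp_net, 3L)
  expect_equal(res3$ilp$flp_gross, 3L)

  # 12-base insertion crosses the 10 bp gel threshold
  res12 <- run(plant_pair(list(list(kind = "ins", pos = 100, len = 12)), seed = 73))
  expect_equal(res12$ilp$flp_net, 12L)
  expect_identical(res12$ilp$assay_tier, "gel")

  # balanced +4/-4 InDels cancel: no gel-detectable ILP, reported separately
  resb <- run(plant_pair(list(list(kind = "ins", pos = 60, len = 4),
                              list(kind = "del", pos = 200, len = 4)), seed = 79))
  expect_equal(nrow(resb$ilp), 0L)
  expect_equal(nrow(resb$balanced), 1L)
  expect_equal(resb$balanced$flp_gross, 8L)

  # no variation at all: conversion refused with reason no_indel
  res0 <- run(plant_pair(list(), seed = 83))
  expect_equal(nrow(res0$ilp), 0L)
  expect_identical(res0$log$reason, "no_indel")
})

test_that("a gene duplicated verbatim fails the uniqueness screen", {
  pp <- plant_pair(list(list(kind = "del", pos = 100, len = 3)), seed = 89)
  dup_ref <- c(chr = paste0(pp$ref[["chr"]], substr(pp$ref[["chr"]], 301, 900),
                            random_dna(200)))
  ism <- design_genome_ism(dup_ref, pp$models,
                           design_constraints(genomic_product = c(100, 3000)),
                           per_gene = Inf)
  expect_equal(nrow(ism), 0L)
  expect_gt(nrow(attr(ism, "dropped")), 0L)
  expect_identical(unique(attr(ism, "dropped")$uniqueness), "multi")
})
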