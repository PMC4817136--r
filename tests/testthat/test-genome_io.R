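test_that("FASTA reading folds case, maps U to T and validates residues", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", "ACGT"), f)
  g <- read_fasta(f)
  expect_identical(g, c(chr1 = "ACGTACGT"))
})

test_that("FASTA reader maps U and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "ACGUacgu"), f)
  expect_identical(unname(read_fasta(f)), "ACGTACGT")

  writeLines(c(">x", "ACGR"), f)
  expect_error(read_fasta(f), "illegal residue")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_warning(g <- read_fasta(f), "no records")
  expect_length(g, 0L)

  expect_error(read_fasta(file.path(tempdir(), "no_such.fa")), "not found")
})

test_that("write/read FASTA round trip reproduces a simulated genome exactly", {
  sim <- simulate_genome_pair(sim_config(n_chromosomes = 2, n_genes = 4,
                                         intron_len = c(60, 300), seed = 11))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$ref, f)
  expect_identical(read_fasta(f), sim$ref)
})

test_that("GFF3 coordinates convert to 0-based half-open and attributes are honored", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=g1.1.e1;Parent=g1.1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=g1.1.e2;Parent=g1.1",
    "chr1\tsrc\tgene\t401\t500\t.\t-\t.\tID=g2;Note=retrotransposon protein",
    "chr1\tsrc\tmRNA\t401\t500\t.\t-\t.\tID=g2.1;Parent=g2",
    "chr1\tsrc\texon\t401\t500\t.\t-\t.\tID=g2.1.e1;Parent=g2.1"), f)
  genome <- c(chr1 = strrep("A", 600))
  models <- parse_gene_models(f, genome)
  expect_named(models, c("g1", "g2"))
  expect_equal(unname(models$g1$exons), rbind(c(0L, 100L), c(200L, 300L)))
  expect_identical(models$g1$te_class, "non-TE")
  expect_identical(models$g2$te_class, "TE")
  expect_equal(nrow(models$g2$exons), 1L)
  expect_identical(nrow(extract_introns(models$g2, genome)), 0L)
})

test_that("longest-CDS transcript is selected when a gene has several isoforms", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=g1.long;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=g1.long;ID=e1",
    "chr1\tsrc\texon\t201\t500\t.\t+\t.\tParent=g1.long;ID=e2",
    "chr1\tsrc\tCDS\t1\t100\t.\t+\t0\tParent=g1.long;ID=c1",
    "chr1\tsrc\tCDS\t201\t500\t.\t+\t0\tParent=g1.long;ID=c2",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.short;Parent=g1",
    "chr1\tsrc\texon\t1\t300\t.\t+\t.\tParent=g1.short;ID=e3",
    "chr1\tsrc\tCDS\t1\t90\t.\t+\t0\tParent=g1.short;ID=c3"), f)
  genome <- c(chr1 = strrep("C", 600))
  models <- parse_gene_models(f, genome)
  expect_equal(nrow(models$g1$exons), 2L)  # the two-exon long-CDS isoform won
})

test_that("genes on unknown or out-of-bounds sequences are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrX\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chrX\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.1;Parent=g1",
    "chrX\tsrc\texon\t1\t100\t.\t+\t.\tParent=g1.1;ID=e1",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g2",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g2.1;Parent=g2",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=g2.1;ID=e2"), f)
  genome <- c(chr1 = strrep("A", 50))  # g2 exceeds bounds, chrX unknown
  expect_warning(expect_warning(models <- parse_gene_models(f, genome),
                                "unknown sequence"), "exceeds bounds")
  expect_length(models, 0L)
})

test_that("simulator-emitted GFF3 parses back to the simulator's truth models", {
  sim <- simulate_genome_pair(sim_config(n_chromosomes = 2, n_genes = 8,
                                         intron_len = c(60, 400), seed = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  genome <- read_fasta(file.path(dir, "ref.fa"))
  models <- parse_gene_models(file.path(dir, "ref.gff3"), genome)
  expect_setequal(names(models), names(sim$models))
  for (gid in names(models)) {
    expect_equal(unname(models[[gid]]$exons), unname(sim$models[[gid]]$exons), info = gid)
    expect_identical(models[[gid]]$strand, sim$models[[gid]]$strand, info = gid)
    expect_identical(models[[gid]]$te_class, sim$models[[gid]]$te_class, info = gid)
  }
})

test_that("intron extraction reconstructs the gene and respects strand", {
  set.seed(5)
  chrom <- random_dna(1200)
  genome <- c(chr = chrom)
  for (strand in c("+", "-")) {
    g <- gene_model("g", "chr", strand,
                    rbind(c(100L, 300L), c(500L, 650L), c(900L, 1100L)))
    introns <- extract_introns(g, genome)
    expect_equal(nrow(introns), 2L)
    expect_equal(introns$ordinal, c(1L, 2L))
    # reconstruction: exons + introns in genome order tile the gene span
    slices <- substring(chrom, c(101, 301, 501, 651, 901), c(300, 500, 650, 900, 1100))
    gi <- introns[order(introns$start), ]
    got <- if (strand == "+") gi$sequence else reverse_complement(gi$sequence)
    expect_identical(got, slices[c(2, 4)])
    # flank windows cap at 100 and at the adjacent exon length
    expect_equal(nchar(introns$left_flank), c(100L, 100L))
    expect_equal(nchar(gi$right_flank), if (strand == "+") c(100L, 100L) else c(100L, 100L))
    # sum of exon and intron lengths equals the gene span
    span <- unname(g$exons[nrow(g$exons), 2L] - g$exons[1L, 1L])
    expect_equal(sum(g$exons[, 2L] - g$exons[, 1L]) + sum(introns$intron_len), span)
  }
})

test_that("minus-strand introns equal the plus-strand introns of the mirrored chromosome", {
  set.seed(9)
  chrom <- random_dna(800)
  L <- 800L
  exons <- rbind(c(50L, 250L), c(330L, 520L), c(600L, 760L))
  g_minus <- gene_model("g", "chr", "-", exons)
  mirrored <- cbind(L - exons[, 2L], L - exons[, 1L])
  g_plus <- gene_model("g", "chr", "+", mirrored)
  i1 <- extract_introns(g_minus, c(chr = chrom))
  i2 <- extract_introns(g_plus, c(chr = reverse_complement(chrom)))
  expect_identical(i1$sequence, i2$sequence)
  expect_identical(i1$left_flank, i2$left_flank)
  expect_identical(i1$right_flank, i2$right_flank)
})

test_that("single-exon genes and zero-length exon gaps are handled", {
  genome <- c(chr = strrep("ACGT", 100))
  g1 <- gene_model("g1", "chr", "+", rbind(c(0L, 100L)))
  expect_equal(nrow(extract_introns(g1, genome)), 0L)
  g2 <- gene_model("g2", "chr", "+", rbind(c(0L, 100L), c(100L, 200L), c(260L, 380L)))
  expect_warning(introns <- extract_introns(g2, genome), "zero-length")
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$start, 200L)
})
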