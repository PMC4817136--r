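#' Simulation configuration
#'
#' Parameters of the reference/query genome-pair simulator. The defaults
#' emulate the structure of a rice-like gene space at a desk scale: 2-8
#' exons per gene, 80-400 bp exons, 60-2000 bp introns, intronic InDels of
#' 1-101 bp with a small-indel-dominated (truncated geometric) length
#' distribution averaging ~4.8 bp, conserved exons, and random intergenic
#' spacers that keep primer binding sites unique.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Total genes (distributed round-robin over chromosomes).
#' @param exon_len,intron_len,exons_per_gene,spacer_len `c(min, max)` of the
#'   uniform length distributions (bases; exons_per_gene is a count).
#' @param intron_snp_rate Per-base substitution probability in query introns.
#' @param intron_indel_rate Expected planted InDels per intron (Poisson).
#' @param indel_len_p Success probability of the geometric InDel-length
#'   distribution (`mean = 1/p`; 0.21 gives a ~4.8 bp mean).
#' @param indel_len_max Truncation bound of InDel lengths, bases.
#' @param exon_mutation_rate Per-base substitution probability in query exons
#'   (0 = conserved flanks).
#' @param fraction_te_genes Fraction of genes annotated as transposon-
#'   associated.
#' @param duplication_rate Per-gene probability of planting an exact extra
#'   copy of the gene (exercises the primer-uniqueness filter).
#' @param seed RNG seed; all simulator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, n_genes = 50L,
                       exon_len = c(80L, 400L), intron_len = c(60L, 2000L),
                       exons_per_gene = c(2L, 8L),
                       intron_snp_rate = 0.005, intron_indel_rate = 0.4,
                       indel_len_p = 0.21, indel_len_max = 101L,
                       exon_mutation_rate = 0,
                       fraction_te_genes = 0.3, duplication_rate = 0,
                       spacer_len = c(200L, 1000L), seed = 42L) {
  stopifnot(n_chromosomes >= 1L, n_genes >= 1L,
            exon_len[1] >= 1L, exon_len[1] <= exon_len[2],
            intron_len[1] >= 1L, intron_len[1] <= intron_len[2],
            exons_per_gene[1] >= 1L, exons_per_gene[1] <= exons_per_gene[2],
            intron_snp_rate >= 0, intron_snp_rate <= 1,
            intron_indel_rate >= 0, indel_len_p > 0, indel_len_p <= 1,
            exon_mutation_rate >= 0, exon_mutation_rate <= 1,
            fraction_te_genes >= 0, fraction_te_genes <= 1,
            duplication_rate >= 0, duplication_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

.mutate_snps <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

.draw_indel_len <- function(p, lmax) {
  repeat {
    L <- stats::rgeom(1L, p) + 1L
    if (L <= lmax) return(L)
  }
}

#' Simulate a reference/query genome pair with planted intronic variation
#'
#' Builds a reference genome of non-overlapping gene models separated by
#' random intergenic spacers, then derives a query genome by planting
#' substitutions and InDels inside introns (and, if configured, exons).
#' Planted InDels keep an anchor of at least their own length plus 10 bases
#' to either intron end (so each variant is identifiable as the optimal-
#' alignment explanation) and are mutually well-separated. Everything is
#' deterministic given the seed; the truth tables are machine-readable.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_pair`: `ref`, `query` (named character
#'   genomes), `models` (list of [gene_model]), `truth_indels` (per planted
#'   variant: `gene_id`, `intron_ordinal`, `kind`, `length`, `ref_pos`),
#'   `truth_introns` (per intron: reference/query lengths, net and gross
#'   planted size), `truth_genes` (gene spans in both genomes), `cfg`.
#' @export
simulate_genome_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_ids <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  ref_parts <- stats::setNames(rep(list(character(0)), cfg$n_chromosomes), chrom_ids)
  qry_parts <- ref_parts
  ref_off <- stats::setNames(rep(0L, cfg$n_chromosomes), chrom_ids)
  qry_off <- ref_off
  models <- list()
  truth_indels <- list(); truth_introns <- list(); truth_genes <- list()
  dup_queue <- stats::setNames(rep(list(character(0)), cfg$n_chromosomes), chrom_ids)

  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("SIMG%04d", g)
    ci <- ((g - 1L) %% cfg$n_chromosomes) + 1L
    sid <- chrom_ids[ci]
    strand <- sample(c("+", "-"), 1L)
    te <- if (stats::runif(1) < cfg$fraction_te_genes) "TE" else "non-TE"
    n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
    ex_len <- sample(cfg$exon_len[1]:cfg$exon_len[2], n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L)
      sample(cfg$intron_len[1]:cfg$intron_len[2], n_ex - 1L, replace = TRUE) else integer(0)
    exons_seq <- vapply(ex_len, .rand_dna, character(1))
    introns_seq <- vapply(in_len, .rand_dna, character(1))

    # query versions
    q_exons <- if (cfg$exon_mutation_rate > 0)
      vapply(exons_seq, .mutate_snps, character(1), rate = cfg$exon_mutation_rate,
             USE.NAMES = FALSE) else exons_seq
    q_introns <- character(length(introns_seq))
    for (ii in seq_along(introns_seq)) {
      iseq <- .mutate_snps(introns_seq[ii], cfg$intron_snp_rate)
      ilen <- nchar(iseq)
      n_ind <- stats::rpois(1L, cfg$intron_indel_rate)
      placed <- list()
      if (n_ind > 0L && ilen > 12L) {
        occupied <- integer(0)
        for (v in seq_len(n_ind)) {
          L <- .draw_indel_len(cfg$indel_len_p, cfg$indel_len_max)
          kind <- sample(c("insertion", "deletion"), 1L)
          span <- if (kind == "deletion") L else 0L
          # anchor margin scales with indel size: a gap of length L near a
          # sequence end is only the optimal-alignment explanation when the
          # flanking anchor outweighs the affine gap cost
          margin <- L + 10L
          lo <- margin; hi <- ilen - margin - span
          if (hi < lo) next
          ok <- FALSE
          for (try in 1:20) {
            p <- sample(lo:hi, 1L)
            if (!any(abs(p - occupied) <= (cfg$indel_len_max + 2L))) { ok <- TRUE; break }
          }
          if (!ok) next
          occupied <- c(occupied, p)
          placed[[length(placed) + 1L]] <- list(pos = p, kind = kind, length = L)
        }
      }
      gross <- 0L; net <- 0L
      if (length(placed)) {
        ord <- order(-vapply(placed, `[[`, integer(1), "pos"))
        qseq <- iseq
        for (v in placed[ord]) {   # apply right-to-left
          if (v$kind == "deletion") {
            qseq <- paste0(substr(qseq, 1L, v$pos), substr(qseq, v$pos + v$length + 1L, nchar(qseq)))
          } else {
            ins <- .rand_dna(v$length)
            qseq <- paste0(substr(qseq, 1L, v$pos), ins, substr(qseq, v$pos + 1L, nchar(qseq)))
          }
        }
        for (v in placed) {
          truth_indels[[length(truth_indels) + 1L]] <- data.frame(
            gene_id = gid, intron_ordinal = NA_integer_, intron_index = ii,
            kind = v$kind, length = v$length, ref_pos = v$pos,
            stringsAsFactors = FALSE)
          gross <- gross + v$length
          net <- net + if (v$kind == "insertion") v$length else -v$length
        }
        q_introns[ii] <- qseq
      } else {
        q_introns[ii] <- iseq
      }
      truth_introns[[length(truth_introns) + 1L]] <- data.frame(
        gene_id = gid, intron_index = ii, ref_len = ilen,
        query_len = nchar(q_introns[ii]), net = net, gross = gross,
        n_indels = length(placed), query_seq = q_introns[ii],
        stringsAsFactors = FALSE)
    }

    weave <- function(ex, intr) {
      out <- character(0)
      for (i in seq_along(ex)) {
        out <- c(out, ex[i])
        if (i <= length(intr)) out <- c(out, intr[i])
      }
      paste(out, collapse = "")
    }
    ref_gene <- weave(exons_seq, introns_seq)
    qry_gene <- weave(q_exons, q_introns)

    spacer <- .rand_dna(sample(cfg$spacer_len[1]:cfg$spacer_len[2], 1L))
    ref_parts[[sid]] <- c(ref_parts[[sid]], spacer, if (strand == "+") ref_gene else .revcomp(ref_gene))
    qry_parts[[sid]] <- c(qry_parts[[sid]], spacer, if (strand == "+") qry_gene else .revcomp(qry_gene))
    gstart_ref <- ref_off[ci] + nchar(spacer)
    gstart_qry <- qry_off[ci] + nchar(spacer)
    G <- nchar(ref_gene)
    ref_off[ci] <- gstart_ref + G
    qry_off[ci] <- gstart_qry + nchar(qry_gene)

    # coding-offset exon blocks -> chromosome coordinates
    cs <- cumsum(c(0L, utils::head(as.integer(ex_len + c(in_len, 0L)), -1L)))
    coding_ex <- cbind(cs, cs + ex_len)   # [start, end) within the coding string
    if (strand == "+") {
      exm <- coding_ex + gstart_ref
    } else {
      exm <- cbind(gstart_ref + G - coding_ex[, 2L], gstart_ref + G - coding_ex[, 1L])
      exm <- exm[order(exm[, 1L]), , drop = FALSE]
    }
    models[[gid]] <- gene_model(gid, sid, strand, exm, te_class = te)

    # intron ordinal (transcription order) == intron_index by construction
    truth_genes[[length(truth_genes) + 1L]] <- data.frame(
      gene_id = gid, seq_id = sid, strand = strand, te_class = te,
      ref_start = gstart_ref, ref_end = gstart_ref + G,
      query_start = gstart_qry, query_end = gstart_qry + nchar(qry_gene),
      stringsAsFactors = FALSE)

    if (cfg$duplication_rate > 0 && stats::runif(1) < cfg$duplication_rate)
      dup_queue[[sid]] <- c(dup_queue[[sid]], ref_gene)
  }

  for (ci in seq_len(cfg$n_chromosomes)) {
    sid <- chrom_ids[ci]
    for (dup in dup_queue[[sid]]) {
      spacer <- .rand_dna(sample(cfg$spacer_len[1]:cfg$spacer_len[2], 1L))
      ref_parts[[sid]] <- c(ref_parts[[sid]], spacer, dup)
      qry_parts[[sid]] <- c(qry_parts[[sid]], spacer, dup)
    }
    tail_sp <- .rand_dna(sample(cfg$spacer_len[1]:cfg$spacer_len[2], 1L))
    ref_parts[[sid]] <- c(ref_parts[[sid]], tail_sp)
    qry_parts[[sid]] <- c(qry_parts[[sid]], tail_sp)
  }

  ti <- if (length(truth_indels)) do.call(rbind, truth_indels) else
    data.frame(gene_id = character(0), intron_ordinal = integer(0),
               intron_index = integer(0), kind = character(0),
               length = integer(0), ref_pos = integer(0), stringsAsFactors = FALSE)
  ti$intron_ordinal <- ti$intron_index
  tin <- if (length(truth_introns)) do.call(rbind, truth_introns) else
    data.frame(gene_id = character(0), intron_index = integer(0), ref_len = integer(0),
               query_len = integer(0), net = integer(0), gross = integer(0),
               n_indels = integer(0), query_seq = character(0), stringsAsFactors = FALSE)
  tin$intron_ordinal <- tin$intron_index
  structure(list(
    ref = vapply(ref_parts, paste, character(1), collapse = ""),
    query = vapply(qry_parts, paste, character(1), collapse = ""),
    models = models,
    truth_indels = ti,
    truth_introns = tin,
    truth_genes = do.call(rbind, truth_genes),
    cfg = cfg), class = "sim_pair")
}

#' Write a simulated genome pair to disk
#'
#' Emits `ref.fa`, `ref.gff3`, `query.fa`, `truth_indels.tsv`,
#' `truth_genes.tsv` under `dir`.
#'
#' @param sim A `sim_pair` from [simulate_genome_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$ref, file.path(dir, "ref.fa"))
  write_fasta(sim$query, file.path(dir, "query.fa"))
  write_gff3(sim$models, file.path(dir, "ref.gff3"))
  utils::write.table(sim$truth_indels, file.path(dir, "truth_indels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' One gene/mRNA/exon feature hierarchy per model, 1-based inclusive
#' coordinates; transposon-associated genes carry `Note=transposon`.
#'
#' @param models Named list of [gene_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in models) {
    ex <- gm$exons
    gstart <- ex[1L, 1L] + 1L
    gend <- ex[nrow(ex), 2L]
    note <- if (gm$te_class == "TE") ";Note=transposon" else ""
    mid <- paste0(gm$gene_id, ".1")
    writeLines(sprintf("%s\tismilp\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       gm$seq_id, gstart, gend, gm$strand, gm$gene_id, note), con)
    writeLines(sprintf("%s\tismilp\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       gm$seq_id, gstart, gend, gm$strand, mid, gm$gene_id), con)
    for (i in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tismilp\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                         gm$seq_id, ex[i, 1L] + 1L, ex[i, 2L], gm$strand, mid, i, mid), con)
  }
  invisible(path)
}

#' Simulate a group-structured genotype panel
#'
#' Markers are multi-allelic with ancestral allele frequencies drawn from a
#' symmetric Dirichlet. With probability `between_divergence` a group
#' replaces the ancestral frequencies at a marker by near-fixed private ones
#' (a randomly chosen allele at frequency 0.95), emulating
#' lineage-differentiating markers; each accession then jitters its group
#' frequencies by `within_divergence`. Genotypes are two independent allele
#' draws per cell; missingness is per-cell uniform.
#'
#' @param n_markers Number of markers.
#' @param group_sizes Named integer vector of accessions per group; the
#'   default mirrors a 26-accession panel (9 indica, 2 japonica, 10
#'   long-grain aromatic, 3 short-grain aromatic, 2 wild).
#' @param n_alleles `c(min, max)` alleles per marker.
#' @param between_divergence,within_divergence Frequency-perturbation
#'   weights in `[0, 1]`.
#' @param missing_rate Per-cell missing probability.
#' @param seed RNG seed.
#' @return A [genotype_matrix()] with `groups` set to the truth labels.
#' @export
simulate_genotypes <- function(n_markers = 200L,
                               group_sizes = c(indica = 9L, japonica = 2L,
                                               aromatic_long = 10L,
                                               aromatic_short = 3L, wild = 2L),
                               n_alleles = c(2L, 4L),
                               between_divergence = 0.3,
                               within_divergence = 0.05,
                               missing_rate = 0, seed = 1L) {
  stopifnot(n_markers >= 1L, all(group_sizes >= 1L),
            between_divergence >= 0, between_divergence <= 1,
            within_divergence >= 0, within_divergence <= 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  nacc <- sum(group_sizes)
  groups <- rep(names(group_sizes), group_sizes)
  acc_ids <- paste0(groups, "_", unlist(lapply(group_sizes, seq_len)))
  a1 <- matrix(NA_integer_, n_markers, nacc)
  a2 <- matrix(NA_integer_, n_markers, nacc)
  rdirichlet1 <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
  for (m in seq_len(n_markers)) {
    k <- sample(n_alleles[1]:n_alleles[2], 1L)
    anc <- rdirichlet1(k)
    gf <- lapply(names(group_sizes), function(gname) {
      if (stats::runif(1) < between_divergence) {
        fixed <- sample.int(k, 1L)
        f <- rep(0.05 / max(1L, k - 1L), k)
        f[fixed] <- 0.95
        f
      } else anc
    })
    names(gf) <- names(group_sizes)
    for (j in seq_len(nacc)) {
      f <- gf[[groups[j]]]
      if (within_divergence > 0) {
        f <- (1 - within_divergence) * f + within_divergence * rdirichlet1(k)
        f <- f / sum(f)
      }
      a1[m, j] <- sample.int(k, 1L, prob = f)
      a2[m, j] <- sample.int(k, 1L, prob = f)
    }
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_markers * nacc) < missing_rate, n_markers, nacc)
    a1[miss] <- NA_integer_
  }
  genotype_matrix(a1, a2,
                  marker_ids = sprintf("SIMM%04d", seq_len(n_markers)),
                  accession_ids = acc_ids, groups = groups)
}

#' Score planted-variant recovery of a pipeline run
#'
#' Compares the ILP markers recovered by the pipeline against the
#' simulator's truth. A target intron is one whose planted InDels have a
#' nonzero net length (balanced InDels cancel on a gel by construction); it
#' counts as recovered when an ILP marker targets it with `flp_net` equal to
#' the planted net size. A false positive is an ILP marker on an intron with
#' no planted InDel.
#'
#' @param sim A `sim_pair`.
#' @param ilp ILP marker data frame (from [design_ilp()]`$ilp` or
#'   [run_marker_pipeline()]).
#' @return List: `n_targets`, `n_recovered`, `recall_pct`,
#'   `n_false_positives`, `flp_exact_pct` (recovered markers whose flp_net
#'   matches truth exactly, out of ILP markers on target introns).
#' @export
evaluate_recovery <- function(sim, ilp) {
  truth <- sim$truth_introns
  targets <- truth[truth$net != 0, , drop = FALSE]
  key <- function(g, o) paste(g, o, sep = ":")
  tkey <- key(targets$gene_id, targets$intron_ordinal)
  ikey <- key(ilp$gene_id, ilp$intron_ordinal)
  net_by_target <- stats::setNames(abs(targets$net), tkey)
  hit <- ikey %in% tkey & ilp$flp_net == unname(net_by_target[ikey])
  recovered <- unique(ikey[which(hit)])
  planted_any <- key(truth$gene_id[truth$gross > 0], truth$intron_ordinal[truth$gross > 0])
  fp <- sum(!(ikey %in% planted_any))
  on_target <- ikey %in% tkey
  list(n_targets = nrow(targets),
       n_recovered = length(recovered),
       recall_pct = if (nrow(targets)) 100 * length(recovered) / nrow(targets) else NA_real_,
       n_false_positives = fp,
       flp_exact_pct = if (any(on_target)) 100 * sum(hit) / sum(on_target) else NA_real_)
}
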