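#' Read a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a named character vector of uppercase
#' DNA sequences. RNA-style `U` residues are mapped to `T`; any residue outside
#' `A,C,G,T,N,U` is rejected. Record identifiers are the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file (arbitrary line wrapping, any case).
#' @return Named character vector, one element per record; names are sequence
#'   identifiers, values uppercase DNA over `A,C,G,T,N`. An empty file returns
#'   an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) stop("empty record(s) in FASTA: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    res <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    stop("illegal residue(s) ", paste(res, collapse = ","), " in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  stats::setNames(unname(seqs), ids)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), filepath = path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model holds one transcript's exon structure in chromosome
#' coordinates. Coordinates are 0-based half-open internally; all emitted
#' tables use the 1-based inclusive GFF3 convention.
#'
#' @param gene_id Locus identifier.
#' @param seq_id Chromosome/contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of `[start, end)` exon intervals (0-based
#'   half-open), non-overlapping; they are sorted by start internally.
#' @param te_class `"TE"` or `"non-TE"`.
#' @param note Free-text functional annotation.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, te_class = "non-TE", note = "") {
  stopifnot(strand %in% c("+", "-"), te_class %in% c("TE", "non-TE"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene model needs >= 1 exon: ", gene_id)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon interval in gene: ", gene_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in gene: ", gene_id)
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, te_class = te_class, note = note),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s)  [%s]\n",
              x$gene_id, x$seq_id, x$exons[1L, 1L] + 1L, x$exons[nrow(x$exons), 2L],
              x$strand, nrow(x$exons), x$te_class))
  invisible(x)
}

.first_chr <- function(x) {
  vapply(x, function(v) if (length(v)) as.character(v)[1L] else NA_character_, character(1))
}

#' Parse gene models from a GFF3 annotation
#'
#' Reads a GFF3 file (gene/mRNA/exon features, optionally CDS) and assembles
#' one [gene_model] per gene. When a gene has several transcripts, the one
#' with the longest total CDS is selected (falling back to the longest total
#' exon length, then the lexicographically first transcript ID), collapsing
#' alternative splice forms to a single locus-level model. Transposable-
#' element association (`te_class`) is set when the gene's `Note` or `Name`
#' attribute contains "transposon" or "retrotransposon" (case-insensitive).
#'
#' Genes on sequences absent from `genome`, and genes whose exons exceed the
#' chromosome bounds, are skipped with a warning.
#'
#' @param gff3_path Path to a GFF3 file (1-based inclusive coordinates).
#' @param genome Named character vector as returned by [read_fasta()].
#' @return Named list of [gene_model] objects (names are gene IDs), in file
#'   order.
#' @export
parse_gene_models <- function(gff3_path, genome) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)  # 1-based inclusive
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent)) .first_chr(gr$Parent) else rep(NA_character_, length(gr))
  notes <- if (!is.null(gr$Note)) .first_chr(gr$Note) else rep(NA_character_, length(gr))
  nms <- if (!is.null(gr$Name)) as.character(gr$Name) else rep(NA_character_, length(gr))

  gene_rows <- which(type == "gene")
  mrna_rows <- which(type %in% c("mRNA", "transcript"))
  exon_rows <- which(type == "exon")
  cds_rows <- which(type == "CDS")

  exon_by_parent <- split(exon_rows, parents[exon_rows])
  cds_by_parent <- split(cds_rows, parents[cds_rows])
  mrna_by_parent <- split(mrna_rows, parents[mrna_rows])

  models <- list()
  for (g in gene_rows) {
    gid <- ids[g]
    if (is.na(gid)) stop("gene feature without ID attribute at line for ", seqid[g], ":", starts[g])
    if (!(seqid[g] %in% names(genome))) {
      warning("gene ", gid, " on unknown sequence ", seqid[g], "; skipped")
      next
    }
    mr <- mrna_by_parent[[gid]]
    if (is.null(mr) || !length(mr)) {
      warning("gene ", gid, " has no mRNA feature; skipped")
      next
    }
    # pick transcript: longest CDS, fallback longest exon span, then first ID
    mids <- ids[mr]
    cds_len <- vapply(mids, function(m) {
      rr <- cds_by_parent[[m]]
      if (is.null(rr)) 0L else sum(ends[rr] - starts[rr] + 1L)
    }, integer(1))
    exn_len <- vapply(mids, function(m) {
      rr <- exon_by_parent[[m]]
      if (is.null(rr)) 0L else sum(ends[rr] - starts[rr] + 1L)
    }, integer(1))
    ord <- order(-cds_len, -exn_len, mids)
    chosen <- mids[ord[1L]]
    ex <- exon_by_parent[[chosen]]
    if (is.null(ex) || !length(ex)) {
      warning("transcript ", chosen, " of gene ", gid, " has no exons; skipped")
      next
    }
    exm <- cbind(starts[ex] - 1L, ends[ex])  # to 0-based half-open
    if (any(exm[, 1L] < 0L) || any(exm[, 2L] > nchar(genome[[seqid[g]]]))) {
      warning("gene ", gid, " exceeds bounds of ", seqid[g], "; skipped")
      next
    }
    te <- if ((!is.na(notes[g]) && grepl("(retro)?transposon", notes[g], ignore.case = TRUE)) ||
              (!is.na(nms[g]) && grepl("(retro)?transposon", nms[g], ignore.case = TRUE)))
      "TE" else "non-TE"
    models[[gid]] <- gene_model(gid, seqid[g], strands[g], exm, te_class = te,
                                note = if (is.na(notes[g])) "" else notes[g])
  }
  models
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) .revcomp(x)

#' Extract introns and exonic flank windows from a gene model
#'
#' Intron *i* occupies the gap between consecutive exons. All reported
#' sequences (intron, flanks) read 5'->3' on the coding strand: for
#' minus-strand genes they are reverse-complemented and ordinals follow
#' transcription order. Flank windows are the up-to-`flank` exonic bases
#' immediately adjacent to the intron, never extending beyond the adjacent
#' exon. Zero-length gaps between exons are skipped with a warning.
#'
#' @param gene A [gene_model].
#' @param genome Named character vector containing `gene$seq_id`.
#' @param flank Maximum flank window size in bases (default 100).
#' @return A data frame with one row per intron: `gene_id`, `ordinal`,
#'   `seq_id`, `start`, `end` (0-based half-open chromosome coordinates),
#'   `strand`, `intron_len`, `sequence`, `left_flank`, `right_flank`,
#'   `has_n` (TRUE when the intron or a flank contains `N`).
#' @export
extract_introns <- function(gene, genome, flank = 100L) {
  stopifnot(inherits(gene, "gene_model"))
  chrom <- genome[[gene$seq_id]]
  if (is.null(chrom)) stop("sequence ", gene$seq_id, " not in genome")
  ex <- gene$exons
  n <- nrow(ex)
  empty <- data.frame(gene_id = character(0), ordinal = integer(0), seq_id = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      intron_len = integer(0), sequence = character(0),
                      left_flank = character(0), right_flank = character(0),
                      has_n = logical(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  rows <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    s <- ex[i, 2L]; e <- ex[i + 1L, 1L]
    if (e <= s) {
      warning("zero-length intron between exons ", i, " and ", i + 1L,
              " of gene ", gene$gene_id, "; skipped")
      next
    }
    iseq <- substr(chrom, s + 1L, e)
    lw <- min(flank, ex[i, 2L] - ex[i, 1L])
    rw <- min(flank, ex[i + 1L, 2L] - ex[i + 1L, 1L])
    lf <- substr(chrom, ex[i, 2L] - lw + 1L, ex[i, 2L])          # genome-left exon tail
    rf <- substr(chrom, ex[i + 1L, 1L] + 1L, ex[i + 1L, 1L] + rw) # genome-right exon head
    if (gene$strand == "+") {
      ordinal <- i
    } else {
      ordinal <- n - i
      iseq <- .revcomp(iseq)
      tmp <- .revcomp(rf); rf <- .revcomp(lf); lf <- tmp
    }
    rows[[i]] <- data.frame(gene_id = gene$gene_id, ordinal = ordinal,
                            seq_id = gene$seq_id, start = s, end = e,
                            strand = gene$strand, intron_len = e - s,
                            sequence = iseq, left_flank = lf, right_flank = rf,
                            has_n = grepl("N", paste0(iseq, lf, rf), fixed = TRUE),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract introns for a whole set of gene models
#'
#' @param models Named list of [gene_model] objects.
#' @inheritParams extract_introns
#' @return Row-bound data frame as from [extract_introns()].
#' @export
extract_all_introns <- function(models, genome, flank = 100L) {
  out <- do.call(rbind, lapply(models, extract_introns, genome = genome, flank = flank))
  rownames(out) <- NULL
  out
}

#' Write an intron table as TSV (1-based inclusive coordinates)
#'
#' @param introns Data frame from [extract_introns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_introns_tsv <- function(introns, path) {
  out <- data.frame(gene_id = introns$gene_id,
                    intron_ordinal = introns$ordinal,
                    seq_id = introns$seq_id,
                    start_1based = introns$start + 1L,
                    end_1based = introns$end,
                    strand = introns$strand,
                    intron_len = introns$intron_len,
                    left_flank_len = nchar(introns$left_flank),
                    right_flank_len = nchar(introns$right_flank),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
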